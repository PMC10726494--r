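# Genome sequences: FASTA IO, SNP-swapped strain genomes, CpG discovery.

#' Read a genome FASTA into a named character vector
#' @param path FASTA file.
#' @return Named character vector, one element per chromosome.
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write a named character vector of chromosome sequences as FASTA
#' @param genome named character vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  x <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Build a SNP-swapped strain genome
#'
#' Replaces, in the reference sequence, every position where the named
#' strain's allele differs from the reference allele. The reference base at
#' each variant position must equal `ref_allele` — a mismatch aborts, which
#' guards against off-by-one coordinate errors. Applying the function twice
#' with inverted variants restores the reference exactly.
#'
#' @param reference named character vector of chromosome sequences, or a
#'   single unnamed sequence (then variant `chrom` values are ignored).
#' @param variants a variant table (see [read_variant_table()]); may have
#'   zero rows.
#' @param strain name of the allele column to apply.
#' @return Sequences of the same shape as `reference`.
#' @export
swap_snps <- function(reference, variants, strain) {
  validate_variant_table(variants)
  if (!strain %in% variant_table_strains(variants))
    fail("strain '%s' not in variant table", strain)
  single <- is.null(names(reference)) && length(reference) == 1L
  if (single) names(reference) <- "."
  out <- reference
  for (chrom in names(reference)) {
    v <- if (single) variants else variants[variants$chrom == chrom, , drop = FALSE]
    if (!nrow(v)) next
    if (any(v$pos < 1L | v$pos > nchar(reference[[chrom]])))
      fail("variant position outside sequence '%s'", chrom)
    r <- charToRaw(reference[[chrom]])
    have <- rawToChar(r[v$pos], multiple = TRUE)
    bad <- which(toupper(have) != v$ref_allele)
    if (length(bad))
      fail("ref_allele mismatch at %s:%d (sequence has %s, table says %s)",
           chrom, v$pos[bad[1]], have[bad[1]], v$ref_allele[bad[1]])
    diff <- v[[strain]] != v$ref_allele
    if (any(diff))
      r[v$pos[diff]] <- charToRaw(paste(v[[strain]][diff], collapse = ""))
    out[[chrom]] <- rawToChar(r)
  }
  if (single) names(out) <- NULL
  out
}

# Forward-strand C positions of CG dinucleotides in one sequence.
scan_cpg <- function(seq) {
  m <- gregexpr("CG", seq, fixed = TRUE)[[1]]
  if (m[1] == -1L) integer() else as.integer(m)
}

# 5-bp reference context around each position, N-padded at chromosome ends.
context5 <- function(seq, pos) {
  if (!length(pos)) return(character())
  padded <- paste0("NN", seq, "NN")
  substring(padded, pos, pos + 4L)
}

#' Find CpG sites per strain with 5-bp reference contexts
#'
#' Scans the forward strand of the reference (and, when variants are given,
#' of each strain's SNP-swapped sequence) for CG dinucleotides, reporting the
#' 1-based position of the C. Each site carries the 5-bp context of the
#' *reference* sequence centered on the C, padded with `N` at chromosome
#' ends (never silently dropped). Strain-specific gains and losses relative
#' to the reference are flagged in the `status` column.
#'
#' @param genome named character vector of chromosome sequences (a single
#'   unnamed sequence is also accepted).
#' @param variants optional variant table; its strain columns define the
#'   strains scanned.
#' @return data.frame with columns `chrom`, `pos`, `strain`, `context`,
#'   `status` (`"shared"`, `"gained"`, or `"lost"`); `strain = "reference"`
#'   rows give the reference CpG set. Lost rows flag reference CpGs absent
#'   from a strain and are not part of that strain's set.
#' @export
find_cpg_sites <- function(genome, variants = NULL) {
  single <- is.null(names(genome)) && length(genome) == 1L
  if (single) names(genome) <- "."
  strains <- if (is.null(variants)) character() else variant_table_strains(variants)
  res <- list()
  for (chrom in names(genome)) {
    refseq <- toupper(genome[[chrom]])
    ref_pos <- scan_cpg(refseq)
    res[[length(res) + 1L]] <- data.frame(
      chrom = rep(chrom, length(ref_pos)), pos = ref_pos,
      strain = rep("reference", length(ref_pos)),
      context = context5(refseq, ref_pos),
      status = rep("shared", length(ref_pos)), stringsAsFactors = FALSE)
    for (s in strains) {
      sseq <- if (single) swap_snps(unname(refseq), variants, s)
              else swap_snps(genome, variants, s)[[chrom]]
      s_pos <- scan_cpg(toupper(sseq))
      gained <- setdiff(s_pos, ref_pos)
      lost <- setdiff(ref_pos, s_pos)
      pos <- c(s_pos, lost)
      status <- c(ifelse(s_pos %in% ref_pos, "shared", "gained"),
                  rep("lost", length(lost)))
      o <- order(pos)
      res[[length(res) + 1L]] <- data.frame(
        chrom = rep(chrom, length(pos)), pos = pos[o],
        strain = rep(s, length(pos)), context = context5(refseq, pos[o]),
        status = status[o], stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  if (single) out$chrom <- NULL
  out
}
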