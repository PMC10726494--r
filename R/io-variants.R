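# Strain variant tables: chrom, pos (1-based), ref_allele, one allele column
# per strain. Accepts a simple TSV dialect or VCF (SNVs only).

#' Strain names carried by a variant table
#' @param x a variant table.
#' @return Character vector of strain (allele-column) names.
#' @export
variant_table_strains <- function(x) {
  setdiff(names(x), c("chrom", "pos", "ref_allele"))
}

#' Validate a strain variant table
#'
#' Requires single-nucleotide alleles in `{A,C,G,T}`, `pos >= 1`, and that
#' the reference allele differs from at least one strain allele in every row.
#'
#' @param x data.frame with columns chrom, pos, ref_allele and one column per
#'   strain.
#' @return `x`, invisibly.
#' @export
validate_variant_table <- function(x) {
  need <- c("chrom", "pos", "ref_allele")
  miss <- setdiff(need, names(x))
  if (length(miss)) fail("variant table lacks column(s): %s", paste(miss, collapse = ", "))
  strains <- variant_table_strains(x)
  if (!length(strains)) fail("variant table has no strain allele columns")
  if (nrow(x) == 0L) return(invisible(x))
  nt <- c("A", "C", "G", "T")
  for (col in c("ref_allele", strains)) {
    bad <- which(!x[[col]] %in% nt)
    if (length(bad))
      fail("non-SNV or invalid allele in column %s at row(s) %s", col,
           paste(head(bad, 5L), collapse = ", "))
  }
  same <- rep(TRUE, nrow(x))
  for (s in strains) same <- same & x[[s]] == x$ref_allele
  if (any(same))
    fail("row(s) %s have no strain allele differing from ref_allele",
         paste(head(which(same), 5L), collapse = ", "))
  invisible(x)
}

#' Read a strain variant table (TSV dialect or VCF)
#'
#' TSV files need a header `chrom  pos  ref_allele  <strain> ...`. VCF v4.x
#' files (uncompressed or bgzipped) are parsed with each sample's genotype
#' resolved to a single allele; non-SNV records and half-calls are skipped and
#' their count reported via the `"skipped"` attribute.
#'
#' @param path path to a `.tsv`/`.txt` or `.vcf` file.
#' @return A validated variant table; attribute `skipped` counts rejected
#'   VCF records.
#' @export
read_variant_table <- function(path) {
  if (grepl("\\.vcf(\\.gz|\\.bgz)?$", path, ignore.case = TRUE)) {
    x <- read_variants_vcf(path)
  } else {
    x <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
    x$chrom <- as.character(x$chrom)
    attr(x, "skipped") <- 0L
  }
  validate_variant_table(x)
  x
}

# Minimal VCF SNV parser: genotype columns -> single allele per strain.
read_variants_vcf <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^##", lines)]
  hdr <- lines[grepl("^#CHROM", lines)]
  if (!length(hdr)) fail("%s: no #CHROM header line", path)
  fields <- strsplit(sub("^#", "", hdr), "\t")[[1]]
  samples <- fields[-(1:9)]
  if (!length(samples)) fail("%s: VCF has no sample columns", path)
  body <- lines[!grepl("^#", lines)]
  skipped <- 0L
  rows <- vector("list", length(body))
  for (i in seq_along(body)) {
    f <- strsplit(body[i], "\t")[[1]]
    ref <- f[4]; alts <- strsplit(f[5], ",")[[1]]
    alleles <- c(ref, alts)
    if (any(nchar(alleles) != 1L) || !all(alleles %in% c("A", "C", "G", "T"))) {
      skipped <- skipped + 1L
      next
    }
    gts <- sub(":.*", "", f[-(1:9)])
    a1 <- sub("[/|].*", "", gts)
    if (any(a1 == "." | a1 == "")) { skipped <- skipped + 1L; next }
    rows[[i]] <- c(f[1], f[2], ref, alleles[as.integer(a1) + 1L])
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  if (!nrow(out)) {
    out <- data.frame(chrom = character(), pos = integer(),
                      ref_allele = character(), stringsAsFactors = FALSE)
    for (s in samples) out[[s]] <- character()
  } else {
    names(out) <- c("chrom", "pos", "ref_allele", samples)
    out$pos <- as.integer(out$pos)
  }
  attr(out, "skipped") <- skipped
  out
}

#' Write a strain variant table as TSV
#' @param x variant table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(x, path) {
  validate_variant_table(x)
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
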