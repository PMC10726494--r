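# Gene models, chromatin-state tracks, and differential-expression tables.
# Intervals are 0-based half-open throughout (BED/refGene convention).

#' The fixed 15 chromatin state group vocabulary
#'
#' State groups of the universal mouse chromatin-state annotation used for
#' the state-stratified mutation scan. The "artifacts" state is not part of
#' the vocabulary and is dropped on read.
#'
#' @return Character vector of 15 state-group names.
#' @export
chromatin_state_groups <- function() {
  c("Active enhancers", "Bivalent promoters", "DNAase open chromatin",
    "Heterochromatin", "Polycomb repressed",
    "Polycomb repressed and open chromatin", "Promoter flank", "Quiescent",
    "Transcribed enhancers", "Transcription", "Transcription and exons",
    "Transcription start sites", "Weak enhancers", "Weak transcription",
    "Zinc finger genes")
}

#' Read gene models
#'
#' Accepts either a refGene-style flat file (tab-separated, no header, with
#' columns bin, name, chrom, strand, txStart, txEnd, ...) or a GTF/GFF file
#' (parsed with rtracklayer; `gene` features, or all features collapsed by
#' `gene_id` when no `gene` rows exist).
#'
#' @param path path to a refGene flat file (`.txt`/`.tsv`) or `.gtf`/`.gff`.
#' @return data.frame with columns `gene`, `chrom`, `strand`, `txStart`,
#'   `txEnd` (0-based half-open, `txStart < txEnd`).
#' @export
read_gene_models <- function(path) {
  if (grepl("\\.g[tf]f[23]?(\\.gz)?$", path, ignore.case = TRUE)) {
    gr <- rtracklayer::import(path)
    meta <- S4Vectors::mcols(gr)
    if ("type" %in% names(meta) && any(meta$type == "gene"))
      gr <- gr[meta$type == "gene"]
    ids <- S4Vectors::mcols(gr)$gene_id
    if (is.null(ids)) ids <- S4Vectors::mcols(gr)$ID
    if (is.null(ids)) fail("%s: no gene_id attribute found", path)
    out <- data.frame(gene = as.character(ids),
                      chrom = as.character(GenomicRanges::seqnames(gr)),
                      strand = as.character(GenomicRanges::strand(gr)),
                      txStart = GenomicRanges::start(gr) - 1L,
                      txEnd = GenomicRanges::end(gr),
                      stringsAsFactors = FALSE)
    out$strand[!out$strand %in% c("+", "-")] <- "+"
    # collapse transcripts of the same gene to the union span
    if (anyDuplicated(out$gene)) {
      out <- do.call(rbind, lapply(split(out, out$gene), function(g) {
        g$txStart <- min(g$txStart); g$txEnd <- max(g$txEnd); g[1L, ]
      }))
      rownames(out) <- NULL
    }
  } else {
    x <- read.delim(path, header = FALSE, sep = "\t", stringsAsFactors = FALSE)
    if (ncol(x) < 6L) fail("%s: refGene flat file needs >= 6 columns", path)
    out <- data.frame(gene = as.character(x[[2]]), chrom = as.character(x[[3]]),
                      strand = as.character(x[[4]]),
                      txStart = as.integer(x[[5]]), txEnd = as.integer(x[[6]]),
                      stringsAsFactors = FALSE)
  }
  bad <- which(!(out$txStart < out$txEnd))
  if (length(bad)) fail("%s: txStart >= txEnd at row(s) %s", path,
                        paste(head(bad, 5L), collapse = ", "))
  out
}

#' Read a chromatin-state track (BED4)
#'
#' The name column must carry one of the 15 state-group labels of
#' [chromatin_state_groups()]; intervals labeled `artifacts` are removed
#' (count kept in the `"dropped_artifacts"` attribute) and any other label is
#' an error.
#'
#' @param path BED4 file (chrom, start, end, state).
#' @return data.frame with columns `chrom`, `start`, `end`, `state`
#'   (0-based half-open).
#' @export
read_chromatin_states <- function(path) {
  x <- read.delim(path, header = FALSE, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(x) < 4L) fail("%s: BED4 needs 4 columns", path)
  out <- data.frame(chrom = as.character(x[[1]]), start = as.integer(x[[2]]),
                    end = as.integer(x[[3]]), state = as.character(x[[4]]),
                    stringsAsFactors = FALSE)
  art <- tolower(out$state) == "artifacts"
  out <- out[!art, , drop = FALSE]
  bad <- which(!out$state %in% chromatin_state_groups())
  if (length(bad))
    fail("%s: state label(s) outside the 15-group vocabulary at row(s) %s",
         path, paste(head(bad, 5L), collapse = ", "))
  rownames(out) <- NULL
  attr(out, "dropped_artifacts") <- sum(art)
  out
}

#' Write a chromatin-state track or segment set as BED
#'
#' @param x data.frame with chrom/start/end plus either a `state` column
#'   (written as BED4) or a `density` column (BED6 with density in the score
#'   column).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  if (!is.null(x$state)) {
    out <- x[, c("chrom", "start", "end", "state")]
  } else if (!is.null(x$density)) {
    out <- data.frame(x$chrom, x$start, x$end,
                      name = sprintf("seg%06d", seq_len(nrow(x))),
                      score = x$density, strand = ".")
  } else fail("need a 'state' or 'density' column")
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a differential-expression result table
#'
#' DESeq2-style CSV with at least `gene`, `log2FoldChange`, `pvalue` columns
#' (an unnamed first column is taken as the gene id, as in
#' `write.csv(results(dds))` output). One row per gene; p-values in (0, 1].
#'
#' @param path CSV file.
#' @return data.frame with columns `gene`, `log2FoldChange`, `pvalue` (plus
#'   any extra columns present).
#' @export
read_de_results <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"gene" %in% names(x)) {
    names(x)[1] <- "gene"
  }
  need <- c("gene", "log2FoldChange", "pvalue")
  miss <- setdiff(need, names(x))
  if (length(miss)) fail("%s: missing column(s) %s", path, paste(miss, collapse = ", "))
  if (anyDuplicated(x$gene)) fail("%s: duplicated gene ids", path)
  ok <- is.na(x$pvalue) | (x$pvalue > 0 & x$pvalue <= 1)
  if (!all(ok)) fail("%s: p-values outside (0, 1] at row(s) %s", path,
                     paste(head(which(!ok), 5L), collapse = ", "))
  x
}

#' Write a differential-expression result table as CSV
#' @param x DE table with `gene`, `log2FoldChange`, `pvalue`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_de_results <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
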