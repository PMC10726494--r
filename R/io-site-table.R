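# Per-site methylation count tables (allc-style, one row per cytosine).
#
# A site table is a data.frame with columns
#   chrom, pos (1-based position of the C), strand ("+"/"-"), context
#   ("CG"/"CH"), then <strain>.mc and <strain>.cov for each strain.
# Coordinates follow the allc convention (1-based); interval annotations
# elsewhere in the package are 0-based half-open.

#' Strain names carried by a methylation site table
#'
#' @param x a site table as returned by [read_site_table()] or
#'   [generate_strain_methylomes()].
#' @return Character vector of strain names.
#' @export
site_table_strains <- function(x) {
  nm <- names(x)
  sub("\\.mc$", "", nm[grepl("\\.mc$", nm)])
}

#' Validate a methylation site table
#'
#' Checks the invariants of the format: required columns, `pos >= 1`,
#' context codes in `{CG, CH}`, counts non-negative integers with
#' `mc <= cov` for every strain. Violations are reported with the offending
#' (1-based, header excluded) row numbers.
#'
#' @param x data.frame to validate.
#' @return `x`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_site_table <- function(x) {
  need <- c("chrom", "pos", "strand", "context")
  miss <- setdiff(need, names(x))
  if (length(miss)) fail("site table lacks column(s): %s", paste(miss, collapse = ", "))
  strains <- site_table_strains(x)
  if (!length(strains)) fail("site table has no <strain>.mc columns")
  covmiss <- strains[!paste0(strains, ".cov") %in% names(x)]
  if (length(covmiss)) fail("missing .cov column for strain(s): %s",
                            paste(covmiss, collapse = ", "))
  if (nrow(x) == 0L) return(invisible(x))
  bad <- which(!is.finite(x$pos) | x$pos < 1 | x$pos != floor(x$pos))
  if (length(bad)) fail("invalid pos at row(s) %s", paste(head(bad, 5L), collapse = ", "))
  bad <- which(!x$context %in% c("CG", "CH"))
  if (length(bad)) fail("unknown context code at row(s) %s (allowed: CG, CH)",
                        paste(head(bad, 5L), collapse = ", "))
  bad <- which(!x$strand %in% c("+", "-"))
  if (length(bad)) fail("invalid strand at row(s) %s", paste(head(bad, 5L), collapse = ", "))
  for (s in strains) {
    mc <- x[[paste0(s, ".mc")]]
    cov <- x[[paste0(s, ".cov")]]
    if (!is_count(mc) || !is_count(cov))
      fail("counts for strain %s must be non-negative integers", s)
    bad <- which(mc > cov)
    if (length(bad))
      fail("mc > cov for strain %s at row(s) %s", s,
           paste(head(bad, 5L), collapse = ", "))
  }
  invisible(x)
}

#' Read a methylation site table from TSV
#'
#' The file dialect has a header row naming the columns (`chrom`, `pos`,
#' `strand`, `context`, then `<strain>.mc`/`<strain>.cov` pairs) and one row
#' per cytosine. Rows violating the invariants (e.g. `mc > cov`) abort the
#' read with the offending line number; a header-only file yields an empty
#' table. Row order is preserved.
#'
#' @param path path to a tab-separated file.
#' @return A validated site table data.frame.
#' @seealso [write_site_table()] for the byte-stable inverse.
#' @export
read_site_table <- function(path) {
  x <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                  check.names = FALSE)
  x$chrom <- as.character(x$chrom)
  tryCatch(validate_site_table(x), error = function(e) {
    fail("%s: %s (row numbers exclude the header line)", path, conditionMessage(e))
  })
  x
}

#' Write a methylation site table to TSV
#'
#' Inverse of [read_site_table()]; a read/write round trip of a
#' canonical-dialect file is byte-stable.
#'
#' @param x site table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_site_table <- function(x, path) {
  validate_site_table(x)
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Collapse the two strands of symmetric CpGs
#'
#' A CpG is symmetric across strands; reads can be reported on either. This
#' utility merges "-"-strand CG rows into their "+"-strand partner (the C of
#' the forward-strand CG, at `pos - 1`), summing counts per strain. Rows
#' without a partner are re-keyed to the forward C position. Non-CG rows are
#' returned untouched. Readers never collapse implicitly: input strands are
#' preserved unless this function is called.
#'
#' @param x site table.
#' @return A site table keyed by forward-strand C positions, strand `"+"`.
#' @export
collapse_strands <- function(x) {
  validate_site_table(x)
  cg <- x$context == "CG"
  if (!any(cg)) return(x)
  y <- x[cg, , drop = FALSE]
  rest <- x[!cg, , drop = FALSE]
  key_pos <- ifelse(y$strand == "-", y$pos - 1L, y$pos)
  key <- paste(y$chrom, key_pos)
  strains <- site_table_strains(x)
  first <- !duplicated(key)
  out <- y[first, , drop = FALSE]
  out$pos <- key_pos[first]
  out$strand <- "+"
  idx <- match(key, key[first])
  for (s in strains) {
    for (suf in c(".mc", ".cov")) {
      col <- paste0(s, suf)
      out[[col]] <- as.integer(rowsum(y[[col]], idx)[, 1L])
    }
  }
  out <- rbind(out, rest)
  out <- out[order(match(out$chrom, unique(x$chrom)), out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}
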