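# Single-nucleus methylation cell quality control.

#' Filter single-nucleus methylation cells on QC metrics
#'
#' Keeps exactly the cells satisfying all six thresholds (strict
#' inequalities): mCCC level below `mccc_max`, global mCG above `mcg_min`,
#' global mCH below `mch_max`, mapped reads above `reads_min`, mapping rate
#' above `maprate_min`, and percent of genome covered above `coverage_min`.
#' mCCC (methylation at CCC trinucleotides) proxies bisulfite
#' non-conversion. Records with a missing metric are rejected with reason
#' `"incomplete"` and counted separately from threshold failures.
#'
#' @param records data.frame with columns `cell`, `mccc`, `mcg`, `mch`,
#'   `mapped_reads`, `mapping_rate`, `genome_coverage_pct`.
#' @param mccc_max,mcg_min,mch_max,reads_min,maprate_min,coverage_min the six
#'   thresholds; defaults are the standard snmC-seq cutoffs.
#' @return The passing records. Attribute `rejected` is a data.frame of the
#'   removed cells with a `reason` column (comma-joined failing metrics, or
#'   `"incomplete"`); attribute `summary` counts passed / failed_qc /
#'   incomplete.
#' @export
cell_qc_filter <- function(records, mccc_max = 0.03, mcg_min = 0.5,
                           mch_max = 0.2, reads_min = 1e5,
                           maprate_min = 0.5, coverage_min = 2) {
  need <- c("cell", "mccc", "mcg", "mch", "mapped_reads", "mapping_rate",
            "genome_coverage_pct")
  miss <- setdiff(need, names(records))
  if (length(miss)) fail("QC records lack column(s): %s", paste(miss, collapse = ", "))
  metrics <- need[-1]
  frac <- c("mccc", "mcg", "mch", "mapping_rate")
  for (m in frac) {
    bad <- which(!is.na(records[[m]]) & (records[[m]] < 0 | records[[m]] > 1))
    if (length(bad)) fail("%s outside [0,1] at row(s) %s", m,
                          paste(head(bad, 5L), collapse = ", "))
  }
  incomplete <- !complete.cases(records[metrics])
  checks <- cbind(
    mccc = records$mccc < mccc_max,
    mcg = records$mcg > mcg_min,
    mch = records$mch < mch_max,
    mapped_reads = records$mapped_reads > reads_min,
    mapping_rate = records$mapping_rate > maprate_min,
    genome_coverage_pct = records$genome_coverage_pct > coverage_min)
  pass <- !incomplete & rowSums(checks) == ncol(checks)
  reason <- character(nrow(records))
  reason[incomplete] <- "incomplete"
  failed <- which(!pass & !incomplete)
  for (i in failed)
    reason[i] <- paste(colnames(checks)[!checks[i, ]], collapse = ",")
  out <- records[pass, , drop = FALSE]
  rownames(out) <- NULL
  rej <- records[!pass, , drop = FALSE]
  rej$reason <- reason[!pass]
  rownames(rej) <- NULL
  attr(out, "rejected") <- rej
  attr(out, "summary") <- c(passed = sum(pass),
                            failed_qc = sum(!pass & !incomplete),
                            incomplete = sum(incomplete))
  out
}
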