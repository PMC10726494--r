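# Pairwise cross-strain conservation: same-state probability vs. the ratio
# of methylated-site counts, per segment and pooled by CpG density.

#' Proportions of matching methylation states between two call vectors
#'
#' For two equal-length binary vectors (no-call sites must be removed
#' beforehand), computes the marginal proportions of 1s (`p`) and 0s (`q`)
#' in each vector and the joint proportions of positions where both are 1
#' (`prop_pp`) or both are 0 (`prop_qq`). The same-state probability is
#' `prop_pp + prop_qq`: 1 means the methylation state of every site in one
#' strain is fully predictable from the other. Symmetric in its arguments
#' for `prop_pp`, `prop_qq` and `same_state`.
#'
#' @param a,b binary (0/1) vectors of equal length >= 1.
#' @return Named numeric vector: `prop_p_1`, `prop_p_2`, `prop_q_1`,
#'   `prop_q_2`, `prop_pp`, `prop_qq`, `same_state`.
#' @export
prop_occurrence <- function(a, b) {
  if (length(a) != length(b)) fail("call vectors differ in length")
  if (!length(a)) fail("empty call vectors")
  if (anyNA(a) || anyNA(b)) fail("remove no-call (NA) sites before calling prop_occurrence")
  a <- as.integer(a != 0); b <- as.integer(b != 0)
  n <- length(a)
  pp <- sum(a == 1L & b == 1L) / n
  qq <- sum(a == 0L & b == 0L) / n
  c(prop_p_1 = sum(a) / n, prop_p_2 = sum(b) / n,
    prop_q_1 = 1 - sum(a) / n, prop_q_2 = 1 - sum(b) / n,
    prop_pp = pp, prop_qq = qq, same_state = pp + qq)
}

#' Ratio of methylated-site counts between two strains
#'
#' The larger count is the denominator, so the ratio is bounded in `[0, 1]`;
#' 1 means the two strains methylate the same *number* of sites (not
#' necessarily the same sites). Undefined (NA) when both counts are zero;
#' such segments are excluded from pooled ratios.
#'
#' @param n1,n2 non-negative methylated-site counts (vectorized).
#' @return `min/max` per element, NA where both are zero.
#' @export
methylated_count_ratio <- function(n1, n2) {
  if (any(n1 < 0 | n2 < 0, na.rm = TRUE)) fail("negative counts")
  ifelse(n1 == 0 & n2 == 0, NA_real_, pmin(n1, n2) / pmax(n1, n2))
}

#' Per-segment conservation statistics for one strain pair
#'
#' For every segment: restricts to sites callable in both strains (a no-call
#' in one strain of the pair drops the site for this pair only), applies
#' per-segment coverage downsampling (optional, default on), and computes
#' [prop_occurrence()] and [methylated_count_ratio()]. Segments with no
#' jointly callable site are omitted.
#'
#' @param profiles profile table from [segment_profiles()].
#' @param s1,s2 strain names.
#' @param downsample apply [downsample_pair()] first (default TRUE).
#' @param seed seed for the downsampling.
#' @return data.frame with `seg_id`, `density`, `bin`, `n_sites`, `n1`,
#'   `n2`, `prop_pp`, `prop_qq`, `same_state`, `ratio`.
#' @export
pairwise_segment_stats <- function(profiles, s1, s2, downsample = TRUE,
                                   seed = NULL) {
  if (downsample) profiles <- downsample_pair(profiles, s1, s2, seed = seed)
  c1 <- profiles[[paste0(s1, ".call")]]
  c2 <- profiles[[paste0(s2, ".call")]]
  if (is.null(c1) || is.null(c2)) fail("missing call columns for the pair")
  keep <- !is.na(c1) & !is.na(c2)
  seg <- factor(profiles$seg_id[keep])
  c1 <- c1[keep]; c2 <- c2[keep]
  n <- as.vector(table(seg))
  agg <- function(v) rowsum(as.numeric(v), seg)[, 1L]
  n1 <- agg(c1); n2 <- agg(c2)
  pp <- agg(c1 == 1L & c2 == 1L); qq <- agg(c1 == 0L & c2 == 0L)
  ids <- as.integer(levels(seg))
  i <- match(ids, profiles$seg_id)
  out <- data.frame(seg_id = ids, density = profiles$density[i],
                    bin = profiles$bin[i], n_sites = n,
                    n1 = as.integer(n1), n2 = as.integer(n2),
                    prop_pp = pp / n, prop_qq = qq / n,
                    same_state = (pp + qq) / n,
                    ratio = methylated_count_ratio(n1, n2))
  rownames(out) <- NULL
  out
}

#' Pool conservation statistics by CpG density bin
#'
#' Recomputes the same-state probability on the *concatenation* of all
#' member segments' jointly-callable site vectors in each density bin
#' (pooled, not averaged), and the count ratio from the bin totals
#' `min(sum n1, sum n2) / max(sum n1, sum n2)`. Output columns mirror the
#' per-density summary vocabulary: `seg` (the density bin), `s1`, `s2`,
#' `CG.all`, `CG.me.0`, `CG.me.1` (counts by the first strain's call),
#' `mutant.me.0`, `mutant.me.1` (mutated-site counts versus the outgroup,
#' when variants are supplied), `prob`, `ratio`, `s1.me`, `s2.me`.
#'
#' @param profiles profile table from [segment_profiles()].
#' @param s1,s2 strain names.
#' @param downsample,seed see [pairwise_segment_stats()].
#' @param variants,outgroup optional variant table and outgroup strain for
#'   the mutant-site counts (NA columns when absent).
#' @return data.frame, one row per density bin with jointly callable sites;
#'   `prop_pp` and `prop_qq` are included so either convention for the
#'   plotted "probability" can be recovered.
#' @export
aggregate_by_density <- function(profiles, s1, s2, downsample = TRUE,
                                 seed = NULL, variants = NULL,
                                 outgroup = NULL) {
  if (downsample) {
    profiles <- downsample_pair(profiles, s1, s2, seed = seed)
    downsample <- FALSE
  }
  c1 <- profiles[[paste0(s1, ".call")]]
  c2 <- profiles[[paste0(s2, ".call")]]
  keep <- !is.na(c1) & !is.na(c2)
  mut <- if (!is.null(variants)) {
    if (is.null(outgroup)) fail("outgroup required with variants")
    cpg_mutation_flags(profiles, variants, s1, outgroup)$mutated
  } else rep(NA, nrow(profiles))
  b <- factor(profiles$bin[keep])
  c1 <- c1[keep]; c2 <- c2[keep]; mut <- mut[keep]
  n <- as.vector(table(b))
  agg <- function(v) rowsum(as.numeric(v), b)[, 1L]
  n1 <- agg(c1); n2 <- agg(c2)
  pp <- agg(c1 == 1L & c2 == 1L); qq <- agg(c1 == 0L & c2 == 0L)
  out <- data.frame(seg = as.numeric(levels(b)), s1 = s1, s2 = s2,
                    CG.all = n,
                    CG.me.0 = as.integer(n - n1),
                    CG.me.1 = as.integer(n1),
                    mutant.me.0 = as.integer(agg(!is.na(mut) & mut & c1 == 0L)),
                    mutant.me.1 = as.integer(agg(!is.na(mut) & mut & c1 == 1L)),
                    prob = (pp + qq) / n,
                    ratio = methylated_count_ratio(n1, n2),
                    s1.me = as.integer(n1), s2.me = as.integer(n2),
                    prop_pp = pp / n, prop_qq = qq / n,
                    stringsAsFactors = FALSE)
  if (is.null(variants)) out$mutant.me.0 <- out$mutant.me.1 <- NA_integer_
  out <- out[order(out$seg), , drop = FALSE]
  rownames(out) <- NULL
  out
}
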