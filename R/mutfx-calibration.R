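# Permutation calibration of the interaction test and sensitivity sweeps
# over the density threshold and the transcript filters.

#' Permutation calibration of the interaction test
#'
#' Re-assigns expression values among genes (each gene receives the log2
#' fold change of another gene, so all sites of a gene move as a block while
#' mutation and density labels stay put), recomputes the interaction F
#' statistic for every permutation, and reports the empirical p-value of
#' the observed statistic with the add-one convention `(b + 1) / (n + 1)`
#' (never exactly zero). The nominal parametric p-values across
#' permutations are returned with a Kolmogorov-Smirnov uniformity
#' diagnostic: if the model is calibrated they are uniform on (0, 1).
#'
#' @param table site-level analysis table.
#' @param n_perm number of permutations (>= 1).
#' @param seed integer seed for the permutation stream.
#' @inheritParams interaction_anova
#' @return List of class `cpgdm_perm`: `observed` (F, parametric p,
#'   estimate), `perm_F`, `perm_p` (nominal p per permutation),
#'   `p_empirical`, `ks_stat`, `ks_p`, `n_perm`, `seed`.
#' @export
permutation_calibration <- function(table, n_perm = 10000, seed = 1L,
                                    unit = c("gene", "site"),
                                    covariates = c("chromosome", "position",
                                                   "annotation")) {
  if (!is.numeric(n_perm) || n_perm < 1L) fail("n_perm must be >= 1")
  unit <- match.arg(unit)
  d <- interaction_design(table, unit, covariates)
  q0 <- qr(d$X0); q1 <- qr(d$X1)
  if (q1$rank <= q0$rank) fail("degenerate design: interaction collinear")
  obs <- nested_f(q0, q1, d$y)
  beta <- qr.coef(q1, d$y)
  if (unit == "gene") {
    gene_z <- d$y                       # one row per gene already
    expand <- seq_along(d$y)
  } else {
    g <- factor(table$gene)
    first <- !duplicated(g)
    gene_z <- invnorm(table$log2fc[first][order(g[first])])
    expand <- as.integer(g)
  }
  # permuting raw values then transforming equals permuting the transform
  Z <- with_seed(seed, {
    vapply(seq_len(n_perm),
           function(i) gene_z[sample(length(gene_z))][expand],
           numeric(length(d$y)))
  })
  perm <- nested_f(q0, q1, Z)
  ks <- suppressWarnings(ks.test(perm$p, "punif"))
  structure(list(
    observed = list(F = obs$F, p = obs$p, estimate = unname(beta[d$term])),
    perm_F = perm$F, perm_p = perm$p,
    p_empirical = (sum(perm$F >= obs$F) + 1) / (n_perm + 1),
    ks_stat = unname(ks$statistic), ks_p = ks$p.value,
    n_perm = n_perm, seed = seed, unit = unit),
    class = "cpgdm_perm")
}

#' @export
print.cpgdm_perm <- function(x, ...) {
  cat(sprintf(
    "Permutation calibration (%d permutations, %s unit, seed %d)\nobserved F = %.3f (parametric p = %.3g), empirical p = %.3g\nKS uniformity of nominal p-values: D = %.4f, p = %.3g\n",
    x$n_perm, x$unit, x$seed, x$observed$F, x$observed$p, x$p_empirical,
    x$ks_stat, x$ks_p))
  invisible(x)
}

#' Sweep the high/low density threshold
#'
#' Reclassifies sites as high/low at each candidate threshold, refits the
#' interaction model, and records the interaction effect estimate, F and p.
#' Thresholds that empty one class or leave the interaction inestimable are
#' flagged rather than dropped. Because every candidate above the true
#' change point carries the full effect, the *estimate* plateaus beyond it
#' while the F statistic peaks at it; [sweep_change_point()] therefore
#' locates the change point at the F maximum.
#'
#' @param table site-level analysis table.
#' @param thresholds integer densities to test (default 14:60).
#' @inheritParams interaction_anova
#' @return data.frame: `threshold`, `estimate`, `F`, `p`, `n_high_sites`,
#'   `n_high_mut`, `estimable`.
#' @export
sweep_density_threshold <- function(table, thresholds = 14:60,
                                    unit = c("gene", "site"),
                                    covariates = c("chromosome", "position",
                                                   "annotation")) {
  unit <- match.arg(unit)
  gt <- if (unit == "gene") aggregate_by_gene(table) else NULL
  g <- if (unit == "gene") factor(table$gene, levels = gt$gene) else NULL
  rows <- lapply(thresholds, function(th) {
    high <- table$density > th
    res <- if (unit == "gene") {
      # only the high-density mutation count depends on the threshold
      gt$n_mut_high <- as.integer(
        rowsum(as.numeric(table$mutation * high), g)[, 1L])
      tryCatch(interaction_anova(gt, "gene", covariates),
               error = function(e) NULL)
    } else {
      tab <- table
      tab$class <- classify_density(tab$density, th)
      tab$high <- as.integer(high)
      tryCatch(interaction_anova(tab, "site", covariates),
               error = function(e) NULL)
    }
    data.frame(threshold = th,
               estimate = if (is.null(res)) NA_real_ else res$estimate,
               F = if (is.null(res)) NA_real_ else res$F,
               p = if (is.null(res)) NA_real_ else res$p,
               n_high_sites = sum(high),
               n_high_mut = sum(table$mutation[high]),
               estimable = !is.null(res))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Change-point estimate from a density-threshold sweep
#'
#' @param sweep output of [sweep_density_threshold()].
#' @return The estimable threshold with the largest interaction F
#'   statistic (NA if none is estimable).
#' @export
sweep_change_point <- function(sweep) {
  ok <- sweep$estimable & !is.na(sweep$F)
  if (!any(ok)) return(NA_real_)
  sweep$threshold[ok][which.max(sweep$F[ok])]
}

#' Sweep the transcript-inclusion filters
#'
#' For each log2 fold-change cutoff, retains genes whose absolute log2 fold
#' change is below the cutoff (and, when given, whose DE p-value is below
#' `p_threshold`), refits the interaction model on the retained set, and
#' separately fits the mutation term alone on the complementary
#' large-effect set (whose fold changes are expected to be driven by linked
#' structural variants, not methylation loss). A filter retaining fewer
#' than 2 genes is flagged inestimable.
#'
#' @param table site-level analysis table (carrying `log2fc`, `de_p`).
#' @param log2fc_thresholds cutoffs on |log2FC| (default 0.2 to 8).
#' @param p_threshold optional DE p-value cutoff applied with each fold
#'   cutoff (NULL = no p filter).
#' @inheritParams interaction_anova
#' @return data.frame: `log2fc_threshold`, `n_genes`, `estimate`, `F`, `p`
#'   (interaction on the retained set), `n_genes_large`, `large_estimate`,
#'   `large_p` (mutation term on the large-effect set), `estimable`.
#' @export
sweep_transcript_filter <- function(table,
                                    log2fc_thresholds = c(0.2, 0.5, 1, 2, 4, 8),
                                    p_threshold = NULL,
                                    unit = c("gene", "site"),
                                    covariates = c("chromosome", "position",
                                                   "annotation")) {
  unit <- match.arg(unit)
  rows <- lapply(log2fc_thresholds, function(th) {
    keep <- abs(table$log2fc) < th
    if (!is.null(p_threshold)) keep <- keep & table$de_p < p_threshold
    small <- table[keep, , drop = FALSE]
    large <- table[abs(table$log2fc) >= th, , drop = FALSE]
    n_small <- length(unique(small$gene))
    n_large <- length(unique(large$gene))
    res <- if (n_small >= 2L)
      tryCatch(interaction_anova(small, unit, covariates),
               error = function(e) NULL) else NULL
    lf <- if (n_large >= 2L) {
      gt <- aggregate_by_gene(large)
      if (nrow(gt) >= 3L && var(gt$n_mut_total) > 0 && var(gt$log2fc) > 0) {
        cf <- summary(lm(invnorm(gt$log2fc) ~ gt$n_mut_total))$coefficients
        if (nrow(cf) >= 2L) c(cf[2, 1], cf[2, 4]) else c(NA_real_, NA_real_)
      } else c(NA_real_, NA_real_)
    } else c(NA_real_, NA_real_)
    data.frame(log2fc_threshold = th, n_genes = n_small,
               estimate = if (is.null(res)) NA_real_ else res$estimate,
               F = if (is.null(res)) NA_real_ else res$F,
               p = if (is.null(res)) NA_real_ else res$p,
               n_genes_large = n_large,
               large_estimate = lf[1], large_p = lf[2],
               estimable = !is.null(res))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
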