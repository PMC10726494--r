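# Inverse-normal transform and the linear models testing whether the effect
# of methylated-CpG-disrupting mutations on expression depends on density.
#
# Model granularity. The analysis table has one row per site-gene pair, but
# every site of a gene shares the gene's fold change, so site-level rows are
# cluster-correlated and parametric standard errors at site level are
# anti-conservative (the permutation machinery exists to calibrate them).
# The default unit = "gene" collapses to one independent row per gene with
# mutation entering as a per-gene count; unit = "site" keeps the literal
# per-site indicator formulation.

#' Inverse-normal (rank) transform
#'
#' Maps values to standard-normal quantiles of their mid-ranks:
#' `qnorm((rank(x, na.last = "keep") - 0.5) / n_nonmissing)`. Ties receive
#' average ranks; missing values stay missing in place. The transform is
#' monotone rank-preserving and makes regression residuals robust to the
#' response distribution.
#'
#' @param x numeric vector with at least one non-missing value.
#' @return Numeric vector of normal scores.
#' @export
invnorm <- function(x) {
  n <- sum(!is.na(x))
  if (n == 0L) fail("invnorm: all values missing")
  qnorm((rank(x, na.last = "keep") - 0.5) / n)
}

#' Welch two-sample t test
#'
#' Unequal-variance two-sample statistic with Welch-Satterthwaite degrees of
#' freedom and a two-sided p-value, as used to compare normalized fold
#' changes between high- and low-density groups.
#'
#' @param a,b numeric vectors, each with at least 2 values.
#' @return List with `t`, `df`, `p`, `mean_a`, `mean_b`.
#' @export
welch_t <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) fail("each group needs >= 2 values")
  ht <- t.test(a, b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean_a = mean(a), mean_b = mean(b))
}

# Tidy lm coefficients into a data.frame(term, estimate, se, t, p).
tidy_lm <- function(fit) {
  cf <- summary(fit)$coefficients
  data.frame(term = rownames(cf), estimate = cf[, 1], se = cf[, 2],
             t = cf[, 3], p = cf[, 4], row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Within-class linear model for the mutation effect
#'
#' Restricted to one density class, regresses the inverse-normal transformed
#' log2 fold change on the mutation term and continuous CpG density. At the
#' default gene unit the rows are genes with sites in the class, mutation is
#' the class-specific candidate count (`mutation = "indicator"` uses
#' presence/absence) and density the gene's mean site density in the class;
#' at site level the rows are sites with a 0/1 mutation flag. The transform
#' is applied after restriction. Zero-variance predictors are dropped with
#' a warning.
#'
#' @param table site-level analysis table from [build_analysis_table()].
#' @param class `"high"` or `"low"`.
#' @param unit `"gene"` (independent rows, default) or `"site"`.
#' @param mutation `"count"` or `"indicator"` (gene unit only).
#' @return List of class `cpgdm_fit`: `coefficients` (term/estimate/se/t/p),
#'   `n`, `class`, `unit`, and the underlying `fit`.
#' @export
fit_within_class_model <- function(table, class = c("high", "low"),
                                   unit = c("gene", "site"),
                                   mutation = c("count", "indicator")) {
  class <- match.arg(class); unit <- match.arg(unit)
  mutation <- match.arg(mutation)
  if (unit == "gene") {
    gt <- if ("n_mut_high" %in% names(table)) table else aggregate_by_gene(table)
    keep <- if (class == "high") gt$n_sites_high > 0 else gt$n_sites_low > 0
    gt <- gt[keep, , drop = FALSE]
    mut <- if (class == "high") gt$n_mut_high else gt$n_mut_low
    if (mutation == "indicator") mut <- as.integer(mut > 0)
    dat <- data.frame(
      y = invnorm(gt$log2fc), mutation = mut,
      density = if (class == "high") gt$mean_density_high else gt$mean_density_low)
  } else {
    st <- table[table$class == class, , drop = FALSE]
    dat <- data.frame(y = invnorm(st$log2fc), mutation = st$mutation,
                      density = st$density)
  }
  for (v in c("mutation", "density"))
    if (var(dat[[v]]) == 0) {
      warning(sprintf("predictor '%s' has zero variance in class %s; dropped",
                      v, class))
      dat[[v]] <- NULL
    }
  preds <- setdiff(names(dat), "y")
  form <- if (length(preds))
    as.formula(paste("y ~", paste(preds, collapse = " + "))) else y ~ 1
  fit <- lm(form, data = dat)
  structure(list(coefficients = tidy_lm(fit), n = nrow(dat), class = class,
                 unit = unit, fit = fit),
            class = "cpgdm_fit")
}

#' @export
print.cpgdm_fit <- function(x, ...) {
  cat(sprintf("Within-class model (%s density, %s unit, n = %d)\n",
              x$class, x$unit, x$n))
  print(x$coefficients, digits = 4)
  invisible(x)
}

# Build the nested design matrices for the interaction test.
# Gene unit: X0 = covariates + mean density + total mutation count;
#            X1 adds the high-density mutation count.
# Site unit: X0 = covariates + high + mutation; X1 adds high:mutation.
# Covariates (chromosome, position, annotation) are included when they vary.
interaction_design <- function(table, unit = c("gene", "site"),
                               covariates = c("chromosome", "position",
                                              "annotation")) {
  unit <- match.arg(unit)
  if (unit == "gene") {
    gt <- if ("n_mut_high" %in% names(table)) table else aggregate_by_gene(table)
    if (unit == "gene" && !"n_mut_high" %in% names(gt))
      fail("gene-level design needs aggregate_by_gene() columns")
    dat <- data.frame(y = invnorm(gt$log2fc),
                      chromosome = factor(gt$chromosome),
                      position = gt$position,
                      annotation = factor(ifelse(is.na(gt$state_mode), "none",
                                                 gt$state_mode)),
                      density = gt$mean_density,
                      mutations = gt$n_mut_total,
                      mutations_high = gt$n_mut_high)
    add <- "mutations_high"
  } else {
    dat <- data.frame(y = invnorm(table$log2fc),
                      chromosome = factor(table$chrom),
                      position = table$pos,
                      annotation = factor(ifelse(is.na(table$state), "none",
                                                 table$state)),
                      density = table$high,
                      mutations = table$mutation,
                      interaction = table$high * table$mutation)
    add <- "interaction"
  }
  base <- c()
  if ("chromosome" %in% covariates && nlevels(dat$chromosome) > 1L)
    base <- c(base, "chromosome")
  if ("position" %in% covariates) base <- c(base, "position")
  if ("annotation" %in% covariates && nlevels(dat$annotation) > 1L)
    base <- c(base, "annotation")
  base <- c(base, "density", "mutations")
  X0 <- model.matrix(as.formula(paste("~", paste(base, collapse = " + "))), dat)
  X1 <- cbind(X0, dat[[add]])
  colnames(X1)[ncol(X1)] <- add
  list(y = dat$y, X0 = X0, X1 = X1, unit = unit, term = add)
}

# F test for adding the columns of X1 beyond X0, given precomputed QRs.
nested_f <- function(q0, q1, y) {
  rss0 <- colSums(qr.resid(q0, as.matrix(y))^2)
  rss1 <- colSums(qr.resid(q1, as.matrix(y))^2)
  df1 <- q1$rank - q0$rank
  df2 <- NROW(as.matrix(y)) - q1$rank
  Fst <- ((rss0 - rss1) / df1) / (rss1 / df2)
  data.frame(F = Fst, p = pf(Fst, df1, df2, lower.tail = FALSE),
             df1 = df1, df2 = df2, row.names = NULL)
}

#' Nested-model F test for the density-by-mutation interaction
#'
#' Compares a null model of normalized fold change on chromosome, position,
#' chromatin-state annotation, density and mutations against the same model
#' plus the density-by-mutation interaction, via `anova(fit0, fit1)`. At the
#' default gene unit the interaction enters as the count of high-density
#' candidate mutations added over the total mutation count (its coefficient
#' is the extra effect of a high-density mutation); at site level it is the
#' literal `high:mutation` product term.
#'
#' @param table site-level analysis table.
#' @param unit `"gene"` (default) or `"site"` (parametric p-values at site
#'   level should be permutation-calibrated, see
#'   [permutation_calibration()]).
#' @param covariates subset of `c("chromosome", "position", "annotation")`
#'   to adjust for (constant ones are dropped automatically).
#' @return List of class `cpgdm_anova`: `F`, `p`, `df1`, `df2`, `estimate`
#'   (interaction coefficient in the full model), `term`, `n`, `unit`.
#' @export
interaction_anova <- function(table, unit = c("gene", "site"),
                              covariates = c("chromosome", "position",
                                             "annotation")) {
  d <- interaction_design(table, unit, covariates)
  q0 <- qr(d$X0); q1 <- qr(d$X1)
  if (q1$rank <= q0$rank)
    fail(paste("degenerate design: the %s term is collinear with the null",
               "model (is one density class empty of mutations?)"), d$term)
  res <- nested_f(q0, q1, d$y)
  beta <- qr.coef(q1, d$y)
  structure(list(F = res$F, p = res$p, df1 = res$df1, df2 = res$df2,
                 estimate = unname(beta[d$term]), term = d$term,
                 n = length(d$y), unit = d$unit),
            class = "cpgdm_anova")
}

#' @export
print.cpgdm_anova <- function(x, ...) {
  cat(sprintf(
    "Density x mutation interaction (%s unit, n = %d)\nF(%d, %d) = %.3f, p = %.3g, estimate = %.4f\n",
    x$unit, x$n, x$df1, x$df2, x$F, x$p, x$estimate))
  invisible(x)
}

#' Interaction F statistics for many response vectors at once
#'
#' Re-uses the QR decompositions of the nested designs to score a matrix of
#' alternative responses (null replicates, permutations) without refitting.
#' Each column of `Y` is inverse-normal transformed and tested.
#'
#' @param table site-level analysis table (fixes the design).
#' @param Y numeric matrix of raw responses, rows aligned with the design
#'   rows (genes for `unit = "gene"`, sites otherwise), one column per
#'   replicate.
#' @inheritParams interaction_anova
#' @return data.frame with one row per column of `Y`: `F`, `p`, `df1`,
#'   `df2`.
#' @export
interaction_f_repeated <- function(table, Y, unit = c("gene", "site"),
                                   covariates = c("chromosome", "position",
                                                  "annotation")) {
  d <- interaction_design(table, match.arg(unit), covariates)
  Y <- as.matrix(Y)
  if (nrow(Y) != length(d$y))
    fail("Y has %d rows but the design has %d", nrow(Y), length(d$y))
  q0 <- qr(d$X0); q1 <- qr(d$X1)
  if (q1$rank <= q0$rank) fail("degenerate design: interaction collinear")
  Z <- apply(Y, 2L, invnorm)
  nested_f(q0, q1, Z)
}

#' Rows of the gene-level design for a site table
#'
#' Gene identifiers in the order used by gene-unit models, so callers can
#' align replicate response matrices (see [interaction_f_repeated()]).
#'
#' @param table site-level analysis table.
#' @return Character vector of gene ids.
#' @export
design_genes <- function(table) levels(factor(table$gene))

#' Chromatin-state-stratified mutation scan
#'
#' For each of the 15 chromatin state groups crossed with the high/low
#' density classes: counts sites with and without candidate mutations, the
#' percent mutated, and the p-value of the mutation term in a linear model
#' of the inverse-normal transformed fold change (gene unit: genes with
#' sites in the cell, mutation = in-cell candidate count). Cells with zero
#' mutated sites report a missing p-value, not 1. Two multiple-testing
#' flags are reported: the printed Bonferroni threshold 0.001 for 2 x 15
#' tests (`sig_bonferroni`) and `alpha / 30` (`sig_alpha_over_30`).
#'
#' If no site carries a state label the scan degenerates to the
#' unstratified mutation model (one row per class, `state = "(all)"`).
#'
#' @param table site-level analysis table with a `state` column.
#' @param unit `"gene"` (default) or `"site"`.
#' @param alpha family-wise error rate for the `alpha / 30` flag.
#' @return data.frame with one row per state x class.
#' @export
chromatin_state_scan <- function(table, unit = c("gene", "site"),
                                 alpha = 0.05) {
  unit <- match.arg(unit)
  states <- chromatin_state_groups()
  if (all(is.na(table$state))) {
    table$state <- "(all)"
    states <- "(all)"
  }
  cell_fit <- function(sub) {
    if (!nrow(sub)) return(c(NA_real_, NA_real_))
    if (unit == "gene") {
      g <- factor(sub$gene)
      y <- invnorm(sub$log2fc[!duplicated(g)][order(g[!duplicated(g)])])
      x <- rowsum(as.numeric(sub$mutation), g)[, 1L]
    } else {
      y <- invnorm(sub$log2fc); x <- sub$mutation
    }
    if (length(y) < 3L || var(x) == 0 || var(y) == 0) return(c(NA_real_, NA_real_))
    cf <- summary(lm(y ~ x))$coefficients
    if (nrow(cf) < 2L) return(c(NA_real_, NA_real_))
    c(cf[2, 1], cf[2, 4])
  }
  rows <- list()
  for (s in states) for (cl in c("high", "low")) {
    sub <- table[!is.na(table$state) & table$state == s & table$class == cl, ,
                 drop = FALSE]
    n_mut <- sum(sub$mutation)
    ep <- if (n_mut == 0L) c(NA_real_, NA_real_) else cell_fit(sub)
    rows[[length(rows) + 1L]] <- data.frame(
      state = s, class = cl,
      n_no_mut = nrow(sub) - n_mut, n_mut = n_mut,
      pct_mut = if (nrow(sub)) 100 * n_mut / nrow(sub) else NA_real_,
      estimate = ep[1], p = ep[2], stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$sig_bonferroni <- !is.na(out$p) & out$p < 0.001
  out$sig_alpha_over_30 <- !is.na(out$p) & out$p < alpha / 30
  rownames(out) <- NULL
  out
}
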