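test_that("invnorm matches the closed-form normal scores", {
  expect_equal(invnorm(c(1, 2, 3)),
               qnorm(c(1, 2, 3) / 3 - 0.5 / 3), tolerance = 1e-12)
  expect_equal(round(invnorm(c(1, 2, 3)), 4), c(-0.9674, 0, 0.9674))
  # missing values stay missing in place
  expect_equal(invnorm(c(5, NA, 7)), c(qnorm(0.25), NA, qnorm(0.75)))
  # ties get average ranks: ranks (1.5, 1.5, 3) -> (1/3, 1/3, 2.5/3)
  expect_equal(invnorm(c(2, 2, 9)),
               c(qnorm(1 / 3), qnorm(1 / 3), qnorm(2.5 / 3)))
  expect_error(invnorm(c(NA_real_, NA_real_)), "missing")
})

test_that("invnorm is monotone rank-preserving with near-zero mean", {
  set.seed(9)
  for (i in 1:20) {
    x <- rnorm(sample(3:200, 1))
    z <- invnorm(x)
    expect_equal(order(x), order(z))
    expect_lt(abs(mean(z)), 1e-6)
    # odd-length strictly increasing input maps its median to 0
    x2 <- sort(x)[seq_len(length(x) - (1 - length(x) %% 2))]
    expect_equal(invnorm(x2)[(length(x2) + 1) / 2], 0)
  }
})

test_that("welch_t matches the textbook Welch computation", {
  a <- c(2.1, 3.5, 2.8, 4.0, 3.1)
  b <- c(1.0, 1.9, 1.4, 2.2, 1.6)
  w <- welch_t(a, b)
  o <- oracle_welch(a, b)
  expect_equal(w$t, o$t)
  expect_equal(w$df, o$df)
  expect_equal(w$p, o$p)
  # identical groups: t = 0, p = 1
  w0 <- welch_t(a, a)
  expect_equal(w0$t, 0)
  expect_equal(w0$p, 1)
  expect_error(welch_t(1, a), ">= 2")
})

test_that("with equal sizes and variances Welch reduces to the pooled t", {
  a <- c(1, 2, 3, 4)
  b <- c(2, 3, 4, 5)   # same sample variance, shifted
  w <- welch_t(a, b)
  sp2 <- (var(a) + var(b)) / 2
  t_pooled <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 4 + 1 / 4))
  expect_equal(w$t, t_pooled)
  expect_equal(w$df, 6)
})

make_gene_table <- function(n = 400, beta_high = 0.3, seed = 1) {
  set.seed(seed)
  g <- data.frame(gene = sprintf("g%04d", 1:n),
                  chromosome = sample(c("chr1", "chr2"), n, TRUE),
                  position = runif(n, 0, 1e6),
                  de_p = runif(n),
                  n_sites_high = rpois(n, 2), n_sites_low = rpois(n, 5) + 1L,
                  n_mut_high = rpois(n, 0.3), n_mut_low = rpois(n, 1),
                  mean_density_high = runif(n, 45, 90),
                  mean_density_low = runif(n, 2, 35),
                  mean_density = runif(n, 10, 60),
                  state_mode = sample(c("Quiescent", "Active enhancers"), n, TRUE),
                  stringsAsFactors = FALSE)
  g$n_mut_total <- g$n_mut_high + g$n_mut_low
  g$log2fc <- beta_high * g$n_mut_high + rnorm(n)
  g
}

test_that("the within-class fit recovers a constant response as zero slopes", {
  gt <- make_gene_table()
  gt$log2fc <- 0.7
  fit <- fit_within_class_model(gt, "high")
  cf <- fit$coefficients
  expect_equal(cf$estimate[cf$term != "(Intercept)"], c(0, 0),
               tolerance = 1e-10)
})

test_that("zero-variance predictors are dropped with a warning", {
  gt <- make_gene_table()
  gt$n_mut_high <- 0L
  expect_warning(fit <- fit_within_class_model(gt, "high"), "zero variance")
  expect_false("mutation" %in% fit$coefficients$term)
})

test_that("gene-level interaction F equals anova() on explicitly fitted models", {
  gt <- make_gene_table(beta_high = 0.4)
  res <- interaction_anova(gt)
  dat <- data.frame(y = invnorm(gt$log2fc), chromosome = factor(gt$chromosome),
                    position = gt$position,
                    annotation = factor(gt$state_mode),
                    density = gt$mean_density, mutations = gt$n_mut_total,
                    mutations_high = gt$n_mut_high)
  fit0 <- lm(y ~ chromosome + position + annotation + density + mutations,
             data = dat)
  fit1 <- update(fit0, . ~ . + mutations_high)
  an <- anova(fit0, fit1)
  expect_equal(res$F, an$F[2])
  expect_equal(res$p, an$`Pr(>F)`[2])
  expect_equal(res$estimate, unname(coef(fit1)["mutations_high"]))
})

test_that("site-level interaction matches the literal product-term model", {
  set.seed(2)
  n <- 300
  tab <- data.frame(gene = sample(sprintf("g%02d", 1:30), n, TRUE),
                    chrom = "chr1", pos = sample.int(1e5, n),
                    density = runif(n, 5, 90), stringsAsFactors = FALSE)
  tab$high <- as.integer(tab$density > 40)
  tab$class <- ifelse(tab$high == 1L, "high", "low")
  tab$mutation <- rbinom(n, 1, 0.2)
  tab$state <- NA_character_
  fc <- rnorm(30)
  tab$log2fc <- fc[match(tab$gene, sprintf("g%02d", 1:30))]
  res <- interaction_anova(tab, unit = "site",
                           covariates = c("chromosome", "position"))
  y <- invnorm(tab$log2fc)
  fit0 <- lm(y ~ pos + density + mutation, data = transform(tab, density = high))
  fit1 <- lm(y ~ pos + density + mutation + density:mutation,
             data = transform(tab, density = high))
  an <- anova(fit0, fit1)
  expect_equal(res$F, an$F[2])
  expect_equal(res$p, an$`Pr(>F)`[2])
})

test_that("a design without low-density mutations is rejected as degenerate", {
  gt <- make_gene_table()
  gt$n_mut_low <- 0L
  gt$n_mut_total <- gt$n_mut_high
  expect_error(interaction_anova(gt), "collinear")
})

test_that("interaction_f_repeated reproduces single-fit statistics per column", {
  gt <- make_gene_table(beta_high = 0.25)
  res1 <- interaction_anova(gt)
  Y <- cbind(gt$log2fc, rnorm(nrow(gt)))
  rep2 <- interaction_f_repeated(gt, Y)
  expect_equal(rep2$F[1], res1$F)
  expect_equal(rep2$p[1], res1$p)
  expect_equal(nrow(rep2), 2L)
})

test_that("chromatin-state scan counts cells and flags both Bonferroni rules", {
  set.seed(4)
  n <- 1000
  tab <- data.frame(gene = sprintf("g%03d", rep(1:200, each = 5)),
                    chrom = "chr1", pos = 1:n, density = 60,
                    class = "high", high = 1L,
                    mutation = c(rep(1L, 10), rep(0L, 990)),
                    state = "Active enhancers", stringsAsFactors = FALSE)
  fc <- rnorm(200)
  tab$log2fc <- fc[rep(1:200, each = 5)]
  sc <- chromatin_state_scan(tab)
  row <- sc[sc$state == "Active enhancers" & sc$class == "high", ]
  expect_equal(row$pct_mut, 1.0)
  expect_equal(row$n_mut, 10L)
  expect_equal(row$n_no_mut, 990L)
  # cells with zero mutated sites report NA p, not 1
  empty <- sc[sc$state == "Quiescent" & sc$class == "high", ]
  expect_true(is.na(empty$p))
  expect_false(empty$sig_bonferroni)
})

test_that("an empty state track degenerates to the unstratified scan", {
  tab <- data.frame(gene = rep(sprintf("g%02d", 1:20), each = 2),
                    chrom = "chr1", pos = 1:40, density = 60, class = "high",
                    high = 1L, mutation = rbinom(40, 1, 0.4),
                    state = NA_character_, stringsAsFactors = FALSE)
  tab$log2fc <- rep(rnorm(20), each = 2)
  sc <- chromatin_state_scan(tab)
  expect_equal(unique(sc$state), "(all)")
  expect_equal(nrow(sc), 2L)
})
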