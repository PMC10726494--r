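calib_gene_table <- function(n = 300, beta_high = 0, seed = 3) {
  set.seed(seed)
  g <- data.frame(gene = sprintf("g%04d", 1:n),
                  chromosome = sample(c("chr1", "chr2"), n, TRUE),
                  position = runif(n, 0, 1e6), de_p = runif(n),
                  n_sites_high = rpois(n, 2), n_sites_low = rpois(n, 5) + 1L,
                  n_mut_high = rpois(n, 0.4), n_mut_low = rpois(n, 1.2),
                  mean_density_high = runif(n, 45, 90),
                  mean_density_low = runif(n, 2, 35),
                  mean_density = runif(n, 10, 60),
                  state_mode = sample(c("Quiescent", "Transcription"), n, TRUE),
                  stringsAsFactors = FALSE)
  g$n_mut_total <- g$n_mut_high + g$n_mut_low
  g$log2fc <- beta_high * g$n_mut_high + rnorm(n)
  g
}

test_that("the permutation stream is reproducible under a seed", {
  gt <- calib_gene_table()
  a <- permutation_calibration(gt, n_perm = 50, seed = 42)
  b <- permutation_calibration(gt, n_perm = 50, seed = 42)
  expect_identical(a$perm_F, b$perm_F)
  expect_identical(a$p_empirical, b$p_empirical)
  c2 <- permutation_calibration(gt, n_perm = 50, seed = 43)
  expect_false(identical(a$perm_F, c2$perm_F))
  expect_error(permutation_calibration(gt, n_perm = 0), "n_perm")
})

test_that("an observed statistic above all permutations gets the add-one p", {
  gt <- calib_gene_table(beta_high = 2)   # overwhelming effect
  pc <- permutation_calibration(gt, n_perm = 99, seed = 1)
  expect_equal(pc$p_empirical, 1 / 100)
})

test_that("site-level permutation moves each gene's expression as a block", {
  set.seed(11)
  tab <- data.frame(gene = rep(sprintf("g%02d", 1:40), each = 4),
                    chrom = "chr1", pos = 1:160, density = runif(160, 5, 90),
                    state = NA_character_, stringsAsFactors = FALSE)
  tab$high <- as.integer(tab$density > 40)
  tab$class <- ifelse(tab$high == 1, "high", "low")
  tab$mutation <- rbinom(160, 1, 0.2)
  tab$log2fc <- rep(rnorm(40), each = 4)
  pc <- permutation_calibration(tab, n_perm = 20, seed = 5, unit = "site")
  expect_equal(pc$unit, "site")
  expect_length(pc$perm_F, 20)
  expect_true(all(is.finite(pc$perm_F)))
})

test_that("a single-threshold sweep equals the direct interaction test", {
  gt_site <- local({
    set.seed(8)
    n <- 500
    tab <- data.frame(gene = sample(sprintf("g%03d", 1:100), n, TRUE),
                      chrom = "chr1", pos = sample.int(1e6, n),
                      density = runif(n, 5, 100), state = NA_character_,
                      stringsAsFactors = FALSE)
    tab$high <- as.integer(tab$density > 40)
    tab$class <- ifelse(tab$high == 1, "high", "low")
    tab$mutation <- rbinom(n, 1, 0.25)
    fc <- rnorm(100)
    tab$log2fc <- fc[match(tab$gene, sprintf("g%03d", 1:100))] +
      0.3 * tab$mutation * tab$high
    tab
  })
  sw <- sweep_density_threshold(gt_site, thresholds = 40)
  direct <- interaction_anova(gt_site)
  expect_equal(sw$F, direct$F)
  expect_equal(sw$estimate, direct$estimate)
  expect_equal(sweep_change_point(sw), 40)
})

test_that("thresholds outside the density range are flagged inestimable", {
  gt_site <- data.frame(gene = rep(sprintf("g%02d", 1:30), each = 3),
                        chrom = "chr1", pos = 1:90,
                        density = runif(90, 20, 30), state = NA_character_,
                        stringsAsFactors = FALSE)
  gt_site$high <- 0L; gt_site$class <- "low"
  gt_site$mutation <- rbinom(90, 1, 0.3)
  gt_site$log2fc <- rep(rnorm(30), each = 3)
  sw <- sweep_density_threshold(gt_site, thresholds = c(50, 60))
  expect_false(any(sw$estimable))
  expect_true(all(is.na(sw$F)))
  expect_true(is.na(sweep_change_point(sw)))
})

test_that("the transcript filter sweep is monotone and has an identity filter", {
  set.seed(12)
  n <- 600
  tab <- data.frame(gene = rep(sprintf("g%03d", 1:150), each = 4),
                    chrom = "chr1", pos = 1:n, density = runif(n, 5, 90),
                    state = NA_character_, stringsAsFactors = FALSE)
  tab$high <- as.integer(tab$density > 40)
  tab$class <- ifelse(tab$high == 1, "high", "low")
  tab$mutation <- rbinom(n, 1, 0.25)
  fc <- c(rnorm(10) - 6, rnorm(140) * 0.3)  # a clean large-effect subset
  tab$log2fc <- fc[rep(1:150, each = 4)]
  tab$de_p <- runif(n)
  sw <- sweep_transcript_filter(tab, log2fc_thresholds = c(0.2, 1, 2, Inf))
  expect_true(!is.unsorted(sw$n_genes))        # fewer genes at lower cutoffs
  direct <- interaction_anova(tab)
  expect_equal(sw$F[sw$log2fc_threshold == Inf], direct$F)
  expect_equal(sw$n_genes_large[sw$log2fc_threshold == 2], 10L)
})

test_that("a large-effect subset driven by structural variants fits negative", {
  fx <- default_fixture()
  # the large-|FC| subset is dominated by genes whose candidate mutations
  # drag linked structural variants along, so its mutation term is negative;
  # at desk scale a single draw is noisy, so the sign is checked across
  # expression replicates
  est <- vapply(1:20, function(r) {
    ex <- generate_expression(fx$cfg, fx$sim$gene_structure,
                              seed = child_seed(r, "structural"))
    tab <- fx$tab
    tab$log2fc <- ex$de$log2FoldChange[match(tab$gene, ex$de$gene)]
    sweep_transcript_filter(tab, log2fc_thresholds = 2)$large_estimate
  }, numeric(1))
  expect_lt(mean(est), 0)
  expect_gte(mean(est < 0), 0.7)
})
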