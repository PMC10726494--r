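test_that("config validation rejects impossible settings", {
  expect_error(synthetic_config(), "seed")
  expect_error(synthetic_config(seed = 1, density_spectrum =
    data.frame(density = 600, n_segments = 8)), "impossible")
  expect_error(synthetic_config(seed = 1, concordance = 1.2), "rates")
  expect_error(synthetic_config(seed = 1, density_spectrum =
    data.frame(density = 10, n_segments = 9)), "multiple")
})

test_that("realized CpG counts are Poisson around the target density", {
  cfg <- synthetic_config(seed = 11L, n_chrom = 1L,
                          density_spectrum = data.frame(density = 10,
                                                        n_segments = 100))
  ref <- generate_reference(cfg)
  expect_equal(mean(ref$segments$cpg_count), 20, tolerance = 0.05)
  expect_equal(nrow(ref$cpg), sum(ref$segments$cpg_count))
  # the sequence contains exactly the placed CpGs
  found <- find_cpg_sites(ref$genome)
  expect_equal(found$pos, ref$cpg$pos)
})

test_that("the reference generator is deterministic and honors target 0", {
  cfg <- small_config(seed = 5L)
  a <- generate_reference(cfg); b <- generate_reference(cfg)
  expect_identical(a$genome, b$genome)
  cfg0 <- synthetic_config(seed = 2L, n_chrom = 1L,
                           density_spectrum = data.frame(density = 0,
                                                         n_segments = 10))
  expect_equal(nrow(generate_reference(cfg0)$cpg), 0L)
})

test_that("generated methylomes follow the three-fraction density curve", {
  fx <- default_fixture()
  truth <- fx$sim$truth$states_true[, "b6"]
  reg <- fx$sim$cpg$regime
  expect_equal(mean(truth[reg == "low"]), 0.9, tolerance = 0.02)
  expect_equal(mean(truth[reg == "mid"]), 0.5, tolerance = 0.03)
  expect_equal(mean(truth[reg == "high"]), 0.15, tolerance = 0.03)
  validate_site_table(fx$sim$sites)
})

test_that("perfect concordance and error-free reads give same_state 1", {
  ret <- c(b6 = 1, aj = 1, balb = 1, cast = 1, d2 = 1, fvb = 1, pwk = 1,
           wsb = 1)
  cfg <- small_config(seed = 13L, concordance = 1, retention = ret,
                      read_meth_frac = 1, read_error_frac = 0)
  sim <- simulate_dataset(cfg)
  prof <- segment_profiles(sim$sites, sim$segments)
  st <- pairwise_segment_stats(prof, "b6", "d2", downsample = FALSE)
  expect_true(all(st$same_state == 1))
  # and still 1 after coverage downsampling of read counts at these
  # error-free settings for almost every segment
  st2 <- pairwise_segment_stats(prof, "b6", "d2", seed = 1)
  expect_gte(mean(st2$same_state == 1), 0.99)
})

test_that("variant generation respects rates and the truth ledger", {
  fx <- default_fixture()
  v <- fx$sim$variants
  validate_variant_table(v)
  tr <- fx$sim$truth$variants
  # every at-CpG truth record appears in the wide table with that allele
  i <- match(paste(tr$chrom, tr$pos), paste(v$chrom, v$pos))
  expect_false(anyNA(i))
  picked <- mapply(function(row, s) v[[s]][row], i, tr$strain)
  expect_identical(unname(picked), tr$allele)
  # all rates zero -> empty table
  cfg0 <- small_config(seed = 3L,
                       mutation_rates = c(meth_low = 0, unmeth_low = 0,
                                          meth_high = 0, unmeth_high = 0),
                       background_variant_rate = 0)
  ref <- generate_reference(cfg0)
  meth <- generate_strain_methylomes(cfg0, ref)
  expect_equal(nrow(generate_variants(cfg0, ref, meth)$variants), 0L)
})

test_that("chromatin states partition every base exactly once", {
  fx <- default_fixture()
  st <- fx$sim$states
  expect_equal(sum(st$end - st$start), sum(fx$sim$chrom_sizes))
  for (chrom in names(fx$sim$chrom_sizes)) {
    s <- st[st$chrom == chrom, ]
    s <- s[order(s$start), ]
    expect_equal(s$start[-1], s$end[-nrow(s)])  # gapless, non-overlapping
  }
  expect_true(all(st$state %in% chromatin_state_groups()))
  # single-state palette degenerates cleanly
  p1 <- setNames(c(1, rep(0, 14)), chromatin_state_groups())
  cfg1 <- small_config(seed = 4L, state_p_low = p1, state_p_high = p1)
  ref <- generate_reference(cfg1)
  st1 <- generate_chromatin_states(cfg1, ref)
  expect_equal(unique(st1$state), chromatin_state_groups()[1])
})

test_that("expression composes effects, structural shifts and noise exactly", {
  fx <- default_fixture()
  gs <- fx$sim$gene_structure
  cfg <- fx$cfg
  ex <- generate_expression(cfg, gs, seed = 1L)
  recomposed <- ex$truth$mu +
    ifelse(ex$truth$structural, cfg$structural_effect, 0) + ex$truth$noise
  expect_equal(ex$de$log2FoldChange, recomposed)
  expect_equal(ex$truth$mu,
               cfg$beta_high * gs$n_high + cfg$beta_low * gs$n_low +
                 cfg$density_slope * gs$mean_density)
  # zero noise: a gene with one high candidate gets exactly beta_high
  cfg0 <- fx$cfg; cfg0$noise_sd <- 0; cfg0$structural_fraction <- 0
  ex0 <- generate_expression(cfg0, gs, seed = 2L)
  one <- gs$n_high == 1 & gs$n_low == 0
  expect_true(any(one))
  expect_equal(ex0$de$log2FoldChange[one],
               rep(cfg0$beta_high, sum(one)) +
                 cfg0$density_slope * gs$mean_density[one])
  # structural fraction 0 leaves no |log2FC| above 8
  expect_true(all(abs(ex0$de$log2FoldChange) < 8))
})

test_that("generated layers are reproducible and files re-validate", {
  cfg <- small_config(seed = 21L)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_identical(s1$sites, s2$sites)
  expect_identical(s1$variants, s2$variants)
  expect_identical(s1$de, s2$de)
  dir <- withr::local_tempdir()
  paths <- write_simulation(s1, dir)
  expect_equal(read_site_table(paths["sites"]), s1$sites, ignore_attr = TRUE)
  expect_equal(nrow(read_variant_table(paths["variants"])), nrow(s1$variants))
  expect_equal(read_gene_models(paths["genes"])$gene, s1$genes$gene)
  expect_equal(nrow(read_chromatin_states(paths["states"])), nrow(s1$states))
  de <- read_de_results(paths["de"])
  expect_equal(de$log2FoldChange, s1$de$log2FoldChange, tolerance = 1e-12)
  expect_identical(read_genome_fasta(paths["genome"]), s1$genome)
})

test_that("the analysis recovers the generated candidate structure", {
  fx <- default_fixture()
  gt <- fx$gt
  gs <- fx$sim$gene_structure
  m <- merge(gt, gs, by = "gene")
  expect_gt(cor(m$n_mut_high, m$n_high), 0.95)
  expect_gt(cor(m$n_mut_low, m$n_low), 0.95)
})
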