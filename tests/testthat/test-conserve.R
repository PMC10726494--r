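test_that("prop_occurrence reproduces hand-enumerated proportions", {
  r <- prop_occurrence(c(1, 0, 1), c(1, 0, 0))
  expect_equal(unname(r["prop_pp"]), 1 / 3)
  expect_equal(unname(r["prop_qq"]), 1 / 3)
  expect_equal(unname(r["same_state"]), 2 / 3)
  expect_equal(unname(prop_occurrence(c(1, 0, 1), c(1, 0, 1))["same_state"]), 1)
  expect_equal(unname(prop_occurrence(c(1, 0), c(0, 1))["same_state"]), 0)
  expect_error(prop_occurrence(c(1, 0), c(1)), "length")
  expect_error(prop_occurrence(numeric(), numeric()), "empty")
  expect_error(prop_occurrence(c(1, NA), c(1, 0)), "no-call")
})

test_that("prop_occurrence is symmetric in the joint proportions", {
  set.seed(5)
  for (i in 1:50) {
    n <- sample(1:50, 1)
    a <- sample(0:1, n, replace = TRUE)
    b <- sample(0:1, n, replace = TRUE)
    r1 <- prop_occurrence(a, b); r2 <- prop_occurrence(b, a)
    expect_equal(r1[c("prop_pp", "prop_qq", "same_state")],
                 r2[c("prop_pp", "prop_qq", "same_state")])
    expect_equal(r1, oracle_prop(a, b))
  }
})

test_that("methylated_count_ratio is min/max with the degenerate case excluded", {
  expect_equal(methylated_count_ratio(5, 5), 1)
  expect_equal(methylated_count_ratio(3, 6), 0.5)
  expect_true(is.na(methylated_count_ratio(0, 0)))
  expect_equal(methylated_count_ratio(c(1, 0), c(4, 7)), c(0.25, 0))
  expect_error(methylated_count_ratio(-1, 2), "negative")
})

test_that("per-segment stats drop pairwise no-calls and match the oracle", {
  prof <- calls_profile(c(1, NA, 0, 1, 1, 0), c(1, 1, 1, NA, 1, 0),
                        seg_id = c(1, 1, 1, 2, 2, 2), density = c(12, 12, 12, 50, 50, 50))
  st <- pairwise_segment_stats(prof, "a", "b", downsample = FALSE)
  # segment 1 keeps sites 1 and 3; segment 2 keeps sites 5 and 6
  expect_equal(st$n_sites, c(2L, 2L))
  expect_equal(st$same_state[1], unname(oracle_prop(c(1, 0), c(1, 1))["same_state"]))
  expect_equal(st$ratio[2], oracle_ratio(1, 1))
  # a segment with no jointly callable site is omitted
  prof2 <- calls_profile(c(1, NA), c(NA, 0), seg_id = c(1, 1), density = 10)
  expect_equal(nrow(pairwise_segment_stats(prof2, "a", "b", downsample = FALSE)),
               0L)
})

test_that("density pooling equals brute force on concatenated site vectors", {
  set.seed(17)
  for (rep in 1:30) {
    n_seg <- sample(1:10, 1)
    sizes <- sample(1:10, n_seg, replace = TRUE)
    dens <- sample(c(8, 8, 25, 70), n_seg, replace = TRUE)
    a <- sample(0:1, sum(sizes), replace = TRUE)
    b <- sample(0:1, sum(sizes), replace = TRUE)
    prof <- calls_profile(a, b, seg_id = rep(seq_len(n_seg), sizes),
                          density = rep(dens, sizes))
    agg <- aggregate_by_density(prof, "a", "b", downsample = FALSE)
    for (bin in unique(floor(dens))) {
      keep <- rep(floor(dens), sizes) == bin
      o <- oracle_prop(a[keep], b[keep])
      row <- agg[agg$seg == bin, ]
      expect_equal(row$prob, unname(o["same_state"]))
      expect_equal(row$ratio, oracle_ratio(sum(a[keep]), sum(b[keep])))
      expect_equal(row$CG.all, sum(keep))
      expect_equal(row$s1.me, sum(a[keep]))
      expect_equal(row$s2.me, sum(b[keep]))
    }
  }
})

test_that("a bin with a single segment reduces to that segment's stats", {
  prof <- calls_profile(c(1, 0, 1, 1), c(1, 0, 0, 1), seg_id = rep(3, 4),
                        density = 33)
  st <- pairwise_segment_stats(prof, "a", "b", downsample = FALSE)
  agg <- aggregate_by_density(prof, "a", "b", downsample = FALSE)
  expect_equal(agg$prob, st$same_state)
  expect_equal(agg$ratio, st$ratio)
  expect_equal(agg$prop_pp, st$prop_pp)
})

test_that("mutant site counts per bin follow the first strain's calls", {
  prof <- calls_profile(c(1, 0, 1), c(1, 1, 1), seg_id = rep(1, 3),
                        density = 10)
  v <- data.frame(chrom = "chr1", pos = c(1L, 2L), ref_allele = "C",
                  a = c("T", "T"), out = c("C", "C"), stringsAsFactors = FALSE)
  agg <- aggregate_by_density(prof, "a", "b", downsample = FALSE,
                              variants = v, outgroup = "out")
  expect_equal(agg$mutant.me.1, 1L)  # site 1: methylated in strain a, mutated
  expect_equal(agg$mutant.me.0, 1L)  # site 2: unmethylated in strain a, mutated
})
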