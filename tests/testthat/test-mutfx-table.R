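tiny_profiles_for_mutfx <- function() {
  # 6 CpG sites across two segments (density 60 and 10), reference strain b6
  # methylated except sites 3 and 6
  prof <- calls_profile(c(1, 1, 0, 1, 1, 0), c(1, 1, 1, 1, 0, 0),
                        seg_id = c(1, 1, 1, 2, 2, 2),
                        density = c(60, 60, 60, 10, 10, 10),
                        strains = c("b6", "d2"))
  prof
}

tiny_variants_for_mutfx <- function() {
  data.frame(chrom = "chr1", pos = 1:6, ref_allele = "C",
             b6 = "C", d2 = c("T", "G", "A", "A", "C", "T"),
             stringsAsFactors = FALSE)
}

test_that("classify_density uses a strict threshold", {
  expect_equal(classify_density(40.5), "high")
  expect_equal(classify_density(40.0), "low")
  expect_equal(classify_density(39, threshold = 38), "high")
  expect_error(classify_density(-1), "negative")
})

test_that("gene intervals extend symmetrically and clamp at bounds", {
  g <- data.frame(gene = "g", chrom = "chr1", strand = "-",
                  txStart = 10000L, txEnd = 20000L, stringsAsFactors = FALSE)
  gi <- gene_interval(g)
  expect_equal(c(gi$int_start, gi$int_end), c(8000L, 22000L))
  g2 <- within(g, {txStart <- 500L; txEnd <- 1500L})
  gi2 <- gene_interval(g2, chrom_sizes = c(chr1 = 3000))
  expect_equal(c(gi2$int_start, gi2$int_end), c(0L, 3000L))
  gi3 <- gene_interval(g, flank = 0)
  expect_equal(c(gi3$int_start, gi3$int_end), c(10000L, 20000L))
})

test_that("candidate mutations require a methylated CpG and an A/T allele", {
  prof <- tiny_profiles_for_mutfx()
  v <- tiny_variants_for_mutfx()
  cand <- candidate_mutations(prof, v, focal = "d2", reference = "b6")
  # site 1: methylated + T; site 4: methylated + A. site 2 has a G allele,
  # site 3/6 are unmethylated, site 5 has no variant.
  expect_equal(cand$pos, c(1L, 4L))
  expect_equal(cand$class, c("high", "low"))
  expect_equal(attr(cand, "direction"), "reference_methylated")
})

test_that("the direction switch flips which strain carries the methylation", {
  prof <- tiny_profiles_for_mutfx()
  v <- tiny_variants_for_mutfx()
  # focal_methylated: d2 must be called methylated, b6 carries A/T -> none
  cand <- candidate_mutations(prof, v, focal = "d2", reference = "b6",
                              direction = "focal_methylated")
  expect_equal(nrow(cand), 0L)
})

test_that("candidate selection is invariant to input row order", {
  prof <- tiny_profiles_for_mutfx()
  v <- tiny_variants_for_mutfx()
  o <- c(4, 2, 6, 1, 3, 5)
  prof2 <- prof[o, ]
  attr(prof2, "strains") <- attr(prof, "strains")
  attr(prof2, "params") <- attr(prof, "params")
  c1 <- candidate_mutations(prof, v, "d2", "b6")
  c2 <- candidate_mutations(prof2, v[rev(seq_len(nrow(v))), ], "d2", "b6")
  expect_equal(c1[order(c1$pos), ], c2[order(c2$pos), ], ignore_attr = TRUE)
})

test_that("a mutation overlapping several gene intervals yields one record per gene", {
  prof <- tiny_profiles_for_mutfx()
  v <- tiny_variants_for_mutfx()
  genes <- data.frame(gene = c("gA", "gB"), chrom = "chr1", strand = "+",
                      txStart = c(0L, 0L), txEnd = c(10L, 10L),
                      stringsAsFactors = FALSE)
  cand <- candidate_mutations(prof, v, "d2", "b6", genes = genes, flank = 0)
  expect_equal(sum(cand$pos == 1), 2L)
  expect_setequal(cand$gene[cand$pos == 1], c("gA", "gB"))
})

test_that("build_analysis_table joins sites, genes, DE and states", {
  prof <- tiny_profiles_for_mutfx()
  v <- tiny_variants_for_mutfx()
  genes <- data.frame(gene = c("gA", "gB"), chrom = "chr1", strand = "+",
                      txStart = c(0L, 3L), txEnd = c(3L, 6L),
                      stringsAsFactors = FALSE)
  de <- data.frame(gene = c("gA", "gB"), log2FoldChange = c(0.5, -0.2),
                   pvalue = c(0.01, 0.6), stringsAsFactors = FALSE)
  states <- data.frame(chrom = "chr1", start = 0L, end = 6L,
                       state = "Active enhancers", stringsAsFactors = FALSE)
  tab <- build_analysis_table(prof, v, genes, de, focal = "d2",
                              reference = "b6", states = states, flank = 0)
  # methylated sites: 1, 2, 4, 5; gA spans pos 1..3, gB pos 4..6
  expect_equal(sort(tab$pos), c(1L, 2L, 4L, 5L))
  expect_equal(tab$mutation[order(tab$pos)], c(1L, 0L, 1L, 0L))
  expect_equal(tab$log2fc[tab$gene == "gA"], rep(0.5, 2))
  expect_true(all(tab$state == "Active enhancers"))
  cnt <- attr(tab, "counts")
  expect_equal(unname(cnt["candidate_mutations"]), 2L)
  expect_equal(unname(cnt["candidate_mutations_high"]), 1L)
  # DE p filter drops gB's rows
  tab2 <- build_analysis_table(prof, v, genes, de, focal = "d2",
                               reference = "b6", de_p_max = 0.05, flank = 0)
  expect_true(all(tab2$gene == "gA"))
})

test_that("the accessibility gate blanks unsupported state labels", {
  prof <- tiny_profiles_for_mutfx()
  v <- tiny_variants_for_mutfx()
  genes <- data.frame(gene = "gA", chrom = "chr1", strand = "+",
                      txStart = 0L, txEnd = 6L, stringsAsFactors = FALSE)
  de <- data.frame(gene = "gA", log2FoldChange = 0.5, pvalue = 0.5,
                   stringsAsFactors = FALSE)
  states <- data.frame(chrom = "chr1", start = 0L, end = 6L,
                       state = "Quiescent", stringsAsFactors = FALSE)
  acc <- data.frame(chrom = "chr1", pos = 1:6,
                    reads = c(20L, 3L, 20L, 20L, 0L, 20L))
  tab <- build_analysis_table(prof, v, genes, de, focal = "d2",
                              reference = "b6", states = states,
                              accessibility = acc, flank = 0)
  expect_true(is.na(tab$state[tab$pos == 2]))
  expect_equal(tab$state[tab$pos == 1], "Quiescent")
})

test_that("aggregate_by_gene sums mutations and sites within class", {
  prof <- tiny_profiles_for_mutfx()
  v <- tiny_variants_for_mutfx()
  genes <- data.frame(gene = "gA", chrom = "chr1", strand = "+",
                      txStart = 0L, txEnd = 6L, stringsAsFactors = FALSE)
  de <- data.frame(gene = "gA", log2FoldChange = 0.5, pvalue = 0.5,
                   stringsAsFactors = FALSE)
  tab <- build_analysis_table(prof, v, genes, de, focal = "d2",
                              reference = "b6", flank = 0)
  gt <- aggregate_by_gene(tab)
  expect_equal(nrow(gt), 1L)
  expect_equal(gt$n_mut_high, 1L)
  expect_equal(gt$n_mut_low, 1L)
  expect_equal(gt$n_sites_high, 2L)
  expect_equal(gt$n_sites_low, 2L)
  expect_equal(gt$mean_density_high, 60)
  expect_equal(gt$n_mut_total, 2L)
})
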