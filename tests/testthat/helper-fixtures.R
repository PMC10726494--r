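# Shared fixtures. The default simulation is generated once per test run
# and memoised; every consumer sees the same seeded dataset.

.fixture_env <- new.env(parent = emptyenv())

# Full default-scale simulation plus profiles and the analysis table.
default_fixture <- function() {
  if (is.null(.fixture_env$fx)) {
    cfg <- synthetic_config(seed = 101L)
    sim <- simulate_dataset(cfg)
    prof <- segment_profiles(sim$sites, sim$segments)
    tab <- build_analysis_table(prof, sim$variants, sim$genes, sim$de,
                                focal = cfg$focal_strain,
                                reference = cfg$reference_strain,
                                states = sim$states,
                                accessibility = sim$accessibility)
    .fixture_env$fx <- list(cfg = cfg, sim = sim, prof = prof, tab = tab,
                            gt = aggregate_by_gene(tab))
  }
  .fixture_env$fx
}

# A small, fast simulation for pipeline-level tests.
small_config <- function(seed = 7L, ...) {
  synthetic_config(
    seed = seed,
    density_spectrum = data.frame(density = c(5, 20, 35, 50, 90),
                                  n_segments = c(24, 24, 16, 16, 16)),
    ...)
}

# Minimal site table with two strains; counts chosen so every site is
# callable and states are unambiguous.
tiny_site_table <- function() {
  data.frame(chrom = "chr1", pos = c(3L, 11L, 25L, 33L), strand = "+",
             context = "CG",
             a.mc = c(9L, 0L, 8L, 0L), a.cov = c(10L, 10L, 10L, 10L),
             b.mc = c(9L, 9L, 0L, 0L), b.cov = c(10L, 10L, 10L, 10L),
             stringsAsFactors = FALSE)
}

# Profiles-like table built directly from call vectors, for conservation
# tests that bypass read counts. calls_a/calls_b may contain NA.
calls_profile <- function(calls_a, calls_b, seg_id, density,
                          strains = c("a", "b")) {
  stopifnot(length(calls_a) == length(calls_b),
            length(seg_id) == length(calls_a))
  x <- data.frame(chrom = "chr1", pos = seq_along(calls_a), seg_id = seg_id,
                  density = density, bin = floor(density),
                  stringsAsFactors = FALSE)
  x[[paste0(strains[1], ".call")]] <- as.integer(calls_a)
  x[[paste0(strains[2], ".call")]] <- as.integer(calls_b)
  attr(x, "strains") <- strains
  attr(x, "params") <- list(min_cov = 5, min_frac = 0.1, bin_width = 1)
  x
}

# QC fixture: one passing record plus one record straddling each boundary
# on each side (12 records total).
qc_fixture <- function() {
  base <- data.frame(cell = "ok", mccc = 0.01, mcg = 0.7, mch = 0.1,
                     mapped_reads = 5e5, mapping_rate = 0.8,
                     genome_coverage_pct = 5, stringsAsFactors = FALSE)
  tweak <- function(id, col, val) {
    r <- base; r$cell <- id; r[[col]] <- val; r
  }
  rbind(base,
        tweak("mccc_at", "mccc", 0.03), tweak("mccc_hi", "mccc", 0.05),
        tweak("mcg_at", "mcg", 0.5), tweak("mcg_lo", "mcg", 0.4),
        tweak("mch_at", "mch", 0.2), tweak("mch_hi", "mch", 0.25),
        tweak("reads_at", "mapped_reads", 1e5),
        tweak("reads_lo", "mapped_reads", 5e4),
        tweak("maprate_at", "mapping_rate", 0.5),
        tweak("cov_at", "genome_coverage_pct", 2),
        tweak("cov_lo", "genome_coverage_pct", 1))
}
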