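# Configuration of the synthetic-data generator. The defaults are the study
# conditions every downstream check runs under (a scaled-down genome whose
# statistical structure mirrors the published magnitudes: methylation
# fractions 0.9/0.5/0.15 with breakpoints at 25 and 40 CpG/Kb, pairwise
# same-state ~0.8 below 40 with count conservation, site conservation above,
# mutation-rate reversal at 40, and a mutation effect on expression of 0.16
# confined to high-density candidates). They are overridable but are chosen
# once, not tuned per run.

#' Configuration for the synthetic-data generator
#'
#' @param seed master seed (mandatory); per-layer child seeds are derived
#'   with [child_seed()] so regenerating one layer never perturbs another.
#' @param n_chrom number of chromosomes.
#' @param window segment size in bp.
#' @param density_spectrum data.frame with `density` (target CpG/Kb per
#'   segment) and `n_segments`; segment targets are shuffled across the
#'   genome. Total segments must be a multiple of `2 * n_chrom` (one gene
#'   per two segments).
#' @param meth_levels methylation probabilities of the three density
#'   fractions, named `low`, `mid`, `high`.
#' @param meth_breaks the two density breakpoints (CpG/Kb) separating the
#'   fractions: `low` below the first, `mid` up to the second (inclusive),
#'   `high` above.
#' @param strains strain names; the first is the reference (no variants
#'   relative to the reference genome).
#' @param reference_strain,focal_strain,outgroup roles used downstream.
#' @param concordance target cross-strain same-state probability below the
#'   second breakpoint, realized by count-conserving resampling (equal
#'   methylated counts, sites shuffled).
#' @param retention named per-strain probabilities of retaining each
#'   reference-methylated site above the second breakpoint
#'   (site-conserving copying without compensation; losses lower the count
#'   ratio while kept sites still agree).
#' @param coverage_mean,coverage_disp negative-binomial read-depth model
#'   per site per strain (mean and size).
#' @param read_meth_frac,read_error_frac expected methylated-read fraction
#'   at truly methylated / truly unmethylated sites.
#' @param mutation_rates variant probabilities at CpG sites versus density
#'   regime and the site's true methylation state, named `meth_low`,
#'   `unmeth_low`, `meth_high`, `unmeth_high` (the low/high split is at
#'   `mutation_break`).
#' @param mutation_break density (CpG/Kb) separating the two mutation-rate
#'   regimes; also the true change point of the expression effect.
#' @param background_variant_rate per-bp rate of non-CpG (non-C) variants.
#' @param beta_high,beta_low expression effect (log2 fold change units) per
#'   candidate mutation in high / low density DNA.
#' @param density_slope effect of mean CpG density on log2 fold change.
#' @param noise_sd standard deviation of per-gene expression noise. The
#'   default of 1 puts the raw log2FC scale close to the inverse-normal
#'   scale, so fitted coefficients are comparable to the generating betas.
#' @param structural_fraction probability that each candidate mutation is
#'   accompanied by a linked structural variant; a gene carrying at least
#'   one linked variant receives the large negative structural effect, so
#'   heavily mutated genes are more often structural (as linked indels and
#'   larger rearrangements are in real strain comparisons).
#' @param structural_effect log2FC shift of those genes (default -4, i.e.
#'   well beyond a 2-fold change).
#' @param enhancer_effect if TRUE, only candidates in "Active enhancers" in
#'   high-density DNA carry an expression effect (`beta_enhancer`); all
#'   other candidates carry none.
#' @param beta_enhancer per-mutation effect in the enhancer-targeted mode.
#' @param state_p_low,state_p_high chromatin-state probabilities per
#'   segment for low/high density segments, over the 15-state vocabulary.
#' @return A validated list of class `cpgdm_config`.
#' @export
synthetic_config <- function(
    seed,
    n_chrom = 4L,
    window = 2000L,
    density_spectrum = data.frame(
      density = c(5, 10, 15, 20, 25, 30, 35, 40, 45, 50, 60, 70, 80, 90,
                  100, 110, 120),
      n_segments = c(1150, 1000, 600, 352, 250, 180, 130, 90, 60, 50, 40,
                     30, 24, 20, 16, 6, 2)),
    meth_levels = c(low = 0.9, mid = 0.5, high = 0.15),
    meth_breaks = c(25, 40),
    strains = c("b6", "aj", "balb", "cast", "d2", "fvb", "pwk", "wsb"),
    reference_strain = "b6", focal_strain = "d2", outgroup = "cast",
    concordance = 0.8,
    retention = c(b6 = 1, aj = 0.85, balb = 0.8, cast = 0.75, d2 = 0.7,
                  fvb = 0.9, pwk = 0.65, wsb = 0.72),
    coverage_mean = 20, coverage_disp = 5,
    read_meth_frac = 0.8, read_error_frac = 0.01,
    mutation_rates = c(meth_low = 0.15, unmeth_low = 0.05,
                       meth_high = 0.12, unmeth_high = 0.18),
    mutation_break = 40,
    background_variant_rate = 2e-4,
    beta_high = 0.16, beta_low = 0, density_slope = 0, noise_sd = 1,
    structural_fraction = 0.01, structural_effect = -4,
    enhancer_effect = FALSE, beta_enhancer = 0.4,
    state_p_low = c("Active enhancers" = 0.05, "Bivalent promoters" = 0.02,
                    "DNAase open chromatin" = 0.07, "Heterochromatin" = 0.10,
                    "Polycomb repressed" = 0.05,
                    "Polycomb repressed and open chromatin" = 0.03,
                    "Promoter flank" = 0.03, "Quiescent" = 0.17,
                    "Transcribed enhancers" = 0.05, "Transcription" = 0.15,
                    "Transcription and exons" = 0.05,
                    "Transcription start sites" = 0.01,
                    "Weak enhancers" = 0.12, "Weak transcription" = 0.08,
                    "Zinc finger genes" = 0.02),
    state_p_high = c("Active enhancers" = 0.35, "Bivalent promoters" = 0.06,
                     "DNAase open chromatin" = 0.10, "Heterochromatin" = 0.01,
                     "Polycomb repressed" = 0.04,
                     "Polycomb repressed and open chromatin" = 0.04,
                     "Promoter flank" = 0.06, "Quiescent" = 0.02,
                     "Transcribed enhancers" = 0.06, "Transcription" = 0.05,
                     "Transcription and exons" = 0.04,
                     "Transcription start sites" = 0.10,
                     "Weak enhancers" = 0.04, "Weak transcription" = 0.02,
                     "Zinc finger genes" = 0.01)) {
  if (missing(seed)) fail("seed is mandatory")
  cfg <- as.list(environment())
  validate_config(cfg)
  structure(cfg, class = "cpgdm_config")
}

validate_config <- function(cfg) {
  with(cfg, {
    if (!is.numeric(seed) || length(seed) != 1L) fail("seed must be one integer")
    if (any(density_spectrum$density > 500))
      fail("target density > 500 CpG/Kb is physically impossible (CpGs span 2 bp)")
    if (any(density_spectrum$density < 0) || any(density_spectrum$n_segments < 0))
      fail("density spectrum entries must be non-negative")
    n_seg <- sum(density_spectrum$n_segments)
    if (n_seg %% (2L * n_chrom) != 0L)
      fail("total segments (%d) must be a multiple of 2 * n_chrom", n_seg)
    if (is.unsorted(meth_breaks, strictly = TRUE)) fail("meth_breaks must increase")
    rates <- c(meth_levels, concordance, retention, read_meth_frac,
               read_error_frac, mutation_rates, background_variant_rate,
               structural_fraction)
    if (any(rates < 0 | rates > 1)) fail("all rates must lie in [0, 1]")
    if (!all(strains %in% names(retention))) fail("retention must name every strain")
    if (!all(c(reference_strain, focal_strain, outgroup) %in% strains))
      fail("reference/focal/outgroup must be among strains")
    for (p in list(state_p_low, state_p_high)) {
      if (!setequal(names(p), chromatin_state_groups()))
        fail("state palettes must cover the 15-state vocabulary")
      if (abs(sum(p) - 1) > 1e-8) fail("state palette must sum to 1")
    }
  })
  invisible(cfg)
}
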