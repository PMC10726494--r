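---
title: "CpG density, methylation conservation, and mutation effects: models and design"
author: "cpgdm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CpG density, methylation conservation, and mutation effects: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The scientific question

CpG methylation is copied through cell division and generally represses
transcription, so a mutation that destroys a methylated CpG can
de-repress a gene. Whether it *does* turns out to depend on the local
density of CpG dinucleotides. In CpG-sparse DNA (< 40 CpG per kilobase)
cells maintain the *amount* of methylation in a region — if one site is
lost, another is methylated in its place — so losing any single site is
inconsequential. In CpG-dense DNA the *identity* of methylated sites is
maintained, and destroying one measurably shifts transcript abundance.
`cpgdm` implements the full analysis chain that establishes and exploits
this distinction for variant prioritization between inbred mouse strains,
plus a seeded synthetic-data generator with a ground-truth ledger so every
stage can be validated end to end.

The pipeline: per-site bisulfite count tables (allc-style) for several
strains → 2-kb genome segmentation and CpG density → per-site methylation
calls → density curves and pairwise cross-strain conservation statistics →
candidate methylated-CpG-disrupting variants → inverse-normal-transformed
linear models of differential expression with permutation calibration,
chromatin-state stratification and sensitivity sweeps. `run_full()`
composes the stages deterministically under one seed.

# Core statistics

**Methylation calling.** A site needs ≥ 5 reads to be callable; with
coverage it is called methylated when ≥ 10% of reads are methylated, else
explicitly unmethylated (`call_methylation()`). Both thresholds are the
published analysis values and are configurable. Coverage imbalance between
two strains is corrected per 2-kb segment by Bernoulli-thinning the
methylated counts of the deeper strain at the coverage ratio
(`downsample_segment()`); "proportional random reduction" does not pin down
a distribution, and independent per-read thinning is the
minimal-assumption choice. Thinning is seeded, never increases a count,
and leaves the shallower strain untouched.

**Conservation.** For each segment and strain pair, two statistics are
computed on sites callable in both strains: the *same-state probability*
(fraction of sites with identical calls — `prop_occurrence()` returns the
both-methylated and both-unmethylated components separately, and the
plotted probability is their sum) and the *methylated-count ratio*
min(n₁,n₂)/max(n₁,n₂), which is 1 when the two strains methylate equally
many sites regardless of which. Pooling by integer density bin
(`aggregate_by_density()`) concatenates the member segments' site vectors
rather than averaging per-segment values; the brute-force equivalence of
the two is a tested invariant. Ratio ≈ 1 with probability ≈ 0.8 below 40
CpG/Kb is the count-conservation signature; the ordering reverses in dense
DNA, where the probability stays high while the ratio drops.

**Candidate mutations.** A candidate is a site called methylated in the
reference strain where the focal strain carries `A` or `T` at the C —
bases that cannot be methylated on either strand. The orientation is a
genuinely open reading of the source analysis; the default
(`direction = "reference_methylated"`) is chosen so that, with methylation
repressive, candidates are expected to *raise* the focal:reference
expression ratio; the literal alternative is one switch away and the
orientation used is logged on every output. Sites are matched to genes via
intervals from 2 kb upstream of the transcript start to 2 kb downstream of
the 3′ end (symmetric, strand-independent); a site in several intervals
yields one record per gene.

**Models.** The response is the inverse-normal transform
`qnorm((rank - 0.5)/n)` of the per-gene log2 fold change; ties get average
ranks and missing values stay in place. Within a density class the model
is `invnorm(log2FC) ~ mutation + density`; across classes the
density-by-mutation interaction is tested by a nested-model F test
(`anova(fit0, fit1)`) with chromosome, position and chromatin-state
annotation as covariates.

## Gene-level versus site-level designs

The literal design has one row per site with the gene's fold change
duplicated across all of its sites. Duplicated responses are
cluster-correlated, so site-level parametric standard errors are
anti-conservative — which is exactly why the original analysis leaned on
gene-level permutation to check its p-values. `cpgdm` therefore defaults
to a gene-level design: one row per gene, mutation entering as the
per-gene count of candidates (the interaction term is the count of
*high-density* candidates added over the total count, i.e. the extra
effect of a high-density mutation). Under this design the F test is exact
under the null, confidence intervals attain nominal coverage, and the
permutation p agrees with the parametric p. The site-level formulation is
retained (`unit = "site"`) for fidelity, with the caveat that only its
permutation p-value (`permutation_calibration()`, gene-block permutation,
add-one convention `(b+1)/(n+1)`) is calibrated.

## Sensitivity sweeps and the change point

`sweep_density_threshold()` refits the interaction at every integer
threshold (default 14–60 CpG/Kb), recording the effect estimate and p per
threshold. One subtlety: when every candidate above the true breakpoint
carries the full effect — as in the synthetic generator — the effect
*estimate* plateaus for all thresholds at or above the breakpoint (the
retained candidates still carry the full effect; only their number
shrinks), while the F statistic peaks at the breakpoint, where all signal
carriers are captured at maximal precision. `sweep_change_point()`
therefore locates the change point at the F maximum (equivalently the p
minimum); in the source analysis the peak effect size and the most
significant interaction coincide, so the two estimators agree there.

`sweep_transcript_filter()` varies the |log2FC| inclusion cutoff (0.2–8)
and optionally a DE p-value cutoff. The default pipeline keeps *all*
transcripts (`log2fc_max = Inf`): excluding transcripts by the size of the
response truncates the fold-change distribution in a mutation-correlated
way and attenuates the fitted mutation effect (measurably, ~25% at a
2-fold cutoff on synthetic data), so the cutoff's impact is reported by
the sweep rather than baked into the headline fit. The complementary
large-|FC| set is fitted separately with a mutation term alone; under the
generator (and in the source data) that term is negative, because large
fold changes are dominated by linked structural variation rather than
methylation loss.

**Chromatin-state scan.** For each of the 15 universal chromatin-state
groups crossed with high/low density, the scan counts mutated and
unmutated sites and fits the mutation term per cell. Cells with zero
mutated sites report a missing p-value, not 1. Two multiple-testing
conventions are reported side by side: the published threshold 0.001 for
2 × 15 tests, and α/30 ≈ 0.00167; the 0.001 flag is the default. State
labels can be gated on open-chromatin support (≥ 10 pooled reads at the
site) when an accessibility table is supplied, and are dropped otherwise
unfiltered.

# What the generator emulates

`synthetic_config()` fixes the study conditions once; the defaults are
magnitudes echoing the published analysis, not fitted quantities, and are
deliberately not revisited per run:

* **Genome**: 4 chromosomes, 4,000 segments of 2 kb (8 Mb), with a
  density spectrum from 5 to 120 CpG/Kb skewed toward sparse DNA
  (~135,000 CpGs). CpGs are placed uniformly at odd offsets on an A/T
  background, so the realized landscape is exactly the placed sites and a
  segment can hold at most 500 CpG/Kb.
* **Methylation**: three-fraction curve — methylation probability 0.9
  below 25 CpG/Kb, 0.5 between 25 and 40, 0.15 above 40. Cross-strain
  structure: below 40, count-conserving resampling (same number
  methylated per segment, sites relocated to hit a same-state target of
  0.8); above 40, site-conserving copying with per-strain retention
  0.65–1.0 and no compensation. Reads: negative-binomial coverage (mean
  20, size 5), methylated-read fraction 0.8 at true-methylated sites and
  0.01 otherwise.
* **Variants**: C-disrupting alleles at CpG sites at rates 0.15
  (methylated) vs 0.05 (unmethylated) below 40 CpG/Kb and 0.12 vs 0.18
  above — the mutation-spectrum reversal. The absolute scale is chosen so
  this scaled-down genome carries a few hundred high-density candidates,
  reproducing the precision regime of the published analysis (~1,862 high
  mutations) at 2,000 genes. Background non-C variants exercise the
  exclusion paths.
* **Expression**: 2,000 genes (one per 4 kb); log2FC = 0.16 × (high
  candidates in the gene interval) + 0 × (low candidates) + N(0, 1)
  noise. Noise SD 1 makes the inverse-normal scale coincide with the raw
  scale, so the generating effect is directly recoverable from the
  transformed fit. Each candidate drags a linked structural variant with
  probability 0.01; affected genes get −4 log2FC, mimicking linked
  indels/rearrangements. DE p-values come from the noise model and are
  uniform for null genes. The enhancer-targeted mode moves the whole
  effect (0.4 per mutation) onto candidates in "Active enhancers" ×
  high density — larger per mutation because the same aggregate signal is
  concentrated in ~a third of the high-density candidates.
* **Chromatin states**: one of the 15 state groups per segment, drawn
  from a density-dependent palette (dense DNA enriched for
  enhancer/promoter states, sparse DNA for quiescent/heterochromatin).

A single master seed fans out to per-layer child seeds (`child_seed()`),
so the expression layer can be redrawn thousands of times over a fixed
genome/methylome/variant structure. The calibration, recovery, power and
change-point replicates in the test-suite do exactly that; expression
noise is the dominant stochastic term for those statistics, and the fixed
structure is itself one seeded draw from the generator.

**What it does not emulate.** Read-level artifacts (bisulfite conversion
failure beyond a constant error rate, mapping bias, PCR duplicates),
cell-type mixtures, CH methylation dynamics, linkage disequilibrium
between variants, real gene-length and density covariance, and the loss
of methylation reads at sites a strain has actually mutated away (the
generator reports counts at all reference coordinates). Passing tests
therefore demonstrate that the statistical machinery recovers the
structure it is pointed at — not that real snmC-seq data meet these
idealizations.

# Validation design choices

* **Parameter recovery conditions on the truth ledger.** Recovery of the
  high-class effect uses the generative design matrix (true candidate
  counts) and excludes genes the ledger marks structural. Excluding them
  by observed |log2FC| instead would truncate the response in a
  mutation-correlated way and bias the estimate; conditioning on the
  known truth is the standard for recovery simulations. The low-class
  check additionally restricts to genes without high-density candidates
  so the known high-density effect cannot leak into the low-class term.
  End-to-end fits (called states, observed counts) are attenuated a few
  percent by calling noise and by the structural layer — visible in the
  pipeline's own headline coefficients, and the reason the recovery
  estimand is defined against the truth.
* **Null calibration** redraws expression with both effects at zero and
  checks a 5% rejection rate at α = 0.05 plus Kolmogorov–Smirnov
  uniformity of permutation p-values.
* **Enhancer targeting** replicates drop truth-structural genes before
  the scan: linked structural variation otherwise bleeds a (real)
  mutation-correlated signal into every state cell, which is precisely
  why the original analysis excluded large-effect transcripts.
* **Degenerate inputs** are contracts, not accidents: empty call vectors
  and mismatched lengths are errors in `prop_occurrence()`; a 0/0 count
  ratio is undefined and excluded from pooling; thresholds that empty a
  density class are reported inestimable, never silently dropped; a
  missing QC metric is "incomplete", counted apart from threshold
  failures; truncated 5-bp contexts are N-padded, never dropped.

# Coordinates, ties and other conventions

Site tables are 1-based (allc convention); genes, chromatin states and
segments are 0-based half-open (BED/refGene convention); a CpG at 1-based
position *p* falls in segment [start, end) when start ≤ *p*−1 < end.
A symmetric CpG is keyed by its forward-strand C; readers never merge
strands implicitly (`collapse_strands()` is explicit) because the
original strand treatment is unstated. Density bins are integer floors of
CpG/Kb, matching the published figure resolution; "high density" means
strictly greater than 40 CpG/Kb, so exactly 40 is low. Trailing partial
windows are kept with their true-length density unless `drop_partial` is
set. Exactly 10% methylated reads is called methylated (≥, not >). All
stochastic steps take explicit seeds and two runs of `run_full()` with
the same configuration agree byte-for-byte on every TSV output.

# Problem sizes

The default synthetic conditions — 8 Mb, ~135,000 CpGs, 8 strains, 2,000
genes, ~11,000 candidate mutations of which ~800 are high-density — are
the sizes at which the test-suite and the acceptance script run their
replicates (1,000 null draws, 100 recovery draws, 2,000 permutations, 50
enhancer-scan draws, 10 change-point sweeps). They scale the mouse genome
down ~300-fold while preserving the per-coefficient precision of the
published high-density analysis, which is what the power and recovery
properties depend on.

# Limitations

Parametric p-values from site-level fits remain anti-conservative by
construction and should be read only alongside their permutation
calibration. The change-point estimator assumes a single breakpoint; a
gradual density response would spread the F profile. The generator's
concordance target applies to reference–strain pairs; pairs of two
non-reference strains are less concordant below the breakpoint (their
relocations are independent), so pooled statistics for such pairs sit
below the configured target. Gene-level aggregation discards
within-gene positional information; if several candidate mutations in one
gene had opposing effects, the count model would average them away.
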