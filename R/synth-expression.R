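# Ground-truth candidate structure per gene and the expression generator.

#' Ground-truth candidate-mutation structure per gene
#'
#' Uses the *true* methylation states and variant assignments (not the
#' called ones) to count, per flanked gene interval, the candidate
#' mutations — sites truly methylated in the reference strain where the
#' focal strain carries a disrupting allele — in high and low density DNA,
#' and those falling in "Active enhancers" high-density segments.
#'
#' @param config a [synthetic_config()].
#' @param ref output of [generate_reference()].
#' @param methylomes output of [generate_strain_methylomes()].
#' @param variant_truth the `truth` component of [generate_variants()].
#' @param genes gene models from [synthetic_gene_models()].
#' @param states optional chromatin-state track (needed for the enhancer
#'   counts; otherwise `n_enh_high` is 0).
#' @param flank gene-interval flank in bp.
#' @return data.frame: `gene`, `n_high`, `n_low`, `n_enh_high`, `n_sites`,
#'   `n_sites_high`, `n_sites_low`, `mean_density`, `mean_density_high`,
#'   `mean_density_low`. Renaming `n_high`/`n_low` to
#'   `n_mut_high`/`n_mut_low` makes the table a drop-in gene-level design
#'   for [fit_within_class_model()] and [interaction_anova()].
#' @export
gene_mutation_structure <- function(config, ref, methylomes, variant_truth,
                                    genes, states = NULL, flank = 2000) {
  cpg <- ref$cpg
  focal_var <- variant_truth[variant_truth$strain == config$focal_strain &
                               variant_truth$at_cpg, , drop = FALSE]
  is_cand <- methylomes$truth[, config$reference_strain] &
    paste(cpg$chrom, cpg$pos) %in% paste(focal_var$chrom, focal_var$pos)
  high <- cpg$density > config$mutation_break
  enh <- rep(FALSE, nrow(cpg))
  if (!is.null(states)) {
    h <- overlap_sites(cpg, states, "start", "end")
    h <- h[!duplicated(h$site_row), , drop = FALSE]
    enh[h$site_row] <- states$state[h$iv_row] == "Active enhancers"
  }
  gi <- gene_interval(genes, flank = flank)
  hits <- overlap_sites(cpg, gi)
  g <- factor(gi$gene[hits$iv_row], levels = genes$gene)
  agg <- function(v) rowsum(as.numeric(v[hits$site_row]), g)[, 1L]
  n_sites <- as.vector(table(g))
  n_sh <- agg(high)
  out <- data.frame(gene = genes$gene,
                    n_high = as.integer(agg(is_cand & high)),
                    n_low = as.integer(agg(is_cand & !high)),
                    n_enh_high = as.integer(agg(is_cand & high & enh)),
                    n_sites = n_sites,
                    n_sites_high = as.integer(n_sh),
                    n_sites_low = as.integer(n_sites - n_sh),
                    mean_density = agg(cpg$density) / pmax(n_sites, 1L),
                    mean_density_high = ifelse(
                      n_sh > 0, agg(cpg$density * high) / pmax(n_sh, 1),
                      NA_real_),
                    mean_density_low = ifelse(
                      n_sites - n_sh > 0,
                      agg(cpg$density * !high) / pmax(n_sites - n_sh, 1),
                      NA_real_),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Ground-truth gene-level design table
#'
#' Joins the candidate structure to a differential-expression table and
#' renames the truth columns to the gene-level design vocabulary, giving
#' the generative design matrix for parameter-recovery checks (no
#' methylation-calling noise).
#'
#' @param structure output of [gene_mutation_structure()].
#' @param de a DE table (`gene`, `log2FoldChange`, `pvalue`).
#' @return Gene-level design data.frame usable by
#'   [fit_within_class_model()].
#' @export
truth_gene_table <- function(structure, de) {
  out <- data.frame(gene = structure$gene,
                    n_mut_high = structure$n_high,
                    n_mut_low = structure$n_low,
                    n_mut_total = structure$n_high + structure$n_low,
                    n_sites_high = structure$n_sites_high,
                    n_sites_low = structure$n_sites_low,
                    mean_density_high = structure$mean_density_high,
                    mean_density_low = structure$mean_density_low,
                    mean_density = structure$mean_density,
                    stringsAsFactors = FALSE)
  i <- match(out$gene, de$gene)
  out$log2fc <- de$log2FoldChange[i]
  out$de_p <- de$pvalue[i]
  out
}

#' Generate a differential-expression table from the candidate structure
#'
#' Per gene, the log2 fold change (focal:reference) is
#' `beta_high * n_high + beta_low * n_low + density_slope * mean_density`
#' plus Gaussian noise; with `enhancer_effect` the systematic part is
#' `beta_enhancer * n_enh_high` instead. Each candidate mutation carries a
#' linked structural variant with probability `structural_fraction`; genes
#' with at least one linked variant receive the large negative
#' `structural_effect`, mimicking linked indels/rearrangements that depress
#' transcripts (so heavily mutated genes are more often structural).
#' P-values come from the noise model
#' (`2 * pnorm(-|log2FC| / noise_sd)`), so they are uniform for null genes.
#'
#' Because only the expression layer is redrawn, this function is cheap to
#' replicate over a fixed genome/methylome/variant structure, which is how
#' the null-calibration and parameter-recovery checks are run.
#'
#' @param config a [synthetic_config()].
#' @param structure per-gene table from [gene_mutation_structure()].
#' @param seed optional child-seed override.
#' @return List: `de` (`gene`, `log2FoldChange`, `pvalue`) and `truth`
#'   (per-gene components: `mu`, `structural`, `noise`).
#' @export
generate_expression <- function(config, structure, seed = NULL) {
  if (is.null(seed)) seed <- child_seed(config$seed, "expression")
  if (!nrow(structure)) fail("no genes overlap any segment")
  mu <- if (isTRUE(config$enhancer_effect))
    config$beta_enhancer * structure$n_enh_high
  else
    config$beta_high * structure$n_high + config$beta_low * structure$n_low
  mu <- mu + config$density_slope * structure$mean_density
  with_seed(seed, {
    # each candidate mutation independently drags a linked structural
    # variant along with probability structural_fraction
    p_struct <- 1 - (1 - config$structural_fraction) ^
      (structure$n_high + structure$n_low)
    structural <- runif(nrow(structure)) < p_struct
    noise <- rnorm(nrow(structure), 0, config$noise_sd)
  })
  log2fc <- mu + ifelse(structural, config$structural_effect, 0) + noise
  p <- 2 * pnorm(-abs(log2fc) / config$noise_sd)
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  list(de = data.frame(gene = structure$gene, log2FoldChange = log2fc,
                       pvalue = p, stringsAsFactors = FALSE),
       truth = data.frame(gene = structure$gene, mu = mu,
                          structural = structural, noise = noise,
                          stringsAsFactors = FALSE))
}

#' Generate a complete synthetic dataset
#'
#' Runs every generator layer under child seeds fanned out from the master
#' seed: reference genome, strain methylomes, variants, chromatin states,
#' gene models, accessibility and the expression table, together with the
#' ground-truth ledger needed to recompute every generated quantity.
#'
#' @param config a [synthetic_config()].
#' @return List with `config`, `genome`, `chrom_sizes`, `segments`, `cpg`,
#'   `sites`, `variants`, `genes`, `states`, `accessibility`, `de`,
#'   `gene_structure` and `truth` (`states_true`, `variants`, `gene`).
#' @export
simulate_dataset <- function(config) {
  validate_config(config)
  ref <- generate_reference(config)
  meth <- generate_strain_methylomes(config, ref)
  vars <- generate_variants(config, ref, meth)
  states <- generate_chromatin_states(config, ref)
  genes <- synthetic_gene_models(config, ref)
  acc <- generate_accessibility(config, ref)
  gstruct <- gene_mutation_structure(config, ref, meth, vars$truth, genes,
                                     states)
  expr <- generate_expression(config, gstruct)
  list(config = config, genome = ref$genome, chrom_sizes = ref$chrom_sizes,
       segments = ref$segments, cpg = ref$cpg, sites = meth$sites,
       variants = vars$variants, genes = genes, states = states,
       accessibility = acc, de = expr$de, gene_structure = gstruct,
       truth = list(states_true = meth$truth, variants = vars$truth,
                    gene = expr$truth))
}

#' Write a synthetic dataset to disk in standard formats
#'
#' Emits FASTA (genome), TSV (site table, variant table, accessibility,
#' ground-truth ledgers), refGene-style flat gene models, BED4 chromatin
#' states, BED6 segments with density scores, and a DESeq2-style CSV — all
#' of which re-validate through the package readers.
#'
#' @param sim output of [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    genome = file.path(dir, "genome.fa"),
    sites = file.path(dir, "sites.tsv"),
    variants = file.path(dir, "variants.tsv"),
    genes = file.path(dir, "genes.txt"),
    states = file.path(dir, "states.bed"),
    segments = file.path(dir, "segments.bed"),
    de = file.path(dir, "de.csv"),
    accessibility = file.path(dir, "accessibility.tsv"),
    truth_gene = file.path(dir, "truth_gene.tsv"),
    truth_variants = file.path(dir, "truth_variants.tsv"))
  write_genome_fasta(sim$genome, paths["genome"])
  write_site_table(sim$sites, paths["sites"])
  write_variant_table(sim$variants, paths["variants"])
  flat <- data.frame(0L, sim$genes$gene, sim$genes$chrom, sim$genes$strand,
                     sim$genes$txStart, sim$genes$txEnd)
  write.table(flat, paths["genes"], sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write_bed(sim$states, paths["states"])
  write_bed(sim$segments, paths["segments"])
  write_de_results(sim$de, paths["de"])
  write.table(sim$accessibility, paths["accessibility"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  tg <- merge(sim$gene_structure, sim$truth$gene, by = "gene")
  write.table(tg, paths["truth_gene"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(sim$truth$variants, paths["truth_variants"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(paths)
}
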