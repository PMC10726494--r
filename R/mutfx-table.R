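# Candidate-mutation selection and the per-site / per-gene analysis tables
# feeding the mutation-expression models.

#' Classify CpG density as high or low
#'
#' High density means strictly greater than the threshold (a density exactly
#' at the threshold is low). The 40 CpG/Kb default is the inflection point
#' of the methylation-vs-density curve; the threshold is configurable for
#' sensitivity sweeps.
#'
#' @param density numeric CpG/Kb values.
#' @param threshold class boundary (default 40).
#' @return Character vector `"high"`/`"low"`.
#' @export
classify_density <- function(density, threshold = 40) {
  if (any(density < 0, na.rm = TRUE)) fail("negative density")
  ifelse(density > threshold, "high", "low")
}

#' Extend gene spans into flanked gene intervals
#'
#' The interval runs from `flank` bp upstream of the transcript start to
#' `flank` bp downstream of the transcript end. Flanks are symmetric, so
#' strand does not change the result; intervals are clamped at chromosome
#' bounds when sizes are supplied.
#'
#' @param genes gene models (see [read_gene_models()]).
#' @param flank bp added on both sides (default 2000).
#' @param chrom_sizes optional named lengths for clamping.
#' @return `genes` with `int_start`, `int_end` columns (0-based half-open).
#' @export
gene_interval <- function(genes, flank = 2000, chrom_sizes = NULL) {
  genes$int_start <- pmax(genes$txStart - flank, 0L)
  genes$int_end <- genes$txEnd + flank
  if (!is.null(chrom_sizes)) {
    lim <- chrom_sizes[genes$chrom]
    if (anyNA(lim)) fail("gene chrom missing from chrom_sizes")
    genes$int_end <- pmin(genes$int_end, as.integer(lim))
  }
  genes
}

# Map 1-based site positions onto 0-based half-open intervals.
# Returns a hits data.frame (site_row, iv_row).
overlap_sites <- function(sites, intervals, start_col = "int_start",
                          end_col = "int_end") {
  gr_s <- GenomicRanges::GRanges(sites$chrom,
                                 IRanges::IRanges(sites$pos, sites$pos))
  gr_i <- GenomicRanges::GRanges(intervals$chrom,
                                 IRanges::IRanges(intervals[[start_col]] + 1L,
                                                  intervals[[end_col]]))
  h <- GenomicRanges::findOverlaps(gr_s, gr_i)
  data.frame(site_row = S4Vectors::queryHits(h), iv_row = S4Vectors::subjectHits(h))
}

#' Select candidate methylated-CpG-disrupting mutations
#'
#' A candidate site carries a called-methylated CpG in one strain of the
#' pair while the other strain's allele at the C is `A` or `T` — bases that
#' cannot be methylated on either strand, so the mutation removes the
#' methylation substrate regardless of strand. By default the methylated
#' CpG is required in the *reference* strain and the disrupting allele in
#' the *focal* strain, so that (with methylation acting as a repressive
#' mark) candidate mutations are expected to raise the focal:reference
#' expression ratio; `direction = "focal_methylated"` implements the
#' opposite assignment. Sites with a `G` or `C` focal allele are excluded.
#'
#' @param profiles profile table from [segment_profiles()] (sites outside
#'   all segments were already excluded there).
#' @param variants variant table with both strains' alleles.
#' @param focal,reference strain names (e.g. `"d2"`, `"b6"`).
#' @param direction which strain must carry the methylated CpG.
#' @param threshold high/low density boundary (CpG/Kb).
#' @param genes optional gene models; when given, each mutation yields one
#'   record per overlapping flanked gene interval (`gene = NA` when outside
#'   all intervals).
#' @param states optional chromatin-state track for the `state` column.
#' @param flank gene-interval flank (bp).
#' @return data.frame of mutation records: `chrom`, `pos`, `focal_allele`,
#'   `reference_allele`, `methylated`, `seg_id`, `density`, `class`,
#'   `gene`, `state`. Attribute `direction` logs the orientation used.
#' @export
candidate_mutations <- function(profiles, variants, focal, reference,
                                direction = c("reference_methylated",
                                              "focal_methylated"),
                                threshold = 40, genes = NULL, states = NULL,
                                flank = 2000) {
  direction <- match.arg(direction)
  meth_strain <- if (direction == "reference_methylated") reference else focal
  mut_strain <- if (direction == "reference_methylated") focal else reference
  call <- profiles[[paste0(meth_strain, ".call")]]
  if (is.null(call)) fail("no call column for strain '%s'", meth_strain)
  i <- match(paste(profiles$chrom, profiles$pos),
             paste(variants$chrom, variants$pos))
  allele <- variants[[mut_strain]][i]
  other <- variants[[meth_strain]][i]
  other[is.na(other)] <- "C"
  keep <- !is.na(call) & call == 1L & !is.na(allele) & allele %in% c("A", "T")
  out <- data.frame(chrom = profiles$chrom[keep], pos = profiles$pos[keep],
                    focal_allele = if (direction == "reference_methylated")
                      allele[keep] else other[keep],
                    reference_allele = if (direction == "reference_methylated")
                      other[keep] else allele[keep],
                    methylated = rep(1L, sum(keep)),
                    seg_id = profiles$seg_id[keep],
                    density = profiles$density[keep],
                    stringsAsFactors = FALSE)
  out$class <- classify_density(out$density, threshold)
  out$gene <- rep(NA_character_, nrow(out))
  if (!is.null(genes) && nrow(out)) {
    gi <- gene_interval(genes, flank = flank)
    h <- overlap_sites(out, gi)
    unhit <- setdiff(seq_len(nrow(out)), h$site_row)
    out <- rbind(out[unhit, , drop = FALSE],
                 transform(out[h$site_row, , drop = FALSE],
                           gene = gi$gene[h$iv_row]))
    out <- out[order(match(out$chrom, unique(profiles$chrom)), out$pos), ,
               drop = FALSE]
  }
  out$state <- rep(NA_character_, nrow(out))
  if (!is.null(states) && nrow(out)) {
    h <- overlap_sites(out, states, "start", "end")
    h <- h[!duplicated(h$site_row), , drop = FALSE]  # at most one label per site
    out$state[h$site_row] <- states$state[h$iv_row]
  }
  rownames(out) <- NULL
  attr(out, "direction") <- direction
  out
}

#' Build the per-site mutation-expression analysis table
#'
#' Rows are called-methylated CpG sites (in the strain designated by
#' `direction`) lying within flanked gene intervals of genes present in the
#' differential-expression table — one row per site-gene pair. Each row
#' carries the segment density, the high/low class, a 0/1 candidate-mutation
#' flag, the chromatin state (optionally gated on open-chromatin support),
#' and the gene's log2 fold change and p-value.
#'
#' @inheritParams candidate_mutations
#' @param genes gene models (required here).
#' @param de differential-expression table (`gene`, `log2FoldChange`,
#'   `pvalue`).
#' @param de_p_max keep genes with DE p-value below this (default 1 = all).
#' @param accessibility optional data.frame (`chrom`, `pos`, `reads`):
#'   chromatin states are only assigned at sites with at least
#'   `min_access_reads` pooled open-chromatin reads; skipped when NULL.
#' @param min_access_reads threshold for the accessibility gate (default 10).
#' @return Site-level data.frame with columns `gene`, `chrom`, `pos`,
#'   `seg_id`, `density`, `class`, `high`, `mutation`, `state`, `log2fc`,
#'   `de_p`. Attributes: `counts` (selection bookkeeping), `direction`,
#'   `threshold`.
#' @export
build_analysis_table <- function(profiles, variants, genes, de,
                                 focal, reference,
                                 direction = c("reference_methylated",
                                               "focal_methylated"),
                                 threshold = 40, states = NULL, flank = 2000,
                                 de_p_max = 1, accessibility = NULL,
                                 min_access_reads = 10) {
  direction <- match.arg(direction)
  meth_strain <- if (direction == "reference_methylated") reference else focal
  mut_strain <- if (direction == "reference_methylated") focal else reference
  call <- profiles[[paste0(meth_strain, ".call")]]
  meth <- !is.na(call) & call == 1L
  sites <- profiles[meth, c("chrom", "pos", "seg_id", "density")]
  i <- match(paste(sites$chrom, sites$pos),
             paste(variants$chrom, variants$pos))
  allele <- variants[[mut_strain]][i]
  sites$mutation <- as.integer(!is.na(allele) & allele %in% c("A", "T"))
  sites$class <- classify_density(sites$density, threshold)
  sites$high <- as.integer(sites$class == "high")
  sites$state <- NA_character_
  if (!is.null(states) && nrow(sites)) {
    h <- overlap_sites(sites, states, "start", "end")
    h <- h[!duplicated(h$site_row), , drop = FALSE]
    sites$state[h$site_row] <- states$state[h$iv_row]
    if (!is.null(accessibility)) {
      j <- match(paste(sites$chrom, sites$pos),
                 paste(accessibility$chrom, accessibility$pos))
      supported <- !is.na(j) & accessibility$reads[j] >= min_access_reads
      sites$state[!supported] <- NA_character_
    }
  }
  de <- de[!is.na(de$pvalue) & de$pvalue <= de_p_max, , drop = FALSE]
  gi <- gene_interval(genes[genes$gene %in% de$gene, , drop = FALSE],
                      flank = flank)
  h <- overlap_sites(sites, gi)
  out <- sites[h$site_row, , drop = FALSE]
  out$gene <- gi$gene[h$iv_row]
  k <- match(out$gene, de$gene)
  out$log2fc <- de$log2FoldChange[k]
  out$de_p <- de$pvalue[k]
  rownames(out) <- NULL
  attr(out, "counts") <- c(
    methylated_sites = nrow(sites),
    candidate_mutations = sum(sites$mutation),
    candidate_mutations_high = sum(sites$mutation & sites$high == 1L),
    rows = nrow(out),
    genes = length(unique(out$gene)))
  attr(out, "direction") <- direction
  attr(out, "threshold") <- threshold
  out
}

#' Aggregate the site-level analysis table to one row per gene
#'
#' Summing the candidate-mutation indicator within gene and density class
#' turns the site-level table into an independent-rows design: each gene
#' appears once, with its mutation counts, site counts, mean densities,
#' modal chromatin state, chromosome and representative position.
#'
#' @param table site-level table from [build_analysis_table()].
#' @return data.frame with one row per gene: `gene`, `chromosome`,
#'   `position`, `log2fc`, `de_p`, `n_sites_high`, `n_sites_low`,
#'   `n_mut_high`, `n_mut_low`, `n_mut_total`, `mean_density_high`,
#'   `mean_density_low`, `mean_density`, `state_mode`.
#' @export
aggregate_by_gene <- function(table) {
  g <- factor(table$gene)
  if (is.null(table$de_p)) table$de_p <- NA_real_
  if (is.null(table$state)) table$state <- NA_character_
  agg <- function(v) rowsum(as.numeric(v), g)[, 1L]
  n_high <- agg(table$high); n_all <- as.vector(table(g))
  first <- !duplicated(g)
  mdh <- agg(table$density * (table$high == 1L)) / pmax(n_high, 1)
  mdl <- agg(table$density * (table$high == 0L)) / pmax(n_all - n_high, 1)
  out <- data.frame(
    gene = levels(g),
    chromosome = table$chrom[first][order(g[first])],
    position = agg(table$pos) / n_all,
    log2fc = table$log2fc[first][order(g[first])],
    de_p = table$de_p[first][order(g[first])],
    n_sites_high = as.integer(n_high),
    n_sites_low = as.integer(n_all - n_high),
    n_mut_high = as.integer(agg(table$mutation * (table$high == 1L))),
    n_mut_low = as.integer(agg(table$mutation * (table$high == 0L))),
    mean_density_high = ifelse(n_high > 0, mdh, NA_real_),
    mean_density_low = ifelse(n_all - n_high > 0, mdl, NA_real_),
    mean_density = agg(table$density) / n_all,
    state_mode = vapply(split(table$state, g), function(s) {
      s <- s[!is.na(s)]; if (length(s)) mode_chr(s) else NA_character_
    }, character(1)),
    stringsAsFactors = FALSE)
  out$n_mut_total <- out$n_mut_high + out$n_mut_low
  rownames(out) <- NULL
  out
}
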