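# Synthetic genome, methylomes, variants, chromatin states and gene models.
#
# CpGs are placed at odd offsets within each segment on an A/T background,
# so the reference contains exactly the placed CpGs and nothing else; a
# segment of 2 kb can hold at most 1000 CpGs (500/Kb).

# density regime of realized densities: low < brk1 <= mid <= brk2 < high
density_regime <- function(density, breaks) {
  ifelse(density < breaks[1], "low",
         ifelse(density > breaks[2], "high", "mid"))
}

#' Generate the synthetic reference genome and CpG landscape
#'
#' Tiles `n_chrom` chromosomes into fixed-size segments, shuffles the
#' density spectrum's target densities over them, and realizes each
#' segment's CpG count as Poisson around `target * length/1000` with CpGs
#' placed uniformly (at odd offsets) within the segment. All other bases
#' are A/T, so the reference is CpG-free outside the placed sites.
#'
#' @param config a [synthetic_config()].
#' @param seed optional override of the derived child seed.
#' @return List: `genome` (named character), `chrom_sizes`, `segments`
#'   (with `target_density`, `cpg_count`, realized `density`, `regime`),
#'   `cpg` (per-site `chrom`, `pos`, `seg_id`, `density`, `regime`).
#' @export
generate_reference <- function(config, seed = NULL) {
  validate_config(config)
  if (is.null(seed)) seed <- child_seed(config$seed, "genome")
  window <- config$window
  n_seg <- sum(config$density_spectrum$n_segments)
  per_chrom <- n_seg / config$n_chrom
  chrom_sizes <- setNames(rep(per_chrom * window, config$n_chrom),
                          paste0("chr", seq_len(config$n_chrom)))
  segments <- segment_genome(chrom_sizes, window)
  max_cpg <- floor(window / 2)
  with_seed(seed, {
    targets <- sample(rep(config$density_spectrum$density,
                          config$density_spectrum$n_segments))
    counts <- pmin(rpois(n_seg, targets * window / 1000), max_cpg)
    offsets <- lapply(seq_len(n_seg), function(i) {
      if (counts[i] == 0L) integer() else
        sort(sample.int(max_cpg, counts[i]) * 2L - 1L)
    })
    genome <- vapply(names(chrom_sizes), function(chrom) {
      si <- which(segments$chrom == chrom)
      chars <- sample(c("A", "T"), chrom_sizes[[chrom]], replace = TRUE)
      for (k in si) {
        p <- segments$start[k] + offsets[[k]]   # 1-based C positions
        chars[p] <- "C"; chars[p + 1L] <- "G"
      }
      paste(chars, collapse = "")
    }, character(1))
  })
  segments$target_density <- targets
  segments$cpg_count <- counts
  segments$density <- counts / (window / 1000)
  segments$regime <- density_regime(segments$density, config$meth_breaks)
  cpg <- data.frame(
    chrom = rep(segments$chrom, counts),
    pos = unlist(lapply(seq_len(n_seg),
                        function(i) segments$start[i] + offsets[[i]])),
    seg_id = rep(segments$seg_id, counts),
    density = rep(segments$density, counts),
    regime = rep(segments$regime, counts),
    stringsAsFactors = FALSE)
  list(genome = genome, chrom_sizes = chrom_sizes, segments = segments,
       cpg = cpg)
}

#' Generate per-strain methylomes over the synthetic CpG landscape
#'
#' True states: the reference strain methylates each site with the
#' three-fraction probability of its density regime (`meth_levels`). Below
#' the second breakpoint every other strain conserves the *count*: the same
#' number of sites is methylated per segment, but a fraction of them are
#' relocated so the expected same-state probability equals `concordance`.
#' Above it states are copied site-by-site, each methylated site kept with
#' the strain's `retention` probability and never compensated. Read counts
#' are negative-binomial per site and strain, with binomial methylated
#' reads at `read_meth_frac` (true 1) or `read_error_frac` (true 0).
#'
#' @param config a [synthetic_config()].
#' @param ref output of [generate_reference()].
#' @param seed optional child-seed override.
#' @return List: `sites` (a methylation site table, strand `+`, context
#'   `CG`) and `truth` (logical matrix of true states, sites x strains).
#' @export
generate_strain_methylomes <- function(config, ref, seed = NULL) {
  if (is.null(seed)) seed <- child_seed(config$seed, "methylome")
  cpg <- ref$cpg
  n <- nrow(cpg)
  strains <- config$strains
  p_meth <- config$meth_levels[cpg$regime]
  high <- cpg$density > config$meth_breaks[2]
  truth <- matrix(FALSE, n, length(strains),
                  dimnames = list(NULL, strains))
  with_seed(seed, {
    base <- runif(n) < p_meth
    truth[, config$reference_strain] <- base
    moves_per_site <- (1 - config$concordance) / 2
    for (s in setdiff(strains, config$reference_strain)) {
      st <- base
      # site-conserving regime: thin without compensation
      keep <- runif(n) < config$retention[[s]]
      st[high & base & !keep] <- FALSE
      # count-conserving regime: relocate within segment
      for (k in split(which(!high), cpg$seg_id[!high])) {
        m_on <- k[base[k]]; m_off <- k[!base[k]]
        r <- min(round(length(k) * moves_per_site), length(m_on), length(m_off))
        if (r > 0L) {
          off <- if (length(m_on) == 1L) m_on else sample(m_on, r)
          on <- if (length(m_off) == 1L) m_off else sample(m_off, r)
          st[off[seq_len(r)]] <- FALSE
          st[on[seq_len(r)]] <- TRUE
        }
      }
      truth[, s] <- st
    }
    sites <- data.frame(chrom = cpg$chrom, pos = cpg$pos, strand = "+",
                        context = "CG", stringsAsFactors = FALSE)
    for (s in strains) {
      cov <- rnbinom(n, mu = config$coverage_mean, size = config$coverage_disp)
      frac <- ifelse(truth[, s], config$read_meth_frac, config$read_error_frac)
      sites[[paste0(s, ".mc")]] <- rbinom(n, cov, frac)
      sites[[paste0(s, ".cov")]] <- cov
    }
  })
  list(sites = sites, truth = truth)
}

#' Generate strain variants versus the reference genome
#'
#' At CpG sites, each non-reference strain acquires a C-disrupting variant
#' (allele `T` or `A` at the C) with a probability depending on the site's
#' true methylation state in that strain and its density regime
#' (`mutation_rates`): below `mutation_break` methylated CpGs mutate more
#' often than unmethylated ones, above it the ordering reverses. Outgroup
#' variants arise the same way, producing C gains when a strain retains the
#' C the outgroup lost. Background non-C variants (A/T positions to `G`)
#' are sprinkled at `background_variant_rate` to exercise the non-C
#' exclusion paths downstream.
#'
#' @param config a [synthetic_config()].
#' @param ref output of [generate_reference()].
#' @param methylomes output of [generate_strain_methylomes()].
#' @param seed optional child-seed override.
#' @return List: `variants` (variant table, one allele column per strain)
#'   and `truth` (long data.frame `chrom`, `pos`, `strain`, `allele`,
#'   `at_cpg`).
#' @export
generate_variants <- function(config, ref, methylomes, seed = NULL) {
  if (is.null(seed)) seed <- child_seed(config$seed, "variants")
  cpg <- ref$cpg
  n <- nrow(cpg)
  high <- cpg$density > config$mutation_break
  rates <- config$mutation_rates
  others <- setdiff(config$strains, config$reference_strain)
  with_seed(seed, {
    long <- list()
    for (s in others) {
      meth <- methylomes$truth[, s]
      p <- ifelse(high,
                  ifelse(meth, rates[["meth_high"]], rates[["unmeth_high"]]),
                  ifelse(meth, rates[["meth_low"]], rates[["unmeth_low"]]))
      hit <- runif(n) < p
      if (any(hit))
        long[[length(long) + 1L]] <- data.frame(
          chrom = cpg$chrom[hit], pos = cpg$pos[hit], strain = s,
          allele = sample(c("T", "A"), sum(hit), replace = TRUE),
          at_cpg = TRUE, stringsAsFactors = FALSE)
    }
    # background non-C variants on the A/T backbone
    glen <- sum(ref$chrom_sizes)
    n_bg <- rpois(1L, config$background_variant_rate * glen)
    if (n_bg > 0L) {
      bg_chrom <- sample(names(ref$chrom_sizes), n_bg, replace = TRUE,
                         prob = ref$chrom_sizes / glen)
      bg_pos <- vapply(ref$chrom_sizes[bg_chrom],
                       function(L) sample.int(L, 1L), integer(1))
      at_cpg <- paste(bg_chrom, bg_pos) %in%
        c(paste(cpg$chrom, cpg$pos), paste(cpg$chrom, cpg$pos + 1L))
      keep <- !at_cpg
      if (any(keep))
        long[[length(long) + 1L]] <- data.frame(
          chrom = bg_chrom[keep], pos = unname(bg_pos[keep]),
          strain = sample(others, sum(keep), replace = TRUE),
          allele = "G", at_cpg = FALSE, stringsAsFactors = FALSE)
    }
  })
  long <- if (length(long)) do.call(rbind, long) else
    data.frame(chrom = character(), pos = integer(), strain = character(),
               allele = character(), at_cpg = logical())
  # wide table: one row per mutated position, ref allele from the genome
  key <- paste(long$chrom, long$pos)
  upos <- !duplicated(key)
  variants <- data.frame(chrom = long$chrom[upos], pos = long$pos[upos],
                         stringsAsFactors = FALSE)
  variants$ref_allele <- substring(ref$genome[variants$chrom], variants$pos,
                                   variants$pos)
  for (s in config$strains) variants[[s]] <- variants$ref_allele
  i <- match(key, paste(variants$chrom, variants$pos))
  for (s in unique(long$strain)) {
    rows <- long$strain == s
    col <- variants[[s]]
    col[i[rows]] <- long$allele[rows]
    variants[[s]] <- col
  }
  o <- order(match(variants$chrom, names(ref$chrom_sizes)), variants$pos)
  variants <- variants[o, , drop = FALSE]
  rownames(variants) <- NULL
  list(variants = variants, truth = long)
}

#' Generate a chromatin-state partition of the synthetic genome
#'
#' Each segment is assigned one of the 15 state groups, drawn from the
#' high-density palette above `mutation_break` and the low-density palette
#' otherwise (CpG-dense DNA is enriched for enhancer/promoter states, as in
#' real annotations). The result partitions every base exactly once.
#'
#' @param config a [synthetic_config()].
#' @param ref output of [generate_reference()].
#' @param seed optional child-seed override.
#' @return data.frame `chrom`, `start`, `end`, `state` (BED-style).
#' @export
generate_chromatin_states <- function(config, ref, seed = NULL) {
  if (is.null(seed)) seed <- child_seed(config$seed, "states")
  seg <- ref$segments
  high <- seg$density > config$mutation_break
  states <- chromatin_state_groups()
  with_seed(seed, {
    lab <- character(nrow(seg))
    lab[high] <- sample(names(config$state_p_high), sum(high), replace = TRUE,
                        prob = config$state_p_high)
    lab[!high] <- sample(names(config$state_p_low), sum(!high), replace = TRUE,
                         prob = config$state_p_low)
  })
  data.frame(chrom = seg$chrom, start = seg$start, end = seg$end,
             state = lab, stringsAsFactors = FALSE)
}

#' Synthetic gene models over the generated genome
#'
#' One gene per two segments: the gene body spans the first segment of each
#' pair, the second is intergenic. With the default 2-kb flank the extended
#' gene intervals overlap their neighbours slightly, so a mutation can
#' annotate to more than one gene, as in real gene-dense regions.
#'
#' @param config a [synthetic_config()].
#' @param ref output of [generate_reference()].
#' @return Gene-model data.frame (`gene`, `chrom`, `strand`, `txStart`,
#'   `txEnd`).
#' @export
synthetic_gene_models <- function(config, ref) {
  seg <- ref$segments
  body <- seg[seq(1L, nrow(seg), by = 2L), , drop = FALSE]
  data.frame(gene = sprintf("gene%05d", seq_len(nrow(body))),
             chrom = body$chrom, strand = "+",
             txStart = body$start, txEnd = body$end,
             stringsAsFactors = FALSE)
}

#' Accessibility (pooled open-chromatin read) table for the CpG sites
#'
#' Pooled B6+D2-style read support per CpG position, negative-binomial with
#' twice the per-strain coverage mean, used by the chromatin-state
#' assignment gate.
#'
#' @param config a [synthetic_config()].
#' @param ref output of [generate_reference()].
#' @param seed optional child-seed override.
#' @return data.frame `chrom`, `pos`, `reads`.
#' @export
generate_accessibility <- function(config, ref, seed = NULL) {
  if (is.null(seed)) seed <- child_seed(config$seed, "accessibility")
  with_seed(seed, {
    data.frame(chrom = ref$cpg$chrom, pos = ref$cpg$pos,
               reads = rnbinom(nrow(ref$cpg), mu = 2 * config$coverage_mean,
                               size = config$coverage_disp),
               stringsAsFactors = FALSE)
  })
}
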