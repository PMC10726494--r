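# Genome segmentation, CpG density, methylation calling, downsampling.

#' Tile chromosomes into fixed-size segments
#'
#' Non-overlapping windows per chromosome (0-based half-open). A trailing
#' partial window is emitted and flagged; its density is later computed over
#' its true length. 2-kb windows capture regions of clustered methylation
#' (1-kb and 500-bp tilings behave the same in practice).
#'
#' @param chrom_sizes named numeric vector of chromosome lengths (bp).
#' @param window window size in bp (default 2000).
#' @param drop_partial drop the trailing partial window instead of flagging
#'   it (strict tiling).
#' @return data.frame with `seg_id`, `chrom`, `start`, `end`, `partial`.
#' @export
segment_genome <- function(chrom_sizes, window = 2000, drop_partial = FALSE) {
  if (!is.numeric(window) || length(window) != 1L || window <= 0)
    fail("window must be a positive number")
  if (is.null(names(chrom_sizes)) || any(chrom_sizes <= 0))
    fail("chrom_sizes must be a named vector of positive lengths")
  res <- lapply(names(chrom_sizes), function(chrom) {
    len <- chrom_sizes[[chrom]]
    starts <- seq(0, len - 1, by = window)
    ends <- pmin(starts + window, len)
    data.frame(chrom = chrom, start = starts, end = ends,
               partial = ends - starts < window, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (drop_partial) out <- out[!out$partial, , drop = FALSE]
  out <- cbind(seg_id = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' CpG sequence density of segments
#'
#' Density counts CpG dinucleotides of the reference per kilobase,
#' regardless of methylation state. A CpG at 1-based position `pos` falls in
#' segment `[start, end)` when `start <= pos - 1 < end`; partial segments
#' use their true length.
#'
#' @param segments segment data.frame from [segment_genome()].
#' @param cpg data.frame with `chrom` and sorted `pos` (1-based positions of
#'   the forward-strand C), or a numeric position vector when `segments`
#'   covers a single chromosome.
#' @return `segments` with `cpg_count` and `density` (CpG/Kb) columns.
#' @export
cpg_density <- function(segments, cpg) {
  if (is.numeric(cpg)) {
    if (length(unique(segments$chrom)) > 1L)
      fail("positions without chrom need single-chromosome segments")
    cpg <- data.frame(chrom = rep(segments$chrom[1], length(cpg)), pos = cpg)
  }
  segments$cpg_count <- 0L
  for (chrom in unique(segments$chrom)) {
    si <- which(segments$chrom == chrom)
    pos0 <- cpg$pos[cpg$chrom == chrom] - 1
    if (!length(pos0)) next
    # gapless tiling: findInterval bins are exactly the segments; positions
    # outside [first start, last end) are dropped
    brk <- c(segments$start[si], segments$end[si[length(si)]])
    inside <- pos0 >= brk[1] & pos0 < brk[length(brk)]
    segments$cpg_count[si] <- tabulate(
      findInterval(pos0[inside], brk), nbins = length(si))
  }
  segments$density <- segments$cpg_count / ((segments$end - segments$start) / 1000)
  segments
}

#' Assign 1-based site positions to segments
#'
#' @param sites data.frame with `chrom`, `pos`.
#' @param segments segment data.frame (with `seg_id`).
#' @return Integer vector of `seg_id` per site (NA when uncovered).
#' @export
assign_segments <- function(sites, segments) {
  out <- rep(NA_integer_, nrow(sites))
  for (chrom in unique(sites$chrom)) {
    si <- which(segments$chrom == chrom)
    ri <- which(sites$chrom == chrom)
    if (!length(si)) next
    pos0 <- sites$pos[ri] - 1
    brk <- c(segments$start[si], segments$end[si[length(si)]])
    k <- findInterval(pos0, brk)
    k[k < 1L | k > length(si)] <- NA_integer_
    out[ri] <- segments$seg_id[si][k]
  }
  out
}

#' Call methylation state from read counts
#'
#' A site needs at least `min_cov` reads to be callable; with enough
#' coverage it is called methylated when at least `min_frac` of the reads
#' are methylated, and unmethylated otherwise (callable but without evidence
#' of methylation is an explicit 0, not a missing value).
#'
#' @param mc,cov integer vectors of methylated and total read counts.
#' @param min_cov minimum coverage to call (default 5 reads).
#' @param min_frac minimum methylated-read fraction to call methylated
#'   (default 0.10; exactly 10% is called methylated).
#' @return Integer vector: 1 methylated, 0 unmethylated, NA no call.
#' @export
call_methylation <- function(mc, cov, min_cov = 5, min_frac = 0.10) {
  if (length(mc) != length(cov)) fail("mc and cov must have equal length")
  if (any(mc > cov, na.rm = TRUE)) fail("mc > cov")
  if (any(mc < 0 | cov < 0, na.rm = TRUE)) fail("negative counts")
  out <- ifelse(cov < min_cov, NA_integer_,
                ifelse(mc >= min_frac * cov, 1L, 0L))
  out[is.na(mc) | is.na(cov)] <- NA_integer_
  as.integer(out)
}

#' Build per-segment methylation profiles
#'
#' Joins a CG-context site table to segments, annotates each site with its
#' segment's density and integer density bin, and adds a methylation call
#' column per strain. CH rows are dropped (carried formats may include them).
#'
#' @param sites methylation site table (see [read_site_table()]).
#' @param segments segments with `density` from [cpg_density()].
#' @param min_cov,min_frac calling thresholds, see [call_methylation()].
#' @param bin_width width of the density bins in CpG/Kb (default 1; bins are
#'   `floor(density / bin_width) * bin_width`).
#' @return The site rows with `seg_id`, `density`, `bin`, and
#'   `<strain>.call` columns; sites outside all segments are dropped and
#'   counted in the `"n_unassigned"` attribute. Attribute `strains` lists
#'   the strains, `params` the thresholds.
#' @export
segment_profiles <- function(sites, segments, min_cov = 5, min_frac = 0.10,
                             bin_width = 1) {
  validate_site_table(sites)
  x <- sites[sites$context == "CG", , drop = FALSE]
  seg <- assign_segments(x, segments)
  n_un <- sum(is.na(seg))
  x <- x[!is.na(seg), , drop = FALSE]
  seg <- seg[!is.na(seg)]
  i <- match(seg, segments$seg_id)
  x$seg_id <- seg
  x$density <- segments$density[i]
  x$bin <- floor(x$density / bin_width) * bin_width
  strains <- site_table_strains(sites)
  for (s in strains)
    x[[paste0(s, ".call")]] <- call_methylation(
      x[[paste0(s, ".mc")]], x[[paste0(s, ".cov")]], min_cov, min_frac)
  rownames(x) <- NULL
  attr(x, "strains") <- strains
  attr(x, "params") <- list(min_cov = min_cov, min_frac = min_frac,
                            bin_width = bin_width)
  attr(x, "n_unassigned") <- n_un
  x
}

#' Downsample the higher-coverage strain within one segment
#'
#' Corrects for coverage imbalance between two strains in a segment by
#' randomly reducing the methylated counts of the strain with more total
#' reads, proportionate to the coverage ratio: each methylated read of the
#' higher-coverage strain is kept independently with probability
#' (lower total coverage) / (higher total coverage) (Bernoulli thinning, the
#' minimal-assumption reading of proportional reduction). The
#' lower-coverage strain is untouched; total coverage values are not
#' altered. Seeded and reproducible; counts never increase.
#'
#' @param mc1,cov1,mc2,cov2 per-site counts of the two strains over the
#'   segment's CpG positions.
#' @param seed integer seed (NULL leaves the RNG stream alone).
#' @return List with thinned `mc1`, `mc2`, the thinning `ratio`, and
#'   `thinned` ("none", "strain1" or "strain2").
#' @export
downsample_segment <- function(mc1, cov1, mc2, cov2, seed = NULL) {
  tot1 <- sum(cov1); tot2 <- sum(cov2)
  if ((tot1 == 0 && tot2 == 0) || tot1 == tot2)
    return(list(mc1 = mc1, mc2 = mc2, ratio = 1, thinned = "none"))
  ratio <- min(tot1, tot2) / max(tot1, tot2)
  with_seed(seed, {
    if (tot1 > tot2) {
      mc1 <- rbinom(length(mc1), mc1, ratio)
      thinned <- "strain1"
    } else {
      mc2 <- rbinom(length(mc2), mc2, ratio)
      thinned <- "strain2"
    }
  })
  list(mc1 = mc1, mc2 = mc2, ratio = ratio, thinned = thinned)
}

#' Apply per-segment downsampling to a strain pair across all segments
#'
#' Runs [downsample_segment()] in every segment of a profile table for one
#' strain pair and recomputes the pair's methylation calls from the thinned
#' counts (coverage is unchanged, so callability is unchanged).
#'
#' @param profiles profile table from [segment_profiles()].
#' @param s1,s2 strain names.
#' @param seed integer seed.
#' @return `profiles` with updated `<s>.mc` and `<s>.call` for the pair.
#' @export
downsample_pair <- function(profiles, s1, s2, seed = NULL) {
  p <- attr(profiles, "params")
  mc1 <- profiles[[paste0(s1, ".mc")]]; cov1 <- profiles[[paste0(s1, ".cov")]]
  mc2 <- profiles[[paste0(s2, ".mc")]]; cov2 <- profiles[[paste0(s2, ".cov")]]
  seg <- factor(profiles$seg_id)
  tot1 <- rowsum(cov1, seg); tot2 <- rowsum(cov2, seg)
  i <- match(profiles$seg_id, rownames(tot1))
  t1 <- tot1[i, 1L]; t2 <- tot2[i, 1L]
  ratio <- ifelse(pmax(t1, t2) == 0, 1, pmin(t1, t2) / pmax(t1, t2))
  p1 <- ifelse(t1 > t2, ratio, 1)
  p2 <- ifelse(t2 > t1, ratio, 1)
  with_seed(seed, {
    new1 <- rbinom(length(mc1), mc1, p1)
    new2 <- rbinom(length(mc2), mc2, p2)
  })
  profiles[[paste0(s1, ".mc")]] <- new1
  profiles[[paste0(s2, ".mc")]] <- new2
  profiles[[paste0(s1, ".call")]] <- call_methylation(new1, cov1, p$min_cov, p$min_frac)
  profiles[[paste0(s2, ".call")]] <- call_methylation(new2, cov2, p$min_cov, p$min_frac)
  profiles
}
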