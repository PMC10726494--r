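# Density curves: % methylated and % mutated CpGs per CpG-density bin.

#' Percentage of CpGs methylated, by CpG density bin
#'
#' Pools the callable sites of all segments falling in each integer density
#' bin and reports 100 x methylated / callable. No-call sites enter neither
#' numerator nor denominator; bins without callable sites are omitted.
#'
#' @param profiles profile table from [segment_profiles()].
#' @param strain strain name.
#' @return data.frame with `bin` (CpG/Kb), `pct_methylated`, and supporting
#'   counts `n_methylated`, `n_callable` so the variance is assessable.
#' @export
methylation_fraction_by_density <- function(profiles, strain) {
  call <- profiles[[paste0(strain, ".call")]]
  if (is.null(call)) fail("no call column for strain '%s'", strain)
  keep <- !is.na(call)
  b <- factor(profiles$bin[keep])
  meth <- rowsum(as.numeric(call[keep]), b)[, 1L]
  n <- as.vector(table(b))
  out <- data.frame(bin = as.numeric(levels(b)),
                    pct_methylated = 100 * meth / n,
                    n_methylated = as.integer(meth), n_callable = n)
  out[order(out$bin), , drop = FALSE]
}

# Per-site flag: does the strain-vs-outgroup allele pair lose or gain a C?
# Returns list(mutated = logical per site, excluded_non_c = count).
cpg_mutation_flags <- function(sites, variants, strain, outgroup) {
  for (s in c(strain, outgroup))
    if (!s %in% variant_table_strains(variants))
      fail("strain '%s' not in variant table", s)
  i <- match(paste(sites$chrom, sites$pos), paste(variants$chrom, variants$pos))
  a1 <- variants[[strain]][i]
  a2 <- variants[[outgroup]][i]
  differs <- !is.na(a1) & !is.na(a2) & a1 != a2
  involves_c <- differs & ((a1 == "C") != (a2 == "C"))
  list(mutated = involves_c & differs,
       excluded_non_c = sum(differs & !involves_c))
}

#' Percentage of CpG sites mutated versus an outgroup, by density bin
#'
#' A site counts as mutated when the strain and the outgroup carry different
#' alleles at the C and the difference loses or gains a cytosine; variants
#' where neither allele involves C are excluded (count reported in the
#' `"excluded_non_c"` attribute), as are variants at the partner G.
#' Percentages are computed separately over the strain's called-methylated
#' and called-unmethylated sites in each bin.
#'
#' @param profiles profile table from [segment_profiles()].
#' @param variants variant table carrying `strain` and `outgroup` columns.
#' @param strain focal strain.
#' @param outgroup outgroup strain used to polarize variants.
#' @return data.frame with `bin`, `pct_mutated_methylated`,
#'   `pct_mutated_unmethylated` and the supporting counts; bins with no
#'   callable sites are omitted, and a class without sites in a bin yields
#'   NaN for that class.
#' @export
mutation_fraction_by_density <- function(profiles, variants, strain, outgroup) {
  call <- profiles[[paste0(strain, ".call")]]
  if (is.null(call)) fail("no call column for strain '%s'", strain)
  fl <- cpg_mutation_flags(profiles, variants, strain, outgroup)
  keep <- !is.na(call)
  b <- factor(profiles$bin[keep])
  cl <- call[keep]; mut <- fl$mutated[keep]
  agg <- function(v) rowsum(as.numeric(v), b)[, 1L]
  n_me <- agg(cl == 1L); n_un <- agg(cl == 0L)
  mut_me <- agg(mut & cl == 1L); mut_un <- agg(mut & cl == 0L)
  out <- data.frame(bin = as.numeric(levels(b)),
                    pct_mutated_methylated = 100 * mut_me / n_me,
                    pct_mutated_unmethylated = 100 * mut_un / n_un,
                    n_mutated_methylated = as.integer(mut_me),
                    n_methylated = as.integer(n_me),
                    n_mutated_unmethylated = as.integer(mut_un),
                    n_unmethylated = as.integer(n_un))
  out <- out[order(out$bin), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "excluded_non_c") <- fl$excluded_non_c
  out
}
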