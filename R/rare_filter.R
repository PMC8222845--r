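#' Resolve a variant's population MAF
#'
#' Population reference panels report a variant's minor allele frequency from
#' two datasets (genomes and exomes). The resolved population MAF used by the
#' carrier test is the larger of the two; when neither dataset reports the
#' variant, a small positive default is substituted (3e-6, below the smallest
#' frequency such panels deposit) so the carrier probability is never zero.
#'
#' @param maf_genomes,maf_exomes Allele fractions in `[0, 1]`, or `NA` when
#'   the panel does not report the variant. Vectorized.
#' @param missing_default Value substituted when both fields are missing;
#'   must be positive. Default `3e-6`.
#' @return Numeric vector of resolved MAFs.
#' @export
#' @examples
#' resolve_pmaf(0.0329, 0.0359)  # 0.0359
#' resolve_pmaf(NA, NA)          # 3e-06
resolve_pmaf <- function(maf_genomes, maf_exomes, missing_default = 3e-6) {
  stopifnot(missing_default > 0)
  if (any(c(maf_genomes, maf_exomes) < 0, na.rm = TRUE) ||
      any(c(maf_genomes, maf_exomes) > 1, na.rm = TRUE)) {
    stop("MAF values must lie in [0, 1]", call. = FALSE)
  }
  out <- pmax(maf_genomes, maf_exomes, na.rm = TRUE)
  out[is.na(out)] <- missing_default
  out
}

#' Functional-region categories excluded from rare-variant analysis
#'
#' Regions not expected to change protein function. The list is data, not
#' code: pass a modified vector to [select_rare_variants()] to change it.
#'
#' @return Character vector of excluded region categories.
#' @export
default_excluded_regions <- function() {
  c("UTR5", "ncRNA_intronic", "intronic", "UTR3", "intergenic",
    "upstream", "downstream", "upstream;downstream", "UTR5;UTR3",
    "ncRNA_exonic")
}

#' Select rare, protein-altering variants
#'
#' Keeps variants whose population MAF (the maximum over the genomes and
#' exomes fields; a variant absent from both is treated as rare) is strictly
#' below `maf_cutoff`, whose functional region is not in the excluded set,
#' that are not synonymous SNVs, and that are not flagged as pseudogenic.
#' Splicing and exonic;splicing regions are retained. An unrecognized
#' functional-region category is kept with a warning (conservative), unless
#' `strict = TRUE`, in which case it is an error.
#'
#' The kept set is monotone in the cutoff: tightening `maf_cutoff` can only
#' shrink it, which is what makes nested cutoff tiers (e.g. 0.05 / 0.001 /
#' 0.0005) well-defined.
#'
#' @param variants Cohort variant data frame.
#' @param maf_cutoff Strict upper bound on population MAF. Default 0.05.
#' @param exclude_regions Character vector of excluded functional-region
#'   categories; default [default_excluded_regions()].
#' @param known_regions Categories recognized in addition to the excluded
#'   set; anything else triggers the unknown-category policy.
#' @param strict Error on unknown functional-region categories instead of
#'   keeping them.
#' @return The filtered cohort variant data frame.
#' @export
select_rare_variants <- function(variants, maf_cutoff = 0.05,
                                 exclude_regions = default_excluded_regions(),
                                 known_regions = c("exonic", "splicing",
                                                   "exonic;splicing",
                                                   "ncRNA_splicing"),
                                 strict = FALSE) {
  stopifnot(maf_cutoff >= 0)
  unknown <- setdiff(unique(variants$func_region),
                     c(exclude_regions, known_regions))
  if (length(unknown)) {
    msg <- paste("unknown functional-region categories kept:",
                 paste(unknown, collapse = ", "))
    if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  # for filtering, a variant absent from both panels counts as rare
  pmaf_filter <- pmax(variants$maf_genomes, variants$maf_exomes, na.rm = TRUE)
  pmaf_filter[is.na(pmaf_filter)] <- 0

  keep <- pmaf_filter < maf_cutoff &
    !(variants$func_region %in% exclude_regions) &
    (is.na(variants$exonic_func) | variants$exonic_func != "synonymous SNV") &
    !variants$pseudogene_flag
  variants[keep, , drop = FALSE]
}
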