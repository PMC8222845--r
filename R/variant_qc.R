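#' Quality-control thresholds
#'
#' Bundle of the genotype- and variant-level cutoffs applied by
#' [mask_low_quality_genotypes()] and [filter_variants()]. Defaults follow a
#' conservative whole-exome cohort design: genotypes with GQ below 20 are set
#' missing, variants with per-sample depth below 10 are excluded, variants
#' failing a Hardy-Weinberg exact test at p < 1e-6 are excluded, heterozygous
#' calls with allele balance outside [0.2, 0.8] are set missing, and only
#' variants with a call rate of 1.0 are kept. All boundaries are inclusive on
#' the kept side ("less than" semantics throughout).
#'
#' @param gq_min Minimum kept genotype quality (phred-like). Default 20.
#' @param dp_min Minimum kept variant depth. Default 10.
#' @param hwe_p_min Minimum kept Hardy-Weinberg exact-test p-value. Default 1e-6.
#' @param ab_low,ab_high Kept heterozygote allele-balance bounds. Defaults 0.2, 0.8.
#' @param call_rate_min Required fraction of non-missing genotypes per
#'   variant, in (0, 1]. Default 1.0.
#' @return An object of class `qc_thresholds`.
#' @export
#' @examples
#' qc_thresholds(gq_min = 30)
qc_thresholds <- function(gq_min = 20, dp_min = 10, hwe_p_min = 1e-6,
                          ab_low = 0.2, ab_high = 0.8, call_rate_min = 1.0) {
  stopifnot(ab_low >= 0, ab_low < ab_high, ab_high <= 1,
            call_rate_min > 0, call_rate_min <= 1,
            gq_min >= 0, dp_min >= 0, hwe_p_min >= 0, hwe_p_min <= 1)
  structure(list(gq_min = gq_min, dp_min = dp_min, hwe_p_min = hwe_p_min,
                 ab_low = ab_low, ab_high = ab_high,
                 call_rate_min = call_rate_min),
            class = "qc_thresholds")
}

#' @export
print.qc_thresholds <- function(x, ...) {
  cat("QC thresholds: GQ >=", x$gq_min, "| min DP >=", x$dp_min,
      "| HWE p >=", format(x$hwe_p_min), "| AB in [", x$ab_low, ",",
      x$ab_high, "] | call rate >=", x$call_rate_min, "\n")
  invisible(x)
}

#' Mask low-quality genotype calls
#'
#' Sets to missing (i) any call with GQ below `gq_min` and (ii) any
#' heterozygous call whose allele balance `ad_alt / (ad_ref + ad_alt)` falls
#' below `ab_low` or above `ab_high`. Calls at the boundary values are kept.
#' Heterozygous calls with missing AD fields are, by default, also set
#' missing and counted separately (`het_missing_ad = "mask"`); set
#' `het_missing_ad = "keep"` to retain them.
#'
#' @param genotypes A [genotype_calls] object.
#' @param thresholds A [qc_thresholds] object.
#' @param het_missing_ad Policy for heterozygous calls lacking AD: `"mask"`
#'   (default) or `"keep"`.
#' @return A [genotype_calls] object with masked calls set to `NA` in the
#'   dosage matrix. The attribute `"mask_counts"` records how many genotypes
#'   each rule masked (`gq`, `allele_balance`, `het_missing_ad`).
#' @export
mask_low_quality_genotypes <- function(genotypes, thresholds = qc_thresholds(),
                                       het_missing_ad = c("mask", "keep")) {
  het_missing_ad <- match.arg(het_missing_ad)
  dos <- genotypes$dosage
  called <- !is.na(dos)

  low_gq <- called & !is.na(genotypes$gq) & genotypes$gq < thresholds$gq_min

  het <- called & dos == 1L
  tot <- genotypes$ad_ref + genotypes$ad_alt
  ab <- genotypes$ad_alt / tot
  ab_defined <- het & !is.na(tot) & tot > 0
  bad_ab <- ab_defined & (ab < thresholds$ab_low | ab > thresholds$ab_high)
  het_no_ad <- het & !ab_defined

  mask <- low_gq | bad_ab
  n_missing_ad <- 0L
  if (het_missing_ad == "mask") {
    mask <- mask | het_no_ad
    n_missing_ad <- sum(het_no_ad & !low_gq)
  }
  dos[mask] <- NA_integer_
  out <- genotypes
  out$dosage <- dos
  attr(out, "mask_counts") <- c(gq = sum(low_gq),
                                allele_balance = sum(bad_ab & !low_gq),
                                het_missing_ad = n_missing_ad)
  out
}

#' Hardy-Weinberg equilibrium exact test
#'
#' Exact test of genotype counts against Hardy-Weinberg proportions. With the
#' number of genotypes and the minor-allele count held fixed, the conditional
#' probability of each possible heterozygote count has the hypergeometric-type
#' form; the two-sided p-value sums the probabilities of all heterozygote
#' counts whose probability does not exceed that of the observed count
#' (no mid-p correction). Computation is in log space, so large cohorts are
#' handled without overflow. A chi-square test (1 df, no continuity
#' correction) is available as an asymptotic alternative.
#'
#' @param n_hom_ref,n_het,n_hom_alt Genotype counts (non-negative; at least
#'   one positive).
#' @param method `"exact"` (default) or `"chisq"`.
#' @return The p-value, in (0, 1].
#' @export
#' @examples
#' hwe_exact_p(25, 50, 25)   # modal configuration: p = 1
#' hwe_exact_p(50, 0, 50)    # extreme heterozygote deficit
hwe_exact_p <- function(n_hom_ref, n_het, n_hom_alt,
                        method = c("exact", "chisq")) {
  method <- match.arg(method)
  if (any(c(n_hom_ref, n_het, n_hom_alt) < 0)) {
    stop("genotype counts must be non-negative", call. = FALSE)
  }
  n <- n_hom_ref + n_het + n_hom_alt
  if (n == 0) stop("all genotype counts are zero", call. = FALSE)

  if (method == "chisq") return(hwe_chisq_p(n_hom_ref, n_het, n_hom_alt))

  n_a <- 2L * n_hom_ref + n_het
  n_b <- 2L * n_hom_alt + n_het
  n_minor <- min(n_a, n_b)
  if (n_minor == 0L) return(1.0)  # monomorphic: single configuration

  hets <- seq(n_minor %% 2L, n_minor, by = 2L)
  hom_minor <- (n_minor - hets) %/% 2L
  hom_major <- n - hets - hom_minor
  valid <- hom_major >= 0L
  hets <- hets[valid]; hom_minor <- hom_minor[valid]; hom_major <- hom_major[valid]

  logw <- lfactorial(n) - lfactorial(hom_minor) - lfactorial(hets) -
    lfactorial(hom_major) + hets * log(2)
  logp <- logw - max(logw)
  p <- exp(logp) / sum(exp(logp))
  p_obs <- p[match(n_het, hets)]
  # tolerance guards against ties lost to floating-point rounding
  min(1, sum(p[p <= p_obs * (1 + 1e-7)]))
}

hwe_chisq_p <- function(n_hom_ref, n_het, n_hom_alt) {
  n <- n_hom_ref + n_het + n_hom_alt
  q <- (2 * n_hom_alt + n_het) / (2 * n)
  e <- n * c((1 - q)^2, 2 * q * (1 - q), q^2)
  o <- c(n_hom_ref, n_het, n_hom_alt)
  if (any(e == 0)) return(1.0)
  stat <- sum((o - e)^2 / e)
  stats::pchisq(stat, df = 1, lower.tail = FALSE)
}

#' Variant-level quality filters
#'
#' Applies the variant-level cascade to a genotype matrix whose low-quality
#' calls have already been masked (see [mask_low_quality_genotypes()]):
#' depth, Hardy-Weinberg, then call rate, in that order, each recorded in the
#' returned report.
#'
#' * depth: the variant's depth statistic (minimum per-sample DP over calls
#'   with a non-missing dosage, or the mean with `depth_stat = "mean"`) is
#'   below `dp_min`;
#' * HWE: the exact-test p-value computed from the variant's non-missing
#'   dosage counts is below `hwe_p_min`;
#' * call rate: the fraction of non-missing dosages is below `call_rate_min`.
#'
#' @param genotypes A [genotype_calls] object, already masked.
#' @param thresholds A [qc_thresholds] object.
#' @param depth_stat `"min"` (default; strictest reading of a minimum-depth
#'   exclusion) or `"mean"`.
#' @param hwe_method Passed to [hwe_exact_p()].
#' @return A list with `genotypes` (the surviving [genotype_calls]) and
#'   `report` (a `qc_report`: per-filter removal counts in application order).
#' @export
filter_variants <- function(genotypes, thresholds = qc_thresholds(),
                            depth_stat = c("min", "mean"),
                            hwe_method = c("exact", "chisq")) {
  depth_stat <- match.arg(depth_stat)
  hwe_method <- match.arg(hwe_method)
  n_in <- nrow(genotypes$dosage)

  # depth
  dos <- genotypes$dosage
  dp <- genotypes$dp
  dp[is.na(dos)] <- NA  # depth considered over non-missing calls only
  stat <- if (depth_stat == "min") {
    suppressWarnings(apply(dp, 1, min, na.rm = TRUE))
  } else {
    rowMeans(dp, na.rm = TRUE)
  }
  stat[!is.finite(stat)] <- Inf  # no informative calls: leave to call-rate
  drop_depth <- stat < thresholds$dp_min
  keep <- subset_genotypes(genotypes, !drop_depth)

  # HWE on non-missing dosage counts
  dos <- keep$dosage
  n0 <- rowSums(dos == 0L, na.rm = TRUE)
  n1 <- rowSums(dos == 1L, na.rm = TRUE)
  n2 <- rowSums(dos == 2L, na.rm = TRUE)
  hwe_p <- rep(1.0, nrow(dos))
  informative <- (n0 + n1 + n2) > 0
  hwe_p[informative] <- mapply(hwe_exact_p, n0[informative], n1[informative],
                               n2[informative], MoreArgs = list(method = hwe_method))
  drop_hwe <- hwe_p < thresholds$hwe_p_min
  keep <- subset_genotypes(keep, !drop_hwe)

  # call rate
  cr <- rowMeans(!is.na(keep$dosage))
  drop_cr <- cr < thresholds$call_rate_min
  keep <- subset_genotypes(keep, !drop_cr)

  report <- structure(list(
    variants_in = n_in,
    removed = c(depth = sum(drop_depth), hwe = sum(drop_hwe),
                call_rate = sum(drop_cr)),
    variants_out = nrow(keep$dosage),
    mask_counts = attr(genotypes, "mask_counts")
  ), class = "qc_report")
  stopifnot(report$variants_out == n_in - sum(report$removed))
  list(genotypes = keep, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Variant QC report\n")
  if (!is.null(x$mask_counts)) {
    cat("  genotypes masked: GQ", x$mask_counts[["gq"]],
        "| allele balance", x$mask_counts[["allele_balance"]],
        "| het without AD", x$mask_counts[["het_missing_ad"]], "\n")
  }
  cat("  variants in:", x$variants_in, "\n")
  for (f in names(x$removed)) {
    cat(sprintf("  removed by %-10s %d\n", paste0(f, ":"), x$removed[[f]]))
  }
  cat("  variants out:", x$variants_out, "\n")
  invisible(x)
}

#' @rdname print.qc_report
#' @param report A `qc_report`.
#' @param path Output path.
#' @export
write_qc_report <- function(report, path) {
  df <- data.frame(stage = c("input", paste0("removed_", names(report$removed)), "output"),
                   variants = c(report$variants_in, unname(report$removed),
                                report$variants_out))
  write_tsv_dot(df, path)
}
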