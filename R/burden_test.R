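#' Per-individual carrier probability
#'
#' Under Hardy-Weinberg proportions at population allele frequency `q`, the
#' probability that a diploid individual carries at least one alternate
#' allele is `2q(1 - q) + q^2` (dominant model), and the probability of being
#' homozygous alternate is `q^2` (recessive model).
#'
#' @param pmaf Resolved population MAF, in `[0, 1]`. Vectorized.
#' @return Carrier probability in `[0, 1]`.
#' @export
#' @examples
#' p_ind_dominant(0.0359)
#' p_ind_recessive(0.0001)
p_ind_dominant <- function(pmaf) {
  if (any(pmaf < 0 | pmaf > 1, na.rm = TRUE)) {
    stop("pmaf must lie in [0, 1]", call. = FALSE)
  }
  2 * pmaf * (1 - pmaf) + pmaf^2
}

#' @rdname p_ind_dominant
#' @export
p_ind_recessive <- function(pmaf) {
  if (any(pmaf < 0 | pmaf > 1, na.rm = TRUE)) {
    stop("pmaf must lie in [0, 1]", call. = FALSE)
  }
  pmaf^2
}

#' Count carriers of a variant in the cohort
#'
#' Dominant model: individuals with dosage >= 1. Recessive model: individuals
#' homozygous for the alternate allele (dosage 2). Missing dosages are a
#' contract violation — the call-rate filter upstream guarantees complete
#' genotypes — and raise an error.
#'
#' @param dosages Integer vector of alternate-allele dosages over samples.
#' @param mode `"dominant"` or `"recessive"`.
#' @return Carrier count.
#' @export
carrier_count <- function(dosages, mode = c("dominant", "recessive")) {
  mode <- match.arg(mode)
  if (anyNA(dosages)) {
    stop("missing dosage encountered; apply the call-rate filter first",
         call. = FALSE)
  }
  if (mode == "dominant") sum(dosages >= 1L) else sum(dosages == 2L)
}

#' Binomial carrier-overrepresentation probability
#'
#' The probability of observing exactly `n_carrying` carriers among `n_total`
#' unrelated individuals when each is independently a carrier with
#' probability `p_ind`: the binomial point mass
#' `choose(n_total, n_carrying) * p_ind^n_carrying * (1 - p_ind)^(n_total - n_carrying)`.
#' Evaluated in log space via `lchoose`/`log1p`, so factorial-scale terms
#' never overflow. Note this is a point probability, not a tail sum; set
#' `tail = TRUE` for the upper-tail probability `P(X >= n_carrying)` if a
#' conventional one-sided test is wanted instead.
#'
#' @param n_carrying Observed carrier count, `0 <= n_carrying <= n_total`.
#' @param n_total Cohort size.
#' @param p_ind Per-individual carrier probability. Vectorized with
#'   `n_carrying`.
#' @param tail Return the upper-tail probability instead of the point mass.
#' @return Probability. A degenerate `p_ind = 0` with `n_carrying > 0`
#'   returns 0 with a warning.
#' @export
#' @examples
#' overrepresentation_p(20, 93, p_ind_dominant(0.0359))
#' overrepresentation_p(1, 93, p_ind_recessive(1e-4))
overrepresentation_p <- function(n_carrying, n_total, p_ind, tail = FALSE) {
  if (any(n_carrying < 0 | n_carrying > n_total)) {
    stop("n_carrying must lie in [0, n_total]", call. = FALSE)
  }
  if (any(p_ind < 0 | p_ind > 1)) stop("p_ind must lie in [0, 1]", call. = FALSE)
  if (tail) {
    return(stats::pbinom(n_carrying - 1L, n_total, p_ind, lower.tail = FALSE))
  }
  n <- n_total
  len <- max(length(n_carrying), length(p_ind))
  k <- rep_len(n_carrying, len); p <- rep_len(p_ind, len)
  degen0 <- p == 0 & k > 0
  if (any(degen0)) {
    warning("p_ind = 0 with carriers observed; returning probability 0",
            call. = FALSE)
  }
  logp <- lchoose(n, k) + ifelse(k == 0, 0, k * log(p)) +
    ifelse(n - k == 0, 0, (n - k) * log1p(-p))
  res <- exp(logp)
  res[degen0] <- 0
  res
}

#' Bonferroni adjustment
#'
#' Multiplies a raw p-value by the number of tests performed and caps at 1,
#' controlling the family-wise error rate. Output columns elsewhere in the
#' package label this quantity `fdr` for continuity with common usage in
#' cohort scans, but it is a Bonferroni family-wise adjustment, not a
#' false-discovery-rate estimate.
#'
#' @param raw_p Unrounded raw probability (vectorized).
#' @param n_tests Number of tests, >= 1.
#' @return Adjusted value, `min(1, raw_p * n_tests)`.
#' @export
bonferroni_adjust <- function(raw_p, n_tests) {
  stopifnot(n_tests >= 1)
  pmin(1, raw_p * n_tests)
}

#' Scan a cohort for overrepresented rare variants
#'
#' Runs the carrier-probability test over every rare-filtered variant:
#' resolves each variant's population MAF, converts it to a per-individual
#' carrier probability under the chosen inheritance model, counts carriers in
#' the cohort, evaluates the binomial overrepresentation probability, and
#' applies a Bonferroni adjustment across the scan.
#'
#' The dominant scan tests all variants, autosomal and X-linked. The
#' recessive scan first removes X-chromosome variants; the number of tests is
#' the full post-exclusion variant count, while the result table is
#' restricted to variants with at least one homozygous carrier. Results are
#' ordered by raw probability, ties broken by (chrom, pos, alt).
#'
#' @param variants Rare-filtered cohort variant data frame.
#' @param genotypes QC-passed [genotype_calls] (complete dosages).
#' @param mode `"dominant"` or `"recessive"`.
#' @param tail Use the upper-tail probability instead of the point mass; see
#'   [overrepresentation_p()].
#' @param missing_maf_default Population MAF substituted when both panel
#'   fields are missing. Default 3e-6.
#' @return An object of class `burden_scan`: a list with `results` (one row
#'   per reported variant: key, coordinates, gene, MAFs, `pmaf`, `p_ind`,
#'   `n_carrying`, `n_total`, `raw_p`, `fdr`), `mode`, `n_tests`, `n_total`,
#'   and `tail`.
#' @seealso [summary.burden_scan()], [plot.burden_scan()]
#' @export
burden_scan <- function(variants, genotypes,
                        mode = c("dominant", "recessive"),
                        tail = FALSE, missing_maf_default = 3e-6) {
  mode <- match.arg(mode)
  cl <- match.call()

  keys <- intersect(variants$key, rownames(genotypes$dosage))
  v <- variants[match(keys, variants$key), , drop = FALSE]
  if (mode == "recessive") {
    v <- v[normalize_chrom(v$chrom) != "X", , drop = FALSE]
  }
  n_total <- ncol(genotypes$dosage)
  n_tests <- nrow(v)

  if (n_tests == 0L) {
    res <- data.frame(key = character(), chrom = character(), pos = integer(),
                      ref = character(), alt = character(), gene = character(),
                      maf_genomes = numeric(), maf_exomes = numeric(),
                      pmaf = numeric(), p_ind = numeric(),
                      n_carrying = integer(), n_total = integer(),
                      raw_p = numeric(), fdr = numeric(),
                      stringsAsFactors = FALSE)
    return(structure(list(results = res, mode = mode, n_tests = 0L,
                          n_total = n_total, tail = tail, call = cl),
                     class = "burden_scan"))
  }

  dos <- genotypes$dosage[v$key, , drop = FALSE]
  if (anyNA(dos)) {
    stop("missing dosage encountered; apply the call-rate filter first",
         call. = FALSE)
  }
  pmaf <- resolve_pmaf(v$maf_genomes, v$maf_exomes, missing_maf_default)
  p_ind <- if (mode == "dominant") p_ind_dominant(pmaf) else p_ind_recessive(pmaf)
  n_carrying <- if (mode == "dominant") {
    as.integer(rowSums(dos >= 1L))
  } else {
    as.integer(rowSums(dos == 2L))
  }
  raw_p <- overrepresentation_p(n_carrying, n_total, p_ind, tail = tail)
  fdr <- bonferroni_adjust(raw_p, n_tests)

  res <- data.frame(key = v$key, chrom = v$chrom, pos = v$pos, ref = v$ref,
                    alt = v$alt, gene = v$gene,
                    maf_genomes = v$maf_genomes, maf_exomes = v$maf_exomes,
                    pmaf = pmaf, p_ind = p_ind, n_carrying = n_carrying,
                    n_total = n_total, raw_p = raw_p, fdr = fdr,
                    stringsAsFactors = FALSE)
  if (mode == "recessive") {
    res <- res[res$n_carrying >= 1L, , drop = FALSE]
  }
  res <- res[order(res$raw_p, res$chrom, res$pos, res$alt), , drop = FALSE]
  rownames(res) <- NULL
  structure(list(results = res, mode = mode, n_tests = n_tests,
                 n_total = n_total, tail = tail, call = cl),
            class = "burden_scan")
}

#' @export
print.burden_scan <- function(x, n = 6L, ...) {
  cat(sprintf("Rare-variant carrier burden scan (%s model)\n", x$mode))
  cat(sprintf("  %d samples, %d variants tested (Bonferroni multiplier)\n",
              x$n_total, x$n_tests))
  if (x$tail) cat("  statistic: upper-tail binomial probability\n")
  cat(sprintf("  %d variants reported; top %d by raw probability:\n",
              nrow(x$results), min(n, nrow(x$results))))
  if (nrow(x$results)) {
    show <- utils::head(x$results[, c("key", "gene", "pmaf", "n_carrying",
                                      "raw_p", "fdr")], n)
    print(format(show, digits = 4), row.names = FALSE)
  }
  invisible(x)
}

#' Summarize a burden scan
#'
#' Reports hit counts at the three adjusted-significance tiers convention for
#' these scans (0.05, 0.1, 0.2) and the carrier-count spectrum.
#'
#' @param object A `burden_scan`.
#' @param tiers Adjusted-value cutoffs to tabulate.
#' @param ... Unused.
#' @export
summary.burden_scan <- function(object, tiers = c(0.05, 0.1, 0.2), ...) {
  res <- object$results
  out <- list(
    mode = object$mode,
    n_tests = object$n_tests,
    n_total = object$n_total,
    hits = stats::setNames(
      vapply(tiers, function(t) sum(res$fdr < t), integer(1)),
      paste0("fdr<", tiers)),
    carrier_spectrum = if (nrow(res)) table(res$n_carrying) else table(integer())
  )
  class(out) <- "summary.burden_scan"
  out
}

#' @export
print.summary.burden_scan <- function(x, ...) {
  cat(sprintf("Burden scan summary (%s): %d samples, %d tests\n",
              x$mode, x$n_total, x$n_tests))
  cat("  significant variants:",
      paste(names(x$hits), x$hits, collapse = " | "), "\n")
  cat("  carrier-count spectrum:\n")
  print(x$carrier_spectrum)
  invisible(x)
}

#' Scatter plot of a burden scan
#'
#' Plots `-log10` raw probability against the cohort carrier count, one point
#' per variant, with dashed lines marking adjusted significance at 0.05
#' (red), 0.1 (blue) and 0.2 (green).
#'
#' @param x A `burden_scan`.
#' @param tiers Adjusted-value cutoffs for the dashed lines.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.burden_scan <- function(x, tiers = c(0.05, 0.1, 0.2), ...) {
  res <- x$results
  if (!nrow(res)) {
    warning("empty scan; nothing to plot", call. = FALSE)
    return(invisible(x))
  }
  graphics::plot(res$n_carrying, -log10(res$raw_p),
                 xlab = "samples carrying variant",
                 ylab = expression(-log[10] ~ "raw probability"),
                 main = sprintf("Carrier overrepresentation (%s)", x$mode),
                 pch = 16, col = "grey30", ...)
  cols <- c("red", "blue", "darkgreen")
  for (i in seq_along(tiers)) {
    graphics::abline(h = -log10(tiers[i] / x$n_tests), lty = 2, col = cols[i])
  }
  invisible(x)
}

#' @export
as.data.frame.burden_scan <- function(x, ...) x$results

#' Write burden-scan results to TSV
#'
#' @param scan A `burden_scan`.
#' @param path Output path.
#' @export
write_burden_scan <- function(scan, path) {
  write_tsv_dot(scan$results, path)
}
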