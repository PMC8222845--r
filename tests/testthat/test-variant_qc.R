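test_that("genotype masking applies GQ and allele-balance rules with inclusive boundaries", {
  dos <- matrix(c(1L, 1L, 1L, 0L, 2L), nrow = 5,
                dimnames = list(paste0("1:", 1:5, ":A:G"), "S1"))
  gq <- matrix(c(19, 20, 20, 19, 20), 5, 1, dimnames = dimnames(dos))
  ad_ref <- matrix(c(10, 3, 10, 50, 0), 5, 1, dimnames = dimnames(dos))
  ad_alt <- matrix(c(10, 17, 10, 0, 50), 5, 1, dimnames = dimnames(dos))
  dp <- ad_ref + ad_alt
  g <- genotype_calls(dos, gq, dp, ad_ref, ad_alt)

  m <- mask_low_quality_genotypes(g, qc_thresholds())
  # het GQ 19 -> missing; het AB 0.85 -> missing; het AB 0.5 kept;
  # hom-ref GQ 19 -> missing; hom-alt untouched by AB rule
  expect_equal(unname(m$dosage[, 1]), c(NA, NA, 1L, NA, 2L))
  expect_equal(attr(m, "mask_counts")[["gq"]], 2L)
  expect_equal(attr(m, "mask_counts")[["allele_balance"]], 1L)

  # boundary values kept: AB exactly 0.2 and 0.8
  dos2 <- matrix(c(1L, 1L), 2, 1, dimnames = list(c("1:1:A:G", "1:2:A:G"), "S1"))
  g2 <- genotype_calls(dos2, gq = matrix(20, 2, 1, dimnames = dimnames(dos2)),
                       dp = matrix(10, 2, 1, dimnames = dimnames(dos2)),
                       ad_ref = matrix(c(8, 2), 2, 1, dimnames = dimnames(dos2)),
                       ad_alt = matrix(c(2, 8), 2, 1, dimnames = dimnames(dos2)))
  m2 <- mask_low_quality_genotypes(g2)
  expect_equal(unname(m2$dosage[, 1]), c(1L, 1L))
})

test_that("heterozygotes without AD follow the configured policy", {
  dos <- matrix(1L, 1, 1, dimnames = list("1:1:A:G", "S1"))
  g <- genotype_calls(dos, gq = matrix(50, 1, 1, dimnames = dimnames(dos)))
  masked <- mask_low_quality_genotypes(g, het_missing_ad = "mask")
  expect_true(is.na(masked$dosage[1, 1]))
  expect_equal(attr(masked, "mask_counts")[["het_missing_ad"]], 1L)
  kept <- mask_low_quality_genotypes(g, het_missing_ad = "keep")
  expect_equal(kept$dosage[1, 1], 1L, ignore_attr = TRUE)
})

test_that("HWE exact p-values match an exact-rational enumeration oracle", {
  # expected values computed once by full enumeration of heterozygote counts
  # conditional on allele counts, in exact rational arithmetic
  cases <- list(
    list(c(25, 50, 25), 1.0),
    list(c(0, 0, 93), 1.0),
    list(c(5, 5, 5), 0.2978949121930263),
    list(c(10, 3, 2), 0.12337164750957855),
    list(c(1, 1, 13), 0.10344827586206896),
    list(c(3, 7, 2), 1.0),
    list(c(0, 2, 13), 1.0),
    list(c(7, 0, 8), 4.425032066010339e-05),
    list(c(2, 2, 2), 0.4805194805194805)
  )
  for (cs in cases) {
    expect_equal(hwe_exact_p(cs[[1]][1], cs[[1]][2], cs[[1]][3]), cs[[2]],
                 tolerance = 1e-12, info = paste(cs[[1]], collapse = ","))
  }
  # extreme heterozygote deficit at 50% frequency is far below 1e-6
  expect_lt(hwe_exact_p(50, 0, 50), 1e-6)
  expect_error(hwe_exact_p(0, 0, 0), "zero")
})

test_that("HWE exact p is symmetric in hom counts and valid over small configurations", {
  set.seed(31)
  for (i in 1:60) {
    n <- sample(2:15, 1)
    n0 <- sample(0:n, 1); n1 <- sample(0:(n - n0), 1); n2 <- n - n0 - n1
    p <- hwe_exact_p(n0, n1, n2)
    expect_equal(p, hwe_exact_p(n2, n1, n0), tolerance = 1e-12)
    expect_gt(p, 0)
    expect_lte(p, 1)
    # direct-summation oracle in plain double arithmetic (<= 30 alleles, so
    # factorials are modest and the naive form is accurate)
    na <- 2 * n0 + n1; nb <- 2 * n2 + n1
    nm <- min(na, nb)
    if (nm > 0) {
      hets <- seq(nm %% 2, nm, by = 2)
      w <- vapply(hets, function(h) {
        homm <- (nm - h) / 2; homM <- n - h - homm
        if (homM < 0) return(0)
        factorial(n) / (factorial(homm) * factorial(h) * factorial(homM)) * 2^h
      }, numeric(1))
      pr <- w / sum(w)
      pobs <- pr[match(n1, hets)]
      expect_equal(p, sum(pr[pr <= pobs * (1 + 1e-7)]), tolerance = 1e-9)
    }
  }
})

test_that("chi-square HWE option agrees with the asymptotic test", {
  p <- hwe_exact_p(300, 500, 200, method = "chisq")
  q <- (2 * 200 + 500) / 2000
  e <- 1000 * c((1 - q)^2, 2 * q * (1 - q), q^2)
  stat <- sum((c(300, 500, 200) - e)^2 / e)
  expect_equal(p, pchisq(stat, 1, lower.tail = FALSE))
})

test_that("variant filters drop by depth, HWE and call rate in order, with a reconciled report", {
  # 10 variants engineered so exactly 3 survive:
  #  v1-v3 clean; v4,v5 low depth; v6,v7 HWE failures; v8-v10 incomplete calls
  n <- 40
  dos <- matrix(rep(c(0L, 1L), each = n / 2), nrow = 10, ncol = n, byrow = TRUE)
  dos[6, ] <- rep(c(0L, 2L), each = n / 2)   # total het deficit
  dos[7, ] <- rep(c(0L, 2L), each = n / 2)
  rownames(dos) <- paste0("1:", 1:10, ":A:G")
  colnames(dos) <- sprintf("S%02d", 1:n)
  g <- make_genotypes(dos)
  g$dp[4, 3] <- 9
  g$dp[5, 1] <- 0
  g$dosage[8, 1] <- NA
  g$dosage[9, 1:5] <- NA
  g$dosage[10, n] <- NA

  out <- filter_variants(g, qc_thresholds())
  expect_equal(rownames(out$genotypes$dosage), paste0("1:", 1:3, ":A:G"))
  expect_equal(unname(out$report$removed),
               c(2L, 2L, 3L))
  expect_equal(out$report$variants_out, 3L)
  expect_equal(out$report$variants_in - sum(out$report$removed),
               out$report$variants_out)

  # DP exactly 10 is kept
  g2 <- make_genotypes(matrix(c(0L, 1L), 1, 2), dp = 10)
  expect_equal(nrow(filter_variants(g2)$genotypes$dosage), 1L)
})

test_that("variant filtering is idempotent", {
  sim <- simulate_cohort(sim_config(n_samples = 20, n_variants = 80, seed = 5))
  crp <- corrupt_for_qc(sim$genotypes,
                        rates = list(low_gq = 0.01, low_dp = 0.05,
                                     skew_ab = 0.02, missing = 0.01),
                        seed = 9)
  masked <- mask_low_quality_genotypes(crp$genotypes)
  once <- filter_variants(masked)
  twice <- filter_variants(once$genotypes)
  expect_equal(twice$genotypes$dosage, once$genotypes$dosage)
  expect_equal(sum(twice$report$removed), 0L)
})
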