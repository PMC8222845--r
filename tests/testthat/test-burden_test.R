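test_that("per-individual carrier probabilities follow the inheritance model", {
  expect_equal(p_ind_dominant(0), 0)
  expect_equal(p_ind_dominant(1), 1)
  expect_equal(p_ind_dominant(0.0359), 2 * 0.0359 * 0.9641 + 0.0359^2)
  expect_equal(p_ind_recessive(0.0001), 1e-8)
  expect_equal(p_ind_recessive(0), 0)
  expect_equal(p_ind_recessive(1), 1)
  expect_error(p_ind_dominant(-0.1))
  expect_error(p_ind_recessive(1.5))
  # dominant carrier probability is the complement of carrying no alt allele
  q <- c(1e-6, 1e-3, 0.01, 0.05, 0.3)
  expect_equal(p_ind_dominant(q), 1 - (1 - q)^2)
})

test_that("carrier counting distinguishes dominant and recessive carriers", {
  expect_equal(carrier_count(c(0, 1, 2, 0), "dominant"), 2L)
  expect_equal(carrier_count(c(0, 1, 2, 2), "recessive"), 2L)
  expect_equal(carrier_count(c(1, 1, 1), "recessive"), 0L)
  expect_error(carrier_count(c(0, NA, 1), "dominant"), "missing")
})

test_that("the binomial point mass matches frozen exact-rational values", {
  # computed once in exact rational arithmetic (rational p), then frozen
  frozen <- list(
    list(3, 10, 1 / 32, 2.932333214751282e-03),
    list(20, 93, 0.07051119, 4.718343801627730e-06),
    list(0, 5, 3 / 100, 8.587340257000000e-01),
    list(60, 60, 1 / 2, 8.673617379884035e-19),
    list(7, 45, 1 / 10, 8.280874705515852e-02)
  )
  for (f in frozen) {
    expect_equal(overrepresentation_p(f[[1]], f[[2]], f[[3]]), f[[4]],
                 tolerance = 1e-12)
  }
})

test_that("the point mass agrees with dbinom to 1e-10 relative error for all k <= N <= 60", {
  for (N in c(1, 2, 7, 17, 33, 60)) {
    for (p in c(1e-8, 3e-6, 1e-3, 0.0591, 0.25, 0.5, 0.93)) {
      k <- 0:N
      mine <- overrepresentation_p(k, N, p)
      ref <- dbinom(k, N, p)
      expect_equal(mine, ref, tolerance = 1e-10,
                   info = sprintf("N=%d p=%g", N, p))
    }
  }
})

test_that("the point mass normalizes to 1 over k for N up to 200", {
  for (N in c(10, 93, 200)) {
    for (p in c(1e-8, 3e-6, 1e-4, 0.01, 0.0705, 0.5, 0.99)) {
      expect_equal(sum(overrepresentation_p(0:N, N, p)), 1, tolerance = 1e-9)
    }
  }
})

test_that("degenerate and tail variants of the statistic behave", {
  expect_equal(overrepresentation_p(0, 93, 0), 1)
  expect_warning(z <- overrepresentation_p(3, 93, 0), "p_ind = 0")
  expect_equal(z, 0)
  expect_error(overrepresentation_p(5, 3, 0.1), "n_total")
  # upper tail option is a proper tail sum
  expect_equal(overrepresentation_p(4, 10, 0.2, tail = TRUE),
               pbinom(3, 10, 0.2, lower.tail = FALSE))
  expect_gte(overrepresentation_p(4, 10, 0.2, tail = TRUE),
             overrepresentation_p(4, 10, 0.2))
})

test_that("Bonferroni adjustment multiplies and caps at one", {
  expect_equal(bonferroni_adjust(0.5, 3), 1)
  expect_equal(bonferroni_adjust(1e-6, 42325), 0.042325)
  raw <- overrepresentation_p(20, 93, p_ind_dominant(0.0359))
  expect_equal(round(bonferroni_adjust(raw, 42325), 4), 0.1997)
})

test_that("an injected overrepresented variant ranks first in a dominant scan", {
  cfg <- sim_config(n_samples = 93, n_variants = 300, seed = 17,
                    injected = data.frame(index = 42, carrier_prob = 0.5,
                                          mode = "dominant"),
                    quality = FALSE)
  sim <- simulate_cohort(cfg)
  # the injected variant's carrier frequency is ~10x its null p_ind
  v <- sim$variants
  v$func_region[42] <- "exonic"; v$exonic_func[42] <- "nonsynonymous SNV"
  v$pseudogene_flag[42] <- FALSE
  v$maf_exomes[42] <- 0.02; v$maf_genomes[42] <- NA
  vr <- suppressWarnings(select_rare_variants(v))
  scan <- burden_scan(vr, sim$genotypes, "dominant")
  expect_equal(scan$results$key[1], sim$variants$key[42])
  # independent check: raw_p recomputed per variant with dbinom
  dos <- sim$genotypes$dosage[scan$results$key, ]
  raw_chk <- dbinom(rowSums(dos >= 1), 93, scan$results$p_ind)
  expect_equal(scan$results$raw_p, unname(raw_chk), tolerance = 1e-12)
  expect_true(all(diff(scan$results$raw_p) >= 0))
  # n_tests is constant and equals the variant count entering the scan
  expect_equal(scan$n_tests, nrow(vr))
  expect_equal(scan$results$fdr, pmin(1, scan$results$raw_p * scan$n_tests))
})

test_that("the recessive scan excludes X, reports homozygote carriers, and keeps the full multiplier", {
  v <- rbind(
    make_variants(4, chrom = "1", gene = "GA"),
    make_variants(3, chrom = "X", gene = "GX")
  )
  dos <- matrix(0L, 7, 10, dimnames = list(v$key, sprintf("S%02d", 1:10)))
  dos[1, 1:2] <- 2L   # autosomal homozygote carriers
  dos[2, 1] <- 1L     # het only: not a recessive carrier
  dos[5, 1:5] <- 2L   # X homozygotes must not appear
  g <- genotype_calls(dos)
  scan <- burden_scan(v, g, "recessive")
  expect_equal(scan$n_tests, 4L)
  expect_equal(scan$results$key, v$key[1])
  expect_equal(scan$results$n_carrying, 2L)
  expect_equal(scan$results$fdr, scan$results$raw_p * 4)

  # X-only cohort: empty result, zero tests
  vx <- v[v$chrom == "X", ]
  gx <- genotype_calls(dos[vx$key, , drop = FALSE])
  sx <- burden_scan(vx, gx, "recessive")
  expect_equal(nrow(sx$results), 0L)
  expect_equal(sx$n_tests, 0L)
})

test_that("a null cohort at expectation-level carrier counts yields no adjusted hits", {
  # every variant carried by round(N * p_ind) samples: the modal outcome
  set.seed(8)
  n <- 93
  q <- exp(runif(150, log(1e-4), log(0.049)))
  v <- do.call(rbind, lapply(seq_along(q), function(i) {
    make_variant(pos = i, maf_exomes = signif(q[i], 6))
  }))
  p_ind <- p_ind_dominant(v$maf_exomes)
  dos <- matrix(0L, nrow(v), n, dimnames = list(v$key, sprintf("S%03d", 1:n)))
  for (i in seq_len(nrow(v))) {
    k <- round(n * p_ind[i])
    if (k > 0) dos[i, seq_len(k)] <- 1L
  }
  scan <- burden_scan(v, genotype_calls(dos), "dominant")
  expect_gt(min(scan$results$fdr), 0.05)
})

test_that("scan ties are broken by chromosome, position and allele", {
  v <- rbind(make_variant(chrom = "2", pos = 10L),
             make_variant(chrom = "1", pos = 99L),
             make_variant(chrom = "1", pos = 99L, alt = "C"))
  dos <- matrix(0L, 3, 5, dimnames = list(v$key, sprintf("S%d", 1:5)))
  scan <- burden_scan(v, genotype_calls(dos), "dominant")
  expect_equal(scan$results$raw_p, rep(scan$results$raw_p[1], 3))
  expect_equal(scan$results$alt, c("C", "G", "G"))
  expect_equal(scan$results$chrom, c("1", "1", "2"))
})
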