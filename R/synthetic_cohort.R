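#' Configuration for a synthetic cohort
#'
#' Describes a fully synthetic disease-centralized exome cohort: an annotated
#' variant table, a genotype matrix with quality fields, a protein-length
#' table, and a truth file. Defaults emulate a 93-sample whole-exome cohort:
#' a log-uniform population MAF spectrum over `[1e-5, 0.05)`, genotypes drawn
#' under Hardy-Weinberg proportions at each variant's true frequency, and
#' per-genotype GQ/DP/AD decorations at exome-typical coverage (mean depth
#' 85). Enrichment is injected by giving selected variants a per-sample
#' carrier probability above their Hardy-Weinberg null.
#'
#' Randomness is drawn from three purpose-specific streams (annotations,
#' genotypes, quality) derived from the master seed, so e.g. switching
#' quality decoration on or off does not perturb the genotype draws.
#'
#' @param n_samples Cohort size. Default 93.
#' @param n_variants Number of simulated variants. Default 2000.
#' @param seed Master seed; fully determines all outputs.
#' @param maf_range Log-uniform support for true population MAFs.
#' @param missing_maf_rate Fraction of variants with both panel MAF fields
#'   absent. Default 0.05.
#' @param injected `NULL`, or a data frame with columns `index` (variant
#'   row), `carrier_prob` (true per-sample carrier probability), and `mode`
#'   (`"dominant"` or `"recessive"`).
#' @param mean_depth Mean sequencing depth for the quality model. Default 85.
#' @param x_rate Fraction of variants placed on the X chromosome. Default 0.05.
#' @param quality Decorate genotypes with GQ/DP/AD fields. Default `TRUE`;
#'   turning it off speeds up large simulation studies that only use dosages.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_samples = 93L, n_variants = 2000L, seed = 1L,
                       maf_range = c(1e-5, 0.05), missing_maf_rate = 0.05,
                       injected = NULL, mean_depth = 85, x_rate = 0.05,
                       quality = TRUE) {
  stopifnot(n_samples >= 1, n_variants >= 1,
            maf_range[1] > 0, maf_range[2] <= 1, maf_range[1] < maf_range[2],
            missing_maf_rate >= 0, missing_maf_rate <= 1)
  if (!is.null(injected)) {
    stopifnot(all(c("index", "carrier_prob", "mode") %in% names(injected)))
    if (any(injected$index < 1 | injected$index > n_variants)) {
      stop("injected variant index out of range", call. = FALSE)
    }
    stopifnot(all(injected$carrier_prob >= 0 & injected$carrier_prob <= 1))
  }
  structure(list(n_samples = as.integer(n_samples),
                 n_variants = as.integer(n_variants), seed = as.integer(seed),
                 maf_range = maf_range, missing_maf_rate = missing_maf_rate,
                 injected = injected, mean_depth = mean_depth,
                 x_rate = x_rate, quality = quality),
            class = "sim_config")
}

# purpose-specific sub-seeds derived deterministically from the master seed
.sim_substream_seeds <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  stats::setNames(sample.int(.Machine$integer.max - 1L, 3L),
                  c("annotations", "genotypes", "quality"))
}

.sim_func_region_probs <- c(
  exonic = 0.80, splicing = 0.02, intronic = 0.07, UTR3 = 0.03, UTR5 = 0.02,
  ncRNA_exonic = 0.02, ncRNA_intronic = 0.01, upstream = 0.01,
  downstream = 0.01, intergenic = 0.01)

.sim_exonic_func_probs <- c(
  "nonsynonymous SNV" = 0.58, "synonymous SNV" = 0.30,
  "frameshift insertion" = 0.02, "frameshift deletion" = 0.02,
  "nonframeshift insertion" = 0.015, "nonframeshift deletion" = 0.015,
  "stopgain" = 0.04, "stoploss" = 0.01)

#' Simulate a synthetic cohort
#'
#' Generates the four cross-consistent inputs the pipeline consumes. Under
#' the null, the genotype of each sample at each autosomal-style variant is
#' drawn as Binomial(2, q) alternate alleles at the variant's true population
#' MAF q — Hardy-Weinberg proportions — so the cohort carrier count is
#' Binomial(n_samples, p_ind(q)) under either inheritance model. Injected
#' variants instead make each sample a carrier with the specified
#' probability (heterozygous for dominant injections, homozygous alternate
#' for recessive ones).
#'
#' The annotated table reports the true MAF in the genomes/exomes columns
#' (exomes exact, genomes within 10 percent), with a configurable fraction of
#' variants missing from both panels; functional categories, predictor
#' calls, gene assignment and protein lengths are drawn from fixed
#' cohort-realistic distributions.
#'
#' @param config A [sim_config].
#' @return A list of class `sim_cohort`: `variants` (annotated data frame),
#'   `genotypes` ([genotype_calls]), `protein_lengths` (named vector),
#'   `truth` (per-variant data frame: key, true MAF, true carrier
#'   probability per mode, injected flag, gene).
#' @export
#' @examples
#' sim <- simulate_cohort(sim_config(n_samples = 10, n_variants = 50, seed = 7))
#' sim$genotypes
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  seeds <- .sim_substream_seeds(config$seed)
  nv <- config$n_variants
  ns <- config$n_samples

  ## --- annotations stream ---
  set.seed(seeds[["annotations"]])
  n_x <- round(config$x_rate * nv)
  chrom <- c(sample(as.character(1:22), nv - n_x, replace = TRUE),
             rep("X", n_x))
  chrom <- sample(chrom)
  pos <- sample.int(2.4e8, nv, replace = TRUE)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, nv, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))

  func_region <- sample(names(.sim_func_region_probs), nv, replace = TRUE,
                        prob = .sim_func_region_probs)
  exonic_func <- rep(NA_character_, nv)
  is_ex <- func_region == "exonic"
  exonic_func[is_ex] <- sample(names(.sim_exonic_func_probs), sum(is_ex),
                               replace = TRUE, prob = .sim_exonic_func_probs)

  q <- exp(stats::runif(nv, log(config$maf_range[1]), log(config$maf_range[2])))
  both_missing <- stats::runif(nv) < config$missing_maf_rate
  maf_exomes <- signif(q, 4)
  maf_genomes <- signif(q * stats::runif(nv, 0.9, 1.1), 4)
  genomes_only_missing <- stats::runif(nv) < 0.15
  maf_genomes[genomes_only_missing] <- NA_real_
  maf_exomes[both_missing] <- NA_real_
  maf_genomes[both_missing] <- NA_real_

  nonsyn <- !is.na(exonic_func) & exonic_func == "nonsynonymous SNV"
  draw_pred <- function(levels, probs) {
    out <- rep(NA_character_, nv)
    out[nonsyn] <- sample(levels, sum(nonsyn), replace = TRUE, prob = probs)
    out[out == "."] <- NA_character_
    out
  }
  sift <- draw_pred(c("D", "T", "."), c(0.35, 0.55, 0.10))
  polyphen <- draw_pred(c("D", "P", "B", "."), c(0.30, 0.15, 0.45, 0.10))
  fathmm <- draw_pred(c("D", "N", "."), c(0.35, 0.55, 0.10))
  cadd <- rep(NA_real_, nv)
  cadd[nonsyn] <- round(stats::rgamma(sum(nonsyn), shape = 3, scale = 5), 2)
  pseudo <- stats::runif(nv) < 0.01

  # genes: contiguous partition, 1 + Poisson(2) variants per gene
  sizes <- integer(0)
  while (sum(sizes) < nv) sizes <- c(sizes, 1L + stats::rpois(64, 2))
  gene_id <- rep(seq_along(sizes), times = sizes)[seq_len(nv)]
  gene <- sprintf("G%04d", gene_id)
  lengths <- stats::setNames(
    pmax(50L, as.integer(round(stats::rlnorm(max(gene_id), log(450), 0.6)))),
    sprintf("G%04d", seq_len(max(gene_id))))

  variants <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                         gene = gene, func_region = func_region,
                         exonic_func = exonic_func,
                         maf_genomes = maf_genomes, maf_exomes = maf_exomes,
                         sift = sift, polyphen_hvar = polyphen,
                         cadd_phred = cadd, fathmm_mkl = fathmm,
                         pseudogene_flag = pseudo, stringsAsFactors = FALSE)
  # keys must be unique; regenerate positions for any collision
  variants$key <- variant_key(variants$chrom, variants$pos, variants$ref, variants$alt)
  while (anyDuplicated(variants$key)) {
    d <- duplicated(variants$key)
    variants$pos[d] <- sample.int(2.4e8, sum(d), replace = TRUE)
    variants$key <- variant_key(variants$chrom, variants$pos, variants$ref, variants$alt)
  }

  ## --- genotypes stream ---
  set.seed(seeds[["genotypes"]])
  dosage <- matrix(stats::rbinom(nv * ns, 2L, rep(q, ns)), nrow = nv, ncol = ns)
  carrier_prob_dom <- p_ind_dominant(q)
  injected_flag <- rep(FALSE, nv)
  if (!is.null(config$injected)) {
    for (r in seq_len(nrow(config$injected))) {
      i <- config$injected$index[r]
      cp <- config$injected$carrier_prob[r]
      md <- config$injected$mode[r]
      carr <- stats::rbinom(ns, 1L, cp)
      dosage[i, ] <- carr * if (md == "recessive") 2L else 1L
      injected_flag[i] <- TRUE
      carrier_prob_dom[i] <- cp
    }
  }
  dimnames(dosage) <- list(variants$key, sprintf("S%03d", seq_len(ns)))

  ## --- quality stream ---
  if (config$quality) {
    set.seed(seeds[["quality"]])
    n_cell <- nv * ns
    gq <- matrix(pmin(99, pmax(0, round(stats::rnorm(n_cell, 70, 10)))), nv, ns)
    dp <- matrix(stats::rpois(n_cell, config$mean_depth), nv, ns)
    het <- dosage == 1L
    ad_alt <- matrix(0L, nv, ns)
    ad_alt[het] <- stats::rbinom(sum(het), dp[het], 0.5)
    ad_alt[dosage == 2L] <- dp[dosage == 2L]
    ad_ref <- dp - ad_alt
    dimnames(gq) <- dimnames(dp) <- dimnames(ad_ref) <- dimnames(ad_alt) <-
      dimnames(dosage)
    genotypes <- genotype_calls(dosage, gq, dp, ad_ref, ad_alt)
  } else {
    genotypes <- genotype_calls(dosage)
  }

  true_cp_rec <- p_ind_recessive(q)
  if (!is.null(config$injected)) {
    is_rec <- config$injected$mode == "recessive"
    true_cp_rec[config$injected$index[is_rec]] <- config$injected$carrier_prob[is_rec]
    true_cp_rec[config$injected$index[!is_rec]] <- 0  # dominant injections are het
  }
  truth <- data.frame(key = variants$key, true_maf = q,
                      true_carrier_prob_dominant = carrier_prob_dom,
                      true_carrier_prob_recessive = true_cp_rec,
                      injected = injected_flag, gene = gene,
                      stringsAsFactors = FALSE)

  structure(list(variants = variants, genotypes = genotypes,
                 protein_lengths = lengths, truth = truth, config = config),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d samples x %d variants (seed %d)\n",
              x$config$n_samples, x$config$n_variants, x$config$seed))
  cat(sprintf("  %d injected enrichment variant(s); %d genes\n",
              sum(x$truth$injected), length(x$protein_lengths)))
  invisible(x)
}

#' Plant QC-violating genotypes
#'
#' Corrupts a quality-decorated genotype matrix so each QC filter has known
#' work to do: low-GQ calls, low-depth samples at selected variants,
#' allele-balance-skewed heterozygotes, and missing calls. The exact planted
#' positions and counts are returned so QC removal counts can be asserted
#' exactly.
#'
#' @param genotypes A [genotype_calls] with quality fields.
#' @param rates Named list with any of `low_gq`, `low_dp`, `skew_ab`,
#'   `missing`: per-cell (per-variant for `low_dp`) corruption probabilities
#'   in `[0, 1]`.
#' @param seed Seed for the corruption draws.
#' @return List with `genotypes` (corrupted) and `planted` (list of index
#'   matrices/vectors per corruption type, plus `counts`).
#' @export
corrupt_for_qc <- function(genotypes, rates = list(), seed = 1L) {
  defaults <- list(low_gq = 0, low_dp = 0, skew_ab = 0, missing = 0)
  rates <- utils::modifyList(defaults, rates)
  if (any(unlist(rates) < 0 | unlist(rates) > 1)) {
    stop("corruption rates must lie in [0, 1]", call. = FALSE)
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  dos <- genotypes$dosage
  nv <- nrow(dos); ns <- ncol(dos)
  planted <- list()

  # low GQ: called cells get GQ in [0, 19]
  cells <- which(!is.na(dos) & stats::runif(nv * ns) < rates$low_gq)
  genotypes$gq[cells] <- sample(0:19, length(cells), replace = TRUE)
  planted$low_gq <- cells

  # low depth: one sample's DP dropped below 10 at selected variants
  vars <- which(stats::runif(nv) < rates$low_dp)
  for (i in vars) {
    j <- sample.int(ns, 1L)
    genotypes$dp[i, j] <- sample(0:9, 1L)
    genotypes$ad_ref[i, j] <- min(genotypes$ad_ref[i, j], genotypes$dp[i, j],
                                  na.rm = TRUE)
    genotypes$ad_alt[i, j] <- genotypes$dp[i, j] - genotypes$ad_ref[i, j]
  }
  planted$low_dp <- vars

  # skewed allele balance: het cells forced to AB = 0.1
  het <- which(!is.na(dos) & dos == 1L & stats::runif(nv * ns) < rates$skew_ab)
  het <- setdiff(het, cells)  # keep corruption types disjoint for exact counts
  dp_h <- genotypes$dp[het]
  dp_h[is.na(dp_h)] <- 20
  genotypes$dp[het] <- dp_h
  genotypes$ad_alt[het] <- pmax(1L, round(0.1 * dp_h))
  genotypes$ad_ref[het] <- dp_h - genotypes$ad_alt[het]
  planted$skew_ab <- het

  # missing calls; disjoint from the other planted cells so QC mask counts
  # can be asserted exactly
  miss <- which(!is.na(dos) & stats::runif(nv * ns) < rates$missing)
  miss <- setdiff(miss, c(cells, het))
  genotypes$dosage[miss] <- NA_integer_
  planted$missing <- miss

  planted$counts <- c(low_gq = length(planted$low_gq),
                      low_dp = length(planted$low_dp),
                      skew_ab = length(planted$skew_ab),
                      missing = length(planted$missing))
  list(genotypes = genotypes, planted = planted)
}

#' Write a synthetic cohort to a directory
#'
#' Emits the package TSV dialects (`variants.tsv`, `genotypes.tsv`,
#' `protein_lengths.tsv`, `truth.tsv`) and optionally a minimal VCF with
#' GT:GQ:DP:AD FORMAT fields. Identical configurations produce byte-identical
#' files.
#'
#' @param sim A `sim_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @param vcf Also write `cohort.vcf`. Default `FALSE`.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(sim, dir, vcf = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_variants(sim$variants, file.path(dir, "variants.tsv"))
  write_genotypes(sim$genotypes, file.path(dir, "genotypes.tsv"))
  write_tsv_dot(data.frame(gene = names(sim$protein_lengths),
                           protein_length = unname(sim$protein_lengths)),
                file.path(dir, "protein_lengths.tsv"))
  write_tsv_dot(sim$truth, file.path(dir, "truth.tsv"))
  if (vcf) write_cohort_vcf(sim, file.path(dir, "cohort.vcf"))
  invisible(dir)
}

# minimal single-alt VCF emitter for the synthetic cohort
write_cohort_vcf <- function(sim, path) {
  v <- sim$variants
  g <- sim$genotypes
  samples <- colnames(g$dosage)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
               "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
               "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", samples), collapse = "\t")), con)
  gt_str <- matrix(c("0/0", "0/1", "1/1")[g$dosage + 1L],
                   nrow = nrow(g$dosage))
  gt_str[is.na(g$dosage)] <- "./."
  fmt_num <- function(m) { s <- as.character(m); s[is.na(m)] <- "."; matrix(s, nrow = nrow(m)) }
  gq <- fmt_num(g$gq); dp <- fmt_num(g$dp)
  ad <- matrix(paste(ifelse(is.na(g$ad_ref), ".", g$ad_ref),
                     ifelse(is.na(g$ad_alt), ".", g$ad_alt), sep = ","),
               nrow = nrow(g$dosage))
  for (i in seq_len(nrow(v))) {
    cells <- paste(gt_str[i, ], gq[i, ], dp[i, ], ad[i, ], sep = ":")
    writeLines(paste(c(v$chrom[i], v$pos[i], ".", v$ref[i], v$alt[i], ".",
                       "PASS", ".", "GT:GQ:DP:AD", cells), collapse = "\t"), con)
  }
  invisible(path)
}
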