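#' Exonic categories that qualify as damaging by type
#'
#' Protein-truncating or length-changing categories that qualify a variant
#' for gene-level collapsing without any predictor vote. Aliases with spaces
#' ("stop gain", "stop loss") are mapped onto the compact annotation spelling
#' via [exonic_func_synonyms()].
#'
#' @return Character vector of category names.
#' @export
damaging_indel_categories <- function() {
  c("frameshift insertion", "frameshift deletion", "stopgain", "stoploss",
    "nonframeshift insertion", "nonframeshift deletion")
}

#' @rdname damaging_indel_categories
#' @export
exonic_func_synonyms <- function() {
  c("stop gain" = "stopgain", "stop loss" = "stoploss",
    "stop-gain" = "stopgain", "stop-loss" = "stoploss")
}

canon_exonic_func <- function(x, synonyms = exonic_func_synonyms()) {
  hit <- x %in% names(synonyms)
  x[hit] <- synonyms[x[hit]]
  x
}

#' Classify variants as damaging
#'
#' A variant qualifies for gene-level collapsing when it is a truncating or
#' length-changing category (frameshift insertion/deletion, stopgain,
#' stoploss, nonframeshift insertion/deletion), or when it is a nonsynonymous
#' SNV called damaging by at least two of four predictors: SIFT `"D"`,
#' PolyPhen2-HVAR `"D"`, CADD phred strictly above `cadd_cutoff`, and
#' FATHMM-MKL `"D"`. A missing predictor value contributes no vote.
#' PolyPhen2-HVAR `"P"` (possibly damaging) does not count by default; add it
#' to `polyphen_damaging` to change that.
#'
#' @param variants Cohort variant data frame. Vectorized over rows.
#' @param cadd_cutoff CADD phred score above which the CADD vote is damaging
#'   (strict inequality). Default 15.
#' @param polyphen_damaging PolyPhen2-HVAR calls that count as damaging.
#' @param min_votes Number of damaging votes required for a nonsynonymous
#'   SNV. Default 2.
#' @return Logical vector, one element per variant.
#' @export
#' @examples
#' v <- data.frame(exonic_func = "nonsynonymous SNV", sift = "D",
#'                 polyphen_hvar = "D", cadd_phred = 21, fathmm_mkl = "N")
#' is_damaging(v)
is_damaging <- function(variants, cadd_cutoff = 15,
                        polyphen_damaging = "D", min_votes = 2L) {
  ef <- canon_exonic_func(variants$exonic_func)
  by_type <- !is.na(ef) & ef %in% damaging_indel_categories()
  nonsyn <- !is.na(ef) & ef == "nonsynonymous SNV"

  votes <- (!is.na(variants$sift) & variants$sift == "D") +
    (!is.na(variants$polyphen_hvar) & variants$polyphen_hvar %in% polyphen_damaging) +
    (!is.na(variants$cadd_phred) & variants$cadd_phred > cadd_cutoff) +
    (!is.na(variants$fathmm_mkl) & variants$fathmm_mkl == "D")

  by_type | (nonsyn & votes >= min_votes)
}

#' CAST collapse of qualifying variants per gene
#'
#' The cohort allelic sum test (CAST) reduces each sample to a binary
#' indicator per gene: does the sample carry at least one qualifying variant
#' in that gene. The gene-level carrier count is the number of samples with
#' indicator 1 — the size of the union of carrier sets over the gene's
#' variants, so it is at least the largest variant-level carrier count and at
#' most their sum.
#'
#' @param variants Qualifying cohort variant data frame (already rare- and
#'   damaging-filtered as desired).
#' @param genotypes QC-passed [genotype_calls].
#' @return Data frame with one row per gene: `gene`, `n_qualifying_variants`,
#'   `n_carrier_samples`.
#' @export
cast_collapse <- function(variants, genotypes) {
  keys <- intersect(variants$key, rownames(genotypes$dosage))
  v <- variants[match(keys, variants$key), , drop = FALSE]
  if (nrow(v) == 0L) {
    return(data.frame(gene = character(), n_qualifying_variants = integer(),
                      n_carrier_samples = integer(), stringsAsFactors = FALSE))
  }
  dos <- genotypes$dosage[v$key, , drop = FALSE]
  carrier <- !is.na(dos) & dos >= 1L
  genes <- sort(unique(v$gene))
  n_var <- as.integer(table(factor(v$gene, levels = genes)))
  n_carrier <- vapply(genes, function(g) {
    rows <- which(v$gene == g)
    sum(colSums(carrier[rows, , drop = FALSE]) > 0L)
  }, integer(1))
  data.frame(gene = genes, n_qualifying_variants = n_var,
             n_carrier_samples = unname(n_carrier), stringsAsFactors = FALSE)
}

#' Protein-length-normalized mutation fraction
#'
#' Larger genes accumulate more rare variants by chance alone; dividing the
#' CAST carrier count by the protein length (amino acids) corrects for this.
#' Genes absent from the length table keep a missing fraction: they remain in
#' the table but are excluded from fraction-based ranking.
#'
#' @param records Data frame from [cast_collapse()].
#' @param lengths Named integer vector from [read_protein_lengths()].
#' @return `records` with `protein_length` and `mutation_fraction` columns.
#' @export
mutation_fraction <- function(records, lengths) {
  if (any(lengths <= 0)) stop("protein lengths must be positive", call. = FALSE)
  len <- unname(lengths[records$gene])
  records$protein_length <- as.integer(len)
  records$mutation_fraction <- records$n_carrier_samples / len
  records
}

#' Flag genes in the top fraction tier
#'
#' Flags the genes whose mutation fraction falls in the top `percentile`
#' (default 0.1%) of genes with a defined fraction. The cutoff is the
#' smallest fraction among the top `ceiling(percentile * n)` values; every
#' gene at or above the cutoff is flagged, so ties at the threshold are all
#' flagged.
#'
#' @param records Data frame with a `mutation_fraction` column.
#' @param percentile Top tier size as a fraction of ranked genes. Default 0.001.
#' @return `records` with a logical `top_flag` column.
#' @export
flag_top_fraction <- function(records, percentile = 0.001) {
  stopifnot(percentile > 0, percentile <= 1)
  fr <- records$mutation_fraction
  defined <- !is.na(fr)
  records$top_flag <- FALSE
  if (!any(defined)) return(records)
  n_top <- max(1L, ceiling(percentile * sum(defined)))
  cutoff <- sort(fr[defined], decreasing = TRUE)[min(n_top, sum(defined))]
  records$top_flag <- defined & fr >= cutoff
  records
}

#' Gene-level CAST collapsing analysis
#'
#' End-to-end gene analysis: select damaging variants ([is_damaging()];
#' skipped with `damaging_filter = FALSE` to collapse all rare variants),
#' collapse per gene with CAST, normalize by protein length, and flag the top
#' mutation-fraction tier. Genes with no carrier samples are dropped from the
#' mutated-genes table.
#'
#' @param variants Rare-filtered cohort variant data frame.
#' @param genotypes QC-passed [genotype_calls].
#' @param lengths Named protein-length vector; see [read_protein_lengths()].
#' @param cadd_cutoff,polyphen_damaging Passed to [is_damaging()].
#' @param top_percentile Passed to [flag_top_fraction()].
#' @param damaging_filter Set `FALSE` to collapse all rare variants without
#'   the damaging preselection.
#' @return An object of class `gene_collapse`: list with `records` (one row
#'   per mutated gene, ordered by decreasing mutation fraction, undefined
#'   fractions last) and the parameters used.
#' @export
gene_collapse <- function(variants, genotypes, lengths,
                          cadd_cutoff = 15, polyphen_damaging = "D",
                          top_percentile = 0.001, damaging_filter = TRUE) {
  qual <- if (damaging_filter) {
    variants[is_damaging(variants, cadd_cutoff, polyphen_damaging), , drop = FALSE]
  } else {
    variants
  }
  rec <- cast_collapse(qual, genotypes)
  rec <- rec[rec$n_carrier_samples > 0L, , drop = FALSE]
  rec <- mutation_fraction(rec, lengths)
  rec <- flag_top_fraction(rec, top_percentile)
  rec <- rec[order(-rec$mutation_fraction, rec$gene, na.last = TRUE), , drop = FALSE]
  rownames(rec) <- NULL
  structure(list(records = rec, cadd_cutoff = cadd_cutoff,
                 top_percentile = top_percentile,
                 damaging_filter = damaging_filter,
                 n_qualifying_variants = nrow(qual)),
            class = "gene_collapse")
}

#' @export
print.gene_collapse <- function(x, n = 6L, ...) {
  cat("Gene-level CAST collapse\n")
  cat(sprintf("  %d qualifying variants in %d mutated genes%s\n",
              x$n_qualifying_variants, nrow(x$records),
              if (x$damaging_filter) " (damaging-filtered)" else ""))
  cat(sprintf("  %d gene(s) in the top %.3g%% mutation-fraction tier\n",
              sum(x$records$top_flag), 100 * x$top_percentile))
  if (nrow(x$records)) {
    print(format(utils::head(x$records, n), digits = 4), row.names = FALSE)
  }
  invisible(x)
}

#' @export
summary.gene_collapse <- function(object, ...) {
  fr <- object$records$mutation_fraction
  out <- list(n_genes = nrow(object$records),
              n_top = sum(object$records$top_flag),
              fraction_range = if (any(!is.na(fr))) range(fr, na.rm = TRUE)
                               else c(NA_real_, NA_real_),
              n_unranked = sum(is.na(fr)))
  class(out) <- "summary.gene_collapse"
  out
}

#' @export
print.summary.gene_collapse <- function(x, ...) {
  cat(sprintf("%d mutated genes; mutation fraction range %.5f - %.5f; %d flagged top-tier; %d without protein length\n",
              x$n_genes, x$fraction_range[1], x$fraction_range[2], x$n_top,
              x$n_unranked))
  invisible(x)
}

#' Scatter plot of gene mutation fractions
#'
#' One point per mutated gene, ordered along the x axis, with a red dashed
#' line at the top-tier cutoff.
#'
#' @param x A `gene_collapse` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.gene_collapse <- function(x, ...) {
  rec <- x$records[!is.na(x$records$mutation_fraction), , drop = FALSE]
  if (!nrow(rec)) {
    warning("no ranked genes; nothing to plot", call. = FALSE)
    return(invisible(x))
  }
  graphics::plot(seq_len(nrow(rec)), rec$mutation_fraction,
                 xlab = "gene rank", ylab = "mutation fraction",
                 main = "Protein-length-normalized gene mutation fractions",
                 pch = 16, col = ifelse(rec$top_flag, "red", "grey30"), ...)
  if (any(rec$top_flag)) {
    graphics::abline(h = min(rec$mutation_fraction[rec$top_flag]),
                     lty = 2, col = "red")
  }
  invisible(x)
}

#' @export
as.data.frame.gene_collapse <- function(x, ...) x$records

#' Write gene-collapse records to TSV
#'
#' @param collapse A `gene_collapse` object.
#' @param path Output path.
#' @export
write_gene_collapse <- function(collapse, path) {
  write_tsv_dot(collapse$records, path)
}
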