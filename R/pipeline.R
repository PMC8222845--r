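#' Run the full cohort analysis
#'
#' End-to-end driver: genotype masking and variant QC, rare-variant
#' selection, the dominant and recessive carrier-overrepresentation scans,
#' and the gene-level CAST collapse. Per-stage row counts are recorded, and
#' when `out_dir` is given every result table is written as TSV alongside a
#' machine-readable JSON run manifest (inputs, thresholds, package version).
#'
#' @param variants Annotated cohort variant data frame
#'   ([read_annotated_variants()]).
#' @param genotypes A [genotype_calls] object ([read_genotypes()]).
#' @param protein_lengths Named protein-length vector
#'   ([read_protein_lengths()]); `NULL` skips fraction normalization.
#' @param thresholds A [qc_thresholds].
#' @param maf_cutoff Population-MAF cutoff for rare-variant selection.
#' @param missing_maf_default Passed to [burden_scan()].
#' @param cadd_cutoff,top_percentile,damaging_filter Passed to
#'   [gene_collapse()].
#' @param tail Passed to [burden_scan()].
#' @param out_dir Optional output directory for TSVs and the manifest.
#' @return An object of class `cohort_analysis`: list with `qc_report`,
#'   `dominant`, `recessive` (both `burden_scan`), `collapse`
#'   (`gene_collapse` or `NULL`), `stage_counts`, and `manifest`.
#' @export
run_cohort_analysis <- function(variants, genotypes, protein_lengths = NULL,
                                thresholds = qc_thresholds(),
                                maf_cutoff = 0.05, missing_maf_default = 3e-6,
                                cadd_cutoff = 15, top_percentile = 0.001,
                                damaging_filter = TRUE, tail = FALSE,
                                out_dir = NULL) {
  rec <- reconcile_variants(variants, genotypes)
  if (length(rec$only_in_annotations) || length(rec$only_in_genotypes)) {
    stop(sprintf(paste0("annotation/genotype mismatch: %d variants only in ",
                        "annotations, %d only in genotypes; reconcile inputs ",
                        "first (see reconcile_variants())"),
                 length(rec$only_in_annotations),
                 length(rec$only_in_genotypes)), call. = FALSE)
  }

  masked <- mask_low_quality_genotypes(genotypes, thresholds)
  qc <- filter_variants(masked, thresholds)
  gt <- qc$genotypes

  v_qc <- variants[variants$key %in% rownames(gt$dosage), , drop = FALSE]
  v_rare <- select_rare_variants(v_qc, maf_cutoff = maf_cutoff)

  dom <- burden_scan(v_rare, gt, mode = "dominant", tail = tail,
                     missing_maf_default = missing_maf_default)
  rec_scan <- burden_scan(v_rare, gt, mode = "recessive", tail = tail,
                          missing_maf_default = missing_maf_default)
  collapse <- if (!is.null(protein_lengths)) {
    gene_collapse(v_rare, gt, protein_lengths, cadd_cutoff = cadd_cutoff,
                  top_percentile = top_percentile,
                  damaging_filter = damaging_filter)
  }

  stage_counts <- c(variants_in = nrow(variants),
                    variants_qc = nrow(v_qc),
                    variants_rare = nrow(v_rare),
                    dominant_tested = dom$n_tests,
                    recessive_tested = rec_scan$n_tests,
                    recessive_reported = nrow(rec_scan$results),
                    genes_mutated = if (is.null(collapse)) NA_integer_
                                    else nrow(collapse$records))

  manifest <- list(package = "rarecarrier",
                   version = as.character(utils::packageVersion("rarecarrier")),
                   n_samples = ncol(genotypes$dosage),
                   thresholds = unclass(thresholds),
                   maf_cutoff = maf_cutoff,
                   missing_maf_default = missing_maf_default,
                   cadd_cutoff = cadd_cutoff,
                   top_percentile = top_percentile,
                   damaging_filter = damaging_filter,
                   tail = tail,
                   stage_counts = as.list(stage_counts))

  out <- structure(list(qc_report = qc$report, dominant = dom,
                        recessive = rec_scan, collapse = collapse,
                        stage_counts = stage_counts, manifest = manifest),
                   class = "cohort_analysis")
  if (!is.null(out_dir)) write_cohort_analysis(out, out_dir)
  out
}

#' @export
print.cohort_analysis <- function(x, ...) {
  cat("Cohort rare-variant analysis\n")
  for (nm in names(x$stage_counts)) {
    cat(sprintf("  %-20s %s\n", nm, x$stage_counts[[nm]]))
  }
  invisible(x)
}

#' Write all analysis outputs to a directory
#'
#' Emits `qc_report.tsv`, `scan_dominant.tsv`, `scan_recessive.tsv`,
#' `gene_collapse.tsv` (when computed), `stage_counts.tsv` and
#' `manifest.json`.
#'
#' @param analysis A `cohort_analysis`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort_analysis <- function(analysis, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_qc_report(analysis$qc_report, file.path(dir, "qc_report.tsv"))
  write_burden_scan(analysis$dominant, file.path(dir, "scan_dominant.tsv"))
  write_burden_scan(analysis$recessive, file.path(dir, "scan_recessive.tsv"))
  if (!is.null(analysis$collapse)) {
    write_gene_collapse(analysis$collapse, file.path(dir, "gene_collapse.tsv"))
  }
  write_tsv_dot(data.frame(stage = names(analysis$stage_counts),
                           count = unname(analysis$stage_counts)),
                file.path(dir, "stage_counts.tsv"))
  jsonlite::write_json(analysis$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
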