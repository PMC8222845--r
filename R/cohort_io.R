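#' @keywords internal
"_PACKAGE"

# Internal variant key used to join annotation and genotype records.
variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

# Strip a leading "chr" so "chr1" and "1" join; X/Y/MT labels retained.
normalize_chrom <- function(chrom) {
  sub("^chr", "", as.character(chrom))
}

#' Default column mapping for ANNOVAR multianno-style tables
#'
#' Maps the logical columns the pipeline needs onto the header names that
#' `table_annovar.pl` emits with refGene, gnomAD, and dbNSFP annotations.
#' Pass a modified copy to [read_annotated_variants()] when your table uses
#' different headers. The `pseudogene` entry is optional: when the named
#' column is absent the flag defaults to `FALSE` for every variant.
#'
#' @return Named character vector mapping logical names to header names.
#' @export
#' @examples
#' m <- annovar_column_map()
#' m[["gene"]] <- "Gene.ensGene"
annovar_column_map <- function() {
  c(chrom         = "Chr",
    pos           = "Start",
    end           = "End",
    ref           = "Ref",
    alt           = "Alt",
    gene          = "Gene.refGene",
    func_region   = "Func.refGene",
    exonic_func   = "ExonicFunc.refGene",
    maf_genomes   = "gnomAD_genome_ALL",
    maf_exomes    = "gnomAD_exome_ALL",
    sift          = "SIFT_pred",
    polyphen_hvar = "Polyphen2_HVAR_pred",
    cadd_phred    = "CADD_phred",
    fathmm_mkl    = "fathmm-MKL_coding_pred",
    pseudogene    = "pseudogene_flag")
}

.required_logical_cols <- c("chrom", "pos", "ref", "alt", "gene", "func_region",
                            "exonic_func", "maf_genomes", "maf_exomes",
                            "sift", "polyphen_hvar", "cadd_phred", "fathmm_mkl")

.parse_maf <- function(x, col, lines) {
  x <- as.character(x)
  miss <- is.na(x) | x == "." | x == ""
  out <- rep(NA_real_, length(x))
  suppressWarnings(out[!miss] <- as.numeric(x[!miss]))
  bad <- !miss & is.na(out)
  if (any(bad)) {
    stop(sprintf("unparsable %s value '%s' at line %d", col,
                 x[which(bad)[1]], lines[which(bad)[1]]), call. = FALSE)
  }
  if (any(out < 0 | out > 1, na.rm = TRUE)) {
    stop(sprintf("%s outside [0, 1] at line %d", col,
                 lines[which(out < 0 | out > 1)[1]]), call. = FALSE)
  }
  out
}

.parse_pred <- function(x, allowed) {
  x <- as.character(x)
  x[is.na(x) | x == "." | x == "" | !(x %in% allowed)] <- NA_character_
  x
}

#' Read an annotated variant table
#'
#' Reads a tab-delimited, ANNOVAR multianno-style annotated variant table into
#' the cohort variant data frame used by the rest of the pipeline. Rows whose
#' ALT field contains several comma-separated alleles are split into one
#' record per alternate allele; population MAF fields equal to `"."` or empty
#' become `NA` (missing).
#'
#' @param path Path to a tab-delimited file with a header line.
#' @param column_map Named character vector mapping logical column names to
#'   header names; see [annovar_column_map()].
#' @return A `data.frame` with columns `chrom`, `pos`, `ref`, `alt`, `gene`,
#'   `func_region`, `exonic_func`, `maf_genomes`, `maf_exomes`, `sift`,
#'   `polyphen_hvar`, `cadd_phred`, `fathmm_mkl`, `pseudogene_flag`, and the
#'   derived join key `key`.
#' @export
read_annotated_variants <- function(path, column_map = annovar_column_map()) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           na.strings = NULL, quote = "")
  for (lc in .required_logical_cols) {
    if (!lc %in% names(column_map)) {
      stop(sprintf("column_map is missing an entry for '%s'", lc), call. = FALSE)
    }
    if (!column_map[[lc]] %in% names(raw)) {
      stop(sprintf("required column '%s' (mapped from '%s') not found in %s",
                   column_map[[lc]], lc, path), call. = FALSE)
    }
  }
  if (nrow(raw) == 0L) return(empty_variants())

  line_no <- seq_len(nrow(raw)) + 1L  # +1 for the header line
  get <- function(lc) raw[[column_map[[lc]]]]

  df <- data.frame(
    chrom       = normalize_chrom(get("chrom")),
    pos         = as.integer(get("pos")),
    ref         = as.character(get("ref")),
    alt         = as.character(get("alt")),
    gene        = as.character(get("gene")),
    func_region = as.character(get("func_region")),
    exonic_func = .parse_pred(get("exonic_func"),
                              allowed = unique(as.character(get("exonic_func")))),
    maf_genomes = .parse_maf(get("maf_genomes"), "maf_genomes", line_no),
    maf_exomes  = .parse_maf(get("maf_exomes"), "maf_exomes", line_no),
    sift          = .parse_pred(get("sift"), c("D", "T")),
    polyphen_hvar = .parse_pred(get("polyphen_hvar"), c("D", "P", "B")),
    cadd_phred    = .parse_maf_like_score(get("cadd_phred")),
    fathmm_mkl    = .parse_pred(get("fathmm_mkl"), c("D", "N")),
    stringsAsFactors = FALSE
  )
  df$exonic_func[df$exonic_func %in% c(".", "")] <- NA_character_

  pg_col <- column_map["pseudogene"]
  if (!is.na(pg_col) && pg_col %in% names(raw)) {
    df$pseudogene_flag <- as.character(raw[[pg_col]]) %in% c("TRUE", "True", "true", "1", "yes")
  } else {
    df$pseudogene_flag <- FALSE
  }

  # split multi-allelic rows (comma-separated ALT) into one record per allele
  multi <- grepl(",", df$alt, fixed = TRUE)
  if (any(multi)) {
    singles <- df[!multi, , drop = FALSE]
    pieces <- lapply(which(multi), function(i) {
      alts <- strsplit(df$alt[i], ",", fixed = TRUE)[[1]]
      rec <- df[rep(i, length(alts)), , drop = FALSE]
      rec$alt <- alts
      rec
    })
    df <- rbind(singles, do.call(rbind, pieces))
  }

  bad <- df$ref == df$alt
  if (any(bad)) stop("ref equals alt at row ", which(bad)[1], call. = FALSE)
  if (any(df$pos < 1L, na.rm = TRUE)) stop("pos must be >= 1", call. = FALSE)

  df$key <- variant_key(df$chrom, df$pos, df$ref, df$alt)
  rownames(df) <- NULL
  df
}

.parse_maf_like_score <- function(x) {
  x <- as.character(x)
  miss <- is.na(x) | x == "." | x == ""
  out <- rep(NA_real_, length(x))
  suppressWarnings(out[!miss] <- as.numeric(x[!miss]))
  out
}

# Zero-row cohort variant table with the full column contract.
empty_variants <- function() {
  data.frame(chrom = character(), pos = integer(), ref = character(),
             alt = character(), gene = character(), func_region = character(),
             exonic_func = character(), maf_genomes = numeric(),
             maf_exomes = numeric(), sift = character(),
             polyphen_hvar = character(), cadd_phred = numeric(),
             fathmm_mkl = character(), pseudogene_flag = logical(),
             key = character(), stringsAsFactors = FALSE)
}

#' Construct a genotype call set
#'
#' Container for per-sample genotype calls at each variant: alternate-allele
#' dosage plus the quality fields consumed by QC. All five components are
#' variants x samples matrices sharing dimnames; rownames are
#' `chrom:pos:ref:alt` keys and colnames are sample identifiers. Missing
#' values are `NA`.
#'
#' @param dosage Integer matrix of alternate-allele counts (0, 1, 2 or `NA`).
#' @param gq Genotype quality (phred-like), same shape as `dosage`.
#' @param dp Read depth, same shape.
#' @param ad_ref,ad_alt Reference / alternate supporting read counts.
#' @return An object of class `genotype_calls`.
#' @export
genotype_calls <- function(dosage, gq = NULL, dp = NULL,
                           ad_ref = NULL, ad_alt = NULL) {
  dosage <- as.matrix(dosage)
  blank <- function(m) if (is.null(m)) {
    out <- matrix(NA_real_, nrow(dosage), ncol(dosage), dimnames = dimnames(dosage))
    out
  } else {
    m <- as.matrix(m)
    stopifnot(identical(dim(m), dim(dosage)))
    m
  }
  gq <- blank(gq); dp <- blank(dp); ad_ref <- blank(ad_ref); ad_alt <- blank(ad_alt)
  ok <- !is.na(dp) & !is.na(ad_ref) & !is.na(ad_alt)
  if (any(ok & (ad_ref + ad_alt > dp))) {
    stop("ad_ref + ad_alt exceeds dp for at least one call", call. = FALSE)
  }
  structure(list(dosage = dosage, gq = gq, dp = dp,
                 ad_ref = ad_ref, ad_alt = ad_alt),
            class = "genotype_calls")
}

#' @export
print.genotype_calls <- function(x, ...) {
  cat(sprintf("genotype_calls: %d variants x %d samples (%.1f%% missing dosage)\n",
              nrow(x$dosage), ncol(x$dosage),
              100 * mean(is.na(x$dosage))))
  invisible(x)
}

#' @export
dim.genotype_calls <- function(x) dim(x$dosage)

# subset a genotype_calls object by variant index/keys
subset_genotypes <- function(x, i) {
  structure(lapply(x, function(m) m[i, , drop = FALSE]), class = "genotype_calls")
}

# Decode a VCF GT string over alleles {0, 1, .} to a dosage. Phase separators
# are ignored; a haploid GT contributes its allele count; any "." makes the
# call missing.
decode_gt <- function(gt) {
  gt <- as.character(gt)
  out <- rep(NA_integer_, length(gt))
  ok <- !is.na(gt) & gt != ""
  alleles <- strsplit(gt[ok], "[/|]")
  out[ok] <- vapply(alleles, function(a) {
    if (any(a == "." | a == "")) return(NA_integer_)
    v <- suppressWarnings(as.integer(a))
    if (any(is.na(v))) return(NA_integer_)
    sum(v)
  }, integer(1))
  out
}

#' Read genotype calls from a VCF or the package TSV dialect
#'
#' VCF input is parsed with \pkg{vcfR}; `GT` is decoded to dosage (`0/0` to 0,
#' `0/1` or `1/0` to 1, `1/1` to 2, `./.` to missing; phase ignored), and the
#' `GQ`, `DP` and `AD` FORMAT fields populate the quality matrices. The TSV
#' dialect is the long table written by [write_genotypes()]. Multi-allelic
#' VCF records are split per alternate allele before decoding; `AD` for a
#' split record keeps the reference count and that alternate's count only.
#'
#' @param path Path to a VCF (4.x) file or a genotype TSV.
#' @param format `"auto"` (by extension), `"vcf"` or `"tsv"`.
#' @return A [genotype_calls] object; sample order follows the input.
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  }
  if (format == "vcf") read_genotypes_vcf(path) else read_genotypes_tsv(path)
}

read_genotypes_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  gt_raw <- vcf@gt[, -1, drop = FALSE]
  samples <- colnames(gt_raw)
  fmt <- vcf@gt[, 1]

  n_var <- nrow(fix)
  chrom <- normalize_chrom(fix$CHROM)
  pos <- as.integer(fix$POS)
  ref <- fix$REF
  alt_field <- fix$ALT

  field_idx <- function(fmt_str, field) {
    parts <- strsplit(fmt_str, ":", fixed = TRUE)[[1]]
    match(field, parts)
  }
  split_cell <- function(cell) strsplit(cell, ":", fixed = TRUE)[[1]]

  rows <- list()
  for (i in seq_len(n_var)) {
    alts <- strsplit(alt_field[i], ",", fixed = TRUE)[[1]]
    idx <- vapply(c("GT", "GQ", "DP", "AD"), function(f) field_idx(fmt[i], f), integer(1))
    cells <- lapply(gt_raw[i, ], split_cell)
    pull <- function(j) vapply(cells, function(cl) {
      if (is.na(j) || length(cl) < j) NA_character_ else cl[[j]]
    }, character(1))
    gt_s <- pull(idx[1]); gq_s <- pull(idx[2]); dp_s <- pull(idx[3]); ad_s <- pull(idx[4])
    ad_mat <- do.call(rbind, lapply(ad_s, function(a) {
      if (is.na(a) || a == ".") return(rep(NA_integer_, length(alts) + 1L))
      v <- suppressWarnings(as.integer(strsplit(a, ",", fixed = TRUE)[[1]]))
      length(v) <- length(alts) + 1L
      v
    }))
    for (ai in seq_along(alts)) {
      # recode this alt to allele "1"; other alternates count as non-carrier
      gt_recode <- vapply(gt_s, function(g) {
        if (is.na(g) || g == ".") return(NA_character_)
        al <- strsplit(g, "[/|]")[[1]]
        al_new <- vapply(al, function(a) {
          if (a == ".") "." else if (a == as.character(ai)) "1" else "0"
        }, character(1))
        paste(al_new, collapse = "/")
      }, character(1), USE.NAMES = FALSE)
      rows[[length(rows) + 1L]] <- list(
        key = variant_key(chrom[i], pos[i], ref[i], alts[ai]),
        dosage = decode_gt(gt_recode),
        gq = suppressWarnings(as.numeric(ifelse(gq_s == ".", NA, gq_s))),
        dp = suppressWarnings(as.numeric(ifelse(dp_s == ".", NA, dp_s))),
        ad_ref = as.numeric(ad_mat[, 1L]),
        ad_alt = as.numeric(ad_mat[, ai + 1L])
      )
    }
  }
  bindm <- function(f) {
    m <- do.call(rbind, lapply(rows, `[[`, f))
    dimnames(m) <- list(vapply(rows, `[[`, "", "key"), samples)
    m
  }
  genotype_calls(dosage = bindm("dosage"), gq = bindm("gq"), dp = bindm("dp"),
                 ad_ref = bindm("ad_ref"), ad_alt = bindm("ad_alt"))
}

#' Write genotype calls to the package TSV dialect
#'
#' One row per variant x sample with columns `key`, `sample`, `dosage`, `gq`,
#' `dp`, `ad_ref`, `ad_alt`; missing values written as `"."`. Reading the file
#' back with [read_genotypes()] reproduces the object field for field.
#'
#' @param genotypes A [genotype_calls] object.
#' @param path Output path.
#' @export
write_genotypes <- function(genotypes, path) {
  keys <- rownames(genotypes$dosage)
  samples <- colnames(genotypes$dosage)
  long <- data.frame(
    key = rep(keys, times = length(samples)),
    sample = rep(samples, each = length(keys)),
    dosage = as.vector(genotypes$dosage),
    gq = as.vector(genotypes$gq),
    dp = as.vector(genotypes$dp),
    ad_ref = as.vector(genotypes$ad_ref),
    ad_alt = as.vector(genotypes$ad_alt),
    stringsAsFactors = FALSE
  )
  write_tsv_dot(long, path)
}

read_genotypes_tsv <- function(path) {
  long <- utils::read.delim(path, header = TRUE, sep = "\t",
                            colClasses = "character", na.strings = ".",
                            check.names = FALSE, quote = "")
  need <- c("key", "sample", "dosage", "gq", "dp", "ad_ref", "ad_alt")
  miss <- setdiff(need, names(long))
  if (length(miss)) stop("genotype TSV missing columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  keys <- unique(long$key)
  samples <- unique(long$sample)
  shape <- function(col, mode = as.numeric) {
    m <- matrix(mode(long[[col]]), nrow = length(keys), ncol = length(samples),
                dimnames = list(keys, samples))
    m
  }
  # rows are written variants-fastest so matrix() fill order matches
  genotype_calls(dosage = shape("dosage", function(x) as.integer(as.numeric(x))),
                 gq = shape("gq"), dp = shape("dp"),
                 ad_ref = shape("ad_ref"), ad_alt = shape("ad_alt"))
}

#' Read a gene-to-protein-length table
#'
#' Two-column tab-delimited file (gene symbol, protein length in amino
#' acids), UniProt-derived. Lengths must be positive and symbols unique.
#'
#' @param path Path to the TSV (header optional; detected).
#' @return Named integer vector of protein lengths keyed by gene symbol.
#' @export
read_protein_lengths <- function(path) {
  first <- utils::read.delim(path, header = FALSE, sep = "\t", nrows = 1,
                             colClasses = "character", quote = "")
  has_header <- suppressWarnings(is.na(as.numeric(first[[2]])))
  tab <- utils::read.delim(path, header = has_header, sep = "\t",
                           colClasses = "character", quote = "")
  genes <- as.character(tab[[1]])
  len <- suppressWarnings(as.integer(tab[[2]]))
  if (anyNA(len) || any(len <= 0L)) {
    stop("protein lengths must be positive integers", call. = FALSE)
  }
  if (anyDuplicated(genes)) {
    stop("duplicate gene symbols in protein-length table", call. = FALSE)
  }
  stats::setNames(len, genes)
}

#' Reconcile annotated variants with genotype rows
#'
#' After ingestion every annotated variant should have a genotype row and
#' vice versa. Rather than silently dropping unmatched records, this reports
#' the difference exactly.
#'
#' @param variants Cohort variant data frame (from [read_annotated_variants()]).
#' @param genotypes A [genotype_calls] object.
#' @return A list with `matched` (keys present in both),
#'   `only_in_annotations`, and `only_in_genotypes`.
#' @export
reconcile_variants <- function(variants, genotypes) {
  va <- variants$key
  ga <- rownames(genotypes$dosage)
  list(matched = intersect(va, ga),
       only_in_annotations = setdiff(va, ga),
       only_in_genotypes = setdiff(ga, va))
}

# TSV writer used for all outputs: header line, "." for missing, no quoting.
write_tsv_dot <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    col <- out[[j]]
    if (is.numeric(col)) col <- ifelse(is.na(col), ".", format(col, digits = 15, scientific = FALSE, trim = TRUE))
    else { col <- as.character(col); col[is.na(col)] <- "." }
    out[[j]] <- col
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Write a cohort variant table to TSV
#'
#' Writes the internal variant model in the package TSV dialect (header line,
#' `"."` for missing). Re-reading with [read_variants_tsv()] round-trips the
#' table field for field.
#'
#' @param variants Cohort variant data frame.
#' @param path Output path.
#' @export
write_variants <- function(variants, path) {
  write_tsv_dot(variants[, setdiff(names(variants), "key")], path)
}

#' Read a cohort variant table written by [write_variants()]
#'
#' @param path Path to the TSV.
#' @return Cohort variant data frame.
#' @export
read_variants_tsv <- function(path) {
  cm <- c(chrom = "chrom", pos = "pos", end = "pos", ref = "ref", alt = "alt",
          gene = "gene", func_region = "func_region", exonic_func = "exonic_func",
          maf_genomes = "maf_genomes", maf_exomes = "maf_exomes", sift = "sift",
          polyphen_hvar = "polyphen_hvar", cadd_phred = "cadd_phred",
          fathmm_mkl = "fathmm_mkl", pseudogene = "pseudogene_flag")
  read_annotated_variants(path, column_map = cm)
}
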