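# Shared fixture builders. Everything is constructed in code at test time.

# A minimal cohort variant data frame; defaults make a kept (rare,
# nonsynonymous, non-pseudogene) variant, overridable per field.
make_variant <- function(chrom = "1", pos = 1000L, ref = "A", alt = "G",
                         gene = "GENE1", func_region = "exonic",
                         exonic_func = "nonsynonymous SNV",
                         maf_genomes = NA_real_, maf_exomes = 0.001,
                         sift = NA_character_, polyphen_hvar = NA_character_,
                         cadd_phred = NA_real_, fathmm_mkl = NA_character_,
                         pseudogene_flag = FALSE) {
  df <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt, gene = gene,
                   func_region = func_region, exonic_func = exonic_func,
                   maf_genomes = maf_genomes, maf_exomes = maf_exomes,
                   sift = sift, polyphen_hvar = polyphen_hvar,
                   cadd_phred = cadd_phred, fathmm_mkl = fathmm_mkl,
                   pseudogene_flag = pseudogene_flag, stringsAsFactors = FALSE)
  df$key <- paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")
  df
}

make_variants <- function(n, chrom = "1", gene = "GENE1", ...) {
  do.call(rbind, lapply(seq_len(n), function(i) {
    make_variant(chrom = chrom, pos = 1000L + i, gene = gene, ...)
  }))
}

# genotype_calls from a dosage matrix with clean quality fields
make_genotypes <- function(dosage, gq = 60, dp = 50) {
  dosage <- as.matrix(dosage)
  if (is.null(rownames(dosage))) {
    rownames(dosage) <- paste0("1:", 1000L + seq_len(nrow(dosage)), ":A:G")
  }
  if (is.null(colnames(dosage))) {
    colnames(dosage) <- sprintf("S%02d", seq_len(ncol(dosage)))
  }
  shp <- function(x) matrix(x, nrow(dosage), ncol(dosage),
                            dimnames = dimnames(dosage))
  ad_alt <- shp(0)
  ad_alt[dosage == 1L] <- round(dp / 2)
  ad_alt[dosage == 2L] <- dp
  genotype_calls(dosage, gq = shp(gq), dp = shp(dp),
                 ad_ref = shp(dp) - ad_alt, ad_alt = ad_alt)
}

write_lines_tsv <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
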