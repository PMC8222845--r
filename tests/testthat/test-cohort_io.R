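test_that("annotated variant tables parse, with '.' MAFs becoming missing", {
  path <- write_lines_tsv(c(
    paste(c("Chr", "Start", "End", "Ref", "Alt", "Gene.refGene",
            "Func.refGene", "ExonicFunc.refGene", "gnomAD_genome_ALL",
            "gnomAD_exome_ALL", "SIFT_pred", "Polyphen2_HVAR_pred",
            "CADD_phred", "fathmm-MKL_coding_pred"), collapse = "\t"),
    paste(c("11", "59282861", "59282861", "A", "G", "OR4D9", "exonic",
            "nonsynonymous SNV", "0.0329", "0.0359", "D", "D", "21", "N"),
          collapse = "\t"),
    paste(c("4", "27019495", "27019495", "C", "T", "STIM2", "exonic",
            "nonsynonymous SNV", ".", "0.0001", "T", "B", "14.31", "D"),
          collapse = "\t")
  ))
  v <- read_annotated_variants(path)
  expect_equal(nrow(v), 2L)
  expect_equal(v$maf_genomes, c(0.0329, NA))
  expect_equal(v$maf_exomes, c(0.0359, 0.0001))
  expect_equal(v$cadd_phred, c(21, 14.31))
  expect_equal(v$sift, c("D", "T"))
  expect_false(any(v$pseudogene_flag))
  expect_equal(v$key, c("11:59282861:A:G", "4:27019495:C:T"))
})

test_that("multi-allelic rows split per alternate allele and chr prefixes are stripped", {
  path <- write_lines_tsv(c(
    paste(c("Chr", "Start", "End", "Ref", "Alt", "Gene.refGene",
            "Func.refGene", "ExonicFunc.refGene", "gnomAD_genome_ALL",
            "gnomAD_exome_ALL", "SIFT_pred", "Polyphen2_HVAR_pred",
            "CADD_phred", "fathmm-MKL_coding_pred"), collapse = "\t"),
    paste(c("chr2", "500", "500", "A", "C,T", "GENEX", "exonic",
            "nonsynonymous SNV", "0.01", ".", ".", ".", ".", "."),
          collapse = "\t")
  ))
  v <- read_annotated_variants(path)
  expect_equal(nrow(v), 2L)
  expect_equal(v$alt, c("C", "T"))
  expect_equal(unique(v$chrom), "2")
  expect_true(all(is.na(v$sift)))
})

test_that("missing required columns and unparsable MAFs are reported", {
  header_ok <- paste(c("Chr", "Start", "End", "Ref", "Alt", "Gene.refGene",
                       "Func.refGene", "ExonicFunc.refGene",
                       "gnomAD_genome_ALL", "gnomAD_exome_ALL", "SIFT_pred",
                       "Polyphen2_HVAR_pred", "CADD_phred",
                       "fathmm-MKL_coding_pred"), collapse = "\t")
  no_maf <- write_lines_tsv(sub("gnomAD_exome_ALL", "somethingelse", header_ok))
  expect_error(read_annotated_variants(no_maf), "gnomAD_exome_ALL")

  bad_row <- write_lines_tsv(c(header_ok,
    paste(c("1", "10", "10", "A", "G", "G1", "exonic", "nonsynonymous SNV",
            "oops", "0.1", ".", ".", ".", "."), collapse = "\t")))
  expect_error(read_annotated_variants(bad_row), "line 2")

  empty <- write_lines_tsv(header_ok)
  expect_equal(nrow(read_annotated_variants(empty)), 0L)
})

test_that("GT strings decode to dosages with phase ignored", {
  # derived rule: dosage = alternate-allele count over alleles {0,1,.}
  expect_equal(
    rarecarrier:::decode_gt(c("0/0", "0/1", "1/0", "1/1", "./.", "0|1",
                              "1|1", "1", "0", ".", "./1")),
    c(0L, 1L, 1L, 2L, NA, 1L, 2L, 1L, 0L, NA, NA))
})

test_that("VCF genotypes read with quality fields and multi-allelic splitting", {
  path <- write_lines_tsv(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="g">',
    '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="g">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="d">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="a">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "SA", "SB", "SC"), collapse = "\t"),
    paste(c("1", "100", ".", "A", "G", ".", "PASS", ".", "GT:GQ:DP:AD",
            "0/1:35:40:22,18", "0/0:60:50:50,0", "./.:.:.:."), collapse = "\t"),
    paste(c("2", "200", ".", "C", "T,G", ".", "PASS", ".", "GT:GQ:DP:AD",
            "1/2:50:30:10,12,8", "0/2:40:20:12,0,8", "0|1:45:25:13,12,0"),
          collapse = "\t")
  ), ext = ".vcf")
  g <- read_genotypes(path)
  expect_equal(rownames(g$dosage), c("1:100:A:G", "2:200:C:T", "2:200:C:G"))
  expect_equal(unname(g$dosage["1:100:A:G", ]), c(1L, 0L, NA))
  expect_equal(unname(g$gq["1:100:A:G", ]), c(35, 60, NA))
  expect_equal(unname(g$ad_alt["1:100:A:G", ]), c(18, 0, NA))
  # split alt T: 1/2 carries one T allele -> dosage 1; 0/2 carries none -> 0
  expect_equal(unname(g$dosage["2:200:C:T", ]), c(1L, 0L, 1L))
  expect_equal(unname(g$ad_alt["2:200:C:T", ]), c(12, 0, 12))
  # split alt G: 1/2 and 0/2 each carry one G allele; 0|1 carries none
  expect_equal(unname(g$dosage["2:200:C:G", ]), c(1L, 1L, 0L))
  expect_equal(unname(g$ad_alt["2:200:C:G", ]), c(8, 8, 0))
})

test_that("genotype and variant TSV dialects round-trip field for field", {
  sim <- simulate_cohort(sim_config(n_samples = 6, n_variants = 30, seed = 42))
  gpath <- tempfile(fileext = ".tsv")
  write_genotypes(sim$genotypes, gpath)
  g2 <- read_genotypes(gpath)
  for (f in c("dosage", "gq", "dp", "ad_ref", "ad_alt")) {
    expect_equal(g2[[f]], sim$genotypes[[f]], info = f)
  }
  vpath <- tempfile(fileext = ".tsv")
  write_variants(sim$variants, vpath)
  v2 <- read_variants_tsv(vpath)
  expect_equal(v2, sim$variants, tolerance = 1e-12)
})

test_that("protein length tables validate and reconcile reports list differences", {
  path <- write_lines_tsv(c("gene\tprotein_length", "POP4\t220", "DLC1\t1091"))
  len <- read_protein_lengths(path)
  expect_equal(unname(len[c("POP4", "DLC1")]), c(220L, 1091L))
  bad <- write_lines_tsv(c("gene\tprotein_length", "POP4\t0"))
  expect_error(read_protein_lengths(bad), "positive")
  dup <- write_lines_tsv(c("gene\tprotein_length", "A\t10", "A\t20"))
  expect_error(read_protein_lengths(dup), "duplicate")

  v <- make_variants(3)
  g <- make_genotypes(matrix(0L, 2, 2,
                             dimnames = list(v$key[c(1, 3)], c("S1", "S2"))))
  rec <- reconcile_variants(v, g)
  expect_equal(rec$matched, v$key[c(1, 3)])
  expect_equal(rec$only_in_annotations, v$key[2])
  expect_equal(rec$only_in_genotypes, character(0))
})
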