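test_that("read_pedigree parses founders, sorts topologically, adds implicit founders", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tsire\tdam\tbreed",
               "a\t0\t0\tHF",
               "b\t\t\tJ"), f)
  ped <- read_pedigree(f)
  expect_s3_class(ped, "pedigree")
  expect_equal(nrow(ped), 2L)
  expect_true(all(ped$founder))
  expect_true(all(is.na(ped$sire_id)))

  # child listed before parents -> accepted and re-ordered
  writeLines(c("id\tsire\tdam\tbreed",
               "kid\tpa\tma\t",
               "pa\t0\t0\tHF",
               "ma\t0\t0\tJ"), f)
  ped <- read_pedigree(f)
  expect_equal(ped$animal_id[3L], "kid")
  expect_false(ped$founder[3L])

  # referenced-but-undefined parent becomes an implicit unlabelled founder
  writeLines(c("id\tsire\tdam\tbreed",
               "kid\tghost\tma\t",
               "ma\t0\t0\tJ"), f)
  ped <- read_pedigree(f)
  expect_true("ghost" %in% ped$animal_id)
  expect_true(ped$founder[ped$animal_id == "ghost"])
  expect_true(is.na(ped$breed[ped$animal_id == "ghost"]))
})

test_that("cyclic pedigrees are rejected naming a cycle member", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tsire\tdam\tbreed",
               "a\tb\t0\t",
               "b\ta\t0\t"), f)
  expect_error(read_pedigree(f), "cycle.*'(a|b)'")
})

test_that("pedigree round trip is lossless", {
  ped <- small_sim()$pedigree
  f <- withr::local_tempfile(fileext = ".tsv")
  write_pedigree(ped, f)
  ped2 <- read_pedigree(f)
  for (col in names(ped2)) expect_equal(ped2[[col]], ped[[col]])
})

test_that("VCF GT fields map onto dosages per the encoding table", {
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "a1", "a2", "a3"), collapse = "\t"),
    "1\t100\tv1\tA\tG\t.\t.\t.\tGT\t0/1\t1|1\t./.",
    "1\t200\tv2\tC\tT\t.\t.\t.\tGT\t0/0\t0|1\t1/1"), f)
  g <- read_genotypes(f, dialect = "vcf")
  expect_equal(unname(g$dosages["a1", ]), c(1, 0))
  expect_equal(unname(g$dosages["a2", ]), c(2, 1))
  expect_equal(unname(g$dosages["a3", ]), c(NA_real_, 2))
  expect_equal(g$variants$pos, c(100L, 200L))
  expect_equal(g$variants$alt, c("G", "T"))
})

test_that("multi-allelic records are rejected by default and split on request", {
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "a1", "a2"), collapse = "\t"),
    "1\t100\ttri\tA\tG,T\t.\t.\t.\tGT\t1/2\t0/2"), f)
  expect_error(read_genotypes(f, dialect = "vcf"), "tri")
  g <- read_genotypes(f, dialect = "vcf", multiallelic = "split")
  expect_equal(ncol(g$dosages), 2L)
  expect_equal(unname(g$dosages[, 1L]), c(1, 0))  # allele G
  expect_equal(unname(g$dosages[, 2L]), c(1, 1))  # allele T
})

test_that("VCF and TSV dialects yield identical genotype matrices", {
  g <- small_sim()$genotypes
  attr(g, "haplotypes") <- NULL
  vcf <- withr::local_tempfile(fileext = ".vcf")
  tsv <- withr::local_tempfile(fileext = ".dosage.tsv")
  write_genotypes_vcf(g, vcf)
  write_genotypes_tsv(g, tsv)
  g_vcf <- read_genotypes(vcf, dialect = "vcf")
  g_tsv <- read_genotypes(tsv, dialect = "tsv")
  expect_identical(g_vcf$dosages, g_tsv$dosages)
  expect_equal(g_vcf$variants$pos, g$variants$pos)
  expect_identical(g_tsv$dosages, g$dosages)
})

test_that("qc_filter_variants applies the MAF and call-rate cuts and is idempotent", {
  # v1: MAF 0.02 (below 0.025); v2: call rate 0.85 (below 0.9);
  # v3: passes both
  n <- 100
  d <- cbind(
    c(rep(1, 4), rep(0, 96)),                       # alt freq 0.02
    c(rep(NA, 15), rep(1, 85)),                     # call rate 0.85
    rep_len(c(0, 1, 2), 100))
  g <- toy_genotypes(d)
  out <- qc_filter_variants(g, min_maf = 0.025, min_call_rate = 0.9)
  expect_equal(out$variants$variant_id, "v3")
  rep_ <- attr(out, "qc_report")
  expect_equal(rep_$n_low_maf, 1L)
  expect_equal(rep_$n_low_call_rate, 1L)

  # identity on clean input, idempotence in general
  again <- qc_filter_variants(out, min_maf = 0.025, min_call_rate = 0.9)
  expect_identical(again$dosages, out$dosages)
  g2 <- small_sim()$genotypes
  once <- qc_filter_variants(g2)
  twice <- qc_filter_variants(once)
  expect_identical(twice$dosages, once$dosages)
})

test_that("association tables round-trip at declared precision", {
  g <- toy_genotypes(matrix(c(0, 1, 2, 2, 0, 1, 1, 0), 4))
  vm <- variance_model(NULL, 0, sigma2_P = 1, animal_ids = rownames(g$dosages))
  res <- gls_scan(g, c(0.3, 1.2, -0.5, 2.2), vm)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_association_table(res, f)
  back <- read_association_table(f)
  for (cc in c("beta", "se", "chi2", "p"))
    expect_equal(back[[cc]], res[[cc]], tolerance = 1e-12)
  # p-values serialized in scientific notation
  raw <- readLines(f)[-1L]
  expect_true(all(grepl("e[+-][0-9]+$", sapply(strsplit(raw, "\t"), tail, 1L),
                        ignore.case = TRUE)))

  # empty result -> header-only file
  empty <- res[0, ]
  class(empty) <- class(res)
  write_association_table(empty, f)
  expect_equal(length(readLines(f)), 1L)
})

test_that("phenotype, expression and annotation readers enforce their contracts", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("animal_id\tLC", "a\t5.1", "a\t5.2"), f)
  expect_error(read_phenotypes(f), "duplicate")
  writeLines(c("animal_id\tLC\tLY", "a\t5.1\t0.8", "b\t5.2\t0.9"), f)
  phen <- read_phenotypes(f)
  y <- phenotype_vector(phen, "LY")
  expect_equal(y, c(a = 0.8, b = 0.9))
  expect_error(phenotype_vector(phen, "fat"), "not in phenotype table")

  writeLines(c("gene_id\ts1\ts2", "g1\t3\t-1"), f)
  expect_error(read_expression(f), "non-negative")

  writeLines(c("variant_id\tgene_id\tconsequence", "v1\tg1\tnonsense"), f)
  expect_error(read_annotations(f), "unknown consequence")
  writeLines(c("variant_id\tgene_id\tconsequence", "v1\tg1\tmissense"), f)
  expect_equal(nrow(read_annotations(f)), 1L)
})

test_that("CLI simulate/assoc runs end to end from files", {
  dir <- withr::local_tempdir()
  cfgf <- file.path(dir, "cfg.json")
  jsonlite::write_json(
    list(n_founders = list(HF = 10, J = 10), n_generations = 2,
         matings_per_generation = 30, n_variants = 100,
         trait = list(h2 = 0.5, sigma2_P = 1),
         expression = list(n_genes = 2, n_samples = 30)),
    cfgf, auto_unbox = TRUE)
  out <- file.path(dir, "sim")
  suppressMessages(pedgls_main(c("simulate", "--config", cfgf,
                                 "--seed", "3", "--out-dir", out)))
  expect_true(all(file.exists(file.path(
    out, c("pedigree.tsv", "genotypes.tsv", "genotypes.vcf",
           "phenotypes.tsv", "counts.tsv", "truth.json")))))
  phen <- read_phenotypes(file.path(out, "phenotypes.tsv"))
  names(phen)[2] <- "LC"
  data.table::fwrite(phen, file.path(out, "phenotypes.tsv"), sep = "\t")
  suppressMessages(pedgls_main(c(
    "assoc", "--genotypes", file.path(out, "genotypes.tsv"),
    "--phenotypes", file.path(out, "phenotypes.tsv"),
    "--pedigree", file.path(out, "pedigree.tsv"),
    "--trait", "LC", "--h2", "0.5",
    "--out", file.path(dir, "res"))))
  res <- read_association_table(file.path(dir, "res.assoc.tsv"))
  expect_gt(nrow(res), 0L)
  sig <- jsonlite::read_json(file.path(dir, "res.significance.json"))
  expect_equal(sig$bonferroni_p, 0.05 / sig$n_tests, tolerance = 1e-12)
})
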