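test_that("filter cascade applies the AF, population-frequency and consequence rules", {
  toy <- variant_table(
    sample_id = "S1", gene = "TP53", pos = 1:6,
    consequence = c("silent", "silent", "missense", "missense",
                    "missense", "missense"),
    af = c(0.30, 0.03, 0.02, 0.40, 0.35, 0.25),
    popfreq_esp6500 = c(0, 0, 0, 0.02, 0, 0))
  reporting <- filter_variants(toy, filter_profile("reporting"))
  expect_equal(reporting$pos, c(5L, 6L))  # silents dropped, low-AF and common dropped
  tmb <- filter_variants(toy, filter_profile("tmb"))
  expect_equal(tmb$pos, c(1L, 5L, 6L))    # passing silent kept, low-AF silent not

  # AF boundary is inclusive at 0.05; a missense at 0.04 is removed
  low_af <- variant_table("S1", "TP53", af = 0.04)
  expect_equal(nrow(filter_variants(low_af, filter_profile("reporting"))), 0L)
  at_boundary <- variant_table("S1", "TP53", af = 0.05)
  expect_equal(nrow(filter_variants(at_boundary, filter_profile("reporting"))), 1L)

  expect_equal(nrow(filter_variants(empty_variant_table(),
                                    filter_profile("reporting"))), 0L)
})

test_that("amplification is exempt from the AF rule only under the reporting profile", {
  amp <- variant_table("S1", "EGFR", ref = "", alt = "",
                       consequence = "amplification", af = 0)
  expect_equal(nrow(filter_variants(amp, filter_profile("reporting"))), 1L)
  expect_equal(nrow(filter_variants(amp, filter_profile("tmb"))), 0L)
})

test_that("filtering is idempotent, order-preserving, and a subset of its input", {
  for (seed in 1:5) {
    v <- random_variant_table(40, seed)
    for (purpose in c("reporting", "tmb")) {
      prof <- filter_profile(purpose)
      out <- filter_variants(v, prof)
      keys <- paste(v$pos, v$consequence, v$af)
      expect_true(all(paste(out$pos, out$consequence, out$af) %in% keys))
      expect_false(is.unsorted(match(paste(out$pos, out$consequence, out$af),
                                     keys)))
      expect_identical(filter_variants(out, prof), out)
      if (purpose == "reporting")
        expect_false(any(out$consequence == "silent"))
    }
  }
})

test_that("unknown consequence strings are rejected with the offending rows", {
  bad <- variant_table("S1", "TP53", pos = 1:2)
  bad$consequence[2] <- "nonsense_vocab"
  expect_error(filter_variants(bad, filter_profile("reporting")),
               "row\\(s\\) 2.*nonsense_vocab")
})

test_that("MAF-like TSV round-trips the in-memory representation", {
  v <- random_variant_table(10, 42)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_variants(v, path)
  back <- read_variants(path, format = "maf-tsv")
  rownames(v) <- rownames(back) <- NULL
  expect_equal(back, v)

  # 1-based positions preserved exactly
  one_based <- variant_table("S1", "EGFR", pos = 55242465L)
  write_variants(one_based, path)
  expect_identical(read_variants(path)$pos, 55242465L)
})

test_that("MAF-like TSV reader names missing columns", {
  path <- withr::local_tempfile(fileext = ".tsv")
  v <- random_variant_table(3, 1)
  utils::write.table(v[, setdiff(names(v), "consequence")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  expect_error(read_variants(path), "consequence")
})

write_test_vcf <- function(path, info) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=HGVSP,Number=1,Type=String,Description=\"Protein HGVS\">",
    "##INFO=<ID=CONSEQ,Number=1,Type=String,Description=\"Consequence class\">",
    "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Allele fraction\">",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    "##INFO=<ID=AF_1KG,Number=1,Type=Float,Description=\"1000 Genomes AF\">",
    "##INFO=<ID=AF_ESP,Number=1,Type=Float,Description=\"ESP6500 AF\">",
    "##INFO=<ID=DRIVER,Number=1,Type=String,Description=\"Driver flag\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tTUMOR01")
  rows <- sprintf("chr7\t%d\t.\tA\tT\t.\tPASS\t%s\tGT\t0/1", seq_along(info), info)
  writeLines(c(header, rows), path)
}

test_that("annotated VCF input is read through the configured INFO keys", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_test_vcf(path, c(
    "GENE=EGFR;HGVSP=p.L858R;CONSEQ=missense;AF=0.32;DP=800;AF_1KG=0;AF_ESP=0;DRIVER=1",
    "GENE=TP53;HGVSP=p.R175H;CONSEQ=missense;AF=0.12;DP=500;AF_1KG=0.001;AF_ESP=0;DRIVER=0"))
  v <- read_variants(path, format = "vcf")
  expect_equal(nrow(v), 2L)
  expect_equal(v$sample_id, rep("TUMOR01", 2))
  expect_equal(v$hgvs_p, c("p.L858R", "p.R175H"))
  expect_equal(v$af, c(0.32, 0.12))
  expect_equal(v$is_driver, c(TRUE, FALSE))
})

test_that("VCF lacking the consequence annotation errors naming the field", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_test_vcf(path, "GENE=EGFR;HGVSP=p.L858R;AF=0.32;DP=800")
  expect_error(read_variants(path, format = "vcf"), "consequence.*CONSEQ")
})
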