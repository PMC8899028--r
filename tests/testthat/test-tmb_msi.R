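make_variants <- function(n, gene = "TP53", hgvs = "p.A100T") {
  if (n == 0L) return(empty_variant_table())
  variant_table("S1", gene, pos = seq_len(n), hgvs_p = hgvs,
                consequence = "missense", af = 0.3)
}

test_that("TMB is the non-driver count over the coding footprint", {
  wes <- assay_spec("wes")
  expect_equal(compute_tmb(empty_variant_table(), wes)$value, 0)

  res <- compute_tmb(make_variants(45), assay_spec("wes", 30))
  expect_equal(res$value, 1.5)
  expect_equal(res$n_counted, 45L)

  v <- make_variants(10)
  v$gene[1:3] <- "EGFR"
  v$hgvs_p[1:3] <- c("p.L858R", "p.T790M", "p.G719A")
  res <- compute_tmb(v, assay_spec("panel733"))
  expect_equal(res$n_counted, 7L)
  expect_equal(res$value, 7 / 2.2)
  expect_true(is.na(res$classification))

  # the is_driver flag and whole-gene driver entries also exclude
  v2 <- make_variants(4)
  v2$is_driver[1] <- TRUE
  drivers <- data.frame(gene = "KRAS", hgvs_p = "")
  v2$gene[2] <- "KRAS"
  expect_equal(compute_tmb(v2, assay_spec("wes"), drivers)$n_counted, 2L)

  expect_error(assay_spec("wes", coding_region_size_mb = 0), "positive")
})

test_that("TMB counts are additive over disjoint variant lists", {
  a <- make_variants(12)
  b <- make_variants(7)
  b$pos <- b$pos + 100L
  spec <- assay_spec("panel733")
  expect_equal(compute_tmb(rbind(a, b), spec)$n_counted,
               compute_tmb(a, spec)$n_counted + compute_tmb(b, spec)$n_counted)
  expect_equal(compute_tmb(rbind(a, b), spec)$value,
               compute_tmb(a, spec)$value + compute_tmb(b, spec)$value)
})

test_that("TMB classification boundary is inclusive", {
  expect_equal(classify_tmb(10.0, 10)$classification, "TMB-High")
  expect_equal(classify_tmb(9.999, 10)$classification, "TMB-Low")
  expect_equal(classify_tmb(14.5, 14.5)$classification, "TMB-High")
  expect_error(classify_tmb(5, 0), "positive")
})

test_that("cutoff harmonization matches the stated examples", {
  # exactly half the WES reference below the cutoff; panel 1..10
  h <- harmonize_cutoff(c(1, 2, 3, 20, 30, 40), 10, 1:10)
  expect_equal(h$p, 0.5)
  expect_equal(h$panel_cutoff, 5.5)

  # constant panel list collapses to that constant for any p
  for (p_num in c(1, 3, 5)) {
    wes <- c(rep(1, p_num), rep(20, 6 - p_num))
    expect_equal(harmonize_cutoff(wes, 10, rep(7, 9))$panel_cutoff, 7)
  }

  # 1000 WES values with 694 below the cutoff
  set.seed(11)
  wes <- c(runif(694, 0, 9.9), runif(306, 10.1, 40))
  panel <- rlnorm(1000, 2.2, 1)
  h <- harmonize_cutoff(wes, 10, panel)
  expect_equal(h$p, 0.694)
  expect_equal(h$panel_cutoff, oracle_quantile(panel, 0.694))

  expect_error(harmonize_cutoff(numeric(), 10, 1:5), "empty")
  expect_warning(harmonize_cutoff(c(20, 30), 10, 1:5), "minimum")
  expect_warning(harmonize_cutoff(c(1, 2), 10, 1:5), "maximum")
})

test_that("harmonization is monotone in the WES cutoff", {
  set.seed(4)
  wes <- rlnorm(200, 1.8, 0.9)
  panel <- rlnorm(200, 2.2, 1)
  cuts <- vapply(seq(2, 30, by = 0.5), function(cutoff)
    suppressWarnings(harmonize_cutoff(wes, cutoff, panel)$panel_cutoff),
    numeric(1))
  expect_false(is.unsorted(cuts))
})

msi_profile <- function(id, hist, base, modal = 15L) {
  msi_locus_profile(id, modal, hist, base)
}

test_that("locus selection keeps the k best-covered loci with deterministic ties", {
  base <- c(`14` = 100, `15` = 800, `16` = 100)
  loci <- lapply(1:100, function(i)
    msi_profile(sprintf("MS%03d", i), c(`14` = 10, `15` = 100 + i, `16` = 10), base))
  top <- select_msi_loci(loci, 30)
  expect_length(top, 30L)
  expect_equal(vapply(top, function(l) l$coverage, numeric(1)),
               sort(vapply(loci, function(l) l$coverage, numeric(1)),
                    decreasing = TRUE)[1:30])

  # a tie spanning rank 30 resolves by ascending locus_id
  tied <- lapply(1:40, function(i)
    msi_profile(sprintf("MS%03d", 41 - i), c(`15` = 500), base))
  expect_warning(sel <- select_msi_loci(tied, 30), "tie")
  expect_equal(vapply(sel, function(l) l$locus_id, character(1)),
               sprintf("MS%03d", 1:30))

  few <- loci[1:12]
  expect_warning(all12 <- select_msi_loci(few, 30), "12")
  expect_length(all12, 12L)
  expect_error(select_msi_loci(list(), 30), "empty")
})

test_that("locus instability is called from the novel-length read fraction", {
  base <- c(`13` = 20, `14` = 300, `15` = 1400, `16` = 300, `17` = 20)
  # identical to baseline: stable
  expect_false(call_locus_instability(msi_profile("MS001", base, base)))
  # 30% of reads at lengths absent from the baseline: unstable
  shifted <- c(`10` = 150, `11` = 150, `14` = 100, `15` = 500, `16` = 100)
  expect_true(call_locus_instability(msi_profile("MS002", shifted, base)))
  # 5% at novel lengths: stable under the 20% default
  mild <- c(`10` = 50, `14` = 150, `15` = 650, `16` = 150)
  expect_false(call_locus_instability(msi_profile("MS003", mild, base)))
  # low-frequency baseline lengths (< 1% support) count as novel
  rare_base <- c(`10` = 5, `14` = 300, `15` = 1400, `16` = 300)
  at_rare <- c(`10` = 300, `15` = 700)
  expect_true(call_locus_instability(msi_profile("MS004", at_rare, rare_base)))
})

test_that("MSI score is the unstable fraction with an inclusive 0.4 boundary", {
  base <- c(`15` = 1000)
  loci30 <- lapply(1:30, function(i) msi_profile(sprintf("MS%03d", i), base, base))
  s0 <- compute_msi_score(loci30, rep(FALSE, 30))
  expect_equal(s0$score, 0)
  expect_equal(s0$classification, "MSS")

  s12 <- compute_msi_score(loci30, rep(c(TRUE, FALSE), c(12, 18)))
  expect_equal(s12$score, 0.4)
  expect_equal(s12$classification, "MSI-H")

  s11 <- compute_msi_score(loci30, rep(c(TRUE, FALSE), c(11, 19)))
  expect_equal(round(s11$score, 4), 0.3667)
  expect_equal(s11$classification, "MSS")

  # monotone in the number of unstable calls
  scores <- vapply(0:30, function(k)
    compute_msi_score(loci30, rep(c(TRUE, FALSE), c(k, 30 - k)))$score,
    numeric(1))
  expect_false(is.unsorted(scores))
  expect_error(compute_msi_score(list(), logical()), "zero")
  expect_error(compute_msi_score(loci30, rep(TRUE, 3)), "align")
})

test_that("microsatellite profile TSV round-trips", {
  prof <- generate_msi_profiles("MSI-H", n_loci = 5, seed = 3)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_msi_profiles(list(S1 = prof), path)
  back <- read_msi_profiles(path)
  expect_equal(length(back$S1), 5L)
  orig_cov <- sort(vapply(prof, function(l) l$coverage, numeric(1)))
  back_cov <- sort(vapply(back$S1, function(l) l$coverage, numeric(1)))
  expect_equal(back_cov, orig_cov)
  back_ids <- sort(vapply(back$S1, function(l) l$locus_id, character(1)))
  expect_equal(back_ids, sprintf("MS%03d", 1:5))
})
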