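egfr_v <- function(hgvs, consequence = NULL) {
  if (is.null(consequence)) {
    consequence <- vapply(hgvs, function(h) {
      if (grepl("del", h)) "inframe_indel"
      else if (grepl("ins|dup", h)) "inframe_insertion_dup"
      else "missense"
    }, character(1))
  }
  variant_table("S1", "EGFR", pos = seq_along(hgvs), hgvs_p = hgvs,
                consequence = consequence)
}

test_that("point mutations classify by exact protein match, G719* collapsing to G719X", {
  expect_equal(classify_egfr(egfr_v("p.L858R"))$label, "L858R")
  expect_equal(classify_egfr(egfr_v("p.T790M"))$label, "T790M")
  expect_equal(classify_egfr(egfr_v("p.S768I"))$label, "S768I")
  expect_equal(classify_egfr(egfr_v("p.L861Q"))$label, "L861Q")
  for (g in c("p.G719A", "p.G719C", "p.G719S"))
    expect_equal(classify_egfr(egfr_v(g))$label, "G719X")
  # a substitution that is none of the named hotspots
  expect_equal(classify_egfr(egfr_v("p.N468K"))$label, "other_uncommon")
})

test_that("indel categories follow the residue-to-exon map", {
  exons <- egfr_exon_map()
  e19 <- exons[exons$exon == 19, ]
  e20 <- exons[exons$exon == 20, ]

  expect_equal(classify_egfr(egfr_v("p.E746_A750del"))$label, "19del")
  expect_equal(classify_egfr(egfr_v("p.L747_P753delinsS"))$label, "19del")
  expect_equal(classify_egfr(egfr_v("p.A767_V769dup"))$label, "20ins")
  expect_equal(classify_egfr(egfr_v("p.D770_N771insSVD"))$label, "20ins")
  expect_equal(classify_egfr(egfr_v("p.H773dup"))$label, "20ins")

  # derived check against the exon map: dels inside exon 19 are 19del, all
  # others other_uncommon; ins/dups inside exon 20 are 20ins
  for (start in c(e19$start, e19$end - 4L)) {
    hg <- sprintf("p.E%d_A%ddel", start, start + 4L)
    expect_equal(classify_egfr(egfr_v(hg))$label, "19del")
  }
  expect_equal(classify_egfr(egfr_v("p.K713_I715del"))$label, "other_uncommon")
  expect_equal(classify_egfr(egfr_v(sprintf("p.A%d_V%ddup", e20$end, e20$end + 2L)))$label,
               "other_uncommon")
  expect_equal(classify_egfr(egfr_v("p.I740_K745dup"))$label, "other_uncommon")
  expect_equal(classify_egfr(egfr_v("p.N771delinsGY"))$label, "other_uncommon")
})

test_that("sample-level label handles wildtype, multiple, and amplification", {
  expect_equal(classify_egfr(empty_variant_table())$label, "wildtype")
  expect_equal(classify_egfr(egfr_v(c("p.G719A", "p.S768I")))$label, "multiple")
  expect_equal(classify_egfr(egfr_v(c("p.L858R", "p.T790M")))$label, "multiple")
  amp <- variant_table("S1", "EGFR", ref = "", alt = "", hgvs_p = "",
                       consequence = "amplification")
  expect_equal(classify_egfr(amp)$label, "other_uncommon")
  expect_equal(classify_egfr(amp)$constituent_alterations, "amplification")
  # two alterations in the same category are not 'multiple'
  expect_equal(classify_egfr(egfr_v(c("p.E746_A750del", "p.L747_T751del")))$label,
               "19del")
})

test_that("classification is order-insensitive and rejects bad input", {
  a <- egfr_v(c("p.L858R", "p.T790M", "p.G719A"))
  b <- a[c(3, 1, 2), ]
  expect_equal(classify_egfr(a)$label, classify_egfr(b)$label)
  expect_error(classify_egfr(egfr_v("p.L858fs*xx")), "p\\.L858fs\\*xx")
  non_egfr <- variant_table("S1", "KRAS", hgvs_p = "p.G12C")
  expect_error(classify_egfr(non_egfr), "KRAS")
})

test_that("frequency tables reproduce the follow-up cohort percents", {
  counts <- utils::read.delim(system.file("extdata", "followup_subtype_counts.tsv",
                                          package = "egfrmarkers"))
  labels <- rep(counts$label, counts$count)
  expect_equal(length(labels), 98L)
  tab <- tabulate_subtype_frequencies(labels, "all")
  expect_equal(tab$percent[tab$label == "19del"], 17.35)
  expect_equal(tab$percent[tab$label == "L858R"], 14.29)
  expect_equal(tab$percent[tab$label == "G719X"], 12.24)
  expect_equal(tab$percent[tab$label == "S768I"], 13.27)
  expect_equal(tab$percent[tab$label == "other_uncommon"], 15.31)
  expect_equal(tab$percent[tab$label == "multiple"], 14.29)
  expect_equal(sum(tab$count), attr(tab, "denominator"))
})

test_that("frequency table normalization and denominator modes", {
  expect_equal(tabulate_subtype_frequencies("L858R")$percent, 100)
  labels <- c(rep("19del", 25), rep("L858R", 15), rep("wildtype", 60))
  all_tab <- tabulate_subtype_frequencies(labels, "all")
  mut_tab <- tabulate_subtype_frequencies(labels, "mutated_only")
  expect_equal(attr(all_tab, "denominator"), 100L)
  expect_equal(attr(mut_tab, "denominator"), 40L)
  expect_equal(all_tab$percent[all_tab$label == "19del"], 25)
  expect_equal(mut_tab$percent[mut_tab$label == "19del"], 62.5)
  expect_error(tabulate_subtype_frequencies(character()), "empty")

  # percents sum to 100 within rounding on random label sets
  for (seed in 1:5) {
    set.seed(seed)
    lab <- sample(egfr_subtype_labels(), 37, replace = TRUE)
    expect_lt(abs(sum(tabulate_subtype_frequencies(lab)$percent) - 100), 0.1)
  }
})
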