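#!/usr/bin/env Rscript
# EGFR subtype landscape: re-derive every sample's subtype from its variant
# calls (reporting filter + HGVS classification) and tabulate frequencies
# over all samples and over mutation carriers; also reproduce the published
# follow-up cohort table from its printed counts.

library(egfrmarkers)

variants <- read_variants("results/cohort/variants.tsv")
samples <- utils::read.delim("results/cohort/samples.tsv")

kept <- filter_variants(variants, filter_profile("reporting"))
by_sample <- split(kept, kept$sample_id)
subtype <- vapply(samples$sample_id, function(sid) {
  v <- by_sample[[sid]]
  if (is.null(v)) v <- empty_variant_table()
  classify_egfr(v)$label
}, character(1))

stopifnot(identical(unname(subtype), samples$subtype))  # generator round-trip

freq_all <- tabulate_subtype_frequencies(subtype, "all")
freq_mut <- tabulate_subtype_frequencies(subtype, "mutated_only")
write_tsv <- function(df, p) utils::write.table(df, p, sep = "\t",
                                                quote = FALSE, row.names = FALSE)
dir.create("results/subtypes", showWarnings = FALSE, recursive = TRUE)
write_tsv(freq_all, "results/subtypes/freq_all.tsv")
write_tsv(freq_mut, "results/subtypes/freq_mutated.tsv")

cat(sprintf("EGFR mutated: %.1f%% of %d samples\n",
            100 * mean(subtype != "wildtype"), length(subtype)))
cat(sprintf("19del / L858R among mutated: %.2f%% / %.2f%%\n",
            freq_mut$percent[freq_mut$label == "19del"],
            freq_mut$percent[freq_mut$label == "L858R"]))

counts <- utils::read.delim(system.file("extdata", "followup_subtype_counts.tsv",
                                        package = "egfrmarkers"))
followup <- tabulate_subtype_frequencies(rep(counts$label, counts$count))
write_tsv(followup, "results/subtypes/followup_freq.tsv")
cat("follow-up cohort subtype percents (n = 98):\n")
print(followup)
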