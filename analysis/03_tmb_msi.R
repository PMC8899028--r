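#!/usr/bin/env Rscript
# TMB cutoff harmonization and MSI scoring.
#
# The panel has no a-priori TMB-High cutoff. Following the quantile-matching
# principle, the WES TMB-Low proportion (strictly below 10 mut/Mb) in the
# EGFR-wildtype reference group is transferred to the panel distribution of
# the same group, yielding the harmonized panel cutoff. MSI scores come from
# the per-locus read-length histograms: top-30 loci by coverage, novel-length
# instability rule, MSI-H at score >= 0.4.

library(egfrmarkers)

samples <- utils::read.delim("results/cohort/samples.tsv")
wt <- samples$subtype == "wildtype"

h <- harmonize_cutoff(samples$tmb_wes[wt], 10, samples$tmb_panel[wt])
print(h)

samples$tmb_wes_class <- ifelse(samples$tmb_wes >= 10, "TMB-High", "TMB-Low")
samples$tmb_panel_class <- ifelse(samples$tmb_panel >= h$panel_cutoff,
                                  "TMB-High", "TMB-Low")
check <- mean(samples$tmb_panel[wt] < h$panel_cutoff)
cat(sprintf("WES TMB-Low in wildtype: %.1f%%; panel TMB-Low under %.2f mut/Mb: %.1f%%\n",
            100 * h$p, h$panel_cutoff, 100 * check))

tmb_high <- do.call(rbind, lapply(split(samples, samples$subtype), function(g)
  data.frame(subtype = g$subtype[1], n = nrow(g),
             tmb_high_pct_panel = round(100 * mean(g$tmb_panel_class == "TMB-High"), 2))))
dir.create("results/tmb_msi", showWarnings = FALSE, recursive = TRUE)
utils::write.table(tmb_high, "results/tmb_msi/tmb_high_by_subtype.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat("TMB-High proportion by subtype (panel):\n")
print(tmb_high[order(-tmb_high$tmb_high_pct_panel), ], row.names = FALSE)

profiles <- read_msi_profiles("results/cohort/msi_histograms.tsv")
msi <- do.call(rbind, lapply(names(profiles), function(sid) {
  r <- suppressWarnings(score_msi_sample(profiles[[sid]], sample_id = sid))
  data.frame(sample_id = sid, n_loci = r$n_loci_evaluated,
             n_unstable = r$n_unstable, score = r$score,
             classification = r$classification)
}))
utils::write.table(msi, "results/tmb_msi/msi_results.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat(sprintf("MSI-H: %d of %d scored samples (%.2f%%)\n",
            sum(msi$classification == "MSI-H"), nrow(msi),
            100 * mean(msi$classification == "MSI-H")))
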