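#!/usr/bin/env Rscript
# Biomarker-stratified progression-free survival.
#
# Strata: EGFR status, and for each immune population the rank-based
# median split of intratumoral density ("biomarker-high" = top half).
# Each stratification gets Kaplan-Meier curves, a two-group log-rank test,
# and a univariate Cox hazard ratio (high vs low; Efron ties). The same
# splits are also run separately within EGFR-mutated and wildtype samples,
# mirroring the search for subgroup-specific prognostic markers.

library(egfrmarkers)

samples <- utils::read.delim("results/cohort/samples.tsv")
densities <- utils::read.delim("results/cohort/densities.tsv")
surv <- utils::read.delim("results/cohort/survival.tsv")
dir.create("results/survival", showWarnings = FALSE, recursive = TRUE)

strata_of <- function(cell, ids = samples$sample_id) {
  d <- densities[densities$cell_type == cell &
                   densities$compartment == "tumor" &
                   densities$sample_id %in% ids, ]
  suppressWarnings(median_split(setNames(d$density, d$sample_id)))
}

run_one <- function(name, strata, records) {
  records <- records[records$sample_id %in% names(strata), ]
  res <- survival_by_stratum(records, strata)
  write_km_curve(res$km[[1]],
                 sprintf("results/survival/km_%s_%s.tsv", name, res$levels[1]))
  write_km_curve(res$km[[2]],
                 sprintf("results/survival/km_%s_%s.tsv", name, res$levels[2]))
  data.frame(stratification = name,
             hazard_ratio = res$cox$hazard_ratio,
             ci_low = res$cox$ci_low, ci_high = res$cox$ci_high,
             logrank_p = res$logrank$p_value)
}

cells <- c(cd8 = "CD8_T", m1 = "M1_TAM", m2 = "M2_TAM",
           cd56bright = "CD56bright_NK", cd56dim = "CD56dim_NK")

egfr_strata <- setNames(ifelse(samples$subtype == "wildtype", "wt", "mut"),
                        samples$sample_id)
rows <- list(run_one("egfr", egfr_strata, surv))
for (nm in names(cells))
  rows[[nm]] <- run_one(nm, strata_of(cells[[nm]]), surv)

# subgroup analyses within EGFR-mutated / wildtype samples
for (sub in c("mut", "wt")) {
  ids <- samples$sample_id[(samples$subtype != "wildtype") == (sub == "mut")]
  for (nm in c("cd8", "cd56dim"))
    rows[[paste(nm, sub, sep = "_")]] <-
      run_one(paste(nm, sub, sep = "_"), strata_of(cells[[nm]], ids),
              surv[surv$sample_id %in% ids, ])
}

tab <- do.call(rbind, rows)
utils::write.table(tab, "results/survival/summary.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
for (i in seq_len(nrow(tab)))
  cat(sprintf("%-14s HR = %.2f [%.2f, %.2f], log-rank p = %.3g\n",
              tab$stratification[i], tab$hazard_ratio[i], tab$ci_low[i],
              tab$ci_high[i], tab$logrank_p[i]))
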