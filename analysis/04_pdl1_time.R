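#!/usr/bin/env Rscript
# PD-L1 expression tiers and tumor-immune-microenvironment contrasts.
#
# TPS values are tiered (negative < 1%, intermediate [1, 50), strong >= 50%)
# and tabulated against EGFR subtype; immune densities (cells/mm^2) are
# compared between EGFR-mutated and wildtype samples per cell type and
# compartment (Welch t), and intratumoral CD8 density across subtypes
# (one-way ANOVA).

library(egfrmarkers)

samples <- utils::read.delim("results/cohort/samples.tsv")
densities <- utils::read.delim("results/cohort/densities.tsv")
dir.create("results/time", showWarnings = FALSE, recursive = TRUE)

tier <- factor(classify_tps(samples$tps), levels = tps_tiers())
tier_tab <- as.data.frame.matrix(table(samples$subtype, tier))
tier_tab <- cbind(subtype = rownames(tier_tab), tier_tab)
utils::write.table(tier_tab, "results/time/tps_by_subtype.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
strong <- tapply(tier == "strong_positive", samples$subtype, mean)
cat(sprintf("strong PD-L1 (TPS >= 50): %.1f%% wildtype vs %.1f%% 19del\n",
            100 * strong[["wildtype"]], 100 * strong[["19del"]]))

grp <- setNames(ifelse(samples$subtype == "wildtype", "EGFR_wt", "EGFR_mut"),
                samples$sample_id)
cmp <- compare_densities_by_group(densities, grp)
utils::write.table(cmp, "results/time/density_comparisons.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cd8 <- cmp[cmp$cell_type == "CD8_T" & cmp$compartment == "tumor", ]
cat(sprintf("intratumoral CD8 density, wildtype vs mutated: Welch p = %.3g (means %.0f vs %.0f /mm^2)\n",
            cd8$p_value, cd8$EGFR_wt, cd8$EGFR_mut))
m1 <- cmp[cmp$cell_type == "M1_TAM" & cmp$compartment == "tumor", ]
cat(sprintf("intratumoral M1 density, wildtype vs mutated: Welch p = %.3g (means %.0f vs %.0f /mm^2)\n",
            m1$p_value, m1$EGFR_wt, m1$EGFR_mut))

cd8_tumor <- densities[densities$cell_type == "CD8_T" &
                         densities$compartment == "tumor", ]
subtype_of <- setNames(samples$subtype, samples$sample_id)
by_subtype <- split(cd8_tumor$density, subtype_of[cd8_tumor$sample_id])
by_subtype <- by_subtype[vapply(by_subtype, length, integer(1)) >= 2]
an <- compare_groups(by_subtype, method = "anova")
cat(sprintf("intratumoral CD8 across %d subtypes: ANOVA F = %.2f, p = %.3g\n",
            length(by_subtype), an$statistic, an$p_value))
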