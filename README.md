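# egfrmarkers

Immuno-genomic biomarker profiling of non-small-cell lung cancer (NSCLC),
stratified by EGFR mutation subtype. The package re-implements, as a
tested and reusable pipeline, a biomarker analysis workflow built around
targeted-panel and whole-exome sequencing of NSCLC tumors: somatic variant
filtering, EGFR subtype classification from protein-level HGVS, tumor
mutational burden (TMB) with cross-assay cutoff harmonization,
microsatellite instability (MSI) scoring, PD-L1 tumor proportion score
(TPS) tiering, multiplex-immunofluorescence immune-density quantification,
and biomarker-stratified progression-free-survival (PFS) analysis. It is
aimed at bioinformaticians and biostatisticians who need these stages as
testable components rather than one-off scripts.

Because the underlying patient-level data are not publicly deposited, the
package ships a first-class synthetic-cohort generator whose defaults
emulate the published cohort structure, so every stage runs, and is
tested, end to end.

## Methods at a glance

* **Variant filtering.** A call survives iff AF ≥ 5%, max population
  frequency across 1000 Genomes/ESP6500 ≤ 0.015, and its consequence class
  is retained. Two profiles: *reporting* (stopgain, missense, frameshift,
  in-frame indels/insertions, amplification) and *tmb* (adds silent and
  stoploss — the burden statistic counts synonymous and nonsynonymous
  mutations alike).
* **EGFR subtyping.** Protein HGVS is parsed and mapped through a
  residue→exon table (exon 19 ≈ codons 729–761, exon 20 ≈ 762–823):
  exact matches for L858R/T790M/S768I/L861Q, G719A/C/S → G719X, exon-19
  in-frame del/delins → 19del, exon-20 in-frame ins/dup → 20ins,
  everything else (incl. amplification) → other_uncommon; ≥ 2 distinct
  categories → multiple.
* **TMB.** `TMB = n / L`, the non-driver somatic coding SNV+indel count
  over the assay's coding footprint `L` (Mb); TMB-High iff TMB ≥ cutoff.
  The panel cutoff is harmonized from the WES cutoff (10 mut/Mb) by
  quantile matching: with `p = F̂_WES(10)` the TMB-Low proportion in a
  reference population, the panel cutoff is the empirical `p`-quantile of
  the panel values (`Q̂_panel(p)`, linear interpolation between order
  statistics).
* **MSI.** Per locus, reads at repeat lengths with panel-of-normals
  frequency < 1% are "novel"; a locus is unstable iff its novel-read
  fraction ≥ 20%. The MSI score is the unstable fraction over the 30
  best-covered loci; MSI-H iff score ≥ 0.4.
* **PD-L1.** TPS tiers: negative (< 1%), intermediate positive ([1, 50)),
  strong positive (≥ 50%).
* **TIME.** Densities are positively stained cells per mm² (counts and
  areas pooled before division for the tumor+stroma total); group
  contrasts by Welch t (2 groups) or one-way ANOVA (> 2).
* **Survival.** Rank-based median split ("biomarker-high" = top half by
  density), Kaplan-Meier product-limit curves, two-group log-rank test,
  univariate Cox hazard ratios (Efron ties) with 95% CIs.

## Worked example

```r
library(egfrmarkers)
cohort <- generate_cohort(default_cohort_config(n_samples = 300, seed = 7))
report <- run_pipeline(cohort)
print(report)
```

```
Biomarker pipeline report: 300 samples
  EGFR-mutated: 50.3%; harmonized panel TMB cutoff: 16.86 mut/Mb (p = 0.745)
  survival stratifications:
    egfr               HR = 2.31 [1.42, 3.75], log-rank p = 0.000516
    cd8_tumor          HR = 0.37 [0.23, 0.61], log-rank p = 4.9e-05
    m1_tumor           HR = 1.46 [0.92, 2.30], log-rank p = 0.108
    m2_tumor           HR = 0.85 [0.54, 1.34], log-rank p = 0.484
    cd56bright_tumor   HR = 1.26 [0.80, 1.99], log-rank p = 0.318
    cd56dim_tumor      HR = 0.61 [0.38, 0.96], log-rank p = 0.0329
```

Half the cohort is EGFR-mutated; `p = 0.745` is the WES TMB-Low proportion
in the EGFR-wildtype reference group of this 300-sample draw, and 16.86
mut/Mb is the matching panel quantile (at n = 5000 these settle near 69%
and ~14.5–15 mut/Mb). The hazard ratios compare the alphabetically first
stratum level against the other: EGFR-mutated patients progress faster
(HR 2.31), patients with above-median intratumoral CD8⁺ T-cell density
progress slower (HR 0.37), and the CD56^dim NK split also separates
(HR 0.61); the M2 and CD56^bright splits, generated with no prognostic
effect, do not.

The subtype share among mutation carriers is in
`report$subtype_freq_mutated` (here 37.75% 19del, 50.33% L858R at n = 151).

## Analysis workflow

The numbered drivers under `analysis/` run the same stages as a narrative
workflow over a 2000-sample cohort, writing tables under `results/`:

```sh
Rscript analysis/01_simulate_cohort.R      # cohort TSV bundle
Rscript analysis/02_subtype_frequencies.R  # subtype tables incl. follow-up cohort
Rscript analysis/03_tmb_msi.R              # harmonized cutoff, TMB-High by subtype, MSI
Rscript analysis/04_pdl1_time.R            # TPS tiers, density contrasts
Rscript analysis/05_survival.R             # KM / log-rank / Cox per stratification
```

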