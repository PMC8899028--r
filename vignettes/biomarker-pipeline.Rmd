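---
title: "EGFR-subtype-stratified biomarker profiling: models, calibration, and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{EGFR-subtype-stratified biomarker profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the models behind each stage, the parameters that matter and why their
defaults are what they are, what the synthetic-cohort generator does and
does not emulate, and the decisions taken where the underlying study left
the design open.

## The problem

In Chinese NSCLC cohorts roughly half of tumors carry an EGFR mutation,
and the mutation subtype — exon-19 deletion (19del), L858R, T790M,
G719A/C/S, S768I, L861Q, exon-20 insertion, rarer alterations, or several
at once — correlates with immunotherapy-relevant biomarkers: tumor
mutational burden (TMB), PD-L1 expression, microsatellite instability
(MSI), and the composition of the tumor immune microenvironment (TIME).
The pipeline quantifies each biomarker per sample, tabulates it by EGFR
subtype, and asks which biomarkers stratify progression-free survival
(PFS). Since the patient-level data behind the study design are not
deposited, every stage here is exercised on synthetic cohorts whose
statistical structure matches the published cohort-level figures.

## Variant filtering

Annotated somatic calls pass a three-part filter: allele fraction
≥ `min_af` (default 0.05, boundary inclusive), maximum population
frequency across the annotation databases ≤ `max_pop_freq` (default
0.015, removal strictly above — common polymorphisms are treated as
likely germline), and a consequence-class whitelist. Two profiles
reconcile an internal tension in the assay's rules: the *reporting*
profile keeps stopgain, missense, frameshift and in-frame
indel/insertion calls (plus gene amplification, exempt from the AF rule
because copy-number events carry no meaningful allele fraction), while
the *tmb* profile additionally keeps silent and stoploss SNVs, because
the burden statistic explicitly counts synonymous mutations, and drops
amplification, which is not a small coding mutation. Whether the
population-frequency rule applies per database or to the maximum across
databases is not specified by the source material; the maximum is used,
the stricter somatic convention.

## EGFR subtype classification

Protein-level HGVS strings (one-letter codes) are parsed into
substitutions, deletions/delins, insertions, duplications and
frameshifts, then mapped through an embedded residue→exon table for the
canonical EGFR transcript (NM_005228): exon 18 ≈ codons 688–728, exon 19
≈ 729–761, exon 20 ≈ 762–823, exon 21 ≈ 824–875. The study assumes but
never states this mapping, so it is a package constant, exposed via
`egfr_exon_map()`. Classification is then rule-based: exact protein
matches for L858R, T790M, S768I, L861Q; G719A/C/S collapse to G719X;
in-frame del/delins fully inside exon 19 → 19del; in-frame ins/dup fully
inside exon 20 → 20ins; any other syntactically valid alteration, and
amplification, → other_uncommon; two or more distinct categories in one
sample → multiple (so T790M co-occurring with a sensitizing mutation is
"multiple" at sample level); no alterations → wildtype. Unparseable
strings are an error, not a silent bucket: silent coercion would let
annotation bugs masquerade as rare subtypes.

## TMB and cross-assay cutoff harmonization

TMB is the count of retained, non-driver somatic coding SNVs and indels
divided by the assay's interrogated coding footprint (defaults 35 Mb for
WES, 2.2 Mb for the 733-gene panel — configuration defaults, not
measured values). Driver exclusion uses a config-supplied hotspot table
(gene + exact protein change, or whole gene); the shipped default lists
canonical EGFR/KRAS/BRAF hotspots. TMB-High means value ≥ cutoff,
boundary inclusive.

A panel has no a-priori cutoff. The harmonization principle: the TMB-Low
proportion measured by WES and by the panel on the same reference
population should agree. With `p` the fraction of WES reference values
*strictly below* the WES cutoff (strict-below complements the inclusive
≥ classification), the panel cutoff is the empirical `p`-quantile of the
panel reference values. The quantile uses linear interpolation between
order statistics (R type 7): it is smooth, standard, and
oracle-checkable, and on tie-free lists the proportion of panel values
below the resulting cutoff provably falls within ±1/n of `p` — the
property the tests assert. When `p` hits 0 or 1 the cutoff collapses to
the extreme panel value and the result carries a warning flag.

## MSI scoring

Each microsatellite locus is summarized as a read-count histogram over
repeat lengths together with a panel-of-normals baseline histogram. The
assay's published description gives the scoring skeleton — 100 candidate
loci, the 30 with best coverage evaluated, score = unstable fraction,
MSI-H iff score ≥ 0.4 — but not the per-locus decision rule. The rule
implemented here is deliberately concrete and testable: repeat lengths
whose baseline frequency is below `novel_support_min` (default 1%) are
*novel*, and a locus is unstable iff the tumor's novel-read fraction is
at least `instability_fraction_min` (default 20%). Both thresholds are
exposed as arguments. Coverage ties at the selection boundary break by
ascending locus id with a warning, keeping selection deterministic.

## PD-L1 and the immune microenvironment

TPS tiers are negative (< 1%), intermediate positive, and strong
positive (≥ 50%). The published tier wording leaves [49, 50) unassigned;
intermediate is taken as the half-open interval [1, 50) so the three
tiers partition [0, 100] — the only closure consistent with "strong
means ≥ 50".

Immune densities are positively stained cells per mm², with the
percentage taken over nucleated cells. For the tumor+stroma total the
counts and areas are summed before dividing (pooled density), not the
two densities averaged — the published description does not say which;
pooling is the choice here because it weights compartments by their
measured area. Group comparisons default to Welch's t for two groups
(the study names both t variants without a selection rule; Welch is the
safer default under unequal variances) and one-way ANOVA beyond two.
P-values are reported raw, as in the source analysis; callers can apply
`p.adjust` downstream.

## Survival analysis

Biomarker stratification uses a rank-based median split: samples sorted
by descending density, the top ⌈n/2⌉ labeled high. This follows the
"top-half density" wording rather than a value threshold at the median —
the two differ under ties, where the rank rule keeps group sizes fixed
and breaks ties by sample id with a warning. Curves are Kaplan-Meier
product-limit estimates, group differences use the two-group log-rank
test, and effect sizes come from univariate Cox models (Efron tie
handling by default, Breslow exposed) with 95% CIs from the
observed-information standard error. The engines are backed by the
`survival` package; the test suite verifies them against independent
hand-computed oracles — the product-limit formula applied directly, the
hypergeometric O−E/V sums, and grid-search maximization of the written
partial likelihood — so the implementation and its checks never share a
code path.

## The synthetic-cohort generator

The generator is a first-class module: it draws a subtype label per
sample, then concrete EGFR variant calls whose HGVS strings the
classifier maps back to the drawn label (a round-trip the tests require
to hold for ≥ 99.9% of samples at n = 5000), per-assay TMB from
per-subtype log-normals, an MSS/MSI-H status, full per-locus
microsatellite histograms, a TPS from per-subtype tier mixtures,
log-normal immune densities, and exponential PFS times with
multiplicative stratum hazards and independent uniform censoring.
Determinism: one integer seed, with each stage deriving a child seed by
a fixed offset, so cohorts regenerate bit-identically and stages can be
reproduced in isolation.

Calibration of the defaults (all in
`inst/extdata/default_cohort_config.yaml`, plain config rather than
code):

* **Subtype probabilities** reproduce the published cohort-level
  frequencies — 51.3% EGFR-mutated, with 19del and L858R at 39.52% and
  42.61% of mutated samples. The split of the remaining ~17.9% of
  mutated mass across T790M/G719X/S768I/L861Q/20ins/other/multiple is
  not published and is illustrative.
* **TMB log-normals** are anchored to the two published marginal
  statements: the EGFR-wildtype WES distribution puts ~69.4% of its mass
  below 10 mut/Mb (meanlog 1.846, sdlog 0.9 gives Φ(0.507) ≈ 0.694),
  and the panel distribution's matching quantile sits near 14.5 mut/Mb
  (meanlog 2.167, sdlog 1.0). Subtype ordering follows the published
  pattern — wildtype and uncommon subtypes above 19del/L858R/T790M,
  exon-20 insertions lowest. Per-subtype distribution parameters are
  nowhere published; these are working values, not estimates.
* **MSI**: prevalence 0.8% (under the published "< 1%"). MSS tumor
  histograms resample the baseline plus a 0.3% novel-length noise floor,
  far below the 20% locus threshold; MSI-H samples shift 35% of reads at
  60% of loci to contracted lengths, so the expected score is ≈ 0.6 and
  the MSI-H call survives binomial noise. The calibration tests require
  MSS samples to classify MSS in ≥ 99% and MSI-H in ≥ 95% of 200 seeds.
* **Densities**: intratumoral CD8⁺ T density is higher in wildtype
  tumors (meanlog 5.0 vs 4.3, sdlog 0.6 — a raw-scale effect around one
  pooled SD, detected by the Welch comparison with > 90% power at a
  154-sample cohort in the Monte-Carlo property test); intratumoral M1
  macrophages are higher in mutated tumors; other populations are
  equal-by-construction, serving as negative controls.
* **Survival**: baseline rate log(2)/30 per month (30-month median PFS),
  hazard ratios 1.3 for EGFR-mutated, 0.45 for CD8-high, 0.75 for
  CD56^dim-high, censoring uniform on [0, 38] months (~30% censored).
  Exponential times with multiplicative hazards are the simplest model
  under which KM/log-rank/Cox recovery is analytic; the tests require
  the Cox estimate to recover configured ratios of 1.5/2/3 within 10%
  (median over 200 replicates at n = 300) and ~95% null CI coverage.

Per-locus histograms are materialized and scored for up to
`msi_params$profile_cap` samples per cohort (default 100) — at n = 5000,
half a million locus histograms would dominate memory while adding no
statistical information beyond the per-sample status draw. Every
sample's true status is always drawn; the cap only limits which samples
also carry raw histograms.

What the generator does **not** emulate: linkage between biomarkers
beyond the modeled ones (e.g. TMB and TPS are conditionally independent
given subtype), assay noise in TPS reads, spatial structure within
compartments, non-exponential hazards, informative censoring, and
panel-vs-WES measurement correlation within a sample (the two TMB values
are independent draws). Passing tests therefore demonstrate the
*machinery* — classification, scoring, harmonization, inference — under
a known truth, not the biological effect sizes themselves.

## Problem sizes in the test suite

The suite checks distribution recovery and subtype round-trip at
n = 5000, harmonization exhaustively on all integer reference multisets
of length ≤ 12 plus 1000 random float lists, MSI calibration over 200
seeds per status, KM exhaustively on all no-censoring inputs of length
≤ 8, Cox recovery over 200 replicates of n = 300 and null coverage over
500 replicates of n = 100. These sizes make the binomial/SE tolerances
in the assertions tight enough to catch real defects while keeping the
default run lightweight.

## Known limitations

* Nucleotide-level (c.) HGVS, three-letter amino-acid codes, and
  splice-site notation are out of scope for the parser; such calls must
  arrive with protein-level annotation.
* The locus-instability rule is a concrete stand-in for an undisclosed
  in-house rule; its two thresholds are exposed precisely because they
  are not published values.
* The harmonized cutoff inherits the reference population's sampling
  noise (at n ≈ 2500 wildtype reference samples the panel cutoff moves
  a few percent between seeds); the published single-number cutoff
  cannot be recovered without the original data.
* Multivariable Cox, proportional-hazards diagnostics and competing
  risks are deliberately absent; the analysis is univariate by design.
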