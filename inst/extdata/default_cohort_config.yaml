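# Default synthetic-cohort parameters.
#
# Subtype probabilities are calibrated to the published cohort-level
# frequencies (51.3% of samples EGFR-mutated; 19del and L858R at 39.52% and
# 42.61% of mutated samples); the split of the remaining mutated mass across
# the uncommon subtypes is illustrative. TMB log-normals are calibrated so
# the EGFR-wildtype WES marginal has ~69.4% of samples below 10 mut/Mb and
# the matching panel quantile sits near 14.5 mut/Mb, with common sensitizing
# subtypes (19del/L858R/T790M) below wildtype/uncommon subtypes and 20ins
# lowest. All densities are cells per square millimeter; survival times are
# months.
n_samples: 500
seed: 1

subtype_probs:
  wildtype: 0.4870
  "19del": 0.2027
  L858R: 0.2186
  T790M: 0.0080
  G719X: 0.0200
  S768I: 0.0120
  L861Q: 0.0100
  "20ins": 0.0120
  other_uncommon: 0.0100
  multiple: 0.0197

tmb_params:
  wildtype:       {wes: {meanlog: 1.846, sdlog: 0.9}, panel: {meanlog: 2.167, sdlog: 1.0}}
  "19del":        {wes: {meanlog: 1.300, sdlog: 0.9}, panel: {meanlog: 1.620, sdlog: 1.0}}
  L858R:          {wes: {meanlog: 1.300, sdlog: 0.9}, panel: {meanlog: 1.620, sdlog: 1.0}}
  T790M:          {wes: {meanlog: 1.300, sdlog: 0.9}, panel: {meanlog: 1.620, sdlog: 1.0}}
  G719X:          {wes: {meanlog: 1.750, sdlog: 0.9}, panel: {meanlog: 2.070, sdlog: 1.0}}
  S768I:          {wes: {meanlog: 1.750, sdlog: 0.9}, panel: {meanlog: 2.070, sdlog: 1.0}}
  L861Q:          {wes: {meanlog: 1.750, sdlog: 0.9}, panel: {meanlog: 2.070, sdlog: 1.0}}
  "20ins":        {wes: {meanlog: 1.200, sdlog: 0.9}, panel: {meanlog: 1.500, sdlog: 1.0}}
  other_uncommon: {wes: {meanlog: 1.750, sdlog: 0.9}, panel: {meanlog: 2.070, sdlog: 1.0}}
  multiple:       {wes: {meanlog: 1.750, sdlog: 0.9}, panel: {meanlog: 2.070, sdlog: 1.0}}

msi_h_prob: 0.008

# Tier weights are [negative, intermediate_positive, strong_positive];
# within a tier the score is uniform on the tier's TPS interval.
tps_mixture:
  wildtype:       [0.45, 0.35, 0.20]
  "19del":        [0.60, 0.30, 0.10]
  L858R:          [0.60, 0.30, 0.10]
  T790M:          [0.60, 0.30, 0.10]
  G719X:          [0.48, 0.32, 0.20]
  S768I:          [0.48, 0.32, 0.20]
  L861Q:          [0.48, 0.32, 0.20]
  "20ins":        [0.60, 0.30, 0.10]
  other_uncommon: [0.48, 0.32, 0.20]
  multiple:       [0.60, 0.30, 0.10]

# Per (cell type, compartment, subtype group) log-normal density parameters.
# EGFR-wildtype tumors carry more intratumoral CD8+ T cells; EGFR-mutated
# tumors carry more intratumoral M1 macrophages.
subtype_group:
  wildtype: egfr_wt
  default: egfr_mut
density_params:
  CD8_T:
    tumor:  {egfr_wt: {meanlog: 5.0, sdlog: 0.6}, egfr_mut: {meanlog: 4.3, sdlog: 0.6}}
    stroma: {egfr_wt: {meanlog: 5.5, sdlog: 0.6}, egfr_mut: {meanlog: 5.4, sdlog: 0.6}}
  M1_TAM:
    tumor:  {egfr_wt: {meanlog: 3.5, sdlog: 0.6}, egfr_mut: {meanlog: 4.0, sdlog: 0.6}}
    stroma: {egfr_wt: {meanlog: 4.0, sdlog: 0.6}, egfr_mut: {meanlog: 4.1, sdlog: 0.6}}
  M2_TAM:
    tumor:  {egfr_wt: {meanlog: 4.0, sdlog: 0.6}, egfr_mut: {meanlog: 4.0, sdlog: 0.6}}
    stroma: {egfr_wt: {meanlog: 4.5, sdlog: 0.6}, egfr_mut: {meanlog: 4.5, sdlog: 0.6}}
  CD56bright_NK:
    tumor:  {egfr_wt: {meanlog: 2.5, sdlog: 0.6}, egfr_mut: {meanlog: 2.5, sdlog: 0.6}}
    stroma: {egfr_wt: {meanlog: 3.0, sdlog: 0.6}, egfr_mut: {meanlog: 3.0, sdlog: 0.6}}
  CD56dim_NK:
    tumor:  {egfr_wt: {meanlog: 3.0, sdlog: 0.6}, egfr_mut: {meanlog: 3.0, sdlog: 0.6}}
    stroma: {egfr_wt: {meanlog: 3.5, sdlog: 0.6}, egfr_mut: {meanlog: 3.5, sdlog: 0.6}}

# Exponential event times with multiplicative stratum hazard ratios and
# independent uniform censoring on [0, censor_max] months. baseline_rate
# log(2)/30 gives a ~30-month baseline median PFS; censor_max yields ~30%
# censoring at the baseline rate.
survival_params:
  baseline_rate: 0.0231
  censor_max: 38
  hazard_ratios:
    egfr_mut: 1.3
    cd8_tumor_high: 0.45
    cd56dim_tumor_high: 0.75

# Microsatellite histogram generation. Baseline (panel-of-normals) mass
# sits on modal length +/- 2 repeat units; lengths beyond that have
# baseline support below the 1% novel threshold. MSI-H samples shift
# perturb_read_frac of reads at perturb_locus_frac of loci to contracted
# novel lengths.
msi_params:
  n_loci: 100
  select_k: 30
  coverage_meanlog: 6.2146
  coverage_sdlog: 0.3
  baseline_depth: 2000
  noise_rate: 0.003
  perturb_locus_frac: 0.6
  perturb_read_frac: 0.35
  profile_cap: 100
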