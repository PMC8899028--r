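# Synthetic cohort generation. Each stage draws under a child seed derived
# from the single config seed by a fixed offset, so regenerating with the
# same config is bit-identical and stages stay reproducible in isolation.

SEED_OFFSETS <- c(subtype = 101L, variants = 211L, tmb = 307L, msi = 401L,
                  tps = 503L, density = 601L, survival = 701L)

# HGVS exemplars per generated subtype category. All strings round-trip
# through classify_egfr to their category; 'multiple' samples combine two
# distinct categories.
egfr_alteration_pool <- function() {
  list(
    `19del` = c("p.E746_A750del", "p.L747_T751del", "p.L747_P753delinsS"),
    L858R = "p.L858R",
    T790M = "p.T790M",
    G719X = c("p.G719A", "p.G719C", "p.G719S"),
    S768I = "p.S768I",
    L861Q = "p.L861Q",
    `20ins` = c("p.A767_V769dup", "p.P772_H773dup", "p.H773dup",
                "p.D770_N771insSVD"),
    other_uncommon = c("p.N468K", "p.E709A", "p.H870R", "p.R451H",
                       "p.V774M", "p.L747P", "amplification")
  )
}

hgvs_consequence <- function(hgvs) {
  if (hgvs == "amplification") return("amplification")
  p <- parse_hgvs_p(hgvs)
  switch(p$kind,
         substitution = "missense",
         del = , delins = "inframe_indel",
         ins = , dup = "inframe_insertion_dup",
         frameshift = "frameshift_indel",
         "other")
}

#' Generate microsatellite locus profiles for one sample
#'
#' Builds `n_loci` locus profiles with a panel-of-normals baseline
#' concentrated on the modal repeat length +/- 2 units. Microsatellite-
#' stable (MSS) samples draw their tumor histograms from the baseline
#' frequencies plus a small sequencing-noise mass at novel lengths; MSI-H
#' samples additionally shift `perturb_read_frac` of the reads at
#' `perturb_locus_frac` of loci to contracted repeat lengths unsupported by
#' the baseline, enough to push the downstream score past the 0.4 MSI-H
#' boundary in expectation.
#'
#' @param sample_status `"MSS"` or `"MSI-H"`.
#' @param n_loci number of loci (>= 1; the assay default is 100).
#' @param seed integer seed.
#' @param params microsatellite parameter list (fields as in the shipped
#'   config); defaults to the shipped values.
#' @return List of `n_loci` [msi_locus_profile()] objects.
#' @export
generate_msi_profiles <- function(sample_status = c("MSS", "MSI-H"),
                                  n_loci, seed,
                                  params = default_cohort_config()$msi_params) {
  sample_status <- match.arg(sample_status)
  if (!is_scalar_number(n_loci) || n_loci < 1)
    stopf("'n_loci' must be >= 1")
  n_loci <- as.integer(n_loci)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(child_seed(seed, 0L))
  modal <- sample(10:25, n_loci, replace = TRUE)
  coverage <- pmax(50L, as.integer(round(stats::rlnorm(
    n_loci, params$coverage_meanlog, params$coverage_sdlog))))
  perturbed <- sample_status == "MSI-H" &
    stats::runif(n_loci) < params$perturb_locus_frac
  base_shape <- c(0.001, 0.02, 0.15, 0.658, 0.15, 0.02, 0.001)  # m-3 .. m+3
  lapply(seq_len(n_loci), function(i) {
    m <- modal[i]
    lengths <- (m - 5L):(m + 3L)
    base_prob <- c(0, 0, base_shape)
    baseline <- stats::rmultinom(1, params$baseline_depth, base_prob)[, 1]
    # novel = baseline frequency below the 1% support threshold
    novel <- base_prob < 0.01
    tumor_prob <- base_prob * (1 - params$noise_rate) +
      params$noise_rate * novel / sum(novel)
    if (perturbed[i]) {
      contracted <- lengths <= m - 3L
      tumor_prob <- tumor_prob * (1 - params$perturb_read_frac) +
        params$perturb_read_frac * contracted / sum(contracted)
    }
    hist_t <- stats::rmultinom(1, coverage[i], tumor_prob)[, 1]
    names(hist_t) <- names(baseline) <- lengths
    msi_locus_profile(sprintf("MS%03d", i), m, hist_t, baseline)
  })
}

# Save/restore the RNG state so generators do not disturb the caller's
# stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Generate a synthetic cohort
#'
#' Draws a full cohort under the configured model: one EGFR subtype per
#' sample; concrete EGFR variant calls whose HGVS strings classify back to
#' the drawn label (round-trip property); per-assay TMB values from the
#' per-subtype log-normals; an MSS/MSI-H status per sample with
#' materialized read-length histograms (scored through the MSI module) for
#' up to `msi_params$profile_cap` samples; PD-L1 TPS from the per-subtype
#' tier mixtures; log-normal immune densities per cell type and
#' compartment; and exponential progression times whose hazard depends on
#' the configured biomarker strata, with independent uniform censoring.
#'
#' @param config a validated [cohort_config()].
#' @return A list of class `synthetic_cohort` with elements `samples`
#'   (one row per sample), `variants` (MAF-like table), `msi_profiles`
#'   (named list of locus-profile lists), `densities` (long table incl.
#'   the pooled `total` compartment), `survival`, and `provenance`.
#' @export
generate_cohort <- function(config) {
  validate_cohort_config(config)
  n <- as.integer(config$n_samples)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)

  sample_id <- sprintf("S%05d", seq_len(n))
  empty <- n == 0L

  # --- subtype labels ---------------------------------------------------
  set.seed(child_seed(config$seed, SEED_OFFSETS[["subtype"]]))
  probs <- config$subtype_probs[config$subtype_probs > 0]
  subtype <- if (empty) character() else
    sample(names(probs), n, replace = TRUE, prob = probs)

  # --- EGFR variant calls ----------------------------------------------
  set.seed(child_seed(config$seed, SEED_OFFSETS[["variants"]]))
  pool <- egfr_alteration_pool()
  categories <- names(pool)
  variant_rows <- list()
  for (i in seq_len(n)) {
    s <- subtype[i]
    if (s == "wildtype") next
    cats <- if (s == "multiple") sample(categories, 2L) else s
    for (cat in cats) {
      hg <- sample(pool[[cat]], 1L)
      cons <- hgvs_consequence(hg)
      variant_rows[[length(variant_rows) + 1L]] <- data.frame(
        sample_id = sample_id[i], gene = "EGFR", chrom = "chr7",
        pos = 55000000L + sample.int(250000L, 1L),
        ref = if (cons == "amplification") "" else "A",
        alt = if (cons == "amplification") "" else "T",
        hgvs_p = if (cons == "amplification") "" else hg,
        consequence = cons,
        af = round(stats::runif(1, 0.10, 0.60), 4), depth = 500L,
        popfreq_1kg = 0, popfreq_esp6500 = 0, is_driver = TRUE,
        stringsAsFactors = FALSE)
    }
  }
  variants <- if (length(variant_rows)) validate_variants(do.call(rbind, variant_rows))
              else empty_variant_table()

  # --- TMB per assay ----------------------------------------------------
  set.seed(child_seed(config$seed, SEED_OFFSETS[["tmb"]]))
  draw_tmb <- function(assay) {
    if (empty) return(numeric())
    mu <- vapply(subtype, function(s) config$tmb_params[[s]][[assay]]$meanlog,
                 numeric(1))
    sd <- vapply(subtype, function(s) config$tmb_params[[s]][[assay]]$sdlog,
                 numeric(1))
    stats::rlnorm(n, mu, sd)
  }
  tmb_wes <- draw_tmb("wes")
  tmb_panel <- draw_tmb("panel")

  # --- MSI --------------------------------------------------------------
  set.seed(child_seed(config$seed, SEED_OFFSETS[["msi"]]))
  msi_status <- if (empty) character() else
    ifelse(stats::runif(n) < config$msi_h_prob, "MSI-H", "MSS")
  n_profiled <- min(n, as.integer(config$msi_params$profile_cap))
  profile_seeds <- if (empty) integer() else
    sample.int(.Machine$integer.max - 1L, n_profiled)
  msi_profiles <- list()
  msi_score <- rep(NA_real_, n)
  msi_class <- rep(NA_character_, n)
  for (i in seq_len(n_profiled)) {
    prof <- generate_msi_profiles(msi_status[i], config$msi_params$n_loci,
                                  seed = profile_seeds[i],
                                  params = config$msi_params)
    msi_profiles[[sample_id[i]]] <- prof
    res <- score_msi_sample(prof, k = config$msi_params$select_k,
                            sample_id = sample_id[i])
    msi_score[i] <- res$score
    msi_class[i] <- res$classification
  }

  # --- PD-L1 TPS --------------------------------------------------------
  set.seed(child_seed(config$seed, SEED_OFFSETS[["tps"]]))
  tps <- numeric(n)
  if (!empty) {
    tier_idx <- vapply(subtype, function(s)
      sample.int(3L, 1L, prob = config$tps_mixture[[s]]), integer(1))
    lo <- c(0, 1, 50)[tier_idx]
    hi <- c(1, 50, 100)[tier_idx]
    tps <- round(lo + stats::runif(n) * (hi - lo), 1)
    # keep each draw inside its tier after rounding
    tps <- pmin(pmax(tps, lo), ifelse(tier_idx < 3L, hi - 0.1, 100))
  }
  tps_tier <- if (empty) character() else classify_tps(tps)

  # --- immune densities -------------------------------------------------
  set.seed(child_seed(config$seed, SEED_OFFSETS[["density"]]))
  group_of <- function(s) config$subtype_group[[s]] %||% config$subtype_group$default
  groups <- vapply(subtype, group_of, character(1))
  dens_rows <- list()
  for (ct in time_cell_types()) {
    for (comp in c("tumor", "stroma")) {
      if (empty) next
      mu <- vapply(groups, function(g) config$density_params[[ct]][[comp]][[g]]$meanlog,
                   numeric(1))
      sd <- vapply(groups, function(g) config$density_params[[ct]][[comp]][[g]]$sdlog,
                   numeric(1))
      area <- round(stats::runif(n, 0.8, 1.2), 3)
      count <- as.integer(round(stats::rlnorm(n, mu, sd) * area))
      n_nucleated <- count + as.integer(round(stats::rlnorm(n, 8.5, 0.3)))
      dens_rows[[paste(ct, comp)]] <- data.frame(
        sample_id = sample_id, cell_type = ct, compartment = comp,
        count = count, area_mm2 = area, density = count / area,
        n_nucleated = n_nucleated,
        percent_of_nucleated = 100 * count / n_nucleated,
        stringsAsFactors = FALSE)
    }
  }
  densities <- if (length(dens_rows)) add_total_compartment(do.call(rbind, dens_rows))
               else data.frame()

  # --- survival ---------------------------------------------------------
  set.seed(child_seed(config$seed, SEED_OFFSETS[["survival"]]))
  survival_df <- data.frame()
  strata_cols <- list()
  if (!empty && n >= 2L) {
    covars <- list(egfr_mut = as.numeric(subtype != "wildtype"))
    cell_key <- c(cd8 = "CD8_T", m1 = "M1_TAM", m2 = "M2_TAM",
                  cd56bright = "CD56bright_NK", cd56dim = "CD56dim_NK")
    for (hr_name in names(config$survival_params$hazard_ratios)) {
      if (hr_name == "egfr_mut") next
      m <- regmatches(hr_name,
                      regexec("^([a-z0-9]+)_(tumor|stroma|total)_high$", hr_name))[[1]]
      if (!length(m)) stopf("unrecognized hazard-ratio stratum '%s'", hr_name)
      ct <- cell_key[[m[2]]]
      sub <- densities[densities$cell_type == ct &
                         densities$compartment == m[3], ]
      split_lab <- median_split(stats::setNames(sub$density, sub$sample_id))
      covars[[hr_name]] <- as.numeric(split_lab[sample_id] == "high")
    }
    log_rate <- log(config$survival_params$baseline_rate)
    for (hr_name in names(config$survival_params$hazard_ratios)) {
      if (is.null(covars[[hr_name]])) next
      log_rate <- log_rate +
        covars[[hr_name]] * log(config$survival_params$hazard_ratios[[hr_name]])
    }
    t_event <- stats::rexp(n, rate = exp(log_rate))
    t_cens <- stats::runif(n, 0, config$survival_params$censor_max)
    survival_df <- data.frame(sample_id = sample_id,
                              time_months = round(pmin(t_event, t_cens), 3),
                              event = t_event <= t_cens,
                              stringsAsFactors = FALSE)
    for (cn in names(covars))
      survival_df[[cn]] <- ifelse(covars[[cn]] == 1, "yes", "no")
  }

  samples <- data.frame(sample_id = sample_id, subtype = subtype,
                        egfr_mutated = if (empty) logical() else subtype != "wildtype",
                        tmb_wes = tmb_wes, tmb_panel = tmb_panel,
                        msi_status_true = msi_status,
                        msi_score = msi_score, msi_class = msi_class,
                        tps = tps, tps_tier = tps_tier,
                        stringsAsFactors = FALSE)

  provenance <- list(seed = config$seed, n_samples = n,
                     config_hash = config_hash(unclass(config)),
                     generated_by = "egfrmarkers::generate_cohort",
                     package_version = as.character(utils::packageVersion("egfrmarkers")))

  structure(list(samples = samples, variants = variants,
                 msi_profiles = msi_profiles, densities = densities,
                 survival = survival_df, provenance = provenance,
                 config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic NSCLC cohort: %d samples (%d EGFR-mutated), %d variant calls, %d MSI-profiled samples\n",
              nrow(x$samples), sum(x$samples$egfr_mutated),
              nrow(x$variants), length(x$msi_profiles)))
  invisible(x)
}

#' Write a synthetic cohort to a directory of TSV/JSON files
#'
#' Emits `samples.tsv`, `variants.tsv` (MAF-like), `msi_histograms.tsv`
#' (long per-locus histograms), `densities.tsv`, `survival.tsv`, and
#' `provenance.json`.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(cohort$samples, file.path(dir, "samples.tsv"))
  write_variants(cohort$variants, file.path(dir, "variants.tsv"))
  if (length(cohort$msi_profiles))
    write_msi_profiles(cohort$msi_profiles, file.path(dir, "msi_histograms.tsv"))
  if (nrow(cohort$densities))
    write_tsv(cohort$densities, file.path(dir, "densities.tsv"))
  if (nrow(cohort$survival))
    write_tsv(cohort$survival, file.path(dir, "survival.tsv"))
  jsonlite::write_json(cohort$provenance,
                       file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
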