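#' Run the full biomarker analysis over a cohort
#'
#' Ties the stages together in the study's analysis order: variant
#' filtering and EGFR subtype classification, subtype frequency tables
#' (over all samples and over mutated samples), TMB cutoff harmonization
#' on the EGFR-wildtype reference group followed by per-sample
#' classification on both assays, TMB-High proportions per subtype, PD-L1
#' tier-by-subtype tabulation, immune-density group comparisons
#' (EGFR-mutated vs wildtype), and median-split survival analyses
#' (Kaplan-Meier, log-rank, univariate Cox) per configured stratification.
#'
#' The run is deterministic given the cohort and writes nothing until all
#' stages have validated; every table is stamped with the cohort's config
#' hash via the provenance file.
#'
#' @param cohort a `synthetic_cohort` (or an equivalent list with
#'   `samples`, `variants`, `densities`, `survival`, `provenance`).
#' @param out_dir output directory; created on success.
#' @param wes_cutoff WES TMB classification cutoff in mutations/Mb
#'   (default 10).
#' @param survival_strata character vector of density strata to analyse,
#'   as `<cell>_<compartment>` pairs (default `cd8_tumor`, `m1_tumor`,
#'   `m2_tumor`, `cd56bright_tumor`, `cd56dim_tumor`), each median-split
#'   into high/low; EGFR status is always analysed.
#' @return A list of class `pipeline_report` with all result tables;
#'   written to `out_dir` when it is non-`NULL`.
#' @export
run_pipeline <- function(cohort, out_dir = NULL, wes_cutoff = 10,
                         survival_strata = c("cd8_tumor", "m1_tumor",
                                             "m2_tumor", "cd56bright_tumor",
                                             "cd56dim_tumor")) {
  for (field in c("samples", "variants", "densities", "survival"))
    if (is.null(cohort[[field]]))
      stopf("pipeline input is missing '%s'", field)
  samples <- cohort$samples
  if (nrow(samples) == 0L) stopf("empty cohort")

  # --- stage: variant filtering + subtype classification ----------------
  reported <- filter_variants(cohort$variants, filter_profile("reporting"))
  egfr <- reported[reported$gene == "EGFR", , drop = FALSE]
  classified <- vapply(samples$sample_id, function(sid)
    classify_egfr(egfr[egfr$sample_id == sid, , drop = FALSE])$label,
    character(1))
  samples$subtype_called <- unname(classified)

  subtype_freq_all <- tabulate_subtype_frequencies(samples$subtype_called, "all")
  subtype_freq_mut <-
    if (any(samples$subtype_called != "wildtype"))
      tabulate_subtype_frequencies(samples$subtype_called, "mutated_only")
    else NULL

  # --- stage: TMB harmonization + classification ------------------------
  wt <- samples$subtype_called == "wildtype"
  if (!any(wt)) stopf("TMB harmonization needs EGFR-wildtype reference samples")
  harmonization <- harmonize_cutoff(samples$tmb_wes[wt], wes_cutoff,
                                    samples$tmb_panel[wt])
  samples$tmb_wes_class <- ifelse(samples$tmb_wes >= wes_cutoff,
                                  "TMB-High", "TMB-Low")
  samples$tmb_panel_class <- ifelse(samples$tmb_panel >= harmonization$panel_cutoff,
                                    "TMB-High", "TMB-Low")
  tmb_by_subtype <- do.call(rbind, lapply(split(samples, samples$subtype_called),
    function(g) data.frame(
      subtype = g$subtype_called[1L], n = nrow(g),
      median_tmb_panel = stats::median(g$tmb_panel),
      tmb_high_pct_wes = round(100 * mean(g$tmb_wes_class == "TMB-High"), 2),
      tmb_high_pct_panel = round(100 * mean(g$tmb_panel_class == "TMB-High"), 2),
      stringsAsFactors = FALSE)))
  rownames(tmb_by_subtype) <- NULL

  # --- stage: MSI summary ----------------------------------------------
  msi_scored <- samples[!is.na(samples$msi_class), , drop = FALSE]
  msi_summary <- data.frame(
    n_scored = nrow(msi_scored),
    n_msi_h = sum(msi_scored$msi_class == "MSI-H"),
    msi_h_pct = if (nrow(msi_scored))
      round(100 * mean(msi_scored$msi_class == "MSI-H"), 2) else NA_real_)

  # --- stage: PD-L1 tier by subtype ------------------------------------
  tier <- factor(classify_tps(samples$tps), levels = tps_tiers())
  tps_by_subtype <- as.data.frame.matrix(
    table(samples$subtype_called, tier))
  tps_by_subtype <- cbind(subtype = rownames(tps_by_subtype), tps_by_subtype,
                          stringsAsFactors = FALSE)
  rownames(tps_by_subtype) <- NULL

  # --- stage: TIME comparisons -----------------------------------------
  egfr_group <- stats::setNames(
    ifelse(samples$subtype_called == "wildtype", "EGFR_wt", "EGFR_mut"),
    samples$sample_id)
  time_comparisons <-
    if (length(unique(egfr_group)) == 2L)
      compare_densities_by_group(cohort$densities, egfr_group)
    else NULL

  # --- stage: survival --------------------------------------------------
  survival_results <- list()
  if (nrow(cohort$survival) >= 4L && sum(cohort$survival$event) >= 2L) {
    survival_results$egfr <- survival_by_stratum(cohort$survival, egfr_group)
    cell_key <- c(cd8 = "CD8_T", m1 = "M1_TAM", m2 = "M2_TAM",
                  cd56bright = "CD56bright_NK", cd56dim = "CD56dim_NK")
    for (st in survival_strata) {
      m <- regmatches(st, regexec("^([a-z0-9]+)_(tumor|stroma|total)$", st))[[1]]
      if (!length(m)) stopf("unrecognized survival stratum '%s'", st)
      dsub <- cohort$densities[cohort$densities$cell_type == cell_key[[m[2]]] &
                                 cohort$densities$compartment == m[3], ]
      split_lab <- median_split(stats::setNames(dsub$density, dsub$sample_id))
      survival_results[[st]] <- survival_by_stratum(cohort$survival, split_lab)
    }
  }
  survival_table <- do.call(rbind, lapply(names(survival_results), function(nm) {
    r <- survival_results[[nm]]
    data.frame(stratification = nm,
               level_1 = r$levels[1L], level_2 = r$levels[2L],
               logrank_chisq = r$logrank$chi_square,
               logrank_p = r$logrank$p_value,
               hazard_ratio = r$cox$hazard_ratio,
               hr_ci_low = r$cox$ci_low, hr_ci_high = r$cox$ci_high,
               stringsAsFactors = FALSE)
  }))

  report <- structure(list(
    samples = samples,
    subtype_freq_all = subtype_freq_all,
    subtype_freq_mutated = subtype_freq_mut,
    harmonization = harmonization,
    tmb_by_subtype = tmb_by_subtype,
    msi_summary = msi_summary,
    tps_by_subtype = tps_by_subtype,
    time_comparisons = time_comparisons,
    survival_results = survival_results,
    survival_table = survival_table,
    provenance = c(cohort$provenance,
                   list(wes_cutoff = wes_cutoff,
                        panel_cutoff = harmonization$panel_cutoff))),
    class = "pipeline_report")

  if (!is.null(out_dir)) write_pipeline_report(report, out_dir)
  report
}

#' Write a pipeline report bundle to disk
#'
#' @param report a `pipeline_report`.
#' @param out_dir output directory.
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(report$samples, file.path(out_dir, "samples_annotated.tsv"))
  write_tsv(report$subtype_freq_all, file.path(out_dir, "subtype_freq_all.tsv"))
  if (!is.null(report$subtype_freq_mutated))
    write_tsv(report$subtype_freq_mutated,
              file.path(out_dir, "subtype_freq_mutated.tsv"))
  write_tsv(report$tmb_by_subtype, file.path(out_dir, "tmb_by_subtype.tsv"))
  write_tsv(report$msi_summary, file.path(out_dir, "msi_summary.tsv"))
  write_tsv(report$tps_by_subtype, file.path(out_dir, "tps_by_subtype.tsv"))
  if (!is.null(report$time_comparisons))
    write_tsv(report$time_comparisons, file.path(out_dir, "time_comparisons.tsv"))
  if (!is.null(report$survival_table))
    write_tsv(report$survival_table, file.path(out_dir, "survival_results.tsv"))
  jsonlite::write_json(report$provenance, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("Biomarker pipeline report: %d samples\n", nrow(x$samples)))
  cat(sprintf("  EGFR-mutated: %.1f%%; harmonized panel TMB cutoff: %.2f mut/Mb (p = %.3f)\n",
              100 * mean(x$samples$subtype_called != "wildtype"),
              x$harmonization$panel_cutoff, x$harmonization$p))
  if (!is.null(x$survival_table) && nrow(x$survival_table)) {
    cat("  survival stratifications:\n")
    for (i in seq_len(nrow(x$survival_table)))
      cat(sprintf("    %-18s HR = %.2f [%.2f, %.2f], log-rank p = %.3g\n",
                  x$survival_table$stratification[i],
                  x$survival_table$hazard_ratio[i],
                  x$survival_table$hr_ci_low[i], x$survival_table$hr_ci_high[i],
                  x$survival_table$logrank_p[i]))
  }
  invisible(x)
}
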