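#' PD-L1 TPS tier vocabulary
#' @return Character vector of tier labels.
#' @export
tps_tiers <- function() c("negative", "intermediate_positive", "strong_positive")

#' Immune cell types quantified by multiplex immunofluorescence
#' @return Character vector of cell-type labels.
#' @export
time_cell_types <- function() {
  c("CD8_T", "M1_TAM", "M2_TAM", "CD56bright_NK", "CD56dim_NK")
}

#' Classify a PD-L1 tumor proportion score into expression tiers
#'
#' Negative below 1%, strong positive at 50% and above, intermediate
#' positive on `[1, 50)`. The three tiers partition `[0, 100]`; boundaries
#' at 1 and 50 belong to the higher tier.
#'
#' @param tps tumor proportion score(s) in percent, in `[0, 100]`;
#'   vectorized.
#' @param thresholds length-2 numeric `(negative/intermediate,
#'   intermediate/strong)` boundary, default `c(1, 50)`.
#' @return Character vector of tier labels.
#' @export
classify_tps <- function(tps, thresholds = c(1, 50)) {
  if (!is.numeric(tps) || anyNA(tps)) stopf("'tps' must be numeric without NA")
  if (any(tps < 0 | tps > 100)) stopf("'tps' must lie in [0, 100]")
  if (length(thresholds) != 2L || thresholds[1] >= thresholds[2])
    stopf("'thresholds' must be two increasing numbers")
  ifelse(tps < thresholds[1], "negative",
         ifelse(tps < thresholds[2], "intermediate_positive",
                "strong_positive"))
}

#' Compute immune cell density for one measurement
#'
#' Density is the number of positively stained cells per square millimeter;
#' the percentage is taken over all nucleated cells in the same region.
#'
#' @param count non-negative cell count.
#' @param area_mm2 measured region area in mm^2, must be positive.
#' @param n_nucleated total nucleated cells in the region; optional — when
#'   omitted no percentage is computed.
#' @param sample_id,cell_type,compartment identifying labels carried into
#'   the record.
#' @return A one-row data.frame with columns `sample_id`, `cell_type`,
#'   `compartment`, `count`, `area_mm2`, `density` (cells/mm^2), and
#'   `percent_of_nucleated` (`NA` when `n_nucleated` is omitted).
#' @export
compute_density <- function(count, area_mm2, n_nucleated = NULL,
                            sample_id = NA_character_,
                            cell_type = NA_character_,
                            compartment = NA_character_) {
  if (!is_scalar_number(area_mm2) || area_mm2 <= 0)
    stopf("'area_mm2' must be a positive number")
  if (!is_scalar_number(count) || count < 0)
    stopf("'count' must be a non-negative number")
  pct <- NA_real_
  if (!is.null(n_nucleated)) {
    if (!is_scalar_number(n_nucleated) || n_nucleated <= 0)
      stopf("'n_nucleated' must be positive when a percentage is requested")
    if (n_nucleated < count)
      stopf("'n_nucleated' (%s) must be >= 'count' (%s)", n_nucleated, count)
    pct <- 100 * count / n_nucleated
  }
  data.frame(sample_id = sample_id, cell_type = cell_type,
             compartment = compartment, count = count, area_mm2 = area_mm2,
             density = count / area_mm2, percent_of_nucleated = pct,
             stringsAsFactors = FALSE)
}

#' Aggregate tumor and stroma measurements into the total compartment
#'
#' Counts, areas and nucleated-cell totals are summed before the density
#' and percentage are recomputed, so the total-compartment density is the
#' pooled density, not the mean of the two compartment densities.
#'
#' @param densities long data.frame as produced by [compute_density()] /
#'   the cohort generator, with compartments `tumor` and `stroma`.
#' @return The input with `total`-compartment rows appended.
#' @export
add_total_compartment <- function(densities) {
  required <- c("sample_id", "cell_type", "compartment", "count", "area_mm2")
  missing_cols <- setdiff(required, names(densities))
  if (length(missing_cols))
    stopf("density table is missing column(s): %s",
          paste(missing_cols, collapse = ", "))
  ts <- densities[densities$compartment %in% c("tumor", "stroma"), , drop = FALSE]
  agg <- stats::aggregate(cbind(count, area_mm2) ~ sample_id + cell_type,
                          data = ts, FUN = sum)
  agg$compartment <- "total"
  agg$density <- agg$count / agg$area_mm2
  agg$percent_of_nucleated <- NA_real_
  if ("n_nucleated" %in% names(densities)) {
    nn <- stats::aggregate(n_nucleated ~ sample_id + cell_type, data = ts,
                           FUN = sum)
    agg <- merge(agg, nn, by = c("sample_id", "cell_type"))
    agg$percent_of_nucleated <- 100 * agg$count / agg$n_nucleated
  }
  common <- intersect(names(densities), names(agg))
  rbind(densities[, common, drop = FALSE], agg[, common, drop = FALSE])
}

#' Compare a measurement across groups
#'
#' Two-group comparisons use an unpaired t test — Welch's correction by
#' default (`auto`), or Student's equal-variance variant on request; more
#' than two groups are compared by one-way ANOVA. P-values are two-sided
#' and reported raw; an optional Benjamini-Hochberg adjustment is left to
#' the caller (no correction is applied here).
#'
#' @param values_by_group named list mapping group label to numeric values.
#' @param method `"auto"` (Welch for 2 groups, ANOVA for >2), `"welch_t"`,
#'   `"student_t"`, or `"anova"`.
#' @return A list with `statistic`, `p_value`, `method_used`, and `df`.
#' @export
compare_groups <- function(values_by_group,
                           method = c("auto", "welch_t", "student_t", "anova")) {
  method <- match.arg(method)
  if (!is.list(values_by_group) || length(values_by_group) < 2L)
    stopf("need at least two groups")
  sizes <- vapply(values_by_group, length, integer(1))
  small <- names(values_by_group)[sizes < 2L]
  if (length(small))
    stopf("group(s) with fewer than 2 values: %s", paste(small, collapse = ", "))
  k <- length(values_by_group)
  if (method == "auto") method <- if (k == 2L) "welch_t" else "anova"
  if (method %in% c("welch_t", "student_t")) {
    if (k != 2L) stopf("t tests require exactly 2 groups; got %d", k)
    ht <- stats::t.test(values_by_group[[1L]], values_by_group[[2L]],
                        var.equal = method == "student_t")
    return(list(statistic = unname(ht$statistic), p_value = ht$p.value,
                method_used = method, df = unname(ht$parameter)))
  }
  values <- unlist(values_by_group, use.names = FALSE)
  grp <- factor(rep(names(values_by_group), sizes))
  ht <- stats::oneway.test(values ~ grp, var.equal = TRUE)
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       method_used = "anova", df = unname(ht$parameter))
}

#' Compare immune densities between cohort strata
#'
#' Runs [compare_groups()] for every (cell type, compartment) cell of a
#' long density table, grouping samples by an arbitrary stratum label.
#'
#' @param densities long density table (columns `sample_id`, `cell_type`,
#'   `compartment`, `density`).
#' @param group_by named vector mapping sample id to group label.
#' @param method passed to [compare_groups()].
#' @return data.frame with one row per (cell_type, compartment):
#'   `statistic`, `p_value`, `method_used`, and per-group means.
#' @export
compare_densities_by_group <- function(densities, group_by,
                                       method = "auto") {
  densities$group <- group_by[densities$sample_id]
  densities <- densities[!is.na(densities$group), , drop = FALSE]
  cells <- unique(densities[, c("cell_type", "compartment")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sub <- densities[densities$cell_type == cells$cell_type[i] &
                       densities$compartment == cells$compartment[i], ]
    groups <- split(sub$density, sub$group)
    res <- compare_groups(groups, method = method)
    means <- vapply(groups, mean, numeric(1))
    data.frame(cell_type = cells$cell_type[i],
               compartment = cells$compartment[i],
               statistic = res$statistic, p_value = res$p_value,
               method_used = res$method_used,
               t(means), check.names = FALSE, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
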