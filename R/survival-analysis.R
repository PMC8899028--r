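#' Median split by infiltrate density
#'
#' Labels the top half of samples by density as biomarker-high: samples are
#' sorted by descending density and the top `ceiling(n/2)` become `high`,
#' the rest `low`. This is a rank-based top-half split, not a
#' value-threshold at the median — the two differ under ties. Ties at the
#' boundary are broken deterministically by ascending sample id, with a
#' warning.
#'
#' @param values named numeric vector: sample id -> density.
#' @return Named character vector: sample id -> `"high"`/`"low"`, in the
#'   input's order.
#' @export
median_split <- function(values) {
  if (length(values) < 2L) stopf("median split needs at least 2 samples")
  if (is.null(names(values)) || anyNA(names(values)) || !all(nzchar(names(values))))
    stopf("'values' must be named by sample id")
  if (anyNA(values)) stopf("'values' must not contain NA")
  n <- length(values)
  n_high <- ceiling(n / 2)
  ord <- order(-values, names(values))
  boundary_value <- values[ord[n_high]]
  if (n_high < n && values[ord[n_high + 1L]] == boundary_value)
    warnf("density tie at the median-split boundary (density = %s); broken by sample id",
          format(boundary_value))
  labels <- stats::setNames(rep("low", n), names(values))
  labels[ord[seq_len(n_high)]] <- "high"
  labels[names(values)]
}

as_surv_df <- function(records) {
  if (!is.data.frame(records) || !all(c("time_months", "event") %in% names(records)))
    stopf("survival records need columns 'time_months' and 'event'")
  if (nrow(records) == 0L) stopf("empty survival records")
  if (any(records$time_months < 0)) stopf("negative survival times")
  records$event <- as.logical(records$event)
  records
}

#' Kaplan-Meier product-limit estimate
#'
#' At each distinct event time the survivor function drops by the factor
#' `1 - d/n` (events over number at risk); censored subjects leave the risk
#' set after their time. Backed by [survival::survfit()].
#'
#' @param records data.frame with `time_months` and `event` (logical;
#'   `TRUE` = progression observed).
#' @return A list of class `km_curve` with `time`, `surv` (non-increasing,
#'   starts at <= 1), `n_risk`, `n_event`, `n_censor`, and `median`
#'   (median survival time, `NA` if never reached).
#' @export
km_estimate <- function(records) {
  records <- as_surv_df(records)
  fit <- survival::survfit(survival::Surv(time_months, event) ~ 1,
                           data = records)
  med <- unname(summary(fit)$table["median"])
  structure(list(time = fit$time, surv = fit$surv, n_risk = fit$n.risk,
                 n_event = fit$n.event, n_censor = fit$n.censor,
                 median = med),
            class = "km_curve")
}

#' Evaluate a Kaplan-Meier curve at given times
#'
#' Right-continuous step-function evaluation: `S(t)` is the estimate after
#' all events at or before `t`.
#'
#' @param curve a `km_curve` from [km_estimate()].
#' @param times numeric vector of evaluation times.
#' @return Numeric vector of survival probabilities.
#' @export
km_survival_at <- function(curve, times) {
  vapply(times, function(t) {
    idx <- which(curve$time <= t)
    if (!length(idx)) 1 else curve$surv[max(idx)]
  }, numeric(1))
}

#' Two-group log-rank test
#'
#' Standard log-rank: at each event time the expected number of events in
#' each group comes from the hypergeometric mean given the margins, the
#' statistic is `(sum(O) - sum(E))^2 / sum(V)`, and the p-value is from a
#' chi-square with 1 df. Backed by [survival::survdiff()].
#'
#' @param group_a,group_b survival record data.frames (columns
#'   `time_months`, `event`).
#' @return A list with `chi_square`, `p_value`, `observed`, `expected`
#'   (per-group event counts).
#' @export
logrank_test <- function(group_a, group_b) {
  group_a <- as_surv_df(group_a)
  group_b <- as_surv_df(group_b)
  if (sum(group_a$event) + sum(group_b$event) == 0L)
    stopf("log-rank test needs at least one event")
  df <- rbind(data.frame(time_months = group_a$time_months,
                         event = group_a$event, group = "A"),
              data.frame(time_months = group_b$time_months,
                         event = group_b$event, group = "B"))
  sd <- survival::survdiff(survival::Surv(time_months, event) ~ group,
                           data = df)
  chi <- unname(sd$chisq)
  list(chi_square = chi,
       p_value = stats::pchisq(chi, df = 1, lower.tail = FALSE),
       observed = unname(sd$obs), expected = unname(sd$exp))
}

#' Univariate Cox proportional hazards model
#'
#' Maximizes the Cox partial likelihood for a single covariate (Efron tie
#' handling by default, Breslow on request) and reports the hazard ratio
#' with a 95% CI from the observed-information standard error. Backed by
#' [survival::coxph()].
#'
#' @param records survival record data.frame (`sample_id`, `time_months`,
#'   `event`).
#' @param covariate named numeric vector: sample id -> covariate value
#'   (binary strata should be coded 0/1).
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return A list with `hazard_ratio`, `ci_low`, `ci_high`, `beta`, `se`,
#'   `p_value`, `n`, `n_events`.
#' @export
cox_univariate <- function(records, covariate, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  records <- as_surv_df(records)
  if (!"sample_id" %in% names(records))
    stopf("survival records need a 'sample_id' column")
  x <- covariate[records$sample_id]
  if (anyNA(x))
    stopf("covariate missing for sample(s): %s",
          paste(utils::head(records$sample_id[is.na(x)], 5), collapse = ", "))
  if (sum(records$event) < 2L) stopf("Cox model needs at least 2 events")
  if (length(unique(x)) < 2L) stopf("constant covariate")
  fit <- survival::coxph(survival::Surv(records$time_months, records$event) ~ x,
                         ties = ties)
  if (!is.finite(fit$coefficients[["x"]]) ||
      !is.finite(sqrt(fit$var[1, 1])))
    stopf("Cox partial-likelihood maximization did not converge (beta = %s)",
          format(fit$coefficients[["x"]]))
  beta <- unname(fit$coefficients[["x"]])
  se <- sqrt(fit$var[1, 1])
  z <- stats::qnorm(0.975)
  list(hazard_ratio = exp(beta),
       ci_low = exp(beta - z * se), ci_high = exp(beta + z * se),
       beta = beta, se = se,
       p_value = 2 * stats::pnorm(-abs(beta / se)),
       n = nrow(records), n_events = sum(records$event))
}

#' Stratified progression-free-survival analysis
#'
#' For a binary stratification label, runs the Kaplan-Meier estimate per
#' stratum, the two-group log-rank test, and a univariate Cox model with
#' the stratum as a 0/1 covariate (reference = the level sorted first, so
#' for `"high"`/`"low"` the hazard ratio is high vs low).
#'
#' @param records survival record data.frame (`sample_id`, `time_months`,
#'   `event`).
#' @param strata named character vector: sample id -> stratum label
#'   (exactly two levels).
#' @return A list with `levels`, per-level `km` curves, `logrank`, and
#'   `cox` results.
#' @export
survival_by_stratum <- function(records, strata) {
  records <- as_surv_df(records)
  lab <- strata[records$sample_id]
  if (anyNA(lab)) stopf("stratum label missing for some samples")
  levels <- sort(unique(lab))
  if (length(levels) != 2L)
    stopf("expected exactly 2 stratum levels; got %d", length(levels))
  km <- lapply(levels, function(l) km_estimate(records[lab == l, ]))
  names(km) <- levels
  lr <- logrank_test(records[lab == levels[1L], ], records[lab == levels[2L], ])
  x <- stats::setNames(as.numeric(lab == levels[1L]), records$sample_id)
  cox <- cox_univariate(records, x)
  list(levels = levels, km = km, logrank = lr, cox = cox)
}

#' Write a Kaplan-Meier curve as a TSV step function
#' @param curve a `km_curve`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_km_curve <- function(curve, path) {
  write_tsv(data.frame(time = curve$time, surv = curve$surv,
                       n_risk = curve$n_risk, n_event = curve$n_event,
                       n_censor = curve$n_censor), path)
}
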