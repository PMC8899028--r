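# Independent oracles: deliberately naive re-derivations used to check the
# implementation from a second route. None of them call the package code
# they verify.

# Empirical quantile by hand: sort, then interpolate linearly between order
# statistics at position h = (n - 1) p + 1.
oracle_quantile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  if (n == 1L) return(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# Empirical survivor function S(t) = P(T > t) for fully observed times.
oracle_survivor <- function(times, t) mean(times > t)

# Kaplan-Meier by hand: product-limit over distinct event times.
oracle_km <- function(time, event) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]
  ts <- sort(unique(time[event]))
  s <- 1
  surv <- numeric(length(ts))
  for (i in seq_along(ts)) {
    at_risk <- sum(time >= ts[i])
    d <- sum(time == ts[i] & event)
    s <- s * (1 - d / at_risk)
    surv[i] <- s
  }
  list(time = ts, surv = surv)
}

# Two-group log-rank by the hypergeometric sums: at each distinct event
# time, O - E for group A and the hypergeometric variance.
oracle_logrank <- function(time_a, event_a, time_b, event_b) {
  time <- c(time_a, time_b)
  event <- c(event_a, event_b)
  grp <- rep(c("A", "B"), c(length(time_a), length(time_b)))
  o_minus_e <- 0
  v <- 0
  for (t in sort(unique(time[event]))) {
    n <- sum(time >= t)
    n_a <- sum(time >= t & grp == "A")
    d <- sum(time == t & event)
    d_a <- sum(time == t & event & grp == "A")
    e_a <- d * n_a / n
    o_minus_e <- o_minus_e + d_a - e_a
    if (n > 1)
      v <- v + d * (n_a / n) * (1 - n_a / n) * (n - d) / (n - 1)
  }
  chisq <- o_minus_e^2 / v
  list(chi_square = chisq,
       p_value = stats::pchisq(chisq, 1, lower.tail = FALSE))
}

# Welch t statistic from the closed form.
oracle_welch <- function(x, y) {
  se2 <- stats::var(x) / length(x) + stats::var(y) / length(y)
  tstat <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((stats::var(x) / length(x))^2 / (length(x) - 1) +
                   (stats::var(y) / length(y))^2 / (length(y) - 1))
  list(statistic = tstat, df = df,
       p_value = 2 * stats::pt(-abs(tstat), df))
}

# Cox log partial likelihood for untied event times (Efron and Breslow
# coincide), maximized by grid search.
oracle_cox_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (t in time[event]) {
    risk <- time >= t
    i <- which(time == t & event)
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

oracle_cox_beta <- function(time, event, x, grid = seq(-5, 5, by = 1e-3)) {
  ll <- vapply(grid, oracle_cox_loglik, numeric(1),
               time = time, event = event, x = x)
  grid[which.max(ll)]
}

# Small random variant table for filter property tests.
random_variant_table <- function(n, seed) {
  set.seed(seed)
  variant_table(
    sample_id = sprintf("S%02d", sample.int(5, n, replace = TRUE)),
    gene = sample(c("EGFR", "TP53", "KRAS"), n, replace = TRUE),
    pos = sample.int(1e6, n),
    hgvs_p = "p.A100T",
    consequence = sample(setdiff(variant_consequences(), "amplification"),
                         n, replace = TRUE),
    af = round(stats::runif(n), 3),
    popfreq_1kg = round(stats::runif(n, 0, 0.05), 4),
    popfreq_esp6500 = round(stats::runif(n, 0, 0.05), 4))
}
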