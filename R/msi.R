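#' Microsatellite locus profile
#'
#' One locus's tumor read-length histogram together with its
#' panel-of-normals baseline histogram. Repeat lengths are in repeat units;
#' histograms are named integer vectors (names = repeat length, values =
#' read counts). Coverage is the total tumor read count at the locus.
#'
#' @param locus_id locus identifier.
#' @param reference_modal_length modal repeat length in the reference.
#' @param histogram named numeric vector of tumor read counts per repeat
#'   length.
#' @param baseline_histogram named numeric vector of panel-of-normals read
#'   counts per repeat length.
#' @return A list of class `msi_locus_profile`; `coverage` is derived as
#'   the sum of `histogram`.
#' @export
msi_locus_profile <- function(locus_id, reference_modal_length,
                              histogram, baseline_histogram) {
  if (is.null(names(histogram)) || is.null(names(baseline_histogram)))
    stopf("histograms must be named by repeat length")
  if (any(histogram < 0) || any(baseline_histogram < 0))
    stopf("histogram counts must be >= 0")
  structure(list(locus_id = as.character(locus_id),
                 reference_modal_length = as.integer(reference_modal_length),
                 histogram = histogram,
                 baseline_histogram = baseline_histogram,
                 coverage = sum(histogram)),
            class = "msi_locus_profile")
}

#' Select the best-covered microsatellite loci
#'
#' Of the loci assayed, the `k` with the highest tumor coverage enter the
#' final score (default 30). Coverage ties spanning the selection boundary
#' are broken deterministically by ascending `locus_id`, with a warning.
#'
#' @param loci list of [msi_locus_profile()] objects.
#' @param k number of loci to keep (default 30).
#' @return List of the selected profiles; if fewer than `k` loci are
#'   available all are returned with a warning.
#' @export
select_msi_loci <- function(loci, k = 30L) {
  if (!length(loci)) stopf("empty locus list")
  if (!is_scalar_number(k) || k < 1) stopf("'k' must be >= 1")
  cov <- vapply(loci, function(l) l$coverage, numeric(1))
  ids <- vapply(loci, function(l) l$locus_id, character(1))
  if (length(loci) < k) {
    warnf("only %d loci available; fewer than the %d requested", length(loci), k)
    return(loci[order(-cov, ids)])
  }
  ord <- order(-cov, ids)
  cutoff_cov <- cov[ord[k]]
  if (sum(cov == cutoff_cov) > 1L && k < length(loci) && cov[ord[k + 1L]] == cutoff_cov)
    warnf("coverage tie at the selection boundary (coverage = %s); broken by locus_id",
          format(cutoff_cov))
  loci[ord[seq_len(k)]]
}

#' Call instability at one microsatellite locus
#'
#' A locus is unstable when too much of its tumor read mass sits at repeat
#' lengths essentially unsupported by the panel-of-normals baseline: repeat
#' lengths with baseline frequency below `novel_support_min` are "novel",
#' and the locus is called unstable iff the fraction of tumor reads at
#' novel lengths is at least `instability_fraction_min`.
#'
#' @param locus an [msi_locus_profile()].
#' @param novel_support_min baseline-frequency threshold below which a
#'   repeat length counts as novel (default 0.01).
#' @param instability_fraction_min minimum novel-read fraction to call the
#'   locus unstable (default 0.20).
#' @return `TRUE` (unstable) or `FALSE` (stable).
#' @export
call_locus_instability <- function(locus, novel_support_min = 0.01,
                                   instability_fraction_min = 0.20) {
  if (!inherits(locus, "msi_locus_profile"))
    stopf("'locus' must be an msi_locus_profile")
  if (locus$coverage <= 0) stopf("zero coverage at locus %s", locus$locus_id)
  if (!length(locus$baseline_histogram))
    stopf("empty baseline histogram at locus %s", locus$locus_id)
  base_total <- sum(locus$baseline_histogram)
  base_freq <- locus$baseline_histogram / base_total
  supported <- names(base_freq)[base_freq >= novel_support_min]
  novel_reads <- sum(locus$histogram[!names(locus$histogram) %in% supported])
  (novel_reads / locus$coverage) >= instability_fraction_min
}

#' Aggregate per-locus instability calls into an MSI score
#'
#' The MSI score is the fraction of evaluated loci called unstable; a
#' sample is MSI-H iff its score is at least 0.4 (boundary inclusive),
#' otherwise MSS.
#'
#' @param selected_loci list of evaluated [msi_locus_profile()] objects.
#' @param calls logical vector of instability calls aligned with
#'   `selected_loci`.
#' @param sample_id optional sample identifier carried into the result.
#' @param msi_h_cutoff classification cutoff on the score (default 0.4).
#' @return A list of class `msi_result` with `sample_id`,
#'   `n_loci_evaluated`, `n_unstable`, `score`, `classification`.
#' @export
compute_msi_score <- function(selected_loci, calls, sample_id = NA_character_,
                              msi_h_cutoff = 0.4) {
  if (!length(selected_loci)) stopf("zero evaluated loci")
  if (length(calls) != length(selected_loci))
    stopf("'calls' must align with 'selected_loci' (%d vs %d)",
          length(calls), length(selected_loci))
  n <- length(calls)
  n_unstable <- sum(calls)
  score <- n_unstable / n
  structure(list(sample_id = sample_id,
                 n_loci_evaluated = as.integer(n),
                 n_unstable = as.integer(n_unstable),
                 score = score,
                 classification = if (score >= msi_h_cutoff) "MSI-H" else "MSS"),
            class = "msi_result")
}

#' @export
print.msi_result <- function(x, ...) {
  cat(sprintf("MSI score %.4f (%d/%d unstable loci) — %s\n",
              x$score, x$n_unstable, x$n_loci_evaluated, x$classification))
  invisible(x)
}

#' Score a sample's microsatellite profiles end to end
#'
#' Convenience wrapper chaining [select_msi_loci()],
#' [call_locus_instability()] and [compute_msi_score()].
#'
#' @inheritParams select_msi_loci
#' @inheritParams call_locus_instability
#' @inheritParams compute_msi_score
#' @return An `msi_result`.
#' @export
score_msi_sample <- function(loci, k = 30L, sample_id = NA_character_,
                             novel_support_min = 0.01,
                             instability_fraction_min = 0.20,
                             msi_h_cutoff = 0.4) {
  selected <- select_msi_loci(loci, k = k)
  calls <- vapply(selected, call_locus_instability,
                  novel_support_min = novel_support_min,
                  instability_fraction_min = instability_fraction_min,
                  logical(1))
  compute_msi_score(selected, calls, sample_id = sample_id,
                    msi_h_cutoff = msi_h_cutoff)
}

#' Write microsatellite profiles to long TSV
#'
#' Layout: one row per (sample, locus, repeat length) with tumor and
#' baseline read counts.
#'
#' @param profiles named list: sample id -> list of [msi_locus_profile()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_msi_profiles <- function(profiles, path) {
  rows <- lapply(names(profiles), function(sid) {
    do.call(rbind, lapply(profiles[[sid]], function(l) {
      lengths <- sort(unique(as.integer(c(names(l$histogram),
                                          names(l$baseline_histogram)))))
      data.frame(sample_id = sid, locus_id = l$locus_id,
                 reference_modal_length = l$reference_modal_length,
                 repeat_length = lengths,
                 read_count = as.numeric(l$histogram[as.character(lengths)]),
                 baseline_count = as.numeric(
                   l$baseline_histogram[as.character(lengths)]),
                 stringsAsFactors = FALSE)
    }))
  })
  df <- do.call(rbind, rows)
  df$read_count[is.na(df$read_count)] <- 0
  df$baseline_count[is.na(df$baseline_count)] <- 0
  write_tsv(df, path)
}

#' Read microsatellite profiles from long TSV
#'
#' Inverse of [write_msi_profiles()].
#'
#' @param path TSV path.
#' @return Named list: sample id -> list of [msi_locus_profile()].
#' @export
read_msi_profiles <- function(path) {
  df <- read_tsv(path)
  required <- c("sample_id", "locus_id", "reference_modal_length",
                "repeat_length", "read_count", "baseline_count")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stopf("%s: missing required column(s): %s", path,
          paste(missing_cols, collapse = ", "))
  out <- lapply(split(df, df$sample_id), function(sdf) {
    unname(lapply(split(sdf, sdf$locus_id), function(ldf) {
      hist_t <- stats::setNames(ldf$read_count, ldf$repeat_length)
      hist_b <- stats::setNames(ldf$baseline_count, ldf$repeat_length)
      msi_locus_profile(ldf$locus_id[1L], ldf$reference_modal_length[1L],
                        hist_t[hist_t > 0 | hist_b > 0],
                        hist_b[hist_t > 0 | hist_b > 0])
    }))
  })
  out
}
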