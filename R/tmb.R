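#' Assay specification for TMB computation
#'
#' Captures the interrogated coding footprint of an assay and, optionally,
#' its TMB classification cutoff. The conventional WES cutoff is 10
#' mutations/Mb; a targeted panel needs its own cutoff, obtained by
#' reference-population quantile matching (see [harmonize_cutoff()]).
#'
#' @param name `"wes"` or `"panel733"` (a 733-gene whole-exon panel).
#' @param coding_region_size_mb interrogated coding region in megabases;
#'   defaults: 35.0 (wes), 2.2 (panel733).
#' @param tmb_cutoff optional classification cutoff in mutations/Mb.
#' @return A list of class `assay_spec`.
#' @export
assay_spec <- function(name = c("wes", "panel733"),
                       coding_region_size_mb = NULL, tmb_cutoff = NULL) {
  name <- match.arg(name)
  if (is.null(coding_region_size_mb))
    coding_region_size_mb <- switch(name, wes = 35.0, panel733 = 2.2)
  if (!is_scalar_number(coding_region_size_mb) || coding_region_size_mb <= 0)
    stopf("'coding_region_size_mb' must be a positive number")
  if (!is.null(tmb_cutoff) &&
      (!is_scalar_number(tmb_cutoff) || tmb_cutoff <= 0))
    stopf("'tmb_cutoff' must be a positive number")
  structure(list(name = name,
                 coding_region_size_mb = coding_region_size_mb,
                 tmb_cutoff = tmb_cutoff),
            class = "assay_spec")
}

#' Built-in driver hotspot list
#'
#' Canonical EGFR/KRAS/BRAF hotspot alterations excluded from TMB counting.
#' Entries with an empty `hgvs_p` exclude the whole gene. Shipped as a
#' plain-TSV default; callers supply their own table to override.
#'
#' @return data.frame with columns `gene`, `hgvs_p`.
#' @export
default_driver_list <- function() {
  path <- system.file("extdata", "driver_hotspots.tsv",
                      package = "egfrmarkers", mustWork = TRUE)
  df <- read_tsv(path)
  df$hgvs_p <- ifelse(is.na(df$hgvs_p), "", df$hgvs_p)
  df
}

#' Compute tumor mutational burden for one sample
#'
#' TMB is the count of somatic coding SNVs and indels — synonymous and
#' nonsynonymous alike — per megabase of interrogated coding region,
#' excluding designated driver mutations. Input variants are expected to
#' have passed the `tmb` filter profile (which retains silent variants).
#' A variant is excluded as a driver when its `(gene, hgvs_p)` pair matches
#' the driver list, when its gene matches a whole-gene driver entry, or
#' when its own `is_driver` annotation flag is set.
#'
#' @param variants variant table for one sample, pre-filtered with
#'   `filter_profile("tmb")`.
#' @param assay an [assay_spec()].
#' @param driver_list data.frame with columns `gene`, `hgvs_p` (empty
#'   `hgvs_p` = whole gene); defaults to [default_driver_list()].
#' @return A list of class `tmb_result` with `sample_id`, `value`
#'   (mutations/Mb), `n_counted`, `assay`, and `classification` (unset,
#'   `NA`, until [classify_tmb()] is applied).
#' @export
compute_tmb <- function(variants, assay, driver_list = default_driver_list()) {
  validate_variants(variants)
  if (!inherits(assay, "assay_spec")) stopf("'assay' must be an assay_spec")
  if (assay$coding_region_size_mb <= 0)
    stopf("coding region size must be positive")
  sample_id <- if (nrow(variants)) unique(variants$sample_id)[1L] else NA_character_
  if (nrow(variants)) {
    whole_gene <- driver_list$gene[!nzchar(driver_list$hgvs_p)]
    hotspot_key <- paste(driver_list$gene, driver_list$hgvs_p, sep = ":")
    variant_key <- paste(variants$gene, variants$hgvs_p, sep = ":")
    is_excluded <- variants$is_driver |
      variants$gene %in% whole_gene |
      variant_key %in% hotspot_key
    n_counted <- sum(!is_excluded)
  } else {
    n_counted <- 0L
  }
  structure(list(sample_id = sample_id,
                 value = n_counted / assay$coding_region_size_mb,
                 n_counted = as.integer(n_counted),
                 assay = assay$name,
                 classification = NA_character_),
            class = "tmb_result")
}

#' Classify a TMB result against a cutoff
#'
#' TMB-High iff value >= cutoff (boundary inclusive), TMB-Low otherwise.
#'
#' @param result a `tmb_result` from [compute_tmb()], or a bare numeric TMB
#'   value (in which case a minimal result object is built around it).
#' @param cutoff positive cutoff in mutations/Mb.
#' @return The result with `classification` set to `"TMB-High"` or
#'   `"TMB-Low"`.
#' @export
classify_tmb <- function(result, cutoff) {
  if (!is_scalar_number(cutoff) || cutoff <= 0)
    stopf("'cutoff' must be a positive number")
  if (is.numeric(result))
    result <- structure(list(sample_id = NA_character_, value = result,
                             n_counted = NA_integer_, assay = NA_character_,
                             classification = NA_character_),
                        class = "tmb_result")
  if (!inherits(result, "tmb_result"))
    stopf("'result' must be a tmb_result or a numeric TMB value")
  result$classification <- if (result$value >= cutoff) "TMB-High" else "TMB-Low"
  result
}

#' @export
print.tmb_result <- function(x, ...) {
  cat(sprintf("TMB [%s] %s: %.4g mut/Mb (n = %s)%s\n", x$assay,
              x$sample_id %||% NA, x$value, x$n_counted,
              if (is.na(x$classification)) "" else paste0(" — ", x$classification)))
  invisible(x)
}

#' Harmonize a TMB cutoff across assays by quantile matching
#'
#' Transfers a classification cutoff from one assay to another using a
#' reference population measured on both: the fraction `p` of reference
#' samples falling strictly below the source cutoff (the TMB-Low
#' proportion) is computed on the source assay, and the target cutoff is
#' the empirical `p`-quantile of the target-assay values (linear
#' interpolation between order statistics, R type 7). By construction the
#' TMB-Low proportion under the new cutoff matches `p` to within `1/n` on
#' tie-free reference lists.
#'
#' @param wes_reference_values numeric vector of source-assay (WES) TMB
#'   values for the reference population.
#' @param wes_cutoff positive source-assay cutoff (conventionally 10
#'   mutations/Mb).
#' @param panel_reference_values numeric vector of target-assay (panel)
#'   TMB values for the same (or an exchangeable) reference population.
#' @return A list of class `tmb_harmonization` with `p` (TMB-Low
#'   proportion), `panel_cutoff`, and `degenerate` (`TRUE` when `p` hit 0
#'   or 1 and the cutoff collapsed to an extreme of the panel values,
#'   flagged with a warning).
#' @export
harmonize_cutoff <- function(wes_reference_values, wes_cutoff,
                             panel_reference_values) {
  if (!length(wes_reference_values)) stopf("empty WES reference list")
  if (!length(panel_reference_values)) stopf("empty panel reference list")
  if (!is_scalar_number(wes_cutoff) || wes_cutoff <= 0)
    stopf("'wes_cutoff' must be a positive number")
  if (anyNA(wes_reference_values) || anyNA(panel_reference_values))
    stopf("reference TMB lists must not contain NA")
  p <- mean(wes_reference_values < wes_cutoff)
  degenerate <- p == 0 || p == 1
  if (p == 0)
    warnf("no WES reference value below the cutoff; panel cutoff set to the minimum panel value")
  if (p == 1)
    warnf("all WES reference values below the cutoff; panel cutoff set to the maximum panel value")
  panel_cutoff <- unname(stats::quantile(panel_reference_values, probs = p,
                                         type = 7, names = FALSE))
  structure(list(p = p, panel_cutoff = panel_cutoff, degenerate = degenerate),
            class = "tmb_harmonization")
}

#' @export
print.tmb_harmonization <- function(x, ...) {
  cat(sprintf("TMB cutoff harmonization: TMB-Low proportion p = %.4f, panel cutoff = %.4g mut/Mb\n",
              x$p, x$panel_cutoff))
  invisible(x)
}
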