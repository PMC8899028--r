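#' Subtype vocabulary for EGFR alterations
#'
#' The sample-level labels used throughout the pipeline. `19del` and `L858R`
#' are the common sensitizing mutations; `G719X` collapses G719A/C/S;
#' `20ins` covers in-frame exon-20 insertions/duplications; `other_uncommon`
#' absorbs everything else (including gene amplification); `multiple` marks
#' samples carrying at least two distinct mutation categories.
#'
#' @return Character vector of subtype labels, wildtype first.
#' @export
egfr_subtype_labels <- function() {
  c("wildtype", "19del", "L858R", "T790M", "G719X", "S768I", "L861Q",
    "20ins", "other_uncommon", "multiple")
}

#' Residue-to-exon map for the EGFR kinase domain
#'
#' Approximate codon ranges of EGFR exons 18-21 under the canonical
#' NM_005228 transcript numbering. Exon 19 (codons 729-761) hosts the
#' recurrent in-frame deletions; exon 20 (762-823) hosts the in-frame
#' insertions/duplications and T790M/S768I; exon 21 (824-875) hosts
#' L858R/L861Q.
#'
#' @return data.frame with columns `exon`, `start`, `end` (codons, closed).
#' @export
egfr_exon_map <- function() {
  data.frame(exon = 18:21,
             start = c(688L, 729L, 762L, 824L),
             end = c(728L, 761L, 823L, 875L))
}

# Parse one protein-level HGVS string (one-letter amino-acid codes).
# Returns list(kind, start, end) with kind in
# {substitution, del, delins, ins, dup, frameshift} or NULL when the string
# does not match any supported form.
parse_hgvs_p <- function(s) {
  s <- sub("^p\\.", "", trimws(s))
  m <- regmatches(s, regexec("^([A-Z])([0-9]+)([A-Z])$", s))[[1]]
  if (length(m))
    return(list(kind = "substitution", start = as.integer(m[3]),
                end = as.integer(m[3]), from = m[2], to = m[4],
                short = paste0(m[2], m[3], m[4])))
  m <- regmatches(s, regexec(
    "^([A-Z])([0-9]+)(?:_([A-Z])([0-9]+))?del(ins([A-Z*]+))?$", s))[[1]]
  if (length(m)) {
    start <- as.integer(m[3])
    end <- if (nzchar(m[5])) as.integer(m[5]) else start
    kind <- if (nzchar(m[6])) "delins" else "del"
    return(list(kind = kind, start = start, end = end))
  }
  m <- regmatches(s, regexec(
    "^([A-Z])([0-9]+)_([A-Z])([0-9]+)ins([A-Z*]+)$", s))[[1]]
  if (length(m))
    return(list(kind = "ins", start = as.integer(m[3]), end = as.integer(m[5])))
  m <- regmatches(s, regexec(
    "^([A-Z])([0-9]+)(?:_([A-Z])([0-9]+))?dup$", s))[[1]]
  if (length(m)) {
    start <- as.integer(m[3])
    end <- if (nzchar(m[5])) as.integer(m[5]) else start
    return(list(kind = "dup", start = start, end = end))
  }
  m <- regmatches(s, regexec(
    "^([A-Z])([0-9]+)([A-Z]?)fs(\\*[0-9]+)?$", s))[[1]]
  if (length(m))
    return(list(kind = "frameshift", start = as.integer(m[3]),
                end = as.integer(m[3])))
  NULL
}

# Category of a single EGFR alteration. `consequence` disambiguates
# amplification records, which carry no HGVS string.
egfr_alteration_category <- function(hgvs_p, consequence = "other") {
  if (identical(consequence, "amplification") || identical(hgvs_p, "amplification"))
    return("other_uncommon")
  if (is.na(hgvs_p) || !nzchar(hgvs_p))
    stopf("EGFR variant without protein HGVS and not an amplification")
  p <- parse_hgvs_p(hgvs_p)
  if (is.null(p)) stopf("unparseable protein HGVS string: '%s'", hgvs_p)
  exon19 <- egfr_exon_map()[egfr_exon_map()$exon == 19L, ]
  exon20 <- egfr_exon_map()[egfr_exon_map()$exon == 20L, ]
  if (p$kind == "substitution") {
    if (p$short %in% c("L858R", "T790M", "S768I", "L861Q")) return(p$short)
    if (grepl("^G719[ACS]$", p$short)) return("G719X")
    return("other_uncommon")
  }
  if (p$kind %in% c("del", "delins")) {
    if (p$start >= exon19$start && p$end <= exon19$end) return("19del")
    return("other_uncommon")
  }
  if (p$kind %in% c("ins", "dup")) {
    if (p$start >= exon20$start && p$end <= exon20$end) return("20ins")
    return("other_uncommon")
  }
  "other_uncommon"
}

#' Classify a sample's EGFR alterations into a subtype label
#'
#' Deterministic, order-insensitive mapping from a sample's reported EGFR
#' variants to the subtype vocabulary: exact protein matches for the point
#' mutations (G719A/C/S collapse to G719X), exon-19 in-frame
#' deletions/delins to `19del`, exon-20 in-frame insertions/duplications to
#' `20ins`, everything else (including amplification) to `other_uncommon`.
#' Two or more distinct categories — e.g. T790M co-occurring with a
#' sensitizing mutation — yield `multiple`; no alterations yield
#' `wildtype`.
#'
#' @param egfr_variants variant table rows for one sample; every row must
#'   have `gene == "EGFR"` and is expected to have passed the reporting
#'   filter.
#' @return A list of class `egfr_subtype` with `label`,
#'   `constituent_alterations` (HGVS strings, amplification as
#'   `"amplification"`), and `categories` (per-alteration category labels,
#'   for per-alteration tabulations).
#' @export
classify_egfr <- function(egfr_variants) {
  if (!is.data.frame(egfr_variants))
    stopf("'egfr_variants' must be a variant table (data.frame)")
  if (nrow(egfr_variants) == 0L)
    return(structure(list(label = "wildtype",
                          constituent_alterations = character(),
                          categories = character()),
                     class = "egfr_subtype"))
  if (!all(egfr_variants$gene == "EGFR"))
    stopf("classify_egfr expects EGFR variants only; got gene(s): %s",
          paste(setdiff(unique(egfr_variants$gene), "EGFR"), collapse = ", "))
  cats <- mapply(egfr_alteration_category,
                 egfr_variants$hgvs_p, egfr_variants$consequence,
                 USE.NAMES = FALSE)
  constituents <- ifelse(egfr_variants$consequence == "amplification",
                         "amplification", egfr_variants$hgvs_p)
  label <- if (length(unique(cats)) >= 2L) "multiple" else cats[1L]
  structure(list(label = label,
                 constituent_alterations = constituents,
                 categories = cats),
            class = "egfr_subtype")
}

#' @export
print.egfr_subtype <- function(x, ...) {
  cat("EGFR subtype:", x$label, "\n")
  if (length(x$constituent_alterations))
    cat("  alterations:", paste(x$constituent_alterations, collapse = ", "),
        "\n")
  invisible(x)
}

#' Tabulate EGFR subtype frequencies in a cohort
#'
#' Counts samples per subtype label and expresses each as a percentage of
#' the chosen denominator: all samples, or EGFR-mutated samples only (the
#' convention used when quoting e.g. the 19del share among mutation
#' carriers).
#'
#' @param cohort data frame with a `subtype` column, or a character vector
#'   of subtype labels.
#' @param denominator_mode `"all"` (default) or `"mutated_only"` (wildtype
#'   rows are dropped and the denominator is the number of mutated samples).
#' @return data.frame with columns `label`, `count`, `percent` (rounded to
#'   2 decimals); the denominator is attached as attribute `denominator`.
#' @export
tabulate_subtype_frequencies <- function(cohort,
                                         denominator_mode = c("all",
                                                              "mutated_only")) {
  denominator_mode <- match.arg(denominator_mode)
  labels <- if (is.data.frame(cohort)) cohort$subtype else as.character(cohort)
  if (is.null(labels) || length(labels) == 0L)
    stopf("empty cohort: no subtype labels to tabulate")
  unknown <- setdiff(unique(labels), egfr_subtype_labels())
  if (length(unknown))
    stopf("unknown subtype label(s): %s", paste(unknown, collapse = ", "))
  if (denominator_mode == "mutated_only")
    labels <- labels[labels != "wildtype"]
  if (length(labels) == 0L)
    stopf("no EGFR-mutated samples under denominator_mode = 'mutated_only'")
  denom <- length(labels)
  present <- egfr_subtype_labels()[egfr_subtype_labels() %in% labels]
  counts <- vapply(present, function(l) sum(labels == l), integer(1))
  out <- data.frame(label = present, count = unname(counts),
                    percent = round(100 * unname(counts) / denom, 2),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "denominator") <- denom
  out
}
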