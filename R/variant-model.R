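#' Consequence vocabulary for annotated somatic variants
#'
#' The closed set of consequence classes the pipeline understands. Annotated
#' calls must use these labels; anything else is rejected at validation time
#' rather than silently dropped.
#'
#' @return Character vector of valid consequence class labels.
#' @export
variant_consequences <- function() {
  c("missense", "stopgain", "stoploss", "silent",
    "frameshift_indel", "inframe_indel", "inframe_insertion_dup",
    "amplification", "other")
}

#' Column names of the MAF-like variant table
#' @return Character vector of required column names.
#' @export
variant_columns <- function() {
  c("sample_id", "gene", "chrom", "pos", "ref", "alt", "hgvs_p",
    "consequence", "af", "depth", "popfreq_1kg", "popfreq_esp6500",
    "is_driver")
}

#' Build a validated variant table
#'
#' Assembles annotated somatic calls into the canonical MAF-like data frame
#' used everywhere downstream. Coordinates are 1-based, fully closed (VCF
#' convention). Copy-number amplification records carry empty `ref`/`alt`
#' and are only meaningful at the gene level.
#'
#' @param sample_id,gene,chrom,ref,alt,hgvs_p character vectors (recycled to
#'   a common length).
#' @param pos 1-based integer positions.
#' @param consequence consequence class, one of [variant_consequences()].
#' @param af somatic allele fraction in `[0, 1]`.
#' @param depth non-negative read depth.
#' @param popfreq_1kg,popfreq_esp6500 population allele frequencies in
#'   `[0, 1]`; `NA` means not observed in that database.
#' @param is_driver logical flag for known driver alterations.
#' @return A `data.frame` with the columns of [variant_columns()].
#' @export
variant_table <- function(sample_id, gene, chrom = "chr7", pos = 1L,
                          ref = "A", alt = "T", hgvs_p = "",
                          consequence = "missense", af = 0.3, depth = 500L,
                          popfreq_1kg = 0, popfreq_esp6500 = 0,
                          is_driver = FALSE) {
  df <- data.frame(sample_id = sample_id, gene = gene, chrom = chrom,
                   pos = as.integer(pos), ref = ref, alt = alt,
                   hgvs_p = hgvs_p, consequence = consequence,
                   af = as.numeric(af), depth = as.integer(depth),
                   popfreq_1kg = as.numeric(popfreq_1kg),
                   popfreq_esp6500 = as.numeric(popfreq_esp6500),
                   is_driver = as.logical(is_driver),
                   stringsAsFactors = FALSE)
  validate_variants(df)
}

#' An empty variant table with the canonical columns
#' @return Zero-row data.frame in the layout of [variant_table()].
#' @export
empty_variant_table <- function() {
  data.frame(sample_id = character(), gene = character(), chrom = character(),
             pos = integer(), ref = character(), alt = character(),
             hgvs_p = character(), consequence = character(), af = numeric(),
             depth = integer(), popfreq_1kg = numeric(),
             popfreq_esp6500 = numeric(), is_driver = logical(),
             stringsAsFactors = FALSE)
}

#' Validate a variant table
#'
#' Checks column presence, the closed consequence vocabulary, coordinate and
#' frequency ranges, and the amplification convention (empty `ref`/`alt`).
#'
#' @param variants data frame in the layout of [variant_table()].
#' @return The validated data frame, invisibly unchanged.
#' @export
validate_variants <- function(variants) {
  if (!is.data.frame(variants)) stopf("'variants' must be a data.frame")
  missing_cols <- setdiff(variant_columns(), names(variants))
  if (length(missing_cols))
    stopf("variant table is missing required column(s): %s",
          paste(missing_cols, collapse = ", "))
  if (nrow(variants) == 0L) return(variants)
  bad <- which(!variants$consequence %in% variant_consequences())
  if (length(bad))
    stopf("unknown consequence class in row(s) %s: %s",
          paste(bad, collapse = ", "),
          paste(unique(variants$consequence[bad]), collapse = ", "))
  if (any(variants$pos < 1L, na.rm = TRUE)) stopf("'pos' must be >= 1 (1-based)")
  if (any(variants$af < 0 | variants$af > 1, na.rm = TRUE))
    stopf("'af' must lie in [0, 1]")
  if (any(variants$depth < 0L, na.rm = TRUE)) stopf("'depth' must be >= 0")
  amp <- variants$consequence == "amplification"
  if (any(amp & (nzchar(variants$ref) | nzchar(variants$alt))))
    stopf("amplification records must have empty ref/alt")
  variants
}

#' Filter profiles for the somatic variant cascade
#'
#' Two profiles reconcile the assay's reporting rules with TMB counting:
#' the `reporting` profile keeps stopgain, missense, frameshift and in-frame
#' indel/insertion alterations (plus gene amplification, which has no allele
#' fraction and is exempted from the AF rule); the `tmb` profile additionally
#' keeps silent and stoploss SNVs, because the burden statistic counts both
#' synonymous and nonsynonymous coding mutations, and drops amplification,
#' which is not a small coding mutation.
#'
#' Variants observed at `> max_pop_freq` in any population database are
#' removed as likely germline/common polymorphisms under both profiles.
#'
#' @param purpose `"reporting"` or `"tmb"`.
#' @param min_af minimum somatic allele fraction retained (inclusive;
#'   default 0.05).
#' @param max_pop_freq maximum tolerated population frequency (exclusive
#'   removal above; default 0.015), applied to the maximum across databases.
#' @param retained_consequences optional override of the consequence class
#'   whitelist.
#' @return A list of class `filter_profile`.
#' @export
filter_profile <- function(purpose = c("reporting", "tmb"),
                           min_af = 0.05, max_pop_freq = 0.015,
                           retained_consequences = NULL) {
  purpose <- match.arg(purpose)
  if (is.null(retained_consequences)) {
    retained_consequences <- switch(purpose,
      reporting = c("stopgain", "missense", "frameshift_indel",
                    "inframe_indel", "inframe_insertion_dup",
                    "amplification"),
      tmb = c("stopgain", "stoploss", "missense", "silent",
              "frameshift_indel", "inframe_indel", "inframe_insertion_dup"))
  }
  if (!is_probability(min_af)) stopf("'min_af' must be in [0, 1]")
  if (!is_probability(max_pop_freq)) stopf("'max_pop_freq' must be in [0, 1]")
  if (!length(retained_consequences))
    stopf("'retained_consequences' must be non-empty")
  unknown <- setdiff(retained_consequences, variant_consequences())
  if (length(unknown))
    stopf("unknown consequence class(es) in profile: %s",
          paste(unknown, collapse = ", "))
  structure(list(purpose = purpose, min_af = min_af,
                 max_pop_freq = max_pop_freq,
                 retained_consequences = retained_consequences),
            class = "filter_profile")
}

#' Apply the somatic filter cascade
#'
#' A call survives iff its allele fraction is at least `min_af`, its maximum
#' population frequency across databases does not exceed `max_pop_freq`, and
#' its consequence class is on the profile's whitelist. Under the
#' `reporting` profile, amplification records are exempt from the AF rule
#' (copy-number events carry no meaningful allele fraction). Row order is
#' preserved and the operation is idempotent.
#'
#' @param variants validated variant table.
#' @param profile a [filter_profile()].
#' @return The surviving subset of `variants`, original order preserved.
#' @export
filter_variants <- function(variants, profile = filter_profile("reporting")) {
  validate_variants(variants)
  if (!inherits(profile, "filter_profile")) stopf("'profile' must be a filter_profile")
  if (nrow(variants) == 0L) return(variants)
  max_pop <- pmax(ifelse(is.na(variants$popfreq_1kg), 0, variants$popfreq_1kg),
                  ifelse(is.na(variants$popfreq_esp6500), 0,
                         variants$popfreq_esp6500))
  af_ok <- variants$af >= profile$min_af
  if (identical(profile$purpose, "reporting"))
    af_ok <- af_ok | variants$consequence == "amplification"
  keep <- af_ok &
    max_pop <= profile$max_pop_freq &
    variants$consequence %in% profile$retained_consequences
  variants[keep, , drop = FALSE]
}

#' Read annotated somatic variants
#'
#' Reads either the pipeline's MAF-like TSV layout (see [variant_columns()])
#' or an annotated VCF whose INFO fields carry the consequence class and
#' population frequencies under configurable keys.
#'
#' @param path file path.
#' @param format `"maf-tsv"` or `"vcf"`.
#' @param info_keys for VCF input, named list mapping the pipeline fields
#'   `gene`, `hgvs_p`, `consequence`, `af`, `depth`, `popfreq_1kg`,
#'   `popfreq_esp6500`, `is_driver` to INFO keys.
#' @param sample_id for VCF input, sample identifier to assign; defaults to
#'   the first genotype column name, or the file stem when none exists.
#' @return A validated variant table.
#' @export
read_variants <- function(path, format = c("maf-tsv", "vcf"),
                          info_keys = default_vcf_info_keys(),
                          sample_id = NULL) {
  format <- match.arg(format)
  if (format == "maf-tsv") {
    df <- read_tsv(path, colClasses = "character")
    missing_cols <- setdiff(variant_columns(), names(df))
    if (length(missing_cols))
      stopf("%s: missing required column(s): %s", path,
            paste(missing_cols, collapse = ", "))
    df <- df[, variant_columns(), drop = FALSE]
    for (col in c("hgvs_p", "ref", "alt", "chrom", "gene", "sample_id"))
      df[[col]] <- ifelse(is.na(df[[col]]), "", df[[col]])
    df$pos <- suppressWarnings(as.integer(df$pos))
    df$depth <- suppressWarnings(as.integer(df$depth))
    df$af <- suppressWarnings(as.numeric(df$af))
    df$popfreq_1kg <- suppressWarnings(as.numeric(df$popfreq_1kg))
    df$popfreq_esp6500 <- suppressWarnings(as.numeric(df$popfreq_esp6500))
    df$is_driver <- as.logical(df$is_driver)
    bad <- which(!is.finite(df$af) | is.na(df$pos))
    if (length(bad))
      stopf("%s: malformed row(s) at line(s) %s (non-numeric af or pos)",
            path, paste(bad + 1L, collapse = ", "))
    return(validate_variants(df))
  }
  read_variants_vcf(path, info_keys = info_keys, sample_id = sample_id)
}

#' Default INFO key mapping for annotated VCF input
#' @return Named list of INFO keys.
#' @export
default_vcf_info_keys <- function() {
  list(gene = "GENE", hgvs_p = "HGVSP", consequence = "CONSEQ",
       af = "AF", depth = "DP", popfreq_1kg = "AF_1KG",
       popfreq_esp6500 = "AF_ESP", is_driver = "DRIVER")
}

read_variants_vcf <- function(path, info_keys, sample_id = NULL) {
  if (!file.exists(path)) stopf("input file not found: %s", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  info_of <- function(key) vcfR::extract.info(v, element = key)
  required <- c("consequence", "af")
  for (field in required) {
    vals <- info_of(info_keys[[field]])
    if (all(is.na(vals)))
      stopf("%s: VCF INFO lacks required annotation field '%s' (key '%s')",
            path, field, info_keys[[field]])
  }
  popfreq <- function(field) {
    vals <- suppressWarnings(as.numeric(info_of(info_keys[[field]])))
    ifelse(is.na(vals), 0, vals)
  }
  if (is.null(sample_id)) {
    gt_cols <- colnames(v@gt)
    sample_id <- if (!is.null(gt_cols) && length(gt_cols) > 1L) gt_cols[2L]
                 else sub("\\.vcf$", "", basename(path))
  }
  n <- nrow(fix)
  variant_table(
    sample_id = rep(sample_id, n),
    gene = ifelse(is.na(info_of(info_keys$gene)), "", info_of(info_keys$gene)),
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = ifelse(is.na(fix$REF), "", fix$REF),
    alt = ifelse(is.na(fix$ALT), "", fix$ALT),
    hgvs_p = ifelse(is.na(info_of(info_keys$hgvs_p)), "",
                    info_of(info_keys$hgvs_p)),
    consequence = info_of(info_keys$consequence),
    af = suppressWarnings(as.numeric(info_of(info_keys$af))),
    depth = {
      d <- suppressWarnings(as.integer(info_of(info_keys$depth)))
      ifelse(is.na(d), 0L, d)
    },
    popfreq_1kg = popfreq("popfreq_1kg"),
    popfreq_esp6500 = popfreq("popfreq_esp6500"),
    is_driver = {
      dr <- info_of(info_keys$is_driver)
      !is.na(dr) & dr %in% c("1", "TRUE", "T", "yes")
    })
}

#' Write a variant table to MAF-like TSV
#'
#' `read_variants(write_variants(x))` is the identity on the in-memory
#' representation.
#'
#' @param variants validated variant table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_variants <- function(variants, path) {
  validate_variants(variants)
  write_tsv(variants, path)
}
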