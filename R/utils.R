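# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Scalar checks used by the public constructors/validators.
is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

is_probability <- function(x) is_scalar_number(x) && x >= 0 && x <= 1

assert_scalar_number <- function(x, name) {
  if (!is_scalar_number(x)) stopf("'%s' must be a single finite number", name)
  invisible(x)
}

assert_probability <- function(x, name) {
  if (!is_probability(x)) stopf("'%s' must be a probability in [0, 1]", name)
  invisible(x)
}

# All sub-generators derive their streams from one integer seed by fixed
# offsets, so callers never have to book-keep per-stage seeds. Offsets are
# kept small so seed + offset stays well inside 32-bit integer range.
child_seed <- function(seed, offset) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  as.integer((as.numeric(seed) + offset) %% .Machine$integer.max)
}

# Stable hash of an arbitrary config-like object, for provenance stamping.
config_hash <- function(x) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp), add = TRUE)
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                              null = "null", force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

read_tsv <- function(path, ...) {
  if (!file.exists(path)) stopf("input file not found: %s", path)
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}

write_tsv <- function(df, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
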