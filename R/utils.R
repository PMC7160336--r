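`%||%` <- function(x, y) if (is.null(x)) y else x

#' Derive a reproducible sub-seed from a base seed and a string key
#'
#' Hierarchical seeding: every sample (or other named unit) gets its own
#' random stream derived from the cohort seed and its identity string, so
#' adding or removing one sample never perturbs the draws of the others.
#' The hash is a 31-bit polynomial rolling hash, platform independent.
#'
#' @param base integer base seed.
#' @param key character scalar naming the unit.
#' @return an integer in `[0, 2^31 - 2]` suitable for [set.seed()].
#' @export
#' @examples
#' derive_seed(42, "MS01_CD8_naive_t0")
derive_seed <- function(base, key) {
  stopifnot(is.numeric(base), length(base) == 1, is.character(key), length(key) == 1)
  m <- 2147483647 # 2^31 - 1, prime
  h <- as.numeric(base) %% m
  for (b in utf8ToInt(key)) h <- (h * 31 + b) %% m
  as.integer(h)
}

# message() wrapper used for per-file filter counts and skipped pairs;
# always goes to stderr and never to captured stdout tables.
log_note <- function(fmt, ...) message(sprintf(fmt, ...))

is_valid_cdr3 <- function(x) {
  !is.na(x) & nzchar(x) & grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", x)
}

#' Strip allele suffixes from gene labels
#'
#' Reduces e.g. `"TRBV5-1*01"` to `"TRBV5-1"`. The clone key is gene-level,
#' and curated databases mix allele conventions.
#'
#' @param x character vector of V or J gene labels.
#' @return character vector without `*`-delimited allele suffixes.
#' @export
strip_allele <- function(x) sub("\\*.*$", "", trimws(x))

clone_key <- function(v_gene, j_gene, cdr3_aa) {
  paste(v_gene, j_gene, cdr3_aa, sep = "|")
}

check_square_symmetric <- function(m, what = "matrix") {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    stop(sprintf("%s must be a square matrix", what), call. = FALSE)
  }
  if (!isTRUE(all.equal(m, t(m), tolerance = 1e-8, check.attributes = FALSE))) {
    stop(sprintf("%s must be symmetric", what), call. = FALSE)
  }
  invisible(TRUE)
}

write_tsv_file <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_csv_file <- function(df, path, row_names = FALSE) {
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = row_names,
                     col.names = if (row_names) NA else TRUE)
  invisible(path)
}
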