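#' Read a clone table
#'
#' Parses one sample's clonotype table into a normalized clone data.frame.
#' The canonical dialect is the AIRR Rearrangement TSV (columns `v_call`,
#' `j_call`, `junction_aa`, `duplicate_count`); a permissive fallback dialect
#' with a configurable column mapping covers vendor-style exports. Rows with
#' an empty or invalid CDR3 (characters outside the 20 one-letter codes,
#' e.g. stop `*` or frameshift `_`) or a non-positive count are dropped, and
#' the number of dropped rows is reported on standard error. Duplicate clone
#' keys (after allele stripping) are merged by summing counts; frequencies
#' are always recomputed as `count / sum(count)`.
#'
#' @param path path to a tab-separated clone table.
#' @param dialect `"airr"` or `"irepertoire_like"`.
#' @param col_map for `"irepertoire_like"`, a named character vector mapping
#'   the internal fields `v_gene`, `j_gene`, `cdr3_aa`, `count` to the file's
#'   column names. Default `c(v_gene = "vGeneName", j_gene = "jGeneName",
#'   cdr3_aa = "aminoAcid", count = "count")`.
#' @return a clone data.frame with columns `v_gene`, `j_gene`, `cdr3_aa`,
#'   `count`, `frequency`, `v_call`, `j_call`.
#' @export
read_clone_table <- function(path, dialect = c("airr", "irepertoire_like"),
                             col_map = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("clone table not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           check.names = FALSE)

  map <- switch(dialect,
    airr = c(v_gene = "v_call", j_gene = "j_call",
             cdr3_aa = "junction_aa", count = "duplicate_count"),
    irepertoire_like = {
      default <- c(v_gene = "vGeneName", j_gene = "jGeneName",
                   cdr3_aa = "aminoAcid", count = "count")
      if (!is.null(col_map)) default[names(col_map)] <- col_map
      default
    }
  )
  missing <- map[!(map %in% names(raw))]
  if (length(missing)) {
    stop(sprintf("clone table %s is missing required column '%s'",
                 basename(path), missing[[1]]), call. = FALSE)
  }

  df <- data.frame(
    v_call = as.character(raw[[map[["v_gene"]]]]),
    j_call = as.character(raw[[map[["j_gene"]]]]),
    cdr3_aa = toupper(trimws(as.character(raw[[map[["cdr3_aa"]]]]))),
    count = suppressWarnings(as.numeric(raw[[map[["count"]]]])),
    stringsAsFactors = FALSE
  )
  keep <- is_valid_cdr3(df$cdr3_aa) & !is.na(df$count) & df$count > 0
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    log_note("read_clone_table: dropped %d of %d rows (invalid CDR3 or non-positive count) in %s",
             n_dropped, nrow(df), basename(path))
  }
  df <- df[keep, , drop = FALSE]
  if (nrow(df) == 0) {
    stop(sprintf("clone table %s contains no valid clones after filtering",
                 basename(path)), call. = FALSE)
  }
  df$v_gene <- df$v_call
  df$j_gene <- df$j_call
  normalize_clones(df, recompute_frequency = TRUE)
}

#' Write a clone table in AIRR Rearrangement layout
#'
#' Emits the columns `v_call`, `j_call`, `junction_aa`, `duplicate_count`,
#' i.e. exactly the dialect [read_clone_table()] treats as canonical, so that
#' write-then-read round-trips clone keys and counts.
#'
#' @param x a `tcr_repertoire` or a clone data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_clone_table <- function(x, path) {
  clones <- if (inherits(x, "tcr_repertoire")) x$clones else x
  out <- data.frame(
    v_call = clones$v_call %||% clones$v_gene,
    j_call = clones$j_call %||% clones$j_gene,
    junction_aa = clones$cdr3_aa,
    duplicate_count = clones$count,
    stringsAsFactors = FALSE
  )
  write_tsv_file(out, path)
}

metadata_required_cols <- c(
  "sample_id", "patient_id", "treatment", "subpopulation",
  "timepoint", "hla_drb1_1501", "file_name"
)

#' Read and validate a cohort metadata table
#'
#' @param path TSV with one row per sample and columns `sample_id`,
#'   `patient_id`, `treatment`, `subpopulation`, `timepoint`,
#'   `hla_drb1_1501`, `file_name` and optionally `n_cells`.
#' @return validated metadata data.frame.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("metadata table not found: ", path, call. = FALSE)
  md <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  missing <- setdiff(metadata_required_cols, names(md))
  if (length(missing)) {
    stop("metadata is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(md$sample_id)) {
    stop("duplicate sample_id in metadata: ",
         paste(unique(md$sample_id[duplicated(md$sample_id)]), collapse = ", "),
         call. = FALSE)
  }
  check_level <- function(col, levels) {
    bad <- setdiff(unique(md[[col]]), levels)
    if (length(bad)) {
      stop(sprintf("invalid %s value(s): %s (allowed: %s)", col,
                   paste(bad, collapse = ", "), paste(levels, collapse = ", ")),
           call. = FALSE)
    }
  }
  check_level("treatment", TREATMENTS)
  check_level("subpopulation", SUBPOPULATIONS)
  check_level("timepoint", TIMEPOINTS)
  check_level("hla_drb1_1501", HLA_STATUS)
  if (!("n_cells" %in% names(md))) md$n_cells <- NA_real_
  md
}

#' Load a cohort of repertoires from disk
#'
#' Resolves every metadata row to a clone table under `clone_dir` and parses
#' it into a [repertoire()]. The loader makes no completeness assumption:
#' patients may contribute any subset of subpopulation/timepoint samples.
#'
#' @param metadata_path path to the metadata TSV (see [read_metadata()]).
#' @param clone_dir directory containing the per-sample clone tables.
#' @param dialect clone-table dialect passed to [read_clone_table()].
#' @return a `tcr_cohort`: a named list of repertoires plus the metadata.
#' @export
load_cohort <- function(metadata_path, clone_dir, dialect = "airr") {
  md <- read_metadata(metadata_path)
  paths <- file.path(clone_dir, md$file_name)
  missing <- !file.exists(paths)
  if (any(missing)) {
    stop("clone table missing for sample(s): ",
         paste(md$sample_id[missing], collapse = ", "), call. = FALSE)
  }
  reps <- lapply(seq_len(nrow(md)), function(i) {
    repertoire(
      read_clone_table(paths[i], dialect = dialect),
      sample_id = md$sample_id[i], patient_id = md$patient_id[i],
      treatment = md$treatment[i], subpopulation = md$subpopulation[i],
      timepoint = md$timepoint[i], hla_drb1_1501 = md$hla_drb1_1501[i],
      n_cells = md$n_cells[i]
    )
  })
  names(reps) <- md$sample_id
  as_cohort(reps)
}

#' Bundle repertoires into a cohort
#'
#' @param repertoires list of `tcr_repertoire` objects with unique sample ids.
#' @return a `tcr_cohort` object: `$repertoires` (named list) and `$metadata`
#'   (one row per sample).
#' @export
as_cohort <- function(repertoires) {
  stopifnot(length(repertoires) > 0,
            all(vapply(repertoires, inherits, logical(1), "tcr_repertoire")))
  ids <- vapply(repertoires, `[[`, character(1), "sample_id")
  if (anyDuplicated(ids)) {
    stop("duplicate sample_id in cohort: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  names(repertoires) <- ids
  md <- do.call(rbind, lapply(repertoires, function(r) {
    data.frame(sample_id = r$sample_id, patient_id = r$patient_id,
               treatment = r$treatment, subpopulation = r$subpopulation,
               timepoint = r$timepoint, hla_drb1_1501 = r$hla_drb1_1501,
               n_cells = r$n_cells, stringsAsFactors = FALSE)
  }))
  rownames(md) <- NULL
  structure(list(repertoires = repertoires, metadata = md), class = "tcr_cohort")
}

#' @export
print.tcr_cohort <- function(x, ...) {
  md <- x$metadata
  cat(sprintf(
    "<tcr_cohort> %d samples, %d patients (%s)\n  timepoints: %s; subpopulations: %s\n",
    nrow(md), length(unique(md$patient_id)),
    paste(sprintf("%s: %d", names(table(md$treatment)), table(md$treatment)), collapse = ", "),
    paste(sort(unique(md$timepoint)), collapse = ", "),
    paste(sort(unique(md$subpopulation)), collapse = ", ")
  ))
  invisible(x)
}

#' Per-sample summary statistics for a whole cohort
#'
#' @param cohort a `tcr_cohort`.
#' @return data.frame with one row per sample: metadata plus `n_reads`,
#'   `n_clones`, `shannon_evenness`.
#' @export
cohort_stats <- function(cohort) {
  stopifnot(inherits(cohort, "tcr_cohort"))
  stats <- do.call(rbind, lapply(cohort$repertoires, summarize_repertoire))
  rownames(stats) <- NULL
  merge(cohort$metadata[, setdiff(names(cohort$metadata), "n_cells")], stats,
        by = "sample_id", sort = FALSE)
}
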