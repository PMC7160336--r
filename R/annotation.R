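#' Load a curated CDR3 database
#'
#' Supported export layouts: McPAS-TCR (CSV; CDR3 column `CDR3.beta.aa`,
#' category column `Pathology`), VDJdb (TSV; columns `cdr3` and
#' `antigen.species`, with TRB-chain filtering when a `gene` column is
#' present), and a bare one-CDR3-per-line list for literature datasets.
#' Column names can be remapped via `col_map` for other snapshots. CDR3s are
#' uppercased and whitespace-stripped; records with characters outside the
#' amino-acid alphabet are dropped and counted on standard error. Duplicate
#' records (same CDR3/V/J) are collapsed, preserving the union of their
#' category labels (semicolon-separated). Database snapshots are
#' user-supplied files; overlap counts always depend on the snapshot
#' version.
#'
#' @param path path to the database export.
#' @param dialect `"mcpas"`, `"vdjdb"` or `"cdr3_list"`.
#' @param col_map optional named character vector overriding the dialect's
#'   column names for the internal fields `cdr3_aa`, `category`, `v_gene`,
#'   `j_gene`.
#' @param category category label applied to every record of a
#'   `"cdr3_list"` file (e.g. the literature set's disease).
#' @param source_label value stored in the `source` column; defaults to the
#'   dialect name.
#' @return data.frame of database records: `cdr3_aa`, `v_gene`, `j_gene`,
#'   `category` (semicolon-separated union), `source`.
#' @export
load_db <- function(path, dialect = c("mcpas", "vdjdb", "cdr3_list"),
                    col_map = NULL, category = NA_character_,
                    source_label = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("database file not found: ", path, call. = FALSE)
  source_label <- source_label %||% dialect

  if (dialect == "cdr3_list") {
    cdr3 <- readLines(path, warn = FALSE)
    df <- data.frame(cdr3_aa = cdr3, v_gene = NA_character_,
                     j_gene = NA_character_, category = category,
                     stringsAsFactors = FALSE)
  } else {
    map <- switch(dialect,
      mcpas = c(cdr3_aa = "CDR3.beta.aa", category = "Pathology",
                v_gene = "TRBV", j_gene = "TRBJ"),
      vdjdb = c(cdr3_aa = "cdr3", category = "antigen.species",
                v_gene = "v.segm", j_gene = "j.segm")
    )
    if (!is.null(col_map)) map[names(col_map)] <- col_map
    raw <- utils::read.delim(path, sep = if (dialect == "mcpas") "," else "\t",
                             stringsAsFactors = FALSE, check.names = FALSE)
    if (dialect == "vdjdb" && "gene" %in% names(raw)) {
      raw <- raw[raw$gene == "TRB", , drop = FALSE]
    }
    if (!(map[["cdr3_aa"]] %in% names(raw))) {
      stop(sprintf("database %s is missing CDR3 column '%s'",
                   basename(path), map[["cdr3_aa"]]), call. = FALSE)
    }
    pick <- function(field) {
      col <- map[[field]]
      if (col %in% names(raw)) as.character(raw[[col]]) else NA_character_
    }
    df <- data.frame(cdr3_aa = pick("cdr3_aa"), v_gene = pick("v_gene"),
                     j_gene = pick("j_gene"), category = pick("category"),
                     stringsAsFactors = FALSE)
  }

  df$cdr3_aa <- toupper(gsub("\\s", "", df$cdr3_aa))
  df$v_gene <- strip_allele(df$v_gene)
  df$j_gene <- strip_allele(df$j_gene)
  keep <- is_valid_cdr3(df$cdr3_aa)
  if (any(!keep)) {
    log_note("load_db: dropped %d of %d records with invalid CDR3 in %s",
             sum(!keep), nrow(df), basename(path))
  }
  df <- df[keep, , drop = FALSE]
  if (nrow(df) == 0) stop("no valid database records in ", basename(path), call. = FALSE)

  id <- paste(df$cdr3_aa, df$v_gene, df$j_gene, sep = "|")
  cats <- tapply(df$category, id, function(x) {
    x <- sort(unique(x[!is.na(x) & nzchar(x)]))
    if (length(x) == 0) NA_character_ else paste(x, collapse = ";")
  })
  out <- df[!duplicated(id), c("cdr3_aa", "v_gene", "j_gene")]
  out$category <- as.character(cats[id[!duplicated(id)]])
  out$source <- source_label
  out <- out[order(out$cdr3_aa, out$v_gene, out$j_gene), ]
  rownames(out) <- NULL
  out
}

db_categories <- function(x) strsplit(ifelse(is.na(x), "", x), ";", fixed = TRUE)

#' Overlap of a repertoire with a CDR3 database
#'
#' Matching is exact string comparison after case normalization, on the CDR3
#' alone by default (`match_on = "cdr3"`, the reported "CDR3 sequence
#' overlap") or on the full V-CDR3-J key. `n_overlap` counts distinct
#' repertoire clones matched; the percentage is relative to the sample's
#' species richness. A clone matching database records of several categories
#' is tallied once per category.
#'
#' @param r a `tcr_repertoire`.
#' @param db a [load_db()] table.
#' @param match_on `"cdr3"` or `"v_cdr3_j"`.
#' @return an `overlap_summary` list: `$summary` (one-row data.frame
#'   `sample_id`, `source`, `n_overlap`, `n_clones`, `pct_overlap`) and
#'   `$per_category` (data.frame `category`, `n_clones`).
#' @export
match_repertoire <- function(r, db, match_on = c("cdr3", "v_cdr3_j")) {
  stopifnot(inherits(r, "tcr_repertoire"), is.data.frame(db))
  match_on <- match.arg(match_on)
  if (nrow(r$clones) == 0) stop("empty repertoire", call. = FALSE)

  if (match_on == "cdr3") {
    clone_id <- r$clones$cdr3_aa
    db_id <- db$cdr3_aa
  } else {
    clone_id <- repertoire_keys(r)
    db_id <- clone_key(db$v_gene, db$j_gene, db$cdr3_aa)
  }
  matched <- clone_id %in% db_id
  n_overlap <- sum(matched)

  cat_by_id <- tapply(db$category, db_id, function(x) {
    unique(unlist(db_categories(x)))
  })
  matched_ids <- unique(clone_id[matched])
  per_cat <- table(unlist(cat_by_id[matched_ids]))
  # count clones (not distinct ids) per category
  if (length(per_cat)) {
    id_count <- table(clone_id[matched])
    counts <- vapply(names(sort(per_cat, decreasing = TRUE)), function(cat) {
      ids <- matched_ids[vapply(cat_by_id[matched_ids],
                                function(cs) cat %in% cs, logical(1))]
      as.integer(sum(id_count[ids]))
    }, integer(1))
    per_category <- data.frame(category = names(counts), n_clones = as.integer(counts),
                               stringsAsFactors = FALSE)
    per_category <- per_category[order(-per_category$n_clones, per_category$category), ]
    rownames(per_category) <- NULL
  } else {
    per_category <- data.frame(category = character(), n_clones = integer(),
                               stringsAsFactors = FALSE)
  }

  structure(
    list(
      summary = data.frame(
        sample_id = r$sample_id,
        source = paste(unique(db$source), collapse = ","),
        n_overlap = n_overlap,
        n_clones = nrow(r$clones),
        pct_overlap = 100 * n_overlap / nrow(r$clones),
        stringsAsFactors = FALSE
      ),
      per_category = per_category
    ),
    class = "overlap_summary"
  )
}

#' Per-sample, per-category database overlap for a cohort
#'
#' Long table of matched-clone counts per disease/antigen category, ready
#' for group comparison across treatments and timepoints. Samples with no
#' match in a category carry an explicit zero.
#'
#' @param cohort a `tcr_cohort`.
#' @param db a [load_db()] table.
#' @param match_on `"cdr3"` or `"v_cdr3_j"`.
#' @return data.frame: `sample_id`, `treatment`, `subpopulation`,
#'   `timepoint`, `source`, `category`, `n`.
#' @export
overlap_by_category <- function(cohort, db, match_on = "cdr3") {
  stopifnot(inherits(cohort, "tcr_cohort"))
  all_categories <- sort(unique(unlist(db_categories(db$category))))
  if (length(all_categories) == 0) all_categories <- NA_character_
  rows <- lapply(cohort$repertoires, function(r) {
    ov <- match_repertoire(r, db, match_on = match_on)
    n <- stats::setNames(rep(0L, length(all_categories)), all_categories)
    if (nrow(ov$per_category)) {
      hit <- ov$per_category$category
      n[hit] <- ov$per_category$n_clones
    }
    data.frame(sample_id = r$sample_id, treatment = r$treatment,
               subpopulation = r$subpopulation, timepoint = r$timepoint,
               source = ov$summary$source, category = all_categories,
               n = as.integer(n), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
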