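#' Clonal persistence between two repertoires
#'
#' Clones are compared by their V-J-CDR3(a.a.) key; persistence is the
#' absolute number of shared clones scaled by the arithmetic mean of the two
#' repertoire sizes, reported as a percentage:
#' `100 * |A intersect B| / mean(|A|, |B|)`. Symmetric in its arguments;
#' frequencies play no role (the measure counts clones).
#'
#' @param a,b `tcr_repertoire` objects.
#' @return one-row data.frame: `sample_a`, `sample_b`, `n_shared`, `size_a`,
#'   `size_b`, `persistence_pct` (in `[0, 100]`).
#' @export
#' @examples
#' # |A| = 10, |B| = 20, 3 shared -> 100 * 3 / 15 = 20
clonal_persistence <- function(a, b) {
  stopifnot(inherits(a, "tcr_repertoire"), inherits(b, "tcr_repertoire"))
  ka <- repertoire_keys(a)
  kb <- repertoire_keys(b)
  if (length(ka) == 0 || length(kb) == 0) {
    stop("clonal persistence is undefined for an empty repertoire", call. = FALSE)
  }
  n_shared <- length(intersect(ka, kb))
  data.frame(
    sample_a = a$sample_id, sample_b = b$sample_id,
    n_shared = n_shared, size_a = length(ka), size_b = length(kb),
    persistence_pct = 100 * n_shared / mean(c(length(ka), length(kb))),
    stringsAsFactors = FALSE
  )
}

#' Per-patient t0 vs t24 persistence tables
#'
#' For each patient, pairs every t0 repertoire with every t24 repertoire
#' (`pairing = "all_subpopulations"`, the per-patient table layout) or only
#' repertoires of the same subpopulation (`"matched_subpopulation"`).
#' Patients missing one of the two timepoints contribute no rows and are
#' reported on standard error.
#'
#' @param cohort a `tcr_cohort`.
#' @param pairing pairing rule across subpopulations.
#' @return long data.frame: `patient_id`, `treatment`, `subpop_a` (t0 side),
#'   `subpop_b` (t24 side), plus the [clonal_persistence()] columns.
#' @export
persistence_table <- function(cohort,
                              pairing = c("all_subpopulations",
                                          "matched_subpopulation")) {
  stopifnot(inherits(cohort, "tcr_cohort"))
  pairing <- match.arg(pairing)
  md <- cohort$metadata
  rows <- list()
  for (pid in unique(md$patient_id)) {
    s0 <- md[md$patient_id == pid & md$timepoint == "t0", ]
    s24 <- md[md$patient_id == pid & md$timepoint == "t24", ]
    if (nrow(s0) == 0 || nrow(s24) == 0) {
      log_note("persistence_table: patient %s lacks a timepoint; skipped", pid)
      next
    }
    for (i in seq_len(nrow(s0))) {
      for (j in seq_len(nrow(s24))) {
        if (pairing == "matched_subpopulation" &&
            s0$subpopulation[i] != s24$subpopulation[j]) next
        res <- clonal_persistence(cohort$repertoires[[s0$sample_id[i]]],
                                  cohort$repertoires[[s24$sample_id[j]]])
        rows[[length(rows) + 1L]] <- cbind(
          data.frame(patient_id = pid, treatment = s0$treatment[i],
                     subpop_a = s0$subpopulation[i],
                     subpop_b = s24$subpopulation[j],
                     stringsAsFactors = FALSE),
          res
        )
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(patient_id = character(), treatment = character(),
                      subpop_a = character(), subpop_b = character(),
                      sample_a = character(), sample_b = character(),
                      n_shared = integer(), size_a = integer(),
                      size_b = integer(), persistence_pct = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classify clones as private or public across a cohort
#'
#' A clone (V-J-CDR3 a.a.) is private when present in exactly one repertoire
#' and public when shared across at least two. The sharing unit is the
#' sample by default; `"patient"` counts distinct patients instead (a clone
#' seen in two samples of one patient is then still private).
#'
#' @param cohort a `tcr_cohort`.
#' @param sharing_unit `"sample"` or `"patient"`.
#' @return data.frame with one row per distinct clone key: `v_gene`,
#'   `j_gene`, `cdr3_aa`, `n_sharing` (distinct units carrying the clone),
#'   `publicity` (`"private"`/`"public"`), `sample_ids` (comma-separated).
#' @export
classify_publicity <- function(cohort, sharing_unit = c("sample", "patient")) {
  stopifnot(inherits(cohort, "tcr_cohort"))
  sharing_unit <- match.arg(sharing_unit)
  per_sample <- lapply(cohort$repertoires, function(r) {
    data.frame(key = repertoire_keys(r),
               v_gene = r$clones$v_gene, j_gene = r$clones$j_gene,
               cdr3_aa = r$clones$cdr3_aa,
               sample_id = r$sample_id, patient_id = r$patient_id,
               stringsAsFactors = FALSE)
  })
  occ <- do.call(rbind, per_sample)
  unit <- if (sharing_unit == "sample") occ$sample_id else occ$patient_id
  n_sharing <- tapply(unit, occ$key, function(u) length(unique(u)))
  sample_ids <- tapply(occ$sample_id, occ$key,
                       function(s) paste(sort(unique(s)), collapse = ","))
  first <- occ[!duplicated(occ$key), c("key", "v_gene", "j_gene", "cdr3_aa")]
  first <- first[order(first$key), ]
  out <- data.frame(
    v_gene = first$v_gene, j_gene = first$j_gene, cdr3_aa = first$cdr3_aa,
    n_sharing = as.integer(n_sharing[first$key]),
    sample_ids = as.character(sample_ids[first$key]),
    stringsAsFactors = FALSE
  )
  out$publicity <- ifelse(out$n_sharing >= 2, "public", "private")
  rownames(out) <- NULL
  out[, c("v_gene", "j_gene", "cdr3_aa", "n_sharing", "publicity", "sample_ids")]
}

#' Per-sample public-clone counts and percentages
#'
#' @param cohort a `tcr_cohort`.
#' @param publicity optional precomputed [classify_publicity()] table;
#'   computed at sample level when omitted.
#' @return data.frame per sample: metadata plus `n_clones`, `n_public` and
#'   `pct_public` (percentage of the sample's species richness).
#' @export
public_clone_stats <- function(cohort, publicity = NULL) {
  stopifnot(inherits(cohort, "tcr_cohort"))
  if (is.null(publicity)) publicity <- classify_publicity(cohort)
  public_keys <- with(publicity, clone_key(v_gene, j_gene, cdr3_aa)[publicity == "public"])
  stats <- do.call(rbind, lapply(cohort$repertoires, function(r) {
    keys <- repertoire_keys(r)
    n_pub <- sum(keys %in% public_keys)
    data.frame(sample_id = r$sample_id, n_clones = length(keys),
               n_public = n_pub, pct_public = 100 * n_pub / length(keys),
               stringsAsFactors = FALSE)
  }))
  rownames(stats) <- NULL
  merge(cohort$metadata, stats, by = "sample_id", sort = FALSE)
}

#' Highly shared clones and their presence matrix
#'
#' Clones shared by at least `min_samples` sharing units. The default of 11
#' encodes "shared among more than 10 samples". Also returns a binary
#' clone-by-sample presence matrix ready for heatmap export.
#'
#' @param cohort a `tcr_cohort`.
#' @param min_samples minimum number of sharing units (at least 2).
#' @param publicity optional precomputed [classify_publicity()] table.
#' @return list with `records` (the qualifying sharing records) and
#'   `presence` (0/1 integer matrix, clones x samples).
#' @export
highly_shared_clones <- function(cohort, min_samples = 11, publicity = NULL) {
  stopifnot(inherits(cohort, "tcr_cohort"), min_samples >= 2)
  if (is.null(publicity)) publicity <- classify_publicity(cohort)
  records <- publicity[publicity$n_sharing >= min_samples, , drop = FALSE]
  rownames(records) <- NULL
  samples <- cohort$metadata$sample_id
  presence <- matrix(0L, nrow = nrow(records), ncol = length(samples),
                     dimnames = list(with(records, clone_key(v_gene, j_gene, cdr3_aa)),
                                     samples))
  for (i in seq_len(nrow(records))) {
    present <- strsplit(records$sample_ids[i], ",", fixed = TRUE)[[1]]
    presence[i, intersect(present, samples)] <- 1L
  }
  list(records = records, presence = presence)
}
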