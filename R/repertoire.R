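#' Construct a TCR repertoire (one sequenced sample)
#'
#' A repertoire bundles a clone table with its sample metadata. A clone is a
#' unique V gene / J gene / CDR3 amino-acid combination with a read count and
#' a within-repertoire frequency. Duplicate clone keys are merged by summing
#' counts, and frequencies are (by default) recomputed from counts so that
#' they always sum to one.
#'
#' @param clones data.frame with columns `v_gene`, `j_gene`, `cdr3_aa`,
#'   `count`, and optionally `frequency`, `v_call`, `j_call`.
#' @param sample_id,patient_id sample and patient identifiers.
#' @param treatment `"AHSCT"` or `"NTZ"`.
#' @param subpopulation one of the sorted T-cell subpopulations in
#'   [SUBPOPULATIONS].
#' @param timepoint `"t0"` or `"t24"`.
#' @param hla_drb1_1501 HLA-DRB1*15:01 carrier status (`"pos"`, `"neg"`,
#'   `"unknown"`).
#' @param n_cells optional sorted-cell count for the sample.
#' @param recompute_frequency recompute `frequency` as `count / sum(count)`
#'   (the default and the only behaviour for file-loaded data). The synthetic
#'   generator's sampling-free mode passes `FALSE` to retain the exact
#'   generative frequencies.
#' @return an object of class `tcr_repertoire`.
#' @export
#' @examples
#' r <- repertoire(
#'   data.frame(v_gene = "TRBV5-1", j_gene = "TRBJ2-7",
#'              cdr3_aa = c("CASSLF", "CASSLY"), count = c(3, 1)),
#'   sample_id = "s1", patient_id = "p1", treatment = "NTZ",
#'   subpopulation = "CD8_naive", timepoint = "t0"
#' )
#' summarize_repertoire(r)
repertoire <- function(clones, sample_id, patient_id, treatment, subpopulation,
                       timepoint, hla_drb1_1501 = "unknown", n_cells = NULL,
                       recompute_frequency = TRUE) {
  treatment <- match.arg(treatment, TREATMENTS)
  subpopulation <- match.arg(subpopulation, SUBPOPULATIONS)
  timepoint <- match.arg(timepoint, TIMEPOINTS)
  hla_drb1_1501 <- match.arg(hla_drb1_1501, HLA_STATUS)

  clones <- normalize_clones(clones, recompute_frequency = recompute_frequency)

  structure(
    list(
      sample_id = as.character(sample_id),
      patient_id = as.character(patient_id),
      treatment = treatment,
      subpopulation = subpopulation,
      timepoint = timepoint,
      hla_drb1_1501 = hla_drb1_1501,
      n_cells = if (is.null(n_cells) || is.na(n_cells)) NA_real_ else as.numeric(n_cells),
      clones = clones
    ),
    class = "tcr_repertoire"
  )
}

# Validate and normalize a clone table: uppercase CDR3s, allele-stripped gene
# labels, duplicate keys merged by summing counts, frequencies from counts.
normalize_clones <- function(clones, recompute_frequency = TRUE) {
  required <- c("v_gene", "j_gene", "cdr3_aa", "count")
  missing <- setdiff(required, names(clones))
  if (length(missing)) {
    stop("clone table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(clones) == 0) stop("repertoire has no clones", call. = FALSE)

  clones$cdr3_aa <- toupper(trimws(clones$cdr3_aa))
  if (!all(is_valid_cdr3(clones$cdr3_aa))) {
    stop("invalid CDR3 amino-acid sequence(s) in clone table", call. = FALSE)
  }
  if (!("v_call" %in% names(clones))) clones$v_call <- clones$v_gene
  if (!("j_call" %in% names(clones))) clones$j_call <- clones$j_gene
  clones$v_gene <- strip_allele(clones$v_gene)
  clones$j_gene <- strip_allele(clones$j_gene)
  if (any(is.na(clones$count)) || any(clones$count <= 0)) {
    stop("clone counts must be positive", call. = FALSE)
  }

  key <- clone_key(clones$v_gene, clones$j_gene, clones$cdr3_aa)
  if (anyDuplicated(key)) {
    first <- !duplicated(key)
    merged <- clones[first, , drop = FALSE]
    merged$count <- as.vector(rowsum(clones$count, key)[key[first], ])
    if ("frequency" %in% names(clones)) {
      merged$frequency <- as.vector(rowsum(clones$frequency, key)[key[first], ])
    }
    clones <- merged
  }

  if (recompute_frequency || is.null(clones$frequency)) {
    clones$frequency <- clones$count / sum(clones$count)
  }
  if (any(clones$frequency <= 0)) stop("clone frequencies must be positive", call. = FALSE)
  if (abs(sum(clones$frequency) - 1) > 1e-9) {
    stop("clone frequencies must sum to 1 (tolerance 1e-9)", call. = FALSE)
  }
  rownames(clones) <- NULL
  clones[, c("v_gene", "j_gene", "cdr3_aa", "count", "frequency", "v_call", "j_call")]
}

#' @export
print.tcr_repertoire <- function(x, ...) {
  cat(sprintf(
    "<tcr_repertoire> %s  [%s %s %s %s]\n  %d clones, %s reads%s\n",
    x$sample_id, x$patient_id, x$treatment, x$subpopulation, x$timepoint,
    nrow(x$clones), format(sum(x$clones$count), big.mark = ","),
    if (is.na(x$n_cells)) "" else sprintf(", %d sorted cells", round(x$n_cells))
  ))
  invisible(x)
}

#' Clone keys of a repertoire
#'
#' The V-J-CDR3(a.a.) identity strings used for persistence and publicity.
#'
#' @param r a `tcr_repertoire`.
#' @return character vector, one key per clone.
#' @export
repertoire_keys <- function(r) {
  stopifnot(inherits(r, "tcr_repertoire"))
  clone_key(r$clones$v_gene, r$clones$j_gene, r$clones$cdr3_aa)
}

#' Per-sample repertoire summary statistics
#'
#' Total reads, species richness (number of unique clones) and Shannon
#' evenness, the quantities compared across subpopulations and treatments.
#'
#' @param r a `tcr_repertoire`.
#' @return a one-row data.frame with `sample_id`, `n_reads`, `n_clones`,
#'   `shannon_evenness`, `n_cells`.
#' @export
summarize_repertoire <- function(r) {
  stopifnot(inherits(r, "tcr_repertoire"))
  data.frame(
    sample_id = r$sample_id,
    n_reads = sum(r$clones$count),
    n_clones = nrow(r$clones),
    shannon_evenness = shannon_evenness(r$clones$frequency),
    n_cells = r$n_cells,
    stringsAsFactors = FALSE
  )
}

#' Pearson correlation between two repertoire summary statistics
#'
#' Used for the sequencing-saturation checks (e.g. reads vs sorted cells,
#' evenness vs clone number) across the samples of a cohort.
#'
#' @param stats data.frame of per-sample statistics (one row per sample).
#' @param x,y column names to correlate.
#' @return the Pearson product-moment correlation; `NA` (with a warning) when
#'   fewer than 3 complete pairs remain or either field has zero variance.
#' @export
correlate_stats <- function(stats, x, y) {
  stopifnot(is.data.frame(stats), x %in% names(stats), y %in% names(stats))
  xv <- as.numeric(stats[[x]])
  yv <- as.numeric(stats[[y]])
  ok <- stats::complete.cases(xv, yv)
  xv <- xv[ok]
  yv <- yv[ok]
  if (length(xv) < 3) {
    warning("fewer than 3 complete pairs; correlation undefined")
    return(NA_real_)
  }
  if (stats::sd(xv) == 0 || stats::sd(yv) == 0) {
    warning(sprintf("zero variance in '%s' or '%s'; correlation undefined", x, y))
    return(NA_real_)
  }
  stats::cor(xv, yv)
}

#' V or J gene usage of a repertoire
#'
#' @param r a `tcr_repertoire`.
#' @param segment `"V"` or `"J"`.
#' @param weighted if `TRUE`, genes are weighted by clone frequency mass;
#'   otherwise every clone counts once.
#' @return data.frame with `gene` and `frequency` (summing to 1), sorted by
#'   decreasing frequency then gene name.
#' @export
gene_usage <- function(r, segment = c("V", "J"), weighted = FALSE) {
  stopifnot(inherits(r, "tcr_repertoire"))
  segment <- match.arg(segment)
  gene <- if (segment == "V") r$clones$v_gene else r$clones$j_gene
  w <- if (weighted) r$clones$frequency else rep(1, nrow(r$clones))
  agg <- rowsum(w, gene)
  out <- data.frame(gene = rownames(agg), frequency = as.vector(agg) / sum(w),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$frequency, out$gene), ]
  rownames(out) <- NULL
  out
}
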