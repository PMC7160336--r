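#' Wilcoxon group comparison
#'
#' Two-sided Wilcoxon test of a per-sample statistic between two sample
#' groups: the unpaired rank-sum test for comparisons across different
#' patients (e.g. AHSCT vs NTZ within a subpopulation and timepoint) and
#' the paired signed-rank test for within-patient t0 vs t24 comparisons
#' (values matched by order). The p-value is exact (full enumeration) when
#' the combined sample size is at most 12 and there are no ties, and uses
#' the normal approximation with tie/continuity correction otherwise; the
#' method actually used is recorded. A paired comparison with all-zero
#' differences is flagged rather than tested.
#'
#' @param values_a,values_b numeric vectors (matched by order when paired).
#' @param test `"rank_sum_unpaired"` or `"signed_rank_paired"`.
#' @param statistic_name optional label for the compared statistic.
#' @return one-row data.frame: `statistic_name`, `test`, `n_a`, `n_b`,
#'   `statistic_value`, `p_value`, `method`, `note`.
#' @export
#' @examples
#' group_compare(c(1, 2, 3), c(10, 20, 30)) # exact two-sided p = 0.1
group_compare <- function(values_a, values_b,
                          test = c("rank_sum_unpaired", "signed_rank_paired"),
                          statistic_name = NA_character_) {
  test <- match.arg(test)
  a <- as.numeric(values_a)
  b <- as.numeric(values_b)
  if (length(a) == 0 || length(b) == 0) stop("both groups must be non-empty", call. = FALSE)

  row <- function(statistic, p, method, note = "") {
    data.frame(statistic_name = statistic_name, test = test,
               n_a = length(a), n_b = length(b),
               statistic_value = statistic, p_value = p,
               method = method, note = note, stringsAsFactors = FALSE)
  }

  if (test == "signed_rank_paired") {
    if (length(a) != length(b)) {
      stop("paired comparison requires equal-length, patient-matched groups",
           call. = FALSE)
    }
    d <- a - b
    if (all(d == 0)) {
      return(row(NA_real_, NA_real_, "degenerate", "all differences zero"))
    }
    ties <- anyDuplicated(abs(d[d != 0])) > 0 || any(d == 0)
    exact <- !ties && length(d) <= 12
    wt <- suppressWarnings(
      stats::wilcox.test(a, b, paired = TRUE, exact = exact, correct = TRUE)
    )
  } else {
    ties <- anyDuplicated(c(a, b)) > 0
    exact <- !ties && (length(a) + length(b)) <= 12
    wt <- suppressWarnings(
      stats::wilcox.test(a, b, paired = FALSE, exact = exact, correct = TRUE)
    )
  }
  row(unname(wt$statistic), wt$p.value,
      if (exact) "exact" else "normal_approximation_corrected")
}

#' Significance stars at the conventional thresholds
#'
#' @param p numeric vector of p-values.
#' @return `"**"` for p < 0.01, `"*"` for p < 0.05, otherwise `""`.
#' @export
significance_stars <- function(p) {
  ifelse(!is.na(p) & p < 0.01, "**", ifelse(!is.na(p) & p < 0.05, "*", ""))
}

#' Hierarchical clustering of a correlation or distance matrix
#'
#' Correlation-based distance (`d = 1 - r`, the default used for evenness
#' and k-mer profile heatmaps) or Euclidean distance between the matrix rows
#' (used for degree-distribution heatmaps). Agglomeration defaults to
#' average linkage. The merge tree and leaf order are deterministic for a
#' given input (ties resolved by [stats::hclust()]'s fixed rule).
#'
#' @param m square symmetric correlation matrix (for `"one_minus_pearson"`)
#'   or an observations-by-features matrix (for `"euclidean"`).
#' @param distance `"one_minus_pearson"` or `"euclidean"`.
#' @param linkage agglomeration method passed to [stats::hclust()].
#' @return a `repertoire_clustering` list: `distance`, `linkage`, `merge`,
#'   `height`, `order`, `labels` and the underlying `hclust` object.
#' @export
hierarchical_cluster <- function(m, distance = c("one_minus_pearson", "euclidean"),
                                 linkage = "average") {
  distance <- match.arg(distance)
  if (distance == "one_minus_pearson") {
    check_square_symmetric(m, "correlation matrix")
    d <- stats::as.dist(1 - m)
  } else {
    d <- stats::dist(m, method = "euclidean")
  }
  hc <- stats::hclust(d, method = linkage)
  structure(
    list(distance = distance, linkage = linkage, merge = hc$merge,
         height = hc$height, order = hc$order, labels = hc$labels, hclust = hc),
    class = "repertoire_clustering"
  )
}

#' @export
print.repertoire_clustering <- function(x, ...) {
  cat(sprintf("<repertoire_clustering> %d leaves, %s linkage on %s distance\n",
              length(x$order), x$linkage, x$distance))
  invisible(x)
}
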