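check_frequencies <- function(f) {
  if (!is.numeric(f) || length(f) == 0) {
    stop("frequencies must be a non-empty numeric vector", call. = FALSE)
  }
  if (any(is.na(f)) || any(f <= 0)) {
    stop("frequencies must be positive", call. = FALSE)
  }
  if (abs(sum(f) - 1) > 1e-9) {
    stop("frequencies must sum to 1 (tolerance 1e-9)", call. = FALSE)
  }
  invisible(f)
}

as_frequencies <- function(x) {
  if (inherits(x, "tcr_repertoire")) x$clones$frequency else x
}

#' Shannon entropy of a clone-frequency vector
#'
#' `H = -sum(f_i * log(f_i))` with the natural logarithm (the evenness
#' definition exponentiates with `exp`, so the base must cancel).
#'
#' @param frequencies positive frequencies summing to 1, or a
#'   `tcr_repertoire`.
#' @return entropy in nats; 0 for a single-clone repertoire.
#' @export
#' @examples
#' shannon_entropy(c(0.5, 0.5)) # log(2)
shannon_entropy <- function(frequencies) {
  f <- check_frequencies(as_frequencies(frequencies))
  -sum(f * log(f))
}

#' Shannon evenness of a repertoire
#'
#' The quotient of the exponential of the Shannon entropy and the species
#' richness SR (number of unique clones): `exp(H) / SR`. Equal to 1 when all
#' clones have the same frequency (an "even" repertoire) and converging to 0
#' when very few clones dominate (a "polarized" repertoire).
#'
#' @inheritParams shannon_entropy
#' @return evenness in (0, 1].
#' @export
#' @examples
#' shannon_evenness(rep(0.1, 10)) # 1
shannon_evenness <- function(frequencies) {
  f <- check_frequencies(as_frequencies(frequencies))
  exp(shannon_entropy(f)) / length(f)
}

#' Hill diversity of order q
#'
#' `qD = (sum(f_i^q))^(1/(1-q))`, the Hill-number diversity family. `q`
#' weights abundant clones more strongly as it grows: `q = 0` returns the
#' species richness, and the `q = 1` singularity is handled analytically as
#' `exp(H)` (values of `q` within 1e-9 of 1 are routed to the limit).
#'
#' @inheritParams shannon_entropy
#' @param q non-negative diversity order(s); vectorized over `q`.
#' @return Hill diversity, one value per `q`, each in `[1, SR]`.
#' @export
#' @examples
#' hill_diversity(c(0.7, 0.1, 0.1, 0.1), q = c(0, 1, 2))
hill_diversity <- function(frequencies, q) {
  f <- check_frequencies(as_frequencies(frequencies))
  if (!is.numeric(q) || any(is.na(q)) || any(q < 0)) {
    stop("q must be non-negative", call. = FALSE)
  }
  vapply(q, function(qi) {
    if (abs(qi - 1) < 1e-9) {
      exp(-sum(f * log(f)))
    } else if (qi == 0) {
      as.numeric(length(f))
    } else {
      sum(f^qi)^(1 / (1 - qi))
    }
  }, numeric(1))
}

#' Clonal-expansion (evenness) profile of a repertoire
#'
#' Hill diversity scaled by species richness, `qD / SR`, evaluated over a
#' grid of diversity orders (default 0 to 10 in steps of 0.2, 51 points).
#' The profile is 1 at `q = 0` for every repertoire, non-increasing in `q`,
#' and constant at 1 only for a perfectly even repertoire; it is the
#' "state of clonal expansion" summary that is correlated across samples.
#'
#' @inheritParams shannon_entropy
#' @param q_grid numeric grid of diversity orders.
#' @return an `evenness_profile`: data.frame with columns `q` and `value`,
#'   with the sample id (when known) in attribute `"sample_id"`.
#' @export
evenness_profile <- function(frequencies, q_grid = seq(0, 10, by = 0.2)) {
  f <- check_frequencies(as_frequencies(frequencies))
  sample_id <- if (inherits(frequencies, "tcr_repertoire")) frequencies$sample_id else NA_character_
  values <- hill_diversity(f, q_grid) / length(f)
  structure(
    data.frame(q = q_grid, value = values),
    sample_id = sample_id,
    class = c("evenness_profile", "data.frame")
  )
}

#' Evenness profiles for all samples of a cohort
#'
#' @param cohort a `tcr_cohort`.
#' @param q_grid numeric grid of diversity orders.
#' @return numeric matrix, samples in rows (named by sample id), grid points
#'   in columns (named `q0`, `q0.2`, ...).
#' @export
cohort_evenness_profiles <- function(cohort, q_grid = seq(0, 10, by = 0.2)) {
  stopifnot(inherits(cohort, "tcr_cohort"))
  mat <- t(vapply(cohort$repertoires,
                  function(r) evenness_profile(r, q_grid)$value,
                  numeric(length(q_grid))))
  colnames(mat) <- paste0("q", q_grid)
  mat
}

#' Pairwise Pearson correlation of evenness profiles
#'
#' The all-samples profile-correlation matrix whose hierarchically clustered
#' heatmap reveals what drives clonal expansion (treatment, subpopulation,
#' timepoint, HLA type). Profiles must share an identical q-grid. A profile
#' that is constant across the grid (a perfectly even repertoire) has zero
#' variance; its off-diagonal correlations are undefined and returned as
#' `NA`, while the diagonal is fixed at 1.
#'
#' @param profiles a samples-by-grid numeric matrix (e.g. from
#'   [cohort_evenness_profiles()]) or a list of `evenness_profile` objects.
#' @param log_scale correlate `log` profile values instead of raw values.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
profile_correlation_matrix <- function(profiles, log_scale = FALSE) {
  if (is.list(profiles) && !is.data.frame(profiles) && !is.matrix(profiles)) {
    grids <- lapply(profiles, function(p) p$q)
    if (length(profiles) < 2) stop("need at least 2 profiles", call. = FALSE)
    for (g in grids[-1]) {
      if (!identical(g, grids[[1]])) stop("profiles have mismatched q grids", call. = FALSE)
    }
    ids <- vapply(seq_along(profiles), function(i) {
      attr(profiles[[i]], "sample_id") %||% paste0("profile", i)
    }, character(1))
    profiles <- do.call(rbind, lapply(profiles, `[[`, "value"))
    rownames(profiles) <- ids
  }
  stopifnot(is.matrix(profiles), nrow(profiles) >= 2)
  m <- suppressWarnings(stats::cor(t(log_if(profiles, log_scale))))
  diag(m) <- 1
  m
}

log_if <- function(m, log_scale) if (log_scale) log(m) else m
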