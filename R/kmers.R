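#' CDR3 k-mer decomposition profile of a repertoire
#'
#' Every distinct CDR3 amino-acid sequence is deconstructed into its
#' overlapping subsequences of length `k` (default 3), and the occurrences
#' are condensed into a normalized k-mer frequency distribution. Under the
#' default `"unique_cdr3"` weighting each distinct CDR3 contributes each of
#' its `length - k + 1` k-mers once; under `"clone_frequency"` contributions
#' are weighted by the aggregated clone frequency of the CDR3. CDR3s shorter
#' than `k` are skipped and the skip count reported on standard error.
#'
#' @param r a `tcr_repertoire` or a character vector of CDR3 sequences.
#' @param k k-mer length (default 3).
#' @param weighting `"unique_cdr3"` or `"clone_frequency"`.
#' @return a `kmer_profile`: named numeric vector of k-mer frequencies
#'   summing to 1, sorted by k-mer, with attributes `sample_id` and `k`.
#' @export
#' @examples
#' kmer_profile("CASSL") # CAS, ASS, SSL each 1/3
kmer_profile <- function(r, k = 3, weighting = c("unique_cdr3", "clone_frequency")) {
  weighting <- match.arg(weighting)
  stopifnot(k >= 1)
  if (inherits(r, "tcr_repertoire")) {
    freq <- rowsum(r$clones$frequency, r$clones$cdr3_aa)
    cdr3 <- rownames(freq)
    w_cdr3 <- as.vector(freq)
    sample_id <- r$sample_id
  } else {
    cdr3 <- unique(as.character(r))
    w_cdr3 <- rep(1, length(cdr3))
    sample_id <- NA_character_
  }
  len <- nchar(cdr3)
  short <- len < k
  if (any(short)) {
    log_note("kmer_profile: skipped %d CDR3(s) shorter than k = %d", sum(short), k)
    cdr3 <- cdr3[!short]
    w_cdr3 <- w_cdr3[!short]
    len <- len[!short]
  }
  if (length(cdr3) == 0) {
    stop("no CDR3 of length >= k; k-mer profile is empty", call. = FALSE)
  }
  n_kmers <- len - k + 1L
  seqs <- rep.int(cdr3, n_kmers)
  starts <- sequence(n_kmers)
  kmers <- substring(seqs, starts, starts + k - 1L)
  w <- if (weighting == "unique_cdr3") rep(1, length(kmers)) else rep.int(w_cdr3, n_kmers)
  agg <- rowsum(w, kmers)
  out <- as.vector(agg) / sum(w)
  names(out) <- rownames(agg)
  out <- out[order(names(out))]
  structure(out, sample_id = sample_id, k = as.integer(k), class = "kmer_profile")
}

#' Pairwise Pearson correlation of k-mer profiles
#'
#' Profiles are aligned on the union of their k-mers with zero fill before
#' correlating, so repertoires lacking a k-mer contribute an explicit zero
#' frequency. Zero-variance profiles yield `NA` off-diagonal entries; the
#' diagonal is fixed at 1.
#'
#' @param profiles named list of [kmer_profile()] objects with a common `k`.
#' @return symmetric correlation matrix with unit diagonal, named by sample.
#' @export
kmer_correlation_matrix <- function(profiles) {
  stopifnot(is.list(profiles), length(profiles) >= 2)
  ks <- vapply(profiles, attr, integer(1), "k")
  if (length(unique(ks)) != 1) stop("profiles have differing k", call. = FALSE)
  ids <- names(profiles)
  if (is.null(ids)) {
    ids <- vapply(seq_along(profiles), function(i) {
      id <- attr(profiles[[i]], "sample_id")
      if (is.na(id)) paste0("profile", i) else id
    }, character(1))
  }
  all_kmers <- sort(unique(unlist(lapply(profiles, names))))
  mat <- matrix(0, nrow = length(all_kmers), ncol = length(profiles),
                dimnames = list(all_kmers, ids))
  for (i in seq_along(profiles)) mat[names(profiles[[i]]), i] <- profiles[[i]]
  m <- suppressWarnings(stats::cor(mat))
  diag(m) <- 1
  m
}

#' k-mer profiles for all samples of a cohort
#'
#' @param cohort a `tcr_cohort`.
#' @inheritParams kmer_profile
#' @return named list of `kmer_profile` objects, one per sample.
#' @export
cohort_kmer_profiles <- function(cohort, k = 3, weighting = "unique_cdr3") {
  stopifnot(inherits(cohort, "tcr_cohort"))
  lapply(cohort$repertoires, kmer_profile, k = k, weighting = weighting)
}
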