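# Fixture builders and independent oracles shared across the test files.
# Oracles are deliberately naive (brute force / direct formula evaluation)
# and never call the code paths they check.

make_repertoire <- function(counts, cdr3 = NULL, v = "TRBV5-1", j = "TRBJ2-7",
                            sample_id = "s1", patient_id = "p1",
                            treatment = "NTZ", subpopulation = "CD8_naive",
                            timepoint = "t0", ...) {
  n <- length(counts)
  if (is.null(cdr3)) cdr3 <- paste0("CASS", strrep("A", seq_len(n)), "F")
  repertoire(
    data.frame(v_gene = rep_len(v, n), j_gene = rep_len(j, n),
               cdr3_aa = cdr3, count = counts, stringsAsFactors = FALSE),
    sample_id = sample_id, patient_id = patient_id, treatment = treatment,
    subpopulation = subpopulation, timepoint = timepoint, ...
  )
}

# Repertoire with prescribed exact frequencies (counts scaled by 1e6).
make_freq_repertoire <- function(freqs, ...) {
  make_repertoire(counts = round(freqs * 1e6), ...)
}

write_airr_fixture <- function(path, v, j, cdr3, count) {
  df <- data.frame(v_call = v, j_call = j, junction_aa = cdr3,
                   duplicate_count = count, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# --- independent oracles -------------------------------------------------

pearson_oracle <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# all-pairs Levenshtein edge set via utils::adist
ld1_bruteforce <- function(strings) {
  d <- utils::adist(strings)
  idx <- which(d == 1 & upper.tri(d), arr.ind = TRUE)
  m <- cbind(idx[, 1], idx[, 2])
  m <- m[order(m[, 1], m[, 2]), , drop = FALSE]
  dimnames(m) <- list(NULL, c("i", "j"))
  m
}

# exact two-sided rank-sum p-value by full enumeration of label assignments
rank_sum_enumeration <- function(a, b) {
  pooled <- c(a, b)
  r <- rank(pooled)
  na <- length(a)
  obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2    # Mann-Whitney U of group a
  all_w <- combn(length(pooled), na, function(ix) sum(r[ix]) - na * (na + 1) / 2)
  p_lower <- mean(all_w <= obs)
  p_upper <- mean(all_w >= obs)
  min(1, 2 * min(p_lower, p_upper))
}

# random CDR3-like fixture with planted near-duplicates so LD-1 edges exist
random_cdr3_fixture <- function(n, len_range = c(8, 14), mutate_frac = 0.3) {
  base <- generate_cdr3(n, len_range)
  n_mut <- floor(n * mutate_frac)
  if (n_mut > 0) {
    src <- sample(n, n_mut, replace = TRUE)
    for (k in seq_len(n_mut)) {
      s <- base[src[k]]
      op <- sample(c("sub", "del", "ins"), 1)
      pos <- sample(nchar(s), 1)
      mutated <- switch(op,
        sub = `substr<-`(s, pos, pos, sample(AA_ALPHABET, 1)),
        del = paste0(substr(s, 1, pos - 1), substr(s, pos + 1, nchar(s))),
        ins = paste0(substr(s, 1, pos), sample(AA_ALPHABET, 1),
                     substr(s, pos + 1, nchar(s)))
      )
      base[sample(n, 1)] <- mutated
    }
  }
  unique(base[nzchar(base)])
}

tiny_cohort <- function(n_patients = c(AHSCT = 2, NTZ = 2),
                        subpopulations = list(AHSCT = c("CD4_naive", "CD8_memory"),
                                              NTZ = c("CD4_naive", "CD8_CM")),
                        n_clones = 60, seed = 7, ...) {
  generate_cohort(cohort_spec(n_patients = n_patients,
                              subpopulations = subpopulations,
                              n_clones = n_clones,
                              public_pool_size = 20,
                              public_injection_rate = 0.1,
                              seed = seed, ...))
}
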