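# Built-in gene segment labels used by the generator (gene-level, no alleles).
TRBV_GENES <- c(
  "TRBV2", "TRBV3-1", "TRBV4-1", "TRBV5-1", "TRBV5-4", "TRBV6-1", "TRBV6-5",
  "TRBV7-2", "TRBV7-9", "TRBV9", "TRBV10-3", "TRBV11-2", "TRBV12-3", "TRBV13",
  "TRBV14", "TRBV15", "TRBV18", "TRBV19", "TRBV20-1", "TRBV24-1", "TRBV25-1",
  "TRBV27", "TRBV28", "TRBV29-1", "TRBV30"
)
TRBJ_GENES <- c(
  "TRBJ1-1", "TRBJ1-2", "TRBJ1-3", "TRBJ1-4", "TRBJ1-5", "TRBJ1-6",
  "TRBJ2-1", "TRBJ2-2", "TRBJ2-3", "TRBJ2-4", "TRBJ2-5", "TRBJ2-6", "TRBJ2-7"
)

default_subpopulations <- list(
  AHSCT = c("CD4_naive", "CD4_memory", "CD8_naive", "CD8_memory"),
  NTZ = c("CD4_naive", "CD4_CM", "CD4_EM", "CD8_naive", "CD8_CM", "CD8_EM",
          "CD8_TEMRA")
)

#' Specification of a synthetic longitudinal TCR-beta cohort
#'
#' Defines the study design emulated by [generate_cohort()]: two treatment
#' arms with arm-specific sorted subpopulations (the AHSCT arm pools memory
#' cells, the NTZ arm resolves CM/EM/TEMRA), two timepoints per patient,
#' heavy-tailed clone frequencies with a tunable polarization parameter, an
#' injected cross-timepoint persistence fraction, and a shared public-clone
#' pool. Defaults mirror the emulated design: 7 AHSCT patients x 4
#' subpopulations and 8 NTZ patients x 7 subpopulations, two timepoints each
#' (168 samples).
#'
#' @param n_patients named integer vector, patients per arm.
#' @param subpopulations named list of subpopulation vectors per arm.
#' @param n_clones clones per repertoire.
#' @param polarization geometric-decay rate of clone frequencies
#'   (`f_i` proportional to `exp(-polarization * i)`); 0 gives a perfectly
#'   even repertoire and larger values increasingly polarized ones.
#' @param persistence_fraction rho in `[0, 1]`: fraction of a patient's t0
#'   clone keys carried over (with freshly drawn frequencies) to t24.
#' @param public_pool_size number of clones in the cohort-wide shared pool.
#' @param public_injection_rate fraction of each t0 repertoire's clone slots
#'   filled from the shared pool.
#' @param cdr3_length_range integer pair, CDR3 amino-acid length range.
#' @param read_depth reads drawn per repertoire (multinomial sampling);
#'   `0` means the sampling-free mode: frequencies are the exact generative
#'   values and counts a deterministic integer rendering.
#' @param seed integer master seed; every sample's stream is derived from it
#'   with [derive_seed()].
#' @return a validated `tcr_cohort_spec`.
#' @export
cohort_spec <- function(n_patients = c(AHSCT = 7, NTZ = 8),
                        subpopulations = default_subpopulations,
                        n_clones = 1000,
                        polarization = 0.002,
                        persistence_fraction = 0.2,
                        public_pool_size = 500,
                        public_injection_rate = 0.02,
                        cdr3_length_range = c(8L, 20L),
                        read_depth = 0,
                        seed = 42L) {
  n_patients <- unlist(n_patients)          # tolerate YAML-style lists
  subpopulations <- lapply(subpopulations, unlist)
  cdr3_length_range <- unlist(cdr3_length_range)
  stopifnot(
    all(TREATMENTS %in% names(n_patients)),
    all(n_patients >= 1),
    all(TREATMENTS %in% names(subpopulations)),
    all(unlist(subpopulations) %in% SUBPOPULATIONS),
    n_clones >= 1,
    polarization >= 0,
    persistence_fraction >= 0, persistence_fraction <= 1,
    public_pool_size >= 0,
    public_injection_rate >= 0, public_injection_rate <= 1,
    length(cdr3_length_range) == 2, cdr3_length_range[1] >= 3,
    cdr3_length_range[2] >= cdr3_length_range[1],
    read_depth >= 0, seed == as.integer(seed)
  )
  structure(
    list(
      n_patients = n_patients[TREATMENTS],
      subpopulations = subpopulations[TREATMENTS],
      n_clones = as.integer(n_clones),
      polarization = polarization,
      persistence_fraction = persistence_fraction,
      public_pool_size = as.integer(public_pool_size),
      public_injection_rate = public_injection_rate,
      cdr3_length_range = as.integer(cdr3_length_range),
      read_depth = as.integer(read_depth),
      seed = as.integer(seed)
    ),
    class = "tcr_cohort_spec"
  )
}

#' Geometric (exponential-rank) clone-frequency law
#'
#' `f_i` proportional to `exp(-polarization * i)` for ranks
#' `i = 0, ..., n - 1`, normalized to sum 1. Polarization 0 yields the
#' uniform vector; any positive value a strictly decreasing one. The
#' geometric law gives closed-form control over evenness, which is all the
#' downstream analysis needs from a frequency model.
#'
#' @param n_clones number of clones.
#' @param polarization non-negative decay rate.
#' @return frequency vector of length `n_clones` summing to 1.
#' @export
#' @examples
#' generate_frequencies(2, log(3)) # c(0.75, 0.25)
generate_frequencies <- function(n_clones, polarization) {
  stopifnot(n_clones >= 1, polarization >= 0)
  w <- exp(-polarization * (seq_len(n_clones) - 1))
  w / sum(w)
}

#' Draw random CDR3 amino-acid sequences
#'
#' Lengths are uniform over `length_range`; sequences are anchored with a
#' leading cysteine and trailing phenylalanine (`C...F`, mimicking junction
#' conventions) and interior letters are uniform over the 20-letter
#' alphabet. Uses the current R random stream.
#'
#' @param n number of sequences.
#' @param length_range integer pair (min, max), both at least 3.
#' @return character vector of `n` CDR3 sequences.
#' @export
generate_cdr3 <- function(n = 1, length_range = c(8L, 20L)) {
  stopifnot(n >= 1, length(length_range) == 2, length_range[1] >= 3)
  lens <- sample(seq(length_range[1], length_range[2]), n, replace = TRUE)
  interior <- lens - 2L
  ch <- sample(AA_ALPHABET, sum(interior), replace = TRUE)
  idx <- factor(rep.int(seq_len(n), interior), levels = seq_len(n))
  body <- vapply(split(ch, idx), paste0, character(1), collapse = "")
  paste0("C", body, "F")
}

# Draw n clones with unique (V, J, CDR3) keys, avoiding `exclude` keys.
generate_clones <- function(n, length_range, exclude = character()) {
  if (n == 0) {
    return(data.frame(v_gene = character(), j_gene = character(),
                      cdr3_aa = character(), stringsAsFactors = FALSE))
  }
  draw <- function(m) {
    data.frame(
      v_gene = sample(TRBV_GENES, m, replace = TRUE),
      j_gene = sample(TRBJ_GENES, m, replace = TRUE),
      cdr3_aa = generate_cdr3(m, length_range),
      stringsAsFactors = FALSE
    )
  }
  out <- draw(n)
  key <- clone_key(out$v_gene, out$j_gene, out$cdr3_aa)
  for (iter in 1:100) {
    bad <- duplicated(key) | key %in% exclude
    if (!any(bad)) return(out)
    redraw <- draw(sum(bad))
    out[bad, ] <- redraw
    key[bad] <- clone_key(redraw$v_gene, redraw$j_gene, redraw$cdr3_aa)
  }
  stop("could not generate unique clone keys (key space too small?)", call. = FALSE)
}

# Assign frequencies/counts to a fixed set of clone keys and wrap as a
# repertoire. Rank order is randomized so injected/carried clones land at
# random frequency ranks. depth 0: frequencies are the exact generative
# values and counts the deterministic rendering max(1, round(f * 100 * n));
# depth > 0: counts ~ Multinomial(depth, f), zero-count clones dropped,
# frequencies recomputed from counts.
assemble_repertoire <- function(clones, polarization, read_depth, meta) {
  n <- nrow(clones)
  f <- generate_frequencies(n, polarization)
  clones <- clones[sample.int(n), , drop = FALSE]
  if (read_depth == 0) {
    clones$count <- pmax(1L, as.integer(round(f * 100 * n)))
    clones$frequency <- f
    recompute <- FALSE
  } else {
    counts <- as.vector(stats::rmultinom(1, size = read_depth, prob = f))
    keep <- counts > 0
    clones <- clones[keep, , drop = FALSE]
    clones$count <- counts[keep]
    recompute <- TRUE
  }
  repertoire(clones,
    sample_id = meta$sample_id, patient_id = meta$patient_id,
    treatment = meta$treatment, subpopulation = meta$subpopulation,
    timepoint = meta$timepoint, hla_drb1_1501 = meta$hla_drb1_1501,
    n_cells = meta$n_cells, recompute_frequency = recompute
  )
}

#' Generate a single synthetic repertoire
#'
#' @param spec a [cohort_spec()].
#' @param meta list with `sample_id`, `patient_id`, `treatment`,
#'   `subpopulation`, `timepoint` and optionally `hla_drb1_1501`, `n_cells`.
#' @param public_clones optional data.frame of pool clones (columns
#'   `v_gene`, `j_gene`, `cdr3_aa`) to inject; must not exceed `n_clones`.
#' @param exclude clone keys that freshly drawn clones must avoid.
#' @return a `tcr_repertoire` with exactly `n_clones` unique clone keys
#'   (sampling-free mode) whose expected frequencies follow
#'   [generate_frequencies()].
#' @export
generate_repertoire <- function(spec, meta, public_clones = NULL,
                                exclude = character()) {
  stopifnot(inherits(spec, "tcr_cohort_spec"))
  meta$hla_drb1_1501 <- meta$hla_drb1_1501 %||% "unknown"
  meta$n_cells <- meta$n_cells %||% NA_real_
  n_pub <- if (is.null(public_clones)) 0L else nrow(public_clones)
  if (n_pub > spec$n_clones) stop("public pool injection exceeds n_clones", call. = FALSE)
  pub_keys <- if (n_pub) clone_key(public_clones$v_gene, public_clones$j_gene,
                                   public_clones$cdr3_aa) else character()
  fresh <- generate_clones(spec$n_clones - n_pub, spec$cdr3_length_range,
                           exclude = c(exclude, pub_keys))
  clones <- rbind(
    if (n_pub) public_clones[, c("v_gene", "j_gene", "cdr3_aa")] else NULL,
    fresh
  )
  assemble_repertoire(clones, spec$polarization, spec$read_depth, meta)
}

#' Generate a patient's t0/t24 repertoire pair
#'
#' The t24 repertoire contains exactly `round(persistence_fraction *
#' n_clones)` clone keys copied from t0 (a seeded random subset, with fresh
#' frequencies drawn); the remainder are newly generated clones that are
#' guaranteed not to collide with any t0 key, so the measured clonal
#' persistence of the pair equals the injected fraction by construction.
#' Public-pool injection applies to the t0 repertoire; injected clones reach
#' t24 only via carry-over.
#'
#' @inheritParams generate_repertoire
#' @param meta as in [generate_repertoire()] but without `timepoint` and
#'   `sample_id`; ids are derived as `<patient>_<subpopulation>_<t0|t24>`.
#' @return list with elements `t0` and `t24`.
#' @export
generate_patient_pair <- function(spec, meta, public_clones = NULL) {
  stopifnot(inherits(spec, "tcr_cohort_spec"))
  base_id <- paste(meta$patient_id, meta$subpopulation, sep = "_")
  meta0 <- meta
  meta0$timepoint <- "t0"
  meta0$sample_id <- paste0(base_id, "_t0")
  r0 <- generate_repertoire(spec, meta0, public_clones = public_clones)

  n <- spec$n_clones
  n_carry <- round(spec$persistence_fraction * n)
  carried <- r0$clones[sample.int(nrow(r0$clones), n_carry), c("v_gene", "j_gene", "cdr3_aa"),
                       drop = FALSE]
  fresh <- generate_clones(n - n_carry, spec$cdr3_length_range,
                           exclude = repertoire_keys(r0))
  meta24 <- meta
  meta24$timepoint <- "t24"
  meta24$sample_id <- paste0(base_id, "_t24")
  r24 <- assemble_repertoire(rbind(carried, fresh), spec$polarization,
                             spec$read_depth, meta24)
  list(t0 = r0, t24 = r24)
}

#' Generate a full synthetic cohort
#'
#' Builds both arms, all patients, all subpopulations and both timepoints.
#' Every sample's random stream is derived from the master seed and the
#' sample id, so the output is a pure function of the spec. Pool clones are
#' allocated to t0 samples cyclically (round-robin), which spreads them
#' evenly: whenever the cohort-wide number of injections is at least twice
#' the pool size, every pool member occurs in at least two samples and is
#' therefore recovered as public.
#'
#' @param spec a [cohort_spec()].
#' @param dir optional output directory; when given, one AIRR TSV per sample
#'   plus `metadata.tsv` and `manifest.json` (recording the spec and seed)
#'   are written.
#' @return a `tcr_cohort`; when `dir` is given, the emitted file names are
#'   recorded in `$metadata$file_name`.
#' @export
generate_cohort <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "tcr_cohort_spec"))
  n_pub <- round(spec$public_injection_rate * spec$n_clones)
  if (n_pub > 0 && n_pub > spec$public_pool_size) {
    stop("public pool exhausted: injection needs ", n_pub,
         " clones per sample but the pool holds ", spec$public_pool_size,
         call. = FALSE)
  }
  with_preserved_rng({
    set.seed(derive_seed(spec$seed, "public_pool"))
    pool <- generate_clones(spec$public_pool_size, spec$cdr3_length_range)

    reps <- list()
    cursor <- 0L
    for (arm in TREATMENTS) {
      prefix <- if (arm == "AHSCT") "MS" else "Ty"
      for (p in seq_len(spec$n_patients[[arm]])) {
        patient_id <- sprintf("%s%02d", prefix, p)
        set.seed(derive_seed(spec$seed, paste0("patient_", patient_id)))
        hla <- sample(c("pos", "neg"), 1)
        for (subpop in spec$subpopulations[[arm]]) {
          base_id <- paste(patient_id, subpop, sep = "_")
          injected <- if (n_pub > 0) {
            idx <- (cursor + seq_len(n_pub) - 1L) %% spec$public_pool_size + 1L
            cursor <- cursor + n_pub
            pool[idx, , drop = FALSE]
          } else NULL
          set.seed(derive_seed(spec$seed, base_id))
          n_cells <- round(10^stats::runif(2, 4, 5.7))
          pair <- generate_patient_pair(
            spec,
            meta = list(patient_id = patient_id, treatment = arm,
                        subpopulation = subpop, hla_drb1_1501 = hla,
                        n_cells = n_cells[1]),
            public_clones = injected
          )
          pair$t24$n_cells <- n_cells[2]
          reps[[pair$t0$sample_id]] <- pair$t0
          reps[[pair$t24$sample_id]] <- pair$t24
        }
      }
    }
    cohort <- as_cohort(reps)
    if (!is.null(dir)) cohort <- write_cohort(cohort, dir, spec = spec)
    cohort
  })
}

with_preserved_rng <- function(expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv()))
  expr
}

#' Write a cohort to disk in the formats the loader reads
#'
#' One AIRR TSV per sample, a `metadata.tsv`, and a `manifest.json` that
#' records the generating spec (including the seed) when one is supplied.
#'
#' @param cohort a `tcr_cohort`.
#' @param dir output directory (created if needed).
#' @param spec optional `tcr_cohort_spec` recorded in the manifest.
#' @return the cohort, invisibly, with `file_name` added to its metadata.
#' @export
write_cohort <- function(cohort, dir, spec = NULL) {
  stopifnot(inherits(cohort, "tcr_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  md <- cohort$metadata
  md$file_name <- paste0(md$sample_id, ".tsv")
  for (i in seq_len(nrow(md))) {
    write_clone_table(cohort$repertoires[[md$sample_id[i]]],
                      file.path(dir, md$file_name[i]))
  }
  write_tsv_file(md, file.path(dir, "metadata.tsv"))
  manifest <- list(
    package = "tcrdyn",
    version = as.character(utils::packageVersion("tcrdyn")),
    n_samples = nrow(md)
  )
  if (!is.null(spec)) manifest$spec <- unclass(spec)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  cohort$metadata <- md
  invisible(cohort)
}
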