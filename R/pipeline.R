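#' Default pipeline configuration
#'
#' Returns the full configuration the pipeline runs with when the user
#' supplies nothing: a default synthetic cohort, all analysis stages, and
#' the canonical parameters (q-grid 0..10 step 0.2, top 10000 network nodes,
#' k = 3, highly-shared threshold "more than 10 samples", sample-level
#' sharing). User configs (lists or YAML files) override any subset.
#'
#' @return nested configuration list.
#' @export
default_pipeline_config <- function() {
  list(
    seed = 42L,
    cohort = list(
      source = "synthetic",   # or "files" with metadata_path + clone_dir
      spec = list(),
      metadata_path = NULL,
      clone_dir = NULL,
      dialect = "airr"
    ),
    stages = c("simulate", "stats", "diversity", "persistence", "publicity",
               "network", "kmers", "dboverlap", "compare"),
    params = list(
      q_max = 10, q_step = 0.2,
      top_n = 10000, graphml = FALSE,
      k = 3, kmer_weighting = "unique_cdr3",
      min_samples = 11, sharing_unit = "sample",
      pairing = "all_subpopulations",
      linkage = "average"
    ),
    db = list()  # list of load_db() argument lists: path, dialect, ...
  )
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]]) && nm != "db") {
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

#' Run the full repertoire-dynamics pipeline
#'
#' Orchestrates every analysis stage over a cohort (synthetic or loaded from
#' disk) and writes one plain-text table per figure-level output: repertoire
#' statistics and their correlations, the evenness-profile correlation
#' matrix with hierarchical clustering, per-patient t0/t24 persistence
#' tables, public-clone statistics and the highly-shared presence matrix,
#' LD-1 network degree/connectivity tables, the k-mer correlation matrix
#' with clustering, database-overlap summaries, and group-comparison tables
#' annotated at the p < 0.05 and p < 0.01 thresholds. A `manifest.json`
#' records the configuration and seed; outputs are a pure function of
#' (inputs, config, seed). A stage failure aborts with the stage name;
#' tables already written are preserved.
#'
#' @param config configuration list or path to a YAML file; see
#'   [default_pipeline_config()]. Only listed `stages` run.
#' @param outdir output directory (created if needed); overrides
#'   `config$outdir`.
#' @return invisibly, a list with `outdir`, the written `files` (relative
#'   paths) and the analyzed `cohort`.
#' @export
run_pipeline <- function(config = list(), outdir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_config(default_pipeline_config(), config)
  outdir <- outdir %||% cfg$outdir
  if (is.null(outdir)) stop("an output directory is required", call. = FALSE)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- cfg$params
  stages <- cfg$stages
  files <- character()
  emit <- function(df, rel, csv = FALSE, row_names = FALSE) {
    path <- file.path(outdir, rel)
    dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
    if (csv) write_csv_file(df, path, row_names = row_names) else write_tsv_file(df, path)
    files <<- c(files, rel)
  }
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE)
    })
  }

  # ---- cohort ----
  cohort <- run_stage("simulate", {
    if (identical(cfg$cohort$source, "synthetic")) {
      spec <- do.call(cohort_spec, merge_config(list(seed = cfg$seed), cfg$cohort$spec))
      dir <- if ("simulate" %in% stages) file.path(outdir, "cohort") else NULL
      co <- generate_cohort(spec, dir = dir)
      if (!is.null(dir)) files <- c(files, file.path("cohort", c("metadata.tsv", "manifest.json")))
      co
    } else {
      load_cohort(cfg$cohort$metadata_path, cfg$cohort$clone_dir,
                  dialect = cfg$cohort$dialect)
    }
  })
  q_grid <- seq(0, p$q_max, by = p$q_step)

  stats_df <- cohort_stats(cohort)
  publicity <- NULL
  pub_stats <- NULL
  connected <- NULL

  if ("stats" %in% stages) run_stage("stats", {
    emit(stats_df, "stats/repertoire_stats.tsv")
    fields <- c("n_cells", "n_reads", "n_clones", "shannon_evenness")
    pairs <- utils::combn(fields, 2)
    cors <- do.call(rbind, lapply(c("all", TREATMENTS), function(grp) {
      sub <- if (grp == "all") stats_df else stats_df[stats_df$treatment == grp, ]
      do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
        r <- tryCatch(suppressWarnings(correlate_stats(sub, pairs[1, i], pairs[2, i])),
                      error = function(e) NA_real_)
        data.frame(group = grp, x = pairs[1, i], y = pairs[2, i],
                   pearson_r = r, n = nrow(sub), stringsAsFactors = FALSE)
      }))
    }))
    emit(cors, "stats/stat_correlations.tsv")
  })

  if ("diversity" %in% stages) run_stage("diversity", {
    profiles <- cohort_evenness_profiles(cohort, q_grid)
    emit(cbind(data.frame(sample_id = rownames(profiles)), as.data.frame(profiles)),
         "diversity/evenness_profiles.tsv")
    pc <- profile_correlation_matrix(profiles)
    emit(as.data.frame(pc), "diversity/profile_correlation.csv", csv = TRUE, row_names = TRUE)
    if (!anyNA(pc)) {
      cl <- hierarchical_cluster(pc, "one_minus_pearson", linkage = p$linkage)
      emit(clustering_table(cl), "diversity/profile_clustering.tsv")
    }
  })

  if ("persistence" %in% stages) run_stage("persistence", {
    emit(persistence_table(cohort, pairing = p$pairing), "persistence/persistence_t0_t24.tsv")
  })

  if ("publicity" %in% stages) run_stage("publicity", {
    publicity <- classify_publicity(cohort, sharing_unit = p$sharing_unit)
    emit(publicity, "publicity/sharing_records.tsv")
    pub_stats <- public_clone_stats(cohort, publicity = publicity)
    emit(pub_stats, "publicity/public_clone_stats.tsv")
    hs <- highly_shared_clones(cohort, min_samples = p$min_samples, publicity = publicity)
    emit(hs$records, "publicity/highly_shared_records.tsv")
    if (nrow(hs$records)) {
      emit(as.data.frame(hs$presence), "publicity/highly_shared_presence.csv",
           csv = TRUE, row_names = TRUE)
    }
  })

  if ("network" %in% stages) run_stage("network", {
    nets <- lapply(cohort$repertoires, build_ld1_network,
                   top_n = p$top_n, publicity = publicity)
    deg <- do.call(rbind, lapply(nets, function(nt) {
      cbind(data.frame(sample_id = nt$sample_id), degree_distribution(nt))
    }))
    rownames(deg) <- NULL
    emit(deg, "network/degree_distributions.tsv")
    classes <- if (is.null(publicity)) "all" else c("private", "public", "all")
    connected <- do.call(rbind, lapply(nets, function(nt) {
      data.frame(sample_id = nt$sample_id, class = classes,
                 connected_pct = vapply(classes, function(cl) {
                   suppressWarnings(connected_fraction(nt, cl))
                 }, numeric(1)), stringsAsFactors = FALSE)
    }))
    rownames(connected) <- NULL
    emit(connected, "network/connected_fractions.tsv")
    edges <- do.call(rbind, lapply(nets, function(nt) {
      if (nrow(nt$edges) == 0) return(NULL)
      data.frame(sample_id = nt$sample_id, nt$edges[, c("from_cdr3", "to_cdr3")],
                 stringsAsFactors = FALSE)
    }))
    emit(edges %||% data.frame(sample_id = character(), from_cdr3 = character(),
                               to_cdr3 = character()), "network/edges.tsv")
    # degree-fraction matrix (samples x degree) for heatmap-style clustering
    max_deg <- max(deg$degree)
    dm <- matrix(0, nrow = length(nets), ncol = max_deg + 1,
                 dimnames = list(names(nets), paste0("degree_", 0:max_deg)))
    for (i in seq_len(nrow(deg))) {
      dm[deg$sample_id[i], deg$degree[i] + 1] <- deg$fraction[i]
    }
    emit(as.data.frame(dm), "network/degree_matrix.csv", csv = TRUE, row_names = TRUE)
    if (nrow(dm) >= 2) {
      emit(clustering_table(hierarchical_cluster(dm, "euclidean", linkage = p$linkage)),
           "network/degree_clustering.tsv")
    }
    if (isTRUE(p$graphml)) {
      dir.create(file.path(outdir, "network", "graphml"), recursive = TRUE,
                 showWarnings = FALSE)
      for (nt in nets) {
        rel <- file.path("network", "graphml", paste0(nt$sample_id, ".graphml"))
        write_ld1_graphml(nt, file.path(outdir, rel))
        files <<- c(files, rel)
      }
    }
  })

  if ("kmers" %in% stages) run_stage("kmers", {
    profiles <- cohort_kmer_profiles(cohort, k = p$k, weighting = p$kmer_weighting)
    long <- do.call(rbind, lapply(names(profiles), function(id) {
      data.frame(sample_id = id, kmer = names(profiles[[id]]),
                 frequency = as.numeric(profiles[[id]]), stringsAsFactors = FALSE)
    }))
    emit(long, "kmers/kmer_profiles.tsv")
    km <- kmer_correlation_matrix(profiles)
    emit(as.data.frame(km), "kmers/kmer_correlation.csv", csv = TRUE, row_names = TRUE)
    if (!anyNA(km)) {
      emit(clustering_table(hierarchical_cluster(km, "one_minus_pearson",
                                                 linkage = p$linkage)),
           "kmers/kmer_clustering.tsv")
    }
  })

  if ("dboverlap" %in% stages && length(cfg$db)) run_stage("dboverlap", {
    for (dbcfg in cfg$db) {
      db <- do.call(load_db, dbcfg)
      label <- gsub("[^A-Za-z0-9_]", "_", unique(db$source)[1])
      summaries <- do.call(rbind, lapply(cohort$repertoires, function(r) {
        match_repertoire(r, db)$summary
      }))
      rownames(summaries) <- NULL
      emit(merge(cohort$metadata[, c("sample_id", "treatment", "subpopulation", "timepoint")],
                 summaries, by = "sample_id", sort = FALSE),
           file.path("dboverlap", paste0(label, "_summary.tsv")))
      emit(overlap_by_category(cohort, db),
           file.path("dboverlap", paste0(label, "_by_category.tsv")))
    }
  })

  if ("compare" %in% stages) run_stage("compare", {
    value_tables <- list(
      shannon_evenness = stats_df[, c("sample_id", "shannon_evenness")],
      n_clones = stats_df[, c("sample_id", "n_clones")]
    )
    if (!is.null(pub_stats)) {
      value_tables$pct_public <- pub_stats[, c("sample_id", "pct_public")]
    }
    if (!is.null(connected)) {
      conn_all <- connected[connected$class == "all", c("sample_id", "connected_pct")]
      value_tables$connected_pct <- conn_all
    }
    comp <- cohort_group_comparisons(cohort, value_tables)
    if (nrow(comp)) {
      comp$p_adj_bh <- stats::p.adjust(comp$p_value, method = "BH")
      comp$significance <- significance_stars(comp$p_value)
    }
    emit(comp, "compare/group_comparisons.tsv")
  })

  manifest <- list(
    package = "tcrdyn",
    version = as.character(utils::packageVersion("tcrdyn")),
    seed = cfg$seed,
    stages = stages,
    params = p,
    cohort_source = cfg$cohort$source,
    n_samples = nrow(cohort$metadata),
    files = sort(files)
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(outdir = outdir, files = sort(c(files, "manifest.json")),
                 cohort = cohort))
}

clustering_table <- function(cl) {
  merges <- data.frame(step = seq_along(cl$height), left = cl$merge[, 1],
                       right = cl$merge[, 2], height = cl$height)
  leaves <- data.frame(step = NA_integer_,
                       left = -cl$order, right = NA_integer_, height = NA_real_)
  leaves$leaf_order <- cl$labels[cl$order]
  merges$leaf_order <- NA_character_
  rbind(merges, leaves)
}

#' Group-wise Wilcoxon comparisons for per-sample statistics
#'
#' For every supplied statistic: (a) unpaired rank-sum comparisons between
#' treatments within each subpopulation/timepoint where both arms have at
#' least two samples, and (b) paired signed-rank comparisons of t0 vs t24
#' within each treatment/subpopulation, matching samples by patient.
#'
#' @param cohort a `tcr_cohort`.
#' @param value_tables named list of data.frames with columns `sample_id`
#'   and one value column (the statistic, named after it or positioned
#'   second).
#' @return long data.frame of [group_compare()] rows with `group_a` and
#'   `group_b` labels.
#' @export
cohort_group_comparisons <- function(cohort, value_tables) {
  md <- cohort$metadata
  out <- list()
  for (stat in names(value_tables)) {
    vt <- value_tables[[stat]]
    val <- stats::setNames(vt[[2]], vt$sample_id)
    # between treatments, unpaired
    for (sp in sort(unique(md$subpopulation))) {
      for (tp in TIMEPOINTS) {
        ga <- md$sample_id[md$subpopulation == sp & md$timepoint == tp &
                             md$treatment == "AHSCT"]
        gb <- md$sample_id[md$subpopulation == sp & md$timepoint == tp &
                             md$treatment == "NTZ"]
        if (length(ga) < 2 || length(gb) < 2) next
        res <- group_compare(val[ga], val[gb], "rank_sum_unpaired", stat)
        res$group_a <- paste("AHSCT", sp, tp)
        res$group_b <- paste("NTZ", sp, tp)
        out[[length(out) + 1L]] <- res
      }
    }
    # t0 vs t24 within treatment, paired by patient
    for (tr in TREATMENTS) {
      for (sp in sort(unique(md$subpopulation[md$treatment == tr]))) {
        m0 <- md[md$treatment == tr & md$subpopulation == sp & md$timepoint == "t0", ]
        m24 <- md[md$treatment == tr & md$subpopulation == sp & md$timepoint == "t24", ]
        shared <- intersect(m0$patient_id, m24$patient_id)
        if (length(shared) < 2) next
        a <- val[m0$sample_id[match(shared, m0$patient_id)]]
        b <- val[m24$sample_id[match(shared, m24$patient_id)]]
        res <- group_compare(a, b, "signed_rank_paired", stat)
        res$group_a <- paste(tr, sp, "t0")
        res$group_b <- paste(tr, sp, "t24")
        out[[length(out) + 1L]] <- res
      }
    }
  }
  if (!length(out)) {
    return(data.frame(statistic_name = character(), test = character(),
                      n_a = integer(), n_b = integer(),
                      statistic_value = numeric(), p_value = numeric(),
                      method = character(), note = character(),
                      group_a = character(), group_b = character(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
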