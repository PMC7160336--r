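#' All pairs of distinct strings at Levenshtein distance 1
#'
#' Hash-bucketed neighbour search: two distinct strings are at edit distance
#' 1 iff they either (a) have equal length and share the string obtained by
#' masking one position (a single substitution), or (b) differ in length by
#' one and the shorter equals a single-character deletion of the longer.
#' Strings whose lengths differ by two or more are never compared (the
#' length difference is a lower bound on the edit distance). The result is
#' exactly the all-pairs brute-force edge set, at O(total characters) cost
#' instead of O(n^2) distance computations.
#'
#' @param strings character vector of distinct, non-empty strings.
#' @return two-column integer matrix of index pairs (`i < j`), one row per
#'   unordered pair at distance 1.
#' @export
ld1_pairs <- function(strings) {
  n <- length(strings)
  stopifnot(n == length(unique(strings)), all(nzchar(strings)))
  if (n < 2) return(matrix(integer(), ncol = 2, dimnames = list(NULL, c("i", "j"))))
  lens <- nchar(strings)
  pairs <- list()

  add_group_pairs <- function(groups) {
    # groups: list of integer index vectors; all within-group pairs are edges
    for (g in groups) {
      if (length(g) < 2) next
      cp <- utils::combn(sort(g), 2)
      pairs[[length(pairs) + 1L]] <<- cbind(cp[1, ], cp[2, ])
    }
  }

  for (l in sort(unique(lens))) {
    il <- which(lens == l)
    # substitutions: same length, one masked position in common
    if (length(il) >= 2) {
      for (p in seq_len(l)) {
        key <- paste0(substr(strings[il], 1, p - 1), "\r",
                      substr(strings[il], p + 1, l))
        tab <- split(il, key)
        add_group_pairs(tab[lengths(tab) > 1])
      }
    }
    # deletions: length l vs l - 1
    is <- which(lens == l - 1L)
    if (l >= 2 && length(is) && length(il)) {
      hits <- list()
      for (p in seq_len(l)) {
        del <- paste0(substr(strings[il], 1, p - 1), substr(strings[il], p + 1, l))
        m <- match(del, strings[is])
        found <- !is.na(m)
        if (any(found)) {
          hits[[length(hits) + 1L]] <- cbind(il[found], is[m[found]])
        }
      }
      if (length(hits)) {
        h <- do.call(rbind, hits)
        h <- cbind(pmin(h[, 1], h[, 2]), pmax(h[, 1], h[, 2]))
        pairs[[length(pairs) + 1L]] <- unique(h)
      }
    }
  }
  if (length(pairs) == 0) {
    return(matrix(integer(), ncol = 2, dimnames = list(NULL, c("i", "j"))))
  }
  out <- unique(do.call(rbind, pairs))
  out <- out[order(out[, 1], out[, 2]), , drop = FALSE]
  dimnames(out) <- list(NULL, c("i", "j"))
  out
}

#' Build a Levenshtein-distance-1 similarity network over top CDR3s
#'
#' Nodes are the `top_n` distinct CDR3 amino-acid strings of the repertoire
#' ranked by aggregated clone frequency (clones sharing a CDR3 but differing
#' in V/J contribute their summed frequency; ties broken by higher count,
#' then lexicographically). Edges connect nodes at edit distance exactly 1.
#' When a publicity table is supplied, a node is labelled public if any of
#' the repertoire's clones with that CDR3 is public in the cohort.
#'
#' @param r a `tcr_repertoire`.
#' @param top_n node cap (default 10000).
#' @param publicity optional [classify_publicity()] table for node labels.
#' @return a `tcr_ld1_network`: `$sample_id`, `$nodes` (data.frame `cdr3_aa`,
#'   `frequency`, `count`, `publicity`, `degree`) and `$edges` (data.frame
#'   `from`, `to` node indices and `from_cdr3`, `to_cdr3`).
#' @export
build_ld1_network <- function(r, top_n = 10000, publicity = NULL) {
  stopifnot(inherits(r, "tcr_repertoire"), top_n >= 1)
  freq <- rowsum(r$clones$frequency, r$clones$cdr3_aa)
  count <- rowsum(r$clones$count, r$clones$cdr3_aa)
  nodes <- data.frame(cdr3_aa = rownames(freq), frequency = as.vector(freq),
                      count = as.vector(count), stringsAsFactors = FALSE)
  nodes <- nodes[order(-nodes$frequency, -nodes$count, nodes$cdr3_aa), ]
  nodes <- utils::head(nodes, top_n)
  rownames(nodes) <- NULL

  nodes$publicity <- NA_character_
  if (!is.null(publicity)) {
    pub_keys <- with(publicity, clone_key(v_gene, j_gene, cdr3_aa)[publicity == "public"])
    clone_public <- repertoire_keys(r) %in% pub_keys
    cdr3_public <- tapply(clone_public, r$clones$cdr3_aa, any)
    nodes$publicity <- ifelse(cdr3_public[nodes$cdr3_aa], "public", "private")
  }

  e <- ld1_pairs(nodes$cdr3_aa)
  edges <- data.frame(from = e[, 1], to = e[, 2],
                      from_cdr3 = nodes$cdr3_aa[e[, 1]],
                      to_cdr3 = nodes$cdr3_aa[e[, 2]],
                      stringsAsFactors = FALSE)
  nodes$degree <- tabulate(c(e[, 1], e[, 2]), nbins = nrow(nodes))
  structure(list(sample_id = r$sample_id, nodes = nodes, edges = edges),
            class = "tcr_ld1_network")
}

#' @export
print.tcr_ld1_network <- function(x, ...) {
  cat(sprintf("<tcr_ld1_network> %s: %d nodes, %d edges (%.2f%% connected)\n",
              x$sample_id, nrow(x$nodes), nrow(x$edges),
              100 * mean(x$nodes$degree > 0)))
  invisible(x)
}

#' Degree distribution of an LD-1 network
#'
#' The degree of a node is the number of nodes it links to, i.e. the number
#' of CDR3s one amino-acid change apart.
#'
#' @param net a `tcr_ld1_network`.
#' @return data.frame `degree`, `n_nodes`, `fraction` (fractions sum to 1).
#' @export
degree_distribution <- function(net) {
  stopifnot(inherits(net, "tcr_ld1_network"))
  tab <- table(net$nodes$degree)
  data.frame(degree = as.integer(names(tab)), n_nodes = as.integer(tab),
             fraction = as.integer(tab) / nrow(net$nodes))
}

#' Percentage of connected clones by publicity class
#'
#' A node is connected when its degree is at least 1. For
#' `class != "all"` the network must carry publicity labels; an empty class
#' yields `NA` with a warning rather than an error.
#'
#' @param net a `tcr_ld1_network`.
#' @param class `"all"`, `"private"` or `"public"`.
#' @return percentage in `[0, 100]`, or `NA` for an empty class.
#' @export
connected_fraction <- function(net, class = c("all", "private", "public")) {
  stopifnot(inherits(net, "tcr_ld1_network"))
  class <- match.arg(class)
  nodes <- net$nodes
  if (class != "all") {
    if (all(is.na(nodes$publicity))) {
      stop("network has no publicity labels; build it with a publicity table",
           call. = FALSE)
    }
    nodes <- nodes[!is.na(nodes$publicity) & nodes$publicity == class, , drop = FALSE]
  }
  if (nrow(nodes) == 0) {
    warning(sprintf("no '%s' nodes in network %s; connected fraction undefined",
                    class, net$sample_id))
    return(NA_real_)
  }
  100 * mean(nodes$degree > 0)
}

#' Export an LD-1 network
#'
#' GraphML export carries the node attributes `frequency`, `log_frequency`
#' (the rendering size attribute), `publicity` and `degree`.
#'
#' @param net a `tcr_ld1_network`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ld1_graphml <- function(net, path) {
  stopifnot(inherits(net, "tcr_ld1_network"))
  vertices <- data.frame(
    name = net$nodes$cdr3_aa,
    frequency = net$nodes$frequency,
    log_frequency = log10(net$nodes$frequency),
    publicity = ifelse(is.na(net$nodes$publicity), "unlabelled", net$nodes$publicity),
    degree = net$nodes$degree,
    stringsAsFactors = FALSE
  )
  g <- igraph::graph_from_data_frame(
    net$edges[, c("from_cdr3", "to_cdr3")],
    directed = FALSE, vertices = vertices
  )
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @rdname write_ld1_graphml
#' @export
write_ld1_edgelist <- function(net, path) {
  stopifnot(inherits(net, "tcr_ld1_network"))
  write_tsv_file(net$edges[, c("from_cdr3", "to_cdr3")], path)
}
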