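# Integer sample-similarity matrices, the 0-100 threshold sweep, critical
# network selection, modularity partitioning, and graph export. Graphs are
# igraph objects throughout; isolated nodes are always retained so sample
# counts are conserved across thresholds.

#' Round half away from zero
#'
#' Spreadsheet-style rounding of non-negative values: halves go up.
#'
#' @param x numeric vector (non-negative use intended).
#' @return Rounded values.
#' @export
round_half_up <- function(x) floor(x + 0.5)

#' Convert a normalized dissimilarity matrix to an integer similarity matrix
#'
#' S(i, j) = round((1 - d(i, j)) * 100), rounded to the nearest integer
#' with the chosen half convention; the diagonal is fixed at 100.
#'
#' @param d square dissimilarity matrix with values in [0, 1].
#' @param rounding `"half_up"` (default; halves round up) or `"half_even"`
#'   (IEEE banker's rounding).
#' @return Symmetric integer matrix with entries in [0, 100], diagonal 100.
#' @export
to_similarity_matrix <- function(d, rounding = c("half_up", "half_even")) {
  rounding <- match.arg(rounding)
  d <- .check_square_labels(as.matrix(d))
  if (any(d > 1 + 1e-9) || any(d < -1e-9))
    stop("dissimilarities must lie in [0, 1] (not a normalized dissimilarity)")
  s <- (1 - d) * 100
  s <- if (rounding == "half_up") round_half_up(s) else round(s)
  s <- pmin(pmax(s, 0), 100)
  diag(s) <- 100
  storage.mode(s) <- "integer"
  s
}

#' Validate an integer similarity matrix
#'
#' @param s square integer matrix.
#' @return `s`, invisibly; errors on asymmetry, out-of-range entries or a
#'   non-100 diagonal.
#' @export
validate_similarity_matrix <- function(s) {
  if (!is.matrix(s) || nrow(s) != ncol(s)) stop("similarity must be square")
  if (any(s != t(s))) stop("similarity matrix must be symmetric")
  if (any(s < 0) || any(s > 100)) stop("similarities must lie in [0, 100]")
  if (any(diag(s) != 100)) stop("similarity diagonal must be 100")
  invisible(s)
}

#' Threshold graph of a similarity matrix
#'
#' Nodes are all samples (isolated nodes retained); an edge joins i and j
#' (i != j) iff S(i, j) >= t, so a pair with similarity exactly t is
#' connected at threshold t. Edge weights carry the similarity value.
#'
#' @param sim integer similarity matrix.
#' @param t integer threshold in 0..100.
#' @return An undirected `igraph` graph.
#' @export
threshold_graph <- function(sim, t) {
  sim <- .check_square_labels(sim)
  validate_similarity_matrix(sim)
  if (length(t) != 1L || t != floor(t) || t < 0 || t > 100)
    stop("threshold must be an integer in 0..100")
  labels <- rownames(sim)
  ut <- which(upper.tri(sim) & sim >= t, arr.ind = TRUE)
  edges <- data.frame(from = labels[ut[, 1L]], to = labels[ut[, 2L]],
                      weight = sim[ut], stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(edges, directed = FALSE,
                                vertices = data.frame(name = labels))
}

#' Sweep all 101 similarity thresholds
#'
#' Builds one threshold graph for every t in 0..100. Edge sets are nested:
#' E(G_(t+1)) is a subset of E(G_t), and the per-step edge losses telescope
#' to |E(G_0)| - |E(G_100)|.
#'
#' @param sim integer similarity matrix.
#' @return `threshold_sweep`: `thresholds` (0:100), `graphs` (list of
#'   igraph graphs), `edge_counts`, `sim`.
#' @export
sweep_thresholds <- function(sim) {
  sim <- .check_square_labels(sim)
  validate_similarity_matrix(sim)
  graphs <- lapply(0:100, function(t) threshold_graph(sim, t))
  structure(list(thresholds = 0:100,
                 graphs = graphs,
                 edge_counts = vapply(graphs, igraph::ecount, numeric(1)),
                 sim = sim),
            class = "threshold_sweep")
}

#' @export
print.threshold_sweep <- function(x, ...) {
  cat(sprintf("threshold_sweep: %d nodes, |E(G_0)| = %d, |E(G_100)| = %d\n",
              nrow(x$sim), x$edge_counts[1], x$edge_counts[101]))
  invisible(x)
}

.largest_component_sizes <- function(sweep) {
  vapply(sweep$graphs,
         function(g) max(igraph::components(g)$csize), numeric(1))
}

#' Distance curve along a threshold sweep
#'
#' Quantifies how much the network changes as the threshold rises.
#' Methods:
#' \describe{
#'   \item{fragmentation}{D(t) = (S(t) - S(t+1)) / n where S(t) is the size
#'     of the largest connected component of G_t: a percolation-style
#'     measure that peaks where raising the threshold most fragments the
#'     network (default for critical-network selection).}
#'   \item{consecutive}{D(t) = |E(G_t) symmetric-difference E(G_(t+1))| /
#'     C(n, 2), i.e. the normalized per-step edge loss.}
#'   \item{from_initial}{D(t) = |E(G_0) symmetric-difference E(G_t)| /
#'     C(n, 2), monotone in t.}
#' }
#'
#' @param sweep a `threshold_sweep`.
#' @param method distance definition (see Details).
#' @return Named numeric vector (names are thresholds; `fragmentation` and
#'   `consecutive` cover t = 0..99, `from_initial` t = 0..100), with the
#'   method recorded in `attr(, "method")`.
#' @export
network_distance_curve <- function(sweep,
                                   method = c("fragmentation", "consecutive",
                                              "from_initial")) {
  method <- match.arg(method)
  n <- nrow(sweep$sim)
  npairs <- choose(n, 2)
  ec <- sweep$edge_counts
  curve <- switch(method,
    fragmentation = {
      s <- .largest_component_sizes(sweep)
      stats::setNames((s[1:100] - s[2:101]) / n, 0:99)
    },
    consecutive = stats::setNames((ec[1:100] - ec[2:101]) / npairs, 0:99),
    from_initial = stats::setNames((ec[1] - ec) / npairs, 0:100))
  attr(curve, "method") <- method
  curve
}

#' Locate the critical network of a threshold sweep
#'
#' The critical threshold t* attains the maximum of the distance curve
#' (ties broken towards the smallest threshold). For the step-wise methods
#' (`fragmentation`, `consecutive`) the critical graph is G_(t*+1) — the
#' sparser network just after the largest structural drop; for
#' `from_initial` it is G_(t*).
#'
#' @inheritParams network_distance_curve
#' @return `critical_network`: `threshold` (t*), `graph_threshold` (the
#'   threshold of the returned graph), `graph`, `curve`, `method`,
#'   `degenerate` (TRUE when the curve is identically zero, with a warning).
#' @export
find_critical_network <- function(sweep,
                                  method = c("fragmentation", "consecutive",
                                             "from_initial")) {
  method <- match.arg(method)
  curve <- network_distance_curve(sweep, method)
  if (all(curve == 0)) {
    warning("degenerate sweep: distance curve is identically zero")
    return(structure(list(threshold = 0L, graph_threshold = 0L,
                          graph = sweep$graphs[[1L]], curve = curve,
                          method = method, degenerate = TRUE),
                     class = "critical_network"))
  }
  tstar <- as.integer(names(curve)[which.max(curve)])
  gt <- if (method == "from_initial") tstar else tstar + 1L
  structure(list(threshold = tstar, graph_threshold = gt,
                 graph = sweep$graphs[[gt + 1L]], curve = curve,
                 method = method, degenerate = FALSE),
            class = "critical_network")
}

#' @export
print.critical_network <- function(x, ...) {
  cat(sprintf(
    "critical_network (%s): t* = %d, graph at %d%% with %d edges\n",
    x$method, x$threshold, x$graph_threshold, igraph::ecount(x$graph)))
  invisible(x)
}

#' Modularity-based community partition of a graph
#'
#' Heuristically maximizes Newman-Girvan modularity
#' Q = sum_c (e_c / m - (d_c / 2m)^2) with igraph's fast-greedy (default,
#' deterministic) or multilevel (Louvain) algorithm. An edgeless graph gets
#' every node in its own community with Q = 0 and a warning.
#'
#' @param graph an undirected `igraph` graph.
#' @param algorithm `"greedy"` or `"louvain"`.
#' @param seed integer seed (relevant for `louvain`); deterministic output
#'   given (algorithm, seed, node order).
#' @return `graph_partition`: `assignment` (named community id per node),
#'   `Q`, `algorithm`, `seed`.
#' @export
modularity_partition <- function(graph, algorithm = c("greedy", "louvain"),
                                 seed = 1L) {
  algorithm <- match.arg(algorithm)
  nm <- igraph::V(graph)$name
  if (is.null(nm)) nm <- as.character(seq_len(igraph::vcount(graph)))
  if (igraph::ecount(graph) == 0L) {
    warning("edgeless graph: every node is its own community, Q = 0")
    return(structure(list(
      assignment = stats::setNames(seq_along(nm), nm),
      Q = 0, algorithm = algorithm, seed = seed),
      class = "graph_partition"))
  }
  cl <- with_seed(seed, {
    if (algorithm == "greedy") igraph::cluster_fast_greedy(graph)
    else igraph::cluster_louvain(graph)
  })
  memb <- as.integer(igraph::membership(cl))
  q <- igraph::modularity(graph, memb)
  if (q < 0) {
    # never worse than the trivial one-community partition (Q = 0)
    memb <- rep(1L, length(nm))
    q <- 0
  }
  structure(list(assignment = stats::setNames(memb, nm),
                 Q = q, algorithm = algorithm, seed = seed),
            class = "graph_partition")
}

#' @export
print.graph_partition <- function(x, ...) {
  cat(sprintf("graph_partition (%s): %d communities, Q = %.4f\n",
              x$algorithm, length(unique(x$assignment)), x$Q))
  invisible(x)
}

#' Export a graph to GraphML or an edge-list TSV
#'
#' Vertices are written in sorted label order; when a partition is given
#' its community ids are attached as a node attribute (for the edge-list
#' format they go to a companion `<path>.nodes.tsv` file).
#'
#' @param graph an `igraph` graph.
#' @param path output file path.
#' @param partition optional `graph_partition` for the same graph.
#' @param format `"graphml"` or `"edgelist_tsv"`.
#' @return `path`, invisibly.
#' @export
export_graph <- function(graph, path, partition = NULL,
                         format = c("graphml", "edgelist_tsv")) {
  format <- match.arg(format)
  nm <- igraph::V(graph)$name
  g <- igraph::permute(graph, rank(nm, ties.method = "first"))
  if (!is.null(partition)) {
    igraph::V(g)$community <-
      as.integer(partition$assignment[igraph::V(g)$name])
  }
  if (format == "graphml") {
    igraph::write_graph(g, path, format = "graphml")
    return(invisible(path))
  }
  ed <- igraph::as_data_frame(g, what = "edges")
  if (nrow(ed)) {
    swap <- ed$from > ed$to
    tmp <- ed$from[swap]; ed$from[swap] <- ed$to[swap]; ed$to[swap] <- tmp
    ed <- ed[order(ed$from, ed$to), , drop = FALSE]
  }
  utils::write.table(ed, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(partition)) {
    nodes <- data.frame(node = igraph::V(g)$name,
                        community = igraph::V(g)$community)
    utils::write.table(nodes, paste0(path, ".nodes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
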