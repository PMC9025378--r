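# Presence/absence logic: incidence tables, co-occurrence networks within
# sample groups, strict-occupancy core extraction nested across a sampling
# hierarchy, and the Spearman antagonism screen over core candidates.

#' Binarize an abundance table into an incidence table
#'
#' A taxon is present in a sample when its read count reaches `min_count`.
#' One read suffices by default; raise the threshold to guard against
#' index-hopping noise.
#'
#' @param table an `abundance_table`.
#' @param min_count integer presence threshold (>= 1).
#' @return `incidence_table`: logical `presence` matrix (taxa x samples)
#'   and the `min_count` used.
#' @export
to_incidence <- function(table, min_count = 1L) {
  stopifnot(min_count >= 1)
  structure(list(presence = table$counts >= min_count,
                 min_count = as.integer(min_count)),
            class = "incidence_table")
}

#' Merge incidence columns into larger sampling units
#'
#' Presence is combined by logical OR, e.g. pooling the individually
#' sequenced leaves of one tree into a single tree-level unit before core
#' extraction.
#'
#' @param inc an `incidence_table`.
#' @param units named list mapping each new unit id to the sample ids it
#'   absorbs (units must cover disjoint sample sets).
#' @return A new `incidence_table` with one column per unit.
#' @export
aggregate_samples <- function(inc, units) {
  all_s <- unlist(units, use.names = FALSE)
  if (anyDuplicated(all_s)) stop("units must be disjoint")
  miss <- setdiff(all_s, colnames(inc$presence))
  if (length(miss)) stop("unknown samples: ", paste(miss, collapse = ", "))
  p <- vapply(units, function(s)
    rowSums(inc$presence[, s, drop = FALSE]) > 0,
    logical(nrow(inc$presence)))
  structure(list(presence = p, min_count = inc$min_count),
            class = "incidence_table")
}

#' Co-occurrence graph of taxa over a sample group
#'
#' Nodes are the taxa present in at least one selected sample; an edge
#' joins two taxa iff some selected sample contains both. Each edge
#' records its witnessing samples (`witnesses`, comma-joined) and their
#' number (`n_shared`). The graph equals the union over selected samples
#' of the complete graph on each sample's present taxa.
#'
#' @param inc an `incidence_table`.
#' @param samples sample ids to use (default: all).
#' @return An undirected `igraph` graph.
#' @export
cooccurrence_graph <- function(inc, samples = colnames(inc$presence)) {
  if (length(samples) == 0L) stop("empty sample subset")
  miss <- setdiff(samples, colnames(inc$presence))
  if (length(miss)) stop("unknown samples: ", paste(miss, collapse = ", "))
  p <- inc$presence[, samples, drop = FALSE]
  p <- p[rowSums(p) > 0, , drop = FALSE]
  taxa <- rownames(p)
  shared <- tcrossprod(p * 1L)
  ut <- which(upper.tri(shared) & shared > 0, arr.ind = TRUE)
  witnesses <- vapply(seq_len(nrow(ut)), function(k) {
    both <- p[ut[k, 1L], ] & p[ut[k, 2L], ]
    paste(samples[both], collapse = ",")
  }, character(1))
  edges <- data.frame(from = taxa[ut[, 1L]], to = taxa[ut[, 2L]],
                      n_shared = shared[ut], witnesses = witnesses,
                      stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(edges, directed = FALSE,
                                vertices = data.frame(name = taxa))
}

#' Occupancy-defined core taxa of a sample group
#'
#' Occupancy is the fraction of group samples where a taxon is present;
#' the core holds every taxon with occupancy >= `occupancy_cutoff`. The
#' default cutoff 1.0 is the strict core: present in every sample of the
#' group.
#'
#' @param inc an `incidence_table`.
#' @param group_samples non-empty sample id set.
#' @param occupancy_cutoff fraction in (0, 1]; default 1.0.
#' @return `core_set`: `group_samples`, `occupancy_cutoff`, `members`
#'   (taxon ids), `occupancy` (named fraction for every taxon).
#' @export
core_taxa <- function(inc, group_samples, occupancy_cutoff = 1.0) {
  if (length(group_samples) == 0L) stop("group must be non-empty")
  stopifnot(occupancy_cutoff > 0, occupancy_cutoff <= 1)
  miss <- setdiff(group_samples, colnames(inc$presence))
  if (length(miss)) stop("unknown samples: ", paste(miss, collapse = ", "))
  occ <- rowMeans(inc$presence[, group_samples, drop = FALSE])
  structure(list(group_samples = group_samples,
                 occupancy_cutoff = occupancy_cutoff,
                 members = names(occ)[occ >= occupancy_cutoff - 1e-9],
                 occupancy = occ),
            class = "core_set")
}

#' @export
print.core_set <- function(x, ...) {
  cat(sprintf("core_set: %d taxa at occupancy >= %g over %d samples\n",
              length(x$members), x$occupancy_cutoff,
              length(x$group_samples)))
  invisible(x)
}

.validate_hierarchy <- function(hierarchy, all_samples) {
  if (is.null(names(hierarchy)) || anyDuplicated(names(hierarchy)))
    stop("hierarchy nodes must have unique names")
  for (nm in names(hierarchy)) {
    node <- hierarchy[[nm]]
    miss <- setdiff(node$samples, all_samples)
    if (length(miss))
      stop("node '", nm, "' references unknown samples: ",
           paste(miss, collapse = ", "))
    if (!is.null(node$parent) && !is.na(node$parent)) {
      if (!node$parent %in% names(hierarchy))
        stop("node '", nm, "' has unknown parent '", node$parent, "'")
      extra <- setdiff(node$samples, hierarchy[[node$parent]]$samples)
      if (length(extra))
        stop("node '", nm, "' is not a subset of its parent '",
             node$parent, "': ", paste(extra, collapse = ", "))
    }
  }
  invisible(hierarchy)
}

#' Strict cores across a nested sampling hierarchy
#'
#' Computes one core set per hierarchy node and checks the nesting
#' theorem: at occupancy cutoff 1.0, the core of a parent (superset) group
#' is contained in the core of each of its children. Violations are
#' collected in `nesting_report`; an empty report is a mathematical
#' guarantee, so a non-empty one flags an implementation bug upstream.
#'
#' @param inc an `incidence_table`.
#' @param hierarchy named list; each node is `list(samples = <ids>,
#'   parent = <node name or NULL>)`, child samples a subset of the parent's.
#' @param occupancy_cutoff fraction in (0, 1]; default 1.0.
#' @return `core_hierarchy`: `cores` (named list of `core_set`),
#'   `hierarchy`, `nesting_report` (data.frame of violations),
#'   `occupancy_cutoff`.
#' @export
hierarchical_cores <- function(inc, hierarchy, occupancy_cutoff = 1.0) {
  .validate_hierarchy(hierarchy, colnames(inc$presence))
  cores <- lapply(hierarchy, function(node)
    core_taxa(inc, node$samples, occupancy_cutoff))
  report <- data.frame(parent = character(0), child = character(0),
                       taxon = character(0), stringsAsFactors = FALSE)
  if (occupancy_cutoff == 1.0) {
    for (nm in names(hierarchy)) {
      par <- hierarchy[[nm]]$parent
      if (is.null(par) || is.na(par)) next
      bad <- setdiff(cores[[par]]$members, cores[[nm]]$members)
      if (length(bad))
        report <- rbind(report, data.frame(parent = par, child = nm,
                                           taxon = bad,
                                           stringsAsFactors = FALSE))
    }
  }
  structure(list(cores = cores, hierarchy = hierarchy,
                 nesting_report = report,
                 occupancy_cutoff = occupancy_cutoff),
            class = "core_hierarchy")
}

#' @export
print.core_hierarchy <- function(x, ...) {
  cat("core_hierarchy (cutoff", x$occupancy_cutoff, "):\n")
  for (nm in names(x$cores))
    cat(sprintf("  %-14s %3d samples, %3d core taxa\n", nm,
                length(x$cores[[nm]]$group_samples),
                length(x$cores[[nm]]$members)))
  if (nrow(x$nesting_report))
    cat("  !! nesting violations:", nrow(x$nesting_report), "\n")
  invisible(x)
}

#' Write a core hierarchy as long-form TSV
#'
#' One row per (group, core taxon) with its occupancy.
#'
#' @param ch a `core_hierarchy`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_core_tsv <- function(ch, path) {
  rows <- do.call(rbind, lapply(names(ch$cores), function(nm) {
    cs <- ch$cores[[nm]]
    if (!length(cs$members)) return(NULL)
    data.frame(group = nm, taxon = sort(cs$members),
               occupancy = cs$occupancy[sort(cs$members)],
               stringsAsFactors = FALSE)
  }))
  if (is.null(rows))
    rows <- data.frame(group = character(0), taxon = character(0),
                       occupancy = numeric(0))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Antagonism screen over candidate taxa
#'
#' Spearman correlations restricted to the candidate set (typically the
#' strict core), keeping only pairs with negative rho and p below `alpha`,
#' sorted by rho ascending — the signature of putative antagonistic
#' interactions among always-present taxa.
#'
#' @param mat numeric taxa x samples matrix (e.g. Hellinger values).
#' @param candidates taxon ids to screen (>= 2, subset of rownames).
#' @param alpha significance level (default 0.01, raw p).
#' @param adjust `"none"` (default) or `"bh"`.
#' @return `correlation_result` whose `pairs` hold only the flagged
#'   negative pairs.
#' @export
antagonism_screen <- function(mat, candidates, alpha = 0.01,
                              adjust = c("none", "bh")) {
  adjust <- match.arg(adjust)
  miss <- setdiff(candidates, rownames(mat))
  if (length(miss)) stop("unknown candidates: ", paste(miss, collapse = ", "))
  if (length(candidates) < 2L) stop("need at least 2 candidates")
  res <- spearman_screen(mat[candidates, , drop = FALSE],
                         top_k = length(candidates),
                         alpha = alpha, adjust = adjust)
  keep <- res$pairs$rho < 0 & res$pairs$significant
  res$pairs <- res$pairs[keep, , drop = FALSE]
  res$pairs <- res$pairs[order(res$pairs$rho), , drop = FALSE]
  rownames(res$pairs) <- NULL
  res
}
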