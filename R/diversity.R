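# Community-ecology numerics on abundance tables: relative abundance,
# Hellinger transformation, Bray-Curtis and Jensen-Shannon dissimilarities,
# principal coordinates analysis, PERMDISP, and a Spearman correlation
# screen over the most abundant taxa.

.counts_of <- function(x) {
  if (inherits(x, "abundance_table")) x$counts else as.matrix(x)
}

#' Relative abundance matrix
#'
#' Divides each sample column by its total so columns sum to 1.
#'
#' @param x `abundance_table` or numeric taxa x samples matrix.
#' @return Numeric matrix of per-sample proportions.
#' @export
relative_abundance <- function(x) {
  m <- .counts_of(x)
  tot <- colSums(m)
  zero <- colnames(m)[tot == 0]
  if (length(zero))
    stop("sample(s) with zero total reads: ", paste(zero, collapse = ", "))
  sweep(m, 2L, tot, "/")
}

#' Hellinger transformation
#'
#' Square root of relative abundance: entry = sqrt(count / sample total).
#' Each sample column then has unit Euclidean norm, which makes Euclidean
#' distances between samples well-behaved for compositional read counts.
#'
#' @inheritParams relative_abundance
#' @return Numeric matrix of the same shape.
#' @export
hellinger_transform <- function(x) sqrt(relative_abundance(x))

.check_square_labels <- function(m) {
  if (is.null(rownames(m))) {
    rownames(m) <- colnames(m) <- paste0("s", seq_len(nrow(m)))
  }
  m
}

#' Bray-Curtis dissimilarity matrix
#'
#' BC(i, j) = sum_k |x_ki - x_kj| / sum_k (x_ki + x_kj), in [0, 1], on raw
#' counts by default or on Hellinger-transformed values.
#'
#' @param x `abundance_table` or numeric taxa x samples matrix.
#' @param representation `"raw"` (default) or `"hellinger"`.
#' @return Symmetric numeric matrix with zero diagonal, labelled by sample.
#' @export
bray_curtis_matrix <- function(x, representation = c("raw", "hellinger")) {
  representation <- match.arg(representation)
  m <- .counts_of(x)
  if (ncol(m) < 2L) stop("need at least 2 samples")
  if (sum(colSums(m) == 0) >= 2L)
    stop("Bray-Curtis is undefined between two all-zero samples")
  if (representation == "hellinger") m <- hellinger_transform(m)
  d <- as.matrix(vegan::vegdist(t(m), method = "bray"))
  diag(d) <- 0
  dimnames(d) <- list(colnames(m), colnames(m))
  d
}

.shannon_entropy <- function(p, log_base) {
  p <- p[p > 0]
  -sum(p * log(p, base = log_base))
}

#' Jensen-Shannon divergence matrix
#'
#' JSD(P, Q) = H(M) - (H(P) + H(Q)) / 2 with M = (P + Q) / 2, using the
#' convention 0 * log 0 = 0. With base-2 logarithms values lie in [0, 1]
#' and reach 1 only for distributions with disjoint support.
#'
#' @param x `abundance_table` or numeric taxa x samples matrix (columns are
#'   converted to relative abundances).
#' @param log_base 2 (default) or `exp(1)`.
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
jensen_shannon_matrix <- function(x, log_base = 2) {
  stopifnot(log_base %in% c(2, exp(1)))
  p <- relative_abundance(x)
  n <- ncol(p)
  d <- matrix(0, n, n, dimnames = list(colnames(p), colnames(p)))
  h <- apply(p, 2L, .shannon_entropy, log_base = log_base)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    m <- (p[, i] + p[, j]) / 2
    v <- .shannon_entropy(m, log_base) - (h[i] + h[j]) / 2
    d[i, j] <- d[j, i] <- max(v, 0)  # clip tiny negative rounding
  }
  d
}

# Gower-centered matrix of a squared-distance configuration and its
# eigendecomposition; the shared engine of pcoa() and permdisp().
.gower_eigen <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  a <- -0.5 * d^2
  g <- sweep(sweep(a, 1L, rowMeans(a)), 2L, colMeans(a)) + mean(a)
  eigen((g + t(g)) / 2, symmetric = TRUE)
}

#' Principal coordinates analysis (classical scaling)
#'
#' Double-centers -0.5 * D^2 and eigendecomposes it. Axes with eigenvalue
#' above a tolerance are returned as coordinates; negative eigenvalues are
#' reported but excluded from the coordinate matrix.
#'
#' @param d square distance matrix (symmetric, zero diagonal).
#' @param tol relative eigenvalue tolerance for keeping an axis.
#' @return `pcoa_result`: `coordinates` (samples x axes), `eigenvalues`
#'   (all, decreasing), `proportion_explained` (positive axes),
#'   `negative_eigenvalues`.
#' @export
pcoa <- function(d, tol = 1e-8) {
  d <- .check_square_labels(as.matrix(d))
  if (nrow(d) < 2L) stop("need at least 2 samples")
  e <- .gower_eigen(d)
  lam <- e$values
  cut <- tol * max(abs(lam), 1e-300)
  keep <- which(lam > cut)
  coords <- e$vectors[, keep, drop = FALSE] %*%
    diag(sqrt(lam[keep]), length(keep))
  dimnames(coords) <- list(rownames(d), paste0("Axis", seq_along(keep)))
  pos_sum <- sum(lam[lam > 0])
  structure(list(coordinates = coords,
                 eigenvalues = lam,
                 proportion_explained = lam[keep] / pos_sum,
                 negative_eigenvalues = lam[lam < -cut]),
            class = "pcoa_result")
}

# distances from each sample to its group centroid in the principal
# coordinate embedding, keeping negative-eigenvalue axes: squared distance
# = real-part contribution - imaginary-part contribution, floored at 0.
.centroid_distances <- function(pos, neg, groups) {
  z <- numeric(nrow(pos))
  for (g in levels(groups)) {
    idx <- which(groups == g)
    cp <- colMeans(pos[idx, , drop = FALSE])
    d2 <- rowSums(sweep(pos[idx, , drop = FALSE], 2L, cp)^2)
    if (ncol(neg)) {
      cn <- colMeans(neg[idx, , drop = FALSE])
      d2 <- d2 - rowSums(sweep(neg[idx, , drop = FALSE], 2L, cn)^2)
    }
    z[idx] <- sqrt(pmax(d2, 0))
  }
  z
}

.anova_f <- function(z, groups) {
  n <- length(z); k <- nlevels(groups)
  gm <- tapply(z, groups, mean)
  ng <- tabulate(groups)
  ssb <- sum(ng * (gm - mean(z))^2)
  ssw <- sum((z - gm[as.integer(groups)])^2)
  if (ssb + ssw < 1e-24) return(0)  # constant distances
  if (ssw < 1e-24) return(Inf)
  (ssb / (k - 1)) / (ssw / (n - k))
}

#' PERMDISP: permutation test of multivariate dispersion
#'
#' Tests whether groups differ in their spread around their own centroids.
#' Samples are embedded by principal coordinates (negative-eigenvalue axes
#' retained with the usual imaginary-part correction), each sample's
#' distance to its group centroid is computed, and the one-way ANOVA F on
#' those distances is compared with its distribution under random
#' permutation of the group labels, recomputing centroids and distances
#' for every permutation. p = (1 + #\{F_perm >= F_obs\}) / (1 + n_perm).
#'
#' @param d square distance matrix between samples.
#' @param groups group label per sample (2+ groups, each with 2+ samples).
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed; mandatory so p-values are reproducible.
#' @return `dispersion_test`: `F`, `p_perm`, `n_perm`, `group_distances`
#'   (named distances to own centroid), `groups`, `seed`.
#' @export
permdisp <- function(d, groups, n_perm = 999, seed) {
  if (missing(seed) || is.null(seed)) stop("permdisp requires a seed")
  d <- .check_square_labels(as.matrix(d))
  groups <- droplevels(as.factor(groups))
  stopifnot(length(groups) == nrow(d), n_perm >= 1)
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  if (any(tabulate(groups) < 2L)) stop("every group needs at least 2 samples")
  e <- .gower_eigen(d)
  cut <- 1e-8 * max(abs(e$values), 1e-300)
  ip <- e$values > cut
  im <- e$values < -cut
  pos <- sweep(e$vectors[, ip, drop = FALSE], 2L, sqrt(e$values[ip]), "*")
  neg <- sweep(e$vectors[, im, drop = FALSE], 2L, sqrt(-e$values[im]), "*")
  z <- .centroid_distances(pos, neg, groups)
  f_obs <- .anova_f(z, groups)
  f_perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      gp <- groups[sample.int(length(groups))]
      .anova_f(.centroid_distances(pos, neg, gp), gp)
    }, numeric(1))
  })
  structure(list(F = f_obs,
                 p_perm = (1 + sum(f_perm >= f_obs)) / (1 + n_perm),
                 n_perm = n_perm,
                 group_distances = stats::setNames(z, rownames(d)),
                 groups = groups,
                 seed = seed),
            class = "dispersion_test")
}

#' @export
print.dispersion_test <- function(x, ...) {
  cat(sprintf("PERMDISP: F = %.4g, p = %.6g (%d permutations, seed %d)\n",
              x$F, x$p_perm, x$n_perm, x$seed))
  invisible(x)
}

#' Spearman correlation screen over the most abundant taxa
#'
#' Ranks taxa by total abundance (ties broken by taxon id), keeps the top
#' `top_k`, and computes Spearman's rho (average ranks for ties) for every
#' pair, with two-sided p-values from the t approximation
#' t = rho * sqrt((n - 2) / (1 - rho^2)). Constant taxa are excluded and
#' reported in the diagnostics.
#'
#' @param mat numeric taxa x samples matrix (e.g. Hellinger values), with
#'   rownames; at least 4 samples.
#' @param top_k number of taxa to screen (default 100).
#' @param alpha significance level (default 0.01).
#' @param adjust `"none"` (raw p, default) or `"bh"`
#'   (Benjamini-Hochberg over all screened pairs).
#' @return `correlation_result`: `pairs` data.frame (`taxon_a`, `taxon_b`,
#'   `rho`, `p_raw`, `p_adjusted`, `significant`), `diagnostics` (constant
#'   taxa), plus the screen settings.
#' @export
spearman_screen <- function(mat, top_k = 100, alpha = 0.01,
                            adjust = c("none", "bh")) {
  adjust <- match.arg(adjust)
  mat <- as.matrix(mat)
  n <- ncol(mat)
  if (n < 4L) stop("need at least 4 samples")
  if (is.null(rownames(mat)))
    rownames(mat) <- paste0("t", seq_len(nrow(mat)))
  if (top_k < 2L) stop("top_k must be at least 2")
  ord <- order(-rowSums(mat), rownames(mat))
  sub <- mat[ord[seq_len(min(top_k, nrow(mat)))], , drop = FALSE]
  const <- apply(sub, 1L, function(v) diff(range(v)) == 0)
  diagnostics <- character(0)
  if (any(const)) {
    diagnostics <- paste0("constant vector: ", rownames(sub)[const])
    sub <- sub[!const, , drop = FALSE]
  }
  if (nrow(sub) < 2L)
    return(structure(list(pairs = data.frame(taxon_a = character(0),
                                             taxon_b = character(0),
                                             rho = numeric(0),
                                             p_raw = numeric(0),
                                             p_adjusted = numeric(0),
                                             significant = logical(0)),
                          diagnostics = diagnostics, n_samples = n,
                          alpha = alpha, adjust = adjust),
                     class = "correlation_result"))
  rho <- stats::cor(t(sub), method = "spearman")
  ut <- which(upper.tri(rho), arr.ind = TRUE)
  r <- pmin(pmax(rho[ut], -1), 1)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, 0))
  p_raw <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  p_bh <- stats::p.adjust(p_raw, method = "BH")
  p_use <- if (adjust == "bh") p_bh else p_raw
  pairs <- data.frame(taxon_a = rownames(rho)[ut[, 1L]],
                      taxon_b = rownames(rho)[ut[, 2L]],
                      rho = r, p_raw = p_raw, p_adjusted = p_bh,
                      significant = p_use < alpha,
                      stringsAsFactors = FALSE)
  structure(list(pairs = pairs, diagnostics = diagnostics, n_samples = n,
                 alpha = alpha, adjust = adjust),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("spearman screen: %d pairs over %d samples, %d significant\n",
              nrow(x$pairs), x$n_samples, sum(x$pairs$significant)))
  invisible(x)
}

#' Write a correlation result as long-form TSV
#'
#' @param res `correlation_result`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_correlation_tsv <- function(res, path) {
  utils::write.table(res$pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Evaluate code under a temporary RNG seed
#'
#' Sets the seed, runs `code`, and restores the caller's RNG state, so
#' seeded stages do not perturb surrounding randomness.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = .GlobalEnv)
    else suppressWarnings(rm(".Random.seed", envir = .GlobalEnv))
  })
  set.seed(seed)
  force(code)
}
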