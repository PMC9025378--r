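test_that("relative abundance and Hellinger closed forms hold", {
  m <- matrix(c(1, 4, 4), ncol = 1, dimnames = list(c("a", "b", "c"), "s1"))
  expect_equal(as.numeric(relative_abundance(m)), c(1, 4, 4) / 9)
  expect_equal(as.numeric(hellinger_transform(m)), c(1 / 3, 2 / 3, 2 / 3))
  m2 <- matrix(c(0, 0, 9), ncol = 1, dimnames = list(c("a", "b", "c"), "s1"))
  expect_equal(as.numeric(hellinger_transform(m2)), c(0, 0, 1))
  zero <- matrix(c(1, 0), ncol = 2,
                 dimnames = list("a", c("ok", "empty")))
  expect_error(relative_abundance(zero), "empty")
  # unit-norm invariant on a generated table
  h <- hellinger_transform(generate_dataset(seed = 11)$table)
  expect_equal(unname(colSums(h^2)), rep(1, ncol(h)), tolerance = 1e-12)
})

test_that("Bray-Curtis matches the formula and its boundary cases", {
  m <- matrix(c(1, 1, 1, 3), nrow = 2,
              dimnames = list(c("a", "b"), c("s1", "s2")))
  bc <- bray_curtis_matrix(m)
  expect_equal(bc["s1", "s2"], 1 / 3)
  ident <- matrix(c(2, 5, 2, 5), nrow = 2,
                  dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_equal(bray_curtis_matrix(ident)["s1", "s2"], 0)
  disj <- matrix(c(2, 0, 0, 2), nrow = 2,
                 dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_equal(bray_curtis_matrix(disj)["s1", "s2"], 1)
})

test_that("Bray-Curtis agrees with a direct-formula oracle", {
  tab <- generate_dataset(synth_config(n_satellite = 8L), seed = 2)$table
  x <- tab$counts
  bc <- bray_curtis_matrix(tab)
  for (i in 1:3) for (j in 4:6) {
    expect_equal(bc[i, j],
                 sum(abs(x[, i] - x[, j])) / sum(x[, i] + x[, j]),
                 tolerance = 1e-12)
  }
  expect_true(all(abs(bc - t(bc)) < 1e-15))
  expect_true(all(diag(bc) == 0))
  expect_true(all(bc >= 0 & bc <= 1))
})

test_that("Jensen-Shannon divergence matches the entropy formula", {
  m <- matrix(c(1, 0, 1, 0), nrow = 2,
              dimnames = list(c("a", "b"), c("p", "q")))
  expect_equal(jensen_shannon_matrix(m)["p", "q"], 0)
  disj <- matrix(c(1, 0, 0, 1), nrow = 2,
                 dimnames = list(c("a", "b"), c("p", "q")))
  expect_equal(jensen_shannon_matrix(disj)["p", "q"], 1)
  # direct brute-force evaluation for P = (.5,.5), Q = (1,0), base 2:
  # M = (.75,.25); JSD = H(M) - (H(P)+H(Q))/2
  hm <- -(0.75 * log2(0.75) + 0.25 * log2(0.25))
  expected <- hm - (1 + 0) / 2
  mix <- matrix(c(1, 1, 2, 0), nrow = 2,
                dimnames = list(c("a", "b"), c("p", "q")))
  expect_equal(jensen_shannon_matrix(mix)["p", "q"], expected,
               tolerance = 1e-12)
  # base-2 values bounded in [0, 1] on a real-ish table
  j <- jensen_shannon_matrix(generate_dataset(seed = 4)$table)
  expect_true(all(j >= 0 & j <= 1))
  expect_equal(j, t(j))
})

test_that("PCoA reconstructs Euclidean-embeddable distances", {
  # colinear points 0, 1, 3 on a line
  pts <- c(0, 1, 3)
  d <- as.matrix(dist(pts)); dimnames(d) <- list(letters[1:3], letters[1:3])
  ord <- pcoa(d)
  rec <- as.matrix(dist(ord$coordinates))
  expect_equal(unname(rec), unname(d), tolerance = 1e-9)
  # equilateral configuration: two equal positive eigenvalues
  eq <- matrix(1, 3, 3) - diag(3)
  dimnames(eq) <- list(letters[1:3], letters[1:3])
  oeq <- pcoa(eq)
  pos <- oeq$eigenvalues[oeq$eigenvalues > 1e-10]
  expect_equal(pos[1], pos[2], tolerance = 1e-10)
  # random Euclidean cloud reconstructs within 1e-8
  set.seed(42)
  x <- matrix(rnorm(15 * 4), 15)
  d <- as.matrix(dist(x))
  dimnames(d) <- list(paste0("s", 1:15), paste0("s", 1:15))
  ord <- pcoa(d)
  expect_lt(max(abs(as.matrix(dist(ord$coordinates)) - d)), 1e-8)
  expect_true(all(diff(ord$eigenvalues) <= 1e-12))  # decreasing order
  expect_lte(sum(ord$proportion_explained), 1 + 1e-12)
  # cross-check coordinates against classical scaling in stats
  cmd <- stats::cmdscale(d, k = 4, eig = TRUE)
  expect_equal(abs(ord$coordinates[, 1:4]), abs(cmd$points),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("permdisp returns F = 0, p = 1 for mirror-image groups", {
  # two congruent triangles far apart: identical within-group geometry
  x <- rbind(c(0, 0), c(1, 0), c(0, 1),
             c(100, 100), c(101, 100), c(100, 101))
  d <- as.matrix(dist(x))
  dimnames(d) <- list(paste0("s", 1:6), paste0("s", 1:6))
  res <- permdisp(d, rep(c("g1", "g2"), each = 3), n_perm = 99, seed = 1)
  expect_equal(res$F, 0, tolerance = 1e-20)
  expect_equal(res$p_perm, 1)
})

test_that("permdisp matches vegan::betadisper's observed statistic", {
  nd <- null_dataset(n_samples = 24, seed = 8)
  d <- bray_curtis_matrix(nd$table)
  ours <- permdisp(d, nd$metadata$stage, n_perm = 9, seed = 1)
  bd <- vegan::betadisper(stats::as.dist(d), nd$metadata$stage,
                          type = "centroid")
  expect_equal(ours$F, stats::anova(bd)[1, "F value"], tolerance = 1e-10)
  expect_equal(unname(ours$group_distances), unname(bd$distances),
               tolerance = 1e-10)
})

test_that("permdisp is reproducible and validates its inputs", {
  nd <- null_dataset(n_samples = 12, n_taxa = 20, seed = 2)
  d <- bray_curtis_matrix(nd$table)
  g <- nd$metadata$stage
  a <- permdisp(d, g, n_perm = 49, seed = 7)
  b <- permdisp(d, g, n_perm = 49, seed = 7)
  expect_identical(a$p_perm, b$p_perm)
  expect_error(permdisp(d, g, n_perm = 49), "seed")
  expect_error(permdisp(d, rep("g1", 12), n_perm = 9, seed = 1), "2 groups")
  expect_error(permdisp(d, c("a", rep("b", 11)), n_perm = 9, seed = 1),
               "at least 2 samples")
})

test_that("spearman screen agrees with a rank-then-Pearson oracle", {
  set.seed(99)
  for (rep in 1:5) {
    m <- matrix(rnorm(8 * 10), 8,
                dimnames = list(paste0("t", 1:8), paste0("s", 1:10)))
    m[sample(length(m), 10)] <- m[sample(length(m), 10)]  # induce ties
    res <- spearman_screen(m, top_k = 8, alpha = 0.05)
    for (k in seq_len(nrow(res$pairs))) {
      a <- m[res$pairs$taxon_a[k], ]
      b <- m[res$pairs$taxon_b[k], ]
      oracle <- stats::cor(rank(a), rank(b))   # rank then Pearson
      expect_equal(res$pairs$rho[k], oracle, tolerance = 1e-12)
      n <- ncol(m)
      tt <- oracle * sqrt((n - 2) / (1 - oracle^2))
      expect_equal(res$pairs$p_raw[k],
                   2 * stats::pt(abs(tt), n - 2, lower.tail = FALSE),
                   tolerance = 1e-12)
    }
  }
})

test_that("spearman screen handles ties, constants, and ranking rules", {
  m <- rbind(up = 1:6, down = 6:1, const = rep(2, 6),
             noisy = c(2, 1, 4, 3, 6, 5))
  colnames(m) <- paste0("s", 1:6)
  res <- spearman_screen(m, top_k = 4, alpha = 0.05)
  pair <- res$pairs[res$pairs$taxon_a %in% c("down", "up") &
                    res$pairs$taxon_b %in% c("down", "up"), ]
  expect_equal(pair$rho, -1)
  expect_equal(pair$p_raw, 0)
  expect_match(res$diagnostics, "constant vector: const")
  expect_false("const" %in% c(res$pairs$taxon_a, res$pairs$taxon_b))
  # top_k ranking: totals descending, ties by taxon id
  m2 <- rbind(b = c(5, 5), a = c(5, 5), c = c(1, 1), d = c(9, 9))
  colnames(m2) <- c("s1", "s2")
  ord <- order(-rowSums(m2), rownames(m2))
  expect_identical(rownames(m2)[ord], c("d", "a", "b", "c"))
  expect_error(spearman_screen(m[, 1:3], top_k = 4), "4 samples")
})
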