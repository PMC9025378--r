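test_that("similarity rounding follows the chosen half convention", {
  d <- matrix(c(0, 1 / 3, 1 / 3, 0), 2,
              dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(to_similarity_matrix(d)["a", "b"], 67L)  # 66.67 rounds up
  half <- matrix(c(0, 0.125, 0.125, 0), 2,
                 dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(to_similarity_matrix(half, "half_up")["a", "b"], 88L)
  expect_equal(to_similarity_matrix(half, "half_even")["a", "b"], 88L)
  h2 <- matrix(c(0, 0.135, 0.135, 0), 2,
               dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(to_similarity_matrix(h2, "half_up")["a", "b"], 87L)
  expect_equal(to_similarity_matrix(h2, "half_even")["a", "b"], 86L)
  ident <- matrix(0, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(to_similarity_matrix(ident)["a", "b"], 100L)
  ones <- matrix(c(0, 1, 1, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(to_similarity_matrix(ones)["a", "b"], 0L)
  bad <- matrix(c(0, 1.2, 1.2, 0), 2,
                dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(to_similarity_matrix(bad), "normalized")
})

test_that("a pair with similarity exactly at the threshold is connected", {
  s <- matrix(c(100L, 33L, 33L, 100L), 2,
              dimnames = list(c("t1", "t2"), c("t1", "t2")))
  g33 <- threshold_graph(s, 33)
  expect_equal(igraph::ecount(g33), 1)
  g34 <- threshold_graph(s, 34)
  expect_equal(igraph::ecount(g34), 0)
  expect_equal(igraph::vcount(g34), 2)  # isolated nodes retained
  expect_error(threshold_graph(s, 101), "0..100")
  # t = 0 yields the complete graph
  sim <- random_similarity(7, seed = 1)
  expect_equal(igraph::ecount(threshold_graph(sim, 0)), choose(7, 2))
})

test_that("threshold sweeps are nested and telescoping", {
  for (seed in 1:10) {
    n <- sample(4:12, 1)
    sim <- random_similarity(n, seed = seed)
    sw <- sweep_thresholds(sim)
    ec <- sw$edge_counts
    expect_equal(ec[1], choose(n, 2))
    expect_true(all(diff(ec) <= 0))
    # nesting checked on actual edge sets, not just counts
    for (t in seq(1, 100, by = 20)) {
      e_hi <- igraph::as_edgelist(sw$graphs[[t + 1]])
      e_lo <- igraph::as_edgelist(sw$graphs[[t]])
      key <- function(e) paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
      expect_true(all(key(e_hi) %in% key(e_lo)))
    }
    expect_equal(sum(ec[1:100] - ec[2:101]), ec[1] - ec[101])
  }
})

test_that("distance curves match hand-enumerated drops", {
  # n = 3, all off-diagonal similarities 50: all edges drop at t = 50
  s <- matrix(50L, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  diag(s) <- 100L
  sw <- sweep_thresholds(s)
  cons <- network_distance_curve(sw, "consecutive")
  expect_equal(unname(cons[["50"]]), 1)
  expect_equal(sum(cons), 1)  # the only drop
  frm <- network_distance_curve(sw, "from_initial")
  expect_equal(unname(frm[["50"]]), 0)
  expect_equal(unname(frm[["51"]]), 1)
  # constant 100 off-diagonal: identically zero curves
  s2 <- matrix(100L, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  sw2 <- sweep_thresholds(s2)
  expect_true(all(network_distance_curve(sw2, "consecutive") == 0))
  expect_true(all(network_distance_curve(sw2, "fragmentation") == 0))
  # telescoping conservation on random sweeps
  sim <- random_similarity(9, seed = 3)
  sw3 <- sweep_thresholds(sim)
  cons3 <- network_distance_curve(sw3, "consecutive")
  expect_equal(sum(cons3),
               (sw3$edge_counts[1] - sw3$edge_counts[101]) / choose(9, 2))
})

test_that("the critical network lands where the sweep fragments most", {
  # single off-diagonal value 70 everywhere: the unique jump
  s <- matrix(70L, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(s) <- 100L
  sw <- sweep_thresholds(s)
  cr <- find_critical_network(sw)
  expect_equal(cr$threshold, 70L)
  expect_equal(igraph::ecount(cr$graph), 0)
  cr2 <- find_critical_network(sw, "consecutive")
  expect_equal(cr2$threshold, 70L)
  # planted two-block matrix: the critical graph is exactly the two blocks
  b <- generate_block_similarity(seed = 17)
  swb <- sweep_thresholds(b$sim)
  crb <- find_critical_network(swb)
  expect_true(crb$threshold >= 49 && crb$threshold <= 93)
  comp <- igraph::components(crb$graph)
  expect_equal(comp$no, 2)
  split_blocks <- split(names(comp$membership), comp$membership)
  expect_setequal(unname(lapply(split_blocks, sort)),
                  unname(lapply(split(names(b$block_assignment),
                                      b$block_assignment), sort)))
  # monotone distinct values: consecutive argmax equals the oracle's
  set.seed(5)
  for (rep in 1:5) {
    sim <- random_similarity(8, seed = 100 + rep)
    swr <- sweep_thresholds(sim)
    crr <- find_critical_network(swr, "consecutive")
    drops <- swr$edge_counts[1:100] - swr$edge_counts[2:101]
    expect_equal(crr$threshold, which.max(drops) - 1L)
  }
  # degenerate sweep: flagged, t* = 0
  s2 <- matrix(100L, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  expect_warning(crd <- find_critical_network(sweep_thresholds(s2)),
                 "degenerate")
  expect_true(crd$degenerate)
  expect_equal(crd$threshold, 0L)
})

test_that("modularity partition matches the exhaustive oracle on two cliques", {
  # two disjoint 4-cliques
  edges <- NULL
  for (blk in list(letters[1:4], letters[5:8]))
    for (i in 1:3) for (j in (i + 1):4)
      edges <- rbind(edges, data.frame(from = blk[i], to = blk[j]))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  part <- modularity_partition(g)
  expect_equal(part$Q, 0.5, tolerance = 1e-12)
  expect_equal(length(unique(part$assignment)), 2)
  expect_equal(length(unique(part$assignment[letters[1:4]])), 1)
  # exhaustive oracle over all partitions of the 8 nodes
  best <- max(vapply(all_partitions(letters[1:8]),
                     function(p) modularity_oracle(edges, p), numeric(1)))
  expect_equal(part$Q, best, tolerance = 1e-12)
})

test_that("modularity handles complete, edgeless, and repeated runs", {
  full <- igraph::make_full_graph(5)
  igraph::V(full)$name <- letters[1:5]
  p <- modularity_partition(full)
  expect_equal(length(unique(p$assignment)), 1)
  expect_equal(p$Q, 0)
  empty <- igraph::make_empty_graph(n = 3, directed = FALSE)
  igraph::V(empty)$name <- letters[1:3]
  expect_warning(pe <- modularity_partition(empty), "edgeless")
  expect_equal(pe$Q, 0)
  expect_equal(length(unique(pe$assignment)), 3)
  # determinism under identical seed and input
  b <- generate_block_similarity(n_nodes = 12, seed = 2)
  g <- threshold_graph(b$sim, 60)
  p1 <- modularity_partition(g, "louvain", seed = 4)
  p2 <- modularity_partition(g, "louvain", seed = 4)
  expect_identical(p1$assignment, p2$assignment)
  expect_identical(p1$Q, p2$Q)
  # partition Q never worse than the trivial single community (Q = 0)
  expect_gte(p1$Q, 0)
})

test_that("graphs round-trip through GraphML and edge lists", {
  s <- matrix(c(100L, 80L, 10L, 80L, 100L, 90L, 10L, 90L, 100L), 3,
              dimnames = list(c("b", "a", "c"), c("b", "a", "c")))
  g <- threshold_graph(s, 50)
  part <- modularity_partition(g)
  path <- withr::local_tempfile(fileext = ".graphml")
  export_graph(g, path, partition = part)
  back <- igraph::read_graph(path, format = "graphml")
  expect_setequal(igraph::V(back)$name, c("a", "b", "c"))
  expect_identical(igraph::V(back)$name, sort(igraph::V(back)$name))
  expect_equal(igraph::ecount(back), igraph::ecount(g))
  expect_equal(sort(unique(igraph::V(back)$community)),
               sort(unique(unname(part$assignment))))
  # edge list: sorted rows, header only when edgeless
  tsv <- withr::local_tempfile(fileext = ".tsv")
  export_graph(g, tsv, format = "edgelist_tsv")
  ed <- utils::read.delim(tsv)
  expect_equal(nrow(ed), 2)
  expect_true(all(ed$from <= ed$to))
  empty <- threshold_graph(s, 100)
  export_graph(empty, tsv, format = "edgelist_tsv")
  expect_equal(length(readLines(tsv)), 1)  # header only
})
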