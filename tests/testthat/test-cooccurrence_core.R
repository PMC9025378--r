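test_that("incidence binarization respects the presence threshold", {
  counts <- matrix(c(0L, 1L, 4L, 5L), 2,
                   dimnames = list(c("a", "b"), c("s1", "s2")))
  tab <- abundance_table(counts)
  inc1 <- to_incidence(tab)
  expect_identical(as.vector(inc1$presence), c(FALSE, TRUE, TRUE, TRUE))
  inc5 <- to_incidence(tab, min_count = 5)
  expect_identical(as.vector(inc5$presence), c(FALSE, FALSE, FALSE, TRUE))
  expect_error(to_incidence(tab, min_count = 0))
})

test_that("co-occurrence edges are witnessed shared samples", {
  pres <- matrix(c(TRUE, TRUE, FALSE,
                   FALSE, TRUE, TRUE,
                   FALSE, FALSE, FALSE,
                   TRUE, FALSE, FALSE), nrow = 4, byrow = TRUE,
                 dimnames = list(c("A", "B", "zero", "C"),
                                 c("s1", "s2", "s3")))
  inc <- structure(list(presence = pres, min_count = 1L),
                   class = "incidence_table")
  g <- cooccurrence_graph(inc)
  expect_setequal(igraph::V(g)$name, c("A", "B", "C"))  # absent taxon dropped
  ed <- igraph::as_data_frame(g, "edges")
  expect_equal(nrow(ed), 2)  # A-B via s2, A-C via s1
  ab <- ed[(ed$from == "A" & ed$to == "B") | (ed$from == "B" & ed$to == "A"), ]
  expect_equal(ab$witnesses, "s2")
  expect_equal(ab$n_shared, 1)
  expect_error(cooccurrence_graph(inc, character(0)), "empty")
})

test_that("co-occurrence equals the union of per-sample cliques (oracle)", {
  for (seed in 1:20) {
    inc <- random_incidence(n_taxa = 12, n_samples = 6, p = 0.4, seed = seed)
    g <- cooccurrence_graph(inc)
    # oracle: brute-force pairwise intersection of occupancy sets
    pres <- inc$presence[rowSums(inc$presence) > 0, , drop = FALSE]
    taxa <- rownames(pres)
    want <- character(0)
    if (length(taxa) >= 2) {
      for (i in seq_along(taxa)[-length(taxa)])
        for (j in (i + 1):length(taxa))
          if (any(pres[i, ] & pres[j, ]))
            want <- c(want, paste(taxa[i], taxa[j]))
    }
    ed <- igraph::as_data_frame(g, "edges")
    got <- paste(pmin(ed$from, ed$to), pmax(ed$from, ed$to))
    expect_setequal(got, want)
  }
})

test_that("core membership follows the occupancy cutoff exactly", {
  pres <- matrix(c(rep(TRUE, 5),
                   c(TRUE, TRUE, TRUE, TRUE, FALSE),
                   rep(FALSE, 5)), nrow = 3, byrow = TRUE,
                 dimnames = list(c("ubiq", "partial", "absent"),
                                 paste0("s", 1:5)))
  inc <- structure(list(presence = pres, min_count = 1L),
                   class = "incidence_table")
  strict <- core_taxa(inc, paste0("s", 1:5))
  expect_identical(strict$members, "ubiq")
  relaxed <- core_taxa(inc, paste0("s", 1:5), occupancy_cutoff = 0.8)
  expect_setequal(relaxed$members, c("ubiq", "partial"))
  none <- core_taxa(inc, paste0("s", 1:5), occupancy_cutoff = 0.99)
  expect_identical(none$members, "ubiq")
  expect_equal(unname(strict$occupancy["partial"]), 0.8)
})

test_that("core extraction is monotone in cutoff and robust to sample removal", {
  inc <- random_incidence(30, 10, p = 0.7, seed = 9)
  s_all <- colnames(inc$presence)
  prev <- rownames(inc$presence)
  for (cut in c(0.2, 0.5, 0.8, 1.0)) {
    cs <- core_taxa(inc, s_all, cut)
    expect_true(all(cs$members %in% prev))  # monotone decreasing in cutoff
    prev <- cs$members
  }
  # removing a sample never shrinks the strict core
  full <- core_taxa(inc, s_all)$members
  for (drop in s_all[1:5]) {
    sub <- core_taxa(inc, setdiff(s_all, drop))$members
    expect_true(all(full %in% sub))
  }
})

test_that("the core-nesting theorem holds on random nested groups", {
  for (seed in 1:50) {
    inc <- random_incidence(n_taxa = 15, n_samples = 12, p = 0.6,
                            seed = 200 + seed)
    smp <- colnames(inc$presence)
    b <- with_seed(seed, sample(smp, sample(4:12, 1)))
    a <- with_seed(seed + 1, sample(b, sample(2:length(b), 1)))
    core_b <- core_taxa(inc, b)$members
    core_a <- core_taxa(inc, a)$members
    expect_true(all(core_b %in% core_a))
  }
})

test_that("hierarchical cores recover the planted truth and report nesting", {
  g <- generate_dataset(seed = 31)
  inc <- to_incidence(g$table)
  ch <- hierarchical_cores(inc, g$hierarchy)
  expect_equal(nrow(ch$nesting_report), 0)
  for (nm in names(ch$cores))
    expect_setequal(ch$cores[[nm]]$members, g$truth$planted_core[[nm]])
  # the adult core strictly extends the all-sample core
  expect_true(all(ch$cores$all$members %in% ch$cores$adults$members))
  expect_gt(length(ch$cores$adults$members),
            length(ch$cores$all$members))
  # single-node hierarchy degenerates to core_taxa
  solo <- hierarchical_cores(inc, list(all = list(samples =
    colnames(inc$presence), parent = NULL)))
  expect_identical(solo$cores$all$members,
                   core_taxa(inc, colnames(inc$presence))$members)
  # malformed hierarchy: child not a subset of parent
  badh <- list(all = list(samples = c("C1", "C2"), parent = NULL),
               oops = list(samples = c("C1", "P1"), parent = "all"))
  expect_error(hierarchical_cores(inc, badh), "not a subset")
})

test_that("leaf samples can be pooled into tree-level units", {
  g <- generate_dataset(seed = 13)
  inc <- to_incidence(g$table)
  leaves <- g$metadata$sample_id[g$metadata$tree == "T1"]
  units <- list(T1 = leaves)
  agg <- aggregate_samples(inc, units)
  expect_identical(colnames(agg$presence), "T1")
  expect_identical(unname(agg$presence[, "T1"]),
                   unname(rowSums(inc$presence[, leaves]) > 0))
  expect_error(aggregate_samples(inc, list(a = leaves, b = leaves)),
               "disjoint")
})

test_that("the antagonism screen returns only significant negative pairs", {
  g <- generate_dataset(seed = 21)
  hel <- hellinger_transform(g$table)
  core <- g$truth$planted_core$all
  res <- antagonism_screen(hel, core, alpha = 0.05)
  expect_true(all(res$pairs$rho < 0))
  expect_true(all(res$pairs$p_raw < 0.05))
  expect_true(all(diff(res$pairs$rho) >= 0))  # sorted ascending
  pair_key <- paste(res$pairs$taxon_a, res$pairs$taxon_b)
  expect_true(paste(g$truth$antagonist_pairs$taxon_a[1],
                    g$truth$antagonist_pairs$taxon_b[1]) %in% pair_key ||
              paste(g$truth$antagonist_pairs$taxon_b[1],
                    g$truth$antagonist_pairs$taxon_a[1]) %in% pair_key)
  # a positively coupled pair is never returned
  m <- rbind(x = 1:8, y = 1:8 + 0.1, z = 8:1)
  colnames(m) <- paste0("s", 1:8)
  res2 <- antagonism_screen(m, c("x", "y"), alpha = 0.05)
  expect_equal(nrow(res2$pairs), 0)
  expect_error(antagonism_screen(m, c("x", "nope")), "unknown")
})
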