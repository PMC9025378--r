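# Small in-code fixtures shared across test files.

# 5 taxa x 3 samples with mixed taxonomy dialects
tiny_table <- function() {
  counts <- matrix(c(10L, 5L, 0L,
                     4L, 4L, 4L,
                     0L, 0L, 9L,
                     120L, 30L, 1L,
                     1L, 0L, 0L),
                   nrow = 5, byrow = TRUE,
                   dimnames = list(paste0("otu", 1:5),
                                   c("s1", "s2", "s3")))
  tax <- c("k__Fungi;p__Basidiomycota;g__Meira;s__Meira_sp1",
           "Ascomycota sp. 52-1",
           "k__Fungi;p__Ascomycota;g__Trichoderma",
           "Meyerozyma caribbica",
           "k__Fungi;p__Basidiomycota;o__Agaricales")
  abundance_table(counts, parse_taxonomy_table(rownames(counts), tax))
}

tiny_metadata <- function() {
  data.frame(sample_id = c("s1", "s2", "s3"),
             site = c("CNF", "CNF", "TNF"),
             stage = c("adult", "adult", "plantlet"),
             tree = c("t1", "t2", "t3"),
             leaf = NA_character_,
             stringsAsFactors = FALSE)
}

tiny_guild_db <- function() {
  validate_guild_db(data.frame(
    taxon = c("Meira", "Trichoderma", "Meyerozyma caribbica",
              "Meyerozyma", "Agaricales"),
    rank = c("genus", "genus", "species", "genus", "order"),
    trophic_mode = c("Pathotroph", "Saprotroph;Pathotroph", "Saprotroph",
                     "Symbiotroph", "Saprotroph"),
    guild = c("Animal Pathogen", "Mycoparasite", "Undefined Saprotroph",
              "Epiphyte", "Undefined Saprotroph"),
    confidence = "Probable",
    stringsAsFactors = FALSE))
}

# random integer similarity matrix (symmetric, diag 100)
random_similarity <- function(n, seed) {
  with_seed(seed, {
    s <- matrix(0L, n, n,
                dimnames = list(sprintf("v%02d", 1:n), sprintf("v%02d", 1:n)))
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      v <- sample(0:100, 1)
      s[i, j] <- s[j, i] <- v
    }
    diag(s) <- 100L
    s
  })
}

# random incidence table over given taxa/sample counts
random_incidence <- function(n_taxa, n_samples, p = 0.5, seed = 1) {
  with_seed(seed, {
    m <- matrix(runif(n_taxa * n_samples) < p, n_taxa, n_samples,
                dimnames = list(sprintf("t%03d", seq_len(n_taxa)),
                                sprintf("s%03d", seq_len(n_samples))))
    structure(list(presence = m, min_count = 1L), class = "incidence_table")
  })
}

# exhaustive set-partition enumerator (for the exact modularity oracle)
all_partitions <- function(items) {
  if (length(items) == 1L) return(list(list(items)))
  rest <- all_partitions(items[-1L])
  out <- list()
  for (p in rest) {
    for (i in seq_along(p)) {
      q <- p
      q[[i]] <- c(items[1L], q[[i]])
      out[[length(out) + 1L]] <- q
    }
    out[[length(out) + 1L]] <- c(list(items[1L]), p)
  }
  out
}

# Newman-Girvan modularity of a partition, straight from the definition
modularity_oracle <- function(edges, partition) {
  m <- nrow(edges)
  comm <- stats::setNames(rep(seq_along(partition), lengths(partition)),
                          unlist(partition))
  q <- 0
  for (c_id in seq_along(partition)) {
    within <- sum(comm[edges$from] == c_id & comm[edges$to] == c_id)
    deg <- sum(edges$from %in% partition[[c_id]]) +
      sum(edges$to %in% partition[[c_id]])
    q <- q + within / m - (deg / (2 * m))^2
  }
  q
}
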