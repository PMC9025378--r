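# Synthetic phyllosphere communities with planted, recoverable structure:
# hierarchical strict cores, an antagonist taxon trio, a stage-dependent
# dominance shift, low-occupancy satellites, and block-structured
# similarity matrices. The generator emulates a two-site study design with
# adult trees (one of them sampled leaf-by-leaf) and plantlets; reads are
# drawn by multinomial sampling at fixed depth over log-normal relative
# abundances, so every column sum equals the configured depth.

#' Generator configuration
#'
#' Defaults encode the emulated study design: two sites, five adult trees
#' per site with one tree sequenced as five separate leaves, five
#' plantlets (second site only), 50,000 reads per sample, three
#' always-present core taxa (one placeholder-named focal taxon and two
#' basidiomycete yeast partners planted as antagonists at target Spearman
#' rho -0.60 and -0.54), extra adult/site/plantlet cores, a 4-taxon group
#' with 8-fold read enrichment in plantlets, and 60 low-occupancy
#' satellite taxa. Trophic modes are planted at 55% saprotroph, 10%
#' pathotroph, 2% symbiotroph (the rest unassigned).
#'
#' @param ... overrides for any default field.
#' @return `synth_config` list.
#' @export
synth_config <- function(...) {
  cfg <- list(
    sites = c("CNF", "TNF"),
    trees_per_site = 5L,
    leaves_intra = 5L,     # leaves of the one intra-individually sampled tree
    plantlets = 5L,        # plantlets at the second site
    depth = 50000L,
    n_core_all = 3L,
    n_core_adults = 2L,
    n_core_site = 1L,      # per site-adults node
    n_core_plantlets = 1L,
    n_shift = 4L,          # stage-shift (plantlet-enriched) taxa
    n_satellite = 60L,
    satellite_presence_prob = 0.35,
    core_presence_prob = 0.4,   # presence outside a core taxon's home node
    shift_presence_prob = 0.8,
    meanlog_core = log(0.05),
    meanlog_shift = log(0.012),
    meanlog_satellite = log(0.002),
    sdlog_taxon = 1.0,
    sdlog_sample = 0.6,
    antagonist_scale = 2.0,     # latent factor scale s (log scale)
    antagonist_noise_focal = 0.3,
    antagonist_noise_partner = c(0.38, 0.60),  # per partner, sets target rho
    antagonist_target_rho = c(-0.60, -0.54),
    plantlet_fold = 8,
    mode_fractions = c(saprotroph = 0.55, pathotroph = 0.10,
                       symbiotroph = 0.02))
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "synth_config")
}

.synth_metadata <- function(cfg) {
  s1 <- cfg$sites[1]; s2 <- cfg$sites[2]
  rows <- list()
  for (i in seq_len(cfg$trees_per_site))
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = paste0("C", i), site = s1, stage = "adult",
      tree = paste0("C", i), leaf = NA_character_)
  for (i in seq_len(cfg$trees_per_site)) {
    if (i == 1L && cfg$leaves_intra >= 2L) {
      for (l in seq_len(cfg$leaves_intra))
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = paste0("T1_L", l), site = s2, stage = "adult",
          tree = "T1", leaf = paste0("L", l))
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = paste0("T", i), site = s2, stage = "adult",
        tree = paste0("T", i), leaf = NA_character_)
    }
  }
  for (i in seq_len(cfg$plantlets))
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = paste0("P", i), site = s2, stage = "plantlet",
      tree = paste0("P", i), leaf = NA_character_)
  do.call(rbind, rows)
}

#' Default sampling hierarchy from metadata
#'
#' all > adults > (one node per site's adults); all > plantlets. Nodes
#' with no samples are dropped.
#'
#' @param meta metadata data.frame (`sample_id`, `site`, `stage`).
#' @return Named list of `list(samples, parent)` nodes.
#' @export
default_hierarchy <- function(meta) {
  h <- list(all = list(samples = meta$sample_id, parent = NULL))
  ad <- meta$sample_id[meta$stage == "adult"]
  pl <- meta$sample_id[meta$stage == "plantlet"]
  if (length(ad)) h$adults <- list(samples = ad, parent = "all")
  if (length(pl)) h$plantlets <- list(samples = pl, parent = "all")
  for (s in unique(meta$site)) {
    ss <- meta$sample_id[meta$site == s & meta$stage == "adult"]
    if (length(ss) && length(ad))
      h[[paste0(tolower(s), "_adults")]] <-
        list(samples = ss, parent = "adults")
  }
  h
}

# nodes whose sample set is NOT contained in `home_samples`; presence of a
# taxon homed at `home` must miss at least one sample of each of them
.guard_presence <- function(pres, hierarchy, home_samples, sample_names) {
  for (nm in names(hierarchy)) {
    ns <- hierarchy[[nm]]$samples
    outside <- setdiff(ns, home_samples)
    if (!length(outside)) next          # node inside the home: keep covered
    if (all(pres[match(ns, sample_names)])) {
      drop <- if (length(outside) == 1L) outside else sample(outside, 1L)
      pres[match(drop, sample_names)] <- FALSE
    }
  }
  pres
}

.mode_pool <- function(fracs) c(names(fracs), "unassigned")

#' Generate a synthetic dataset with planted structure
#'
#' Draws a full (abundance table, metadata, guild table, truth record)
#' quadruple. Planted core taxa are present (>= 1 read) in every sample of
#' their hierarchy node by construction (the multinomial draw is rejected
#' and resampled until satisfied); every other taxon is guarded to miss at
#' least one sample of every node, so the planted cores are exactly the
#' strict cores. The antagonist trio shares one latent factor with opposed
#' signs, calibrated to the configured target Spearman correlations.
#'
#' @param config a [synth_config()].
#' @param seed integer seed; the same seed reproduces the dataset exactly.
#' @return List: `table` (`abundance_table`), `metadata`, `guild_db`,
#'   `truth` (`synthetic_truth`), `hierarchy`.
#' @export
generate_dataset <- function(config = synth_config(), seed) {
  if (missing(seed) || is.null(seed)) stop("generate_dataset requires a seed")
  cfg <- config
  meta <- .synth_metadata(cfg)
  hierarchy <- default_hierarchy(meta)
  n_s <- nrow(meta)
  smp <- meta$sample_id

  n_core <- cfg$n_core_all + cfg$n_core_adults +
    2L * cfg$n_core_site + cfg$n_core_plantlets
  n_taxa <- n_core + cfg$n_shift + cfg$n_satellite
  if (n_core > n_taxa) stop("infeasible config: more core taxa than taxa")
  if (cfg$n_core_all < 3L)
    stop("need at least 3 all-sample core taxa (focal + 2 partners)")

  with_seed(seed, {
    site_nodes <- paste0(tolower(cfg$sites), "_adults")
    # --- taxon roster: id, home node, taxonomy ---------------------------
    ids <- character(0); home <- character(0); taxonomy <- character(0)
    add <- function(id, hm, tax) {
      ids <<- c(ids, id); home <<- c(home, hm); taxonomy <<- c(taxonomy, tax)
    }
    add("otu_0001", "all", "Ascomycota sp. 52-1")   # focal, SBFS-like
    add("otu_0002", "all",
        paste0("k__Fungi;p__Basidiomycota;c__Exobasidiomycetes;",
               "o__Exobasidiales;f__Brachybasidiaceae;g__Meira;s__Meira_sp1"))
    add("otu_0003", "all",
        paste0("k__Fungi;p__Basidiomycota;c__Exobasidiomycetes;",
               "o__Exobasidiales;f__Brachybasidiaceae;g__Meira;s__Meira_sp2"))
    k <- 3L
    while (k < cfg$n_core_all) {
      k <- k + 1L
      add(sprintf("otu_%04d", k), "all",
          sprintf("k__Fungi;p__Basidiomycota;g__Coreogen%02d", k))
    }
    for (i in seq_len(cfg$n_core_adults)) {
      k <- k + 1L
      tax <- if (i == 1L)
        paste0("k__Fungi;p__Basidiomycota;c__Exobasidiomycetes;",
               "o__Microstromatales;g__Sympodiomycopsis")
      else paste0("k__Fungi;p__Basidiomycota;o__Exobasidiales;",
                  "g__Meira;s__Meira_sp", i + 1)
      add(sprintf("otu_%04d", k), "adults", tax)
    }
    for (j in seq_along(site_nodes)) for (i in seq_len(cfg$n_core_site)) {
      k <- k + 1L
      tax <- if (j == 1L) "k__Fungi;p__Ascomycota;g__Meyerozyma"
             else sprintf("k__Fungi;p__Ascomycota;g__Sitegen%02d", i)
      add(sprintf("otu_%04d", k), site_nodes[j], tax)
    }
    for (i in seq_len(cfg$n_core_plantlets)) {
      k <- k + 1L
      add(sprintf("otu_%04d", k), "plantlets", sprintf("Ascomycota sp. %d", 20 + i))
    }
    for (i in seq_len(cfg$n_shift)) {
      k <- k + 1L
      add(sprintf("otu_%04d", k), NA_character_,
          sprintf(paste0("k__Fungi;p__Basidiomycota;c__Exobasidiomycetes;",
                         "o__Exobasidiales;f__Exobasidiaceae;g__Shiftgen%02d"), i))
    }
    placeholder <- stats::runif(cfg$n_satellite) < 0.15
    for (i in seq_len(cfg$n_satellite)) {
      k <- k + 1L
      tax <- if (placeholder[i]) sprintf("Ascomycota sp. %d", 100 + i)
             else sprintf("k__Fungi;p__%s;g__Satgen%03d",
                          if (i %% 2) "Ascomycota" else "Basidiomycota", i)
      add(sprintf("otu_%04d", k), NA_character_, tax)
    }
    is_shift <- grepl("g__Shiftgen", taxonomy)
    shift_taxa <- ids[is_shift]

    # --- presence masks --------------------------------------------------
    pres <- matrix(FALSE, n_taxa, n_s, dimnames = list(ids, smp))
    for (t in seq_len(n_taxa)) {
      hm <- home[t]
      if (!is.na(hm)) {
        hs <- hierarchy[[hm]]$samples
        p <- rep(FALSE, n_s)
        p[match(hs, smp)] <- TRUE
        out <- setdiff(smp, hs)
        p[match(out, smp)] <- stats::runif(length(out)) < cfg$core_presence_prob
        pres[t, ] <- .guard_presence(p, hierarchy, hs, smp)
      } else {
        pp <- if (is_shift[t]) cfg$shift_presence_prob
              else cfg$satellite_presence_prob
        p <- stats::runif(n_s) < pp
        if (!any(p)) p[sample.int(n_s, 1L)] <- TRUE
        pres[t, ] <- .guard_presence(p, hierarchy, character(0), smp)
      }
    }

    # --- log relative abundances ----------------------------------------
    mu <- numeric(n_taxa)
    mu[!is.na(home)] <- stats::rnorm(sum(!is.na(home)), cfg$meanlog_core, 0.3)
    mu[is_shift] <- stats::rnorm(sum(is_shift), cfg$meanlog_shift, 0.3)
    sat <- is.na(home) & !is_shift
    mu[sat] <- stats::rnorm(sum(sat), cfg$meanlog_satellite, cfg$sdlog_taxon)
    eps <- matrix(stats::rnorm(n_taxa * n_s, 0, cfg$sdlog_sample), n_taxa, n_s)
    z <- stats::qnorm(stats::runif(n_s))      # shared latent factor
    s <- cfg$antagonist_scale / sqrt(12)      # matches Var(sU) of a uniform
    eps[1L, ] <- s * z + stats::rnorm(n_s, 0, cfg$antagonist_noise_focal)
    eps[2L, ] <- -s * z +
      stats::rnorm(n_s, 0, cfg$antagonist_noise_partner[1])
    eps[3L, ] <- -s * z +
      stats::rnorm(n_s, 0, cfg$antagonist_noise_partner[2])
    lam <- exp(mu + eps)
    plantlet_cols <- meta$stage == "plantlet"
    lam[is_shift, plantlet_cols] <- lam[is_shift, plantlet_cols] *
      cfg$plantlet_fold
    lam[!pres] <- 0

    # --- multinomial reads, planted cores forced present -----------------
    counts <- matrix(0L, n_taxa, n_s, dimnames = list(ids, smp))
    for (j in seq_len(n_s)) {
      pj <- lam[, j] / sum(lam[, j])
      need <- which(!is.na(home) &
                      vapply(home, function(hm)
                        !is.na(hm) && smp[j] %in% hierarchy[[hm]]$samples,
                        logical(1)))
      for (try in seq_len(1000L)) {
        cj <- stats::rmultinom(1L, cfg$depth, pj)[, 1L]
        if (all(cj[need] > 0L)) break
        if (try == 1000L) stop("could not satisfy planted presence; ",
                               "raise depth or core abundance")
      }
      counts[, j] <- cj
    }

    # --- trophic modes and guild table ----------------------------------
    genus <- vapply(taxonomy, function(x) parse_taxonomy(x)$genus,
                    character(1), USE.NAMES = FALSE)
    pool <- .mode_pool(cfg$mode_fractions)
    # placeholder-named taxa can never be matched, so they count towards
    # the unassigned mass; upweight the assignable taxa's mode
    # probabilities so the planted fractions hold for the whole community
    n_ph <- sum(is.na(genus))
    upw <- n_taxa / max(n_taxa - n_ph, 1L)
    fr <- pmin(cfg$mode_fractions * upw, 1)
    if (sum(fr) >= 1)
      stop("infeasible config: mode fractions plus placeholder mass exceed 1")
    probs <- c(fr, 1 - sum(fr))
    draw <- sample(pool, n_taxa, replace = TRUE, prob = probs)
    # placeholders cannot be matched; genera share the first-drawn mode so
    # the realized per-taxon modes in the truth record are exactly what
    # guild matching recovers
    mode_by_genus <- list()
    taxon_mode <- character(n_taxa)
    for (t in seq_len(n_taxa)) {
      if (is.na(genus[t])) { taxon_mode[t] <- "unassigned"; next }
      g <- genus[t]
      if (is.null(mode_by_genus[[g]])) mode_by_genus[[g]] <- draw[t]
      taxon_mode[t] <- mode_by_genus[[g]]
    }
    assigned <- Filter(function(m) m != "unassigned", mode_by_genus)
    modes_chr <- unlist(assigned, use.names = FALSE)
    gdf <- data.frame(taxon = names(assigned),
                      rank = "genus",
                      trophic_mode = tools::toTitleCase(modes_chr),
                      guild = paste0("Undefined ",
                                     tools::toTitleCase(modes_chr)),
                      confidence = "Probable",
                      stringsAsFactors = FALSE)
    guild_db <- validate_guild_db(gdf)

    # --- assemble --------------------------------------------------------
    table <- abundance_table(counts, parse_taxonomy_table(ids, taxonomy))
    ancestors <- function(nm) {
      out <- nm
      while (!is.null(hierarchy[[nm]]$parent) &&
             !is.na(hierarchy[[nm]]$parent)) {
        nm <- hierarchy[[nm]]$parent
        out <- c(out, nm)
      }
      out
    }
    planted_core <- lapply(names(hierarchy), function(nm)
      ids[!is.na(home) & home %in% ancestors(nm)])
    names(planted_core) <- names(hierarchy)
    truth <- structure(list(
      planted_core = planted_core,
      antagonist_pairs = data.frame(
        taxon_a = ids[1L], taxon_b = ids[2:3],
        target_rho = cfg$antagonist_target_rho,
        stringsAsFactors = FALSE),
      stage_shift = list(taxa = shift_taxa, fold = cfg$plantlet_fold,
                         stage = "plantlet"),
      mode_fractions = cfg$mode_fractions,
      taxon_modes = stats::setNames(taxon_mode, ids),
      block_structure = NULL,
      seed = seed),
      class = "synthetic_truth")
    list(table = table, metadata = validate_metadata(meta),
         guild_db = guild_db, truth = truth, hierarchy = hierarchy)
  })
}

#' Generate a block-structured integer similarity matrix
#'
#' Similarities are drawn uniformly from `within_range` for same-block
#' pairs and `between_range` for cross-block pairs; the ranges must not
#' overlap, which plants an unambiguous threshold gap for critical-network
#' recovery tests.
#'
#' @param n_nodes number of nodes.
#' @param blocks number of blocks (balanced assignment).
#' @param within_range integer `c(lo, hi)` for same-block similarities.
#' @param between_range integer `c(lo, hi)` for cross-block similarities.
#' @param seed integer seed.
#' @return List: `sim` (integer similarity matrix), `block_assignment`
#'   (named block id per node).
#' @export
generate_block_similarity <- function(n_nodes = 10L, blocks = 2L,
                                      within_range = c(94L, 96L),
                                      between_range = c(49L, 51L),
                                      seed) {
  if (missing(seed)) stop("generate_block_similarity requires a seed")
  stopifnot(n_nodes >= 2L, blocks >= 1L, blocks <= n_nodes)
  wr <- sort(as.integer(within_range)); br <- sort(as.integer(between_range))
  if (blocks > 1L && wr[1] <= br[2] && br[1] <= wr[2])
    stop("within_range and between_range must not overlap")
  if (any(c(wr, br) < 0L) || any(c(wr, br) > 100L))
    stop("similarity ranges must lie in [0, 100]")
  labels <- sprintf("n%02d", seq_len(n_nodes))
  blk <- stats::setNames(sort(rep_len(seq_len(blocks), n_nodes)), labels)
  with_seed(seed, {
    s <- matrix(0L, n_nodes, n_nodes, dimnames = list(labels, labels))
    for (i in seq_len(n_nodes - 1L)) for (j in (i + 1L):n_nodes) {
      r <- if (blk[i] == blk[j]) wr else br
      v <- sample(seq(r[1], r[2]), 1L)
      s[i, j] <- s[j, i] <- v
    }
    diag(s) <- 100L
    list(sim = s, block_assignment = blk)
  })
}

#' Generate a structureless null dataset
#'
#' All samples are exchangeable: no group effects, no planted
#' correlations, no presence structure. The group labels carried in the
#' metadata are arbitrary splits for calibration runs (permutation-test
#' size, correlation false-positive rate).
#'
#' @param n_samples number of samples (split into `n_groups` stages).
#' @param n_taxa number of taxa.
#' @param depth reads per sample.
#' @param sdlog_taxon spread of log mean relative abundances.
#' @param sdlog_sample per-sample log-normal noise.
#' @param n_groups number of exchangeable groups (default 2).
#' @param seed integer seed.
#' @return List: `table`, `metadata`.
#' @export
null_dataset <- function(n_samples = 30L, n_taxa = 60L, depth = 10000L,
                         sdlog_taxon = 1.0, sdlog_sample = 0.5,
                         n_groups = 2L, seed) {
  if (missing(seed)) stop("null_dataset requires a seed")
  stopifnot(n_samples >= 2L * n_groups)
  smp <- sprintf("s%03d", seq_len(n_samples))
  ids <- sprintf("otu_%04d", seq_len(n_taxa))
  with_seed(seed, {
    mu <- stats::rnorm(n_taxa, log(1 / n_taxa), sdlog_taxon)
    lam <- exp(mu + matrix(stats::rnorm(n_taxa * n_samples, 0, sdlog_sample),
                           n_taxa, n_samples))
    counts <- vapply(seq_len(n_samples), function(j)
      stats::rmultinom(1L, depth, lam[, j] / sum(lam[, j]))[, 1L],
      integer(n_taxa))
    dimnames(counts) <- list(ids, smp)
    meta <- data.frame(sample_id = smp, site = "S1",
                       stage = rep(c("adult", "plantlet"),
                                   each = ceiling(n_samples / 2),
                                   length.out = n_samples),
                       tree = smp, leaf = NA_character_,
                       stringsAsFactors = FALSE)
    list(table = abundance_table(counts), metadata = validate_metadata(meta))
  })
}

#' Serialize a synthetic truth record to JSON
#'
#' @param truth a `synthetic_truth`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(
    list(planted_core = truth$planted_core,
         antagonist_pairs = truth$antagonist_pairs,
         stage_shift = truth$stage_shift,
         mode_fractions = as.list(truth$mode_fractions),
         taxon_modes = as.list(truth$taxon_modes),
         seed = truth$seed),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a synthetic truth record back from JSON
#'
#' @param path JSON file written by [write_truth_json()].
#' @return A `synthetic_truth` equivalent to the serialized one.
#' @export
read_truth_json <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  structure(list(
    planted_core = lapply(x$planted_core, as.character),
    antagonist_pairs = as.data.frame(x$antagonist_pairs,
                                     stringsAsFactors = FALSE),
    stage_shift = list(taxa = as.character(x$stage_shift$taxa),
                       fold = x$stage_shift$fold,
                       stage = x$stage_shift$stage),
    mode_fractions = unlist(x$mode_fractions),
    taxon_modes = unlist(x$taxon_modes),
    block_structure = NULL,
    seed = x$seed), class = "synthetic_truth")
}
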