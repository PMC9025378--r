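# End-to-end orchestration: validate a configuration, run every stage in
# order, and write a deterministic report bundle (TSV tables, GraphML
# graphs, a JSON config snapshot and a run log). Reruns under an identical
# configuration produce byte-identical TSV outputs.

#' Pipeline configuration
#'
#' Either point `table`/`metadata`/`guild_db` at TSV files (or pass the
#' objects directly), or set `synthetic = TRUE` to run on a generated
#' dataset. Seeds are mandatory for every stochastic stage and are
#' validated before any computation.
#'
#' @param out_dir output directory for the report bundle.
#' @param table,metadata,guild_db input TSV paths or in-memory objects
#'   (ignored when `synthetic` is TRUE).
#' @param synthetic run on a generated dataset instead of files.
#' @param synth_seed seed for the generator (required when synthetic).
#' @param synth_config a [synth_config()] for the generator.
#' @param occupancy_cutoff core occupancy cutoff in (0, 1].
#' @param min_count presence threshold in reads.
#' @param group_by metadata column defining the PERMDISP groups.
#' @param representation Bray-Curtis input: `"raw"` or `"hellinger"`.
#' @param rounding similarity rounding: `"half_up"` or `"half_even"`.
#' @param distance_method critical-network curve method.
#' @param permdisp_n_perm,permdisp_seed PERMDISP settings (seed required).
#' @param top_k,alpha,adjust correlation-screen settings.
#' @param modularity_seed seed for community detection.
#' @return `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir,
                            table = NULL, metadata = NULL, guild_db = NULL,
                            synthetic = FALSE, synth_seed = NULL,
                            synth_config = phyllocore::synth_config(),
                            occupancy_cutoff = 1.0,
                            min_count = 1L,
                            group_by = "stage",
                            representation = "raw",
                            rounding = "half_up",
                            distance_method = "fragmentation",
                            permdisp_n_perm = 999L,
                            permdisp_seed = NULL,
                            top_k = 100L,
                            alpha = 0.01,
                            adjust = "none",
                            modularity_seed = 1L) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Validate a pipeline configuration
#'
#' Checks seeds and input paths before any stage runs, so misconfiguration
#' fails fast.
#'
#' @param cfg a `pipeline_config`.
#' @return `cfg`, invisibly.
#' @export
validate_pipeline_config <- function(cfg) {
  if (is.null(cfg$permdisp_seed))
    stop("validation error: permdisp_seed is required")
  if (cfg$synthetic) {
    if (is.null(cfg$synth_seed))
      stop("validation error: synth_seed is required for synthetic runs")
  } else {
    for (f in c("table", "metadata")) {
      v <- cfg[[f]]
      if (is.null(v))
        stop("validation error: '", f, "' input is required")
      if (is.character(v) && !file.exists(v))
        stop("validation error: ", f, " file not found: ", v)
    }
    if (is.character(cfg$guild_db) && !file.exists(cfg$guild_db))
      stop("validation error: guild_db file not found: ", cfg$guild_db)
  }
  stopifnot(cfg$occupancy_cutoff > 0, cfg$occupancy_cutoff <= 1,
            cfg$min_count >= 1, cfg$permdisp_n_perm >= 1)
  invisible(cfg)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Per-group composition summary at a taxonomic rank
#'
#' For every group, three proportion vectors over the rank values present
#' (plus `"unknown"`): share of taxa, share of reads, and share of
#' incidence (presence/absence occurrences). Each vector sums to 1.
#'
#' @param table an `abundance_table`.
#' @param metadata covering metadata.
#' @param rank one of the seven ranks or `"otu"`.
#' @param group_by metadata column defining groups.
#' @return data.frame: `group`, `rank_value`, `taxa_share`, `read_share`,
#'   `incidence_share`.
#' @export
summarize_composition <- function(table, metadata, rank = "phylum",
                                  group_by = "stage") {
  stopifnot(rank %in% c(TAXONOMY_RANKS, "otu"))
  check_metadata_covers(table, metadata)
  lab <- if (rank == "otu") taxon_ids(table) else table$taxonomy[[rank]]
  lab[is.na(lab)] <- "unknown"
  meta <- metadata[match(sample_ids(table), metadata$sample_id), ]
  out <- lapply(unique(meta[[group_by]]), function(g) {
    sub <- table$counts[, meta[[group_by]] == g, drop = FALSE]
    keep <- rowSums(sub) > 0
    tx <- tapply(rep(1, sum(keep)), lab[keep], sum)
    rd <- tapply(rowSums(sub)[keep], lab[keep], sum)
    inc <- tapply(rowSums(sub[keep, , drop = FALSE] > 0), lab[keep], sum)
    vals <- sort(names(tx))
    data.frame(group = g, rank_value = vals,
               taxa_share = as.numeric(tx[vals] / sum(tx)),
               read_share = as.numeric(rd[vals] / sum(rd)),
               incidence_share = as.numeric(inc[vals] / sum(inc)),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Run the full analysis pipeline
#'
#' Stage order: load/generate inputs, composition summaries, Hellinger +
#' dissimilarities + PCoA, PERMDISP, similarity threshold sweep with
#' critical-network selection and modularity, per-group co-occurrence
#' graphs, hierarchical strict cores, antagonism screen over the core
#' candidates, guild assignment with trophic profiles, and Venn set
#' algebra over the group cores. Everything is written under
#' `cfg$out_dir`; the run log records options, seeds and a config hash.
#' Deterministic given the configuration (including seeds).
#'
#' @param cfg a validated [pipeline_config()].
#' @return `report_bundle`: the in-memory stage results plus `files`, the
#'   named vector of written paths.
#' @export
run_pipeline <- function(cfg) {
  validate_pipeline_config(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  put <- function(name, path) files[[name]] <<- path

  # --- inputs ------------------------------------------------------------
  truth <- NULL
  if (cfg$synthetic) {
    gen <- .stage("generate", generate_dataset(cfg$synth_config,
                                               seed = cfg$synth_seed))
    table <- gen$table; metadata <- gen$metadata
    guild_db <- gen$guild_db; hierarchy <- gen$hierarchy
    truth <- gen$truth
    put("truth", write_truth_json(truth, file.path(cfg$out_dir,
                                                   "truth.json")))
  } else {
    table <- .stage("read_table", if (is.character(cfg$table))
      read_abundance_table(cfg$table) else cfg$table)
    metadata <- .stage("read_metadata", if (is.character(cfg$metadata))
      read_metadata(cfg$metadata) else validate_metadata(cfg$metadata))
    guild_db <- .stage("read_guild_db", if (is.character(cfg$guild_db))
      read_guild_db(cfg$guild_db) else cfg$guild_db)
    hierarchy <- default_hierarchy(metadata)
  }
  .stage("metadata_join", check_metadata_covers(table, metadata))

  # --- composition summaries ---------------------------------------------
  comp <- .stage("composition", do.call(rbind, lapply(
    c("phylum", "order", "genus"), function(r) {
      cbind(rank = r, summarize_composition(table, metadata, r,
                                            cfg$group_by))
    })))
  put("composition", .write_tsv(comp,
                                file.path(cfg$out_dir, "composition.tsv")))

  # --- diversity ---------------------------------------------------------
  hel <- .stage("hellinger", hellinger_transform(table))
  bc <- .stage("bray_curtis", bray_curtis_matrix(table,
                                                 cfg$representation))
  jsd <- .stage("jsd", jensen_shannon_matrix(table))
  put("distance_bc", write_square_tsv(bc,
                                      file.path(cfg$out_dir,
                                                "distance_bray_curtis.tsv")))
  put("distance_jsd", write_square_tsv(jsd,
                                       file.path(cfg$out_dir,
                                                 "distance_jsd.tsv")))
  ord <- .stage("pcoa", pcoa(jsd))
  coords <- data.frame(sample_id = rownames(ord$coordinates),
                       ord$coordinates, check.names = FALSE)
  put("pcoa", .write_tsv(coords, file.path(cfg$out_dir,
                                           "pcoa_coordinates.tsv")))
  groups <- metadata[[cfg$group_by]][match(sample_ids(table),
                                           metadata$sample_id)]
  disp <- .stage("permdisp", permdisp(jsd, groups,
                                      n_perm = cfg$permdisp_n_perm,
                                      seed = cfg$permdisp_seed))
  put("permdisp", .write_tsv(
    data.frame(F = disp$F, p_perm = disp$p_perm, n_perm = disp$n_perm,
               seed = disp$seed, group_by = cfg$group_by),
    file.path(cfg$out_dir, "permdisp.tsv")))

  # --- similarity network ------------------------------------------------
  sim <- .stage("similarity", to_similarity_matrix(bc, cfg$rounding))
  put("similarity", write_square_tsv(sim,
                                     file.path(cfg$out_dir,
                                               "similarity_matrix.tsv")))
  sweep <- .stage("sweep", sweep_thresholds(sim))
  crit <- .stage("critical", find_critical_network(sweep,
                                                   cfg$distance_method))
  put("distance_curve", .write_tsv(
    data.frame(threshold = as.integer(names(crit$curve)),
               distance = as.numeric(crit$curve)),
    file.path(cfg$out_dir, "distance_curve.tsv")))
  part <- .stage("modularity", if (igraph::ecount(crit$graph) > 0)
    modularity_partition(crit$graph, seed = cfg$modularity_seed)
    else suppressWarnings(modularity_partition(crit$graph,
                                               seed = cfg$modularity_seed)))
  put("critical_summary", .write_tsv(
    data.frame(critical_threshold = crit$threshold,
               graph_threshold = crit$graph_threshold,
               method = crit$method,
               n_edges = igraph::ecount(crit$graph),
               n_modules = length(unique(part$assignment)),
               modularity_Q = part$Q),
    file.path(cfg$out_dir, "critical_network.tsv")))
  export_graph(crit$graph, file.path(cfg$out_dir, "critical_network.graphml"),
               partition = part, format = "graphml")
  put("critical_graphml", file.path(cfg$out_dir, "critical_network.graphml"))

  # --- co-occurrence and cores -------------------------------------------
  inc <- .stage("incidence", to_incidence(table, cfg$min_count))
  leaf_nodes <- names(hierarchy)[!names(hierarchy) %in%
                                   unlist(lapply(hierarchy, `[[`, "parent"))]
  for (nm in leaf_nodes) {
    g <- .stage(paste0("cooccurrence_", nm),
                cooccurrence_graph(inc, hierarchy[[nm]]$samples))
    p <- file.path(cfg$out_dir, paste0("cooccurrence_", nm, ".graphml"))
    export_graph(g, p, format = "graphml")
    put(paste0("cooccurrence_", nm), p)
  }
  cores <- .stage("cores", hierarchical_cores(inc, hierarchy,
                                              cfg$occupancy_cutoff))
  put("cores", write_core_tsv(cores, file.path(cfg$out_dir, "cores.tsv")))
  put("nesting_report", .write_tsv(cores$nesting_report,
                                   file.path(cfg$out_dir,
                                             "nesting_report.tsv")))

  # --- antagonism screen over the strict core ----------------------------
  candidates <- cores$cores[[1L]]$members
  antag <- NULL
  if (length(candidates) >= 2L) {
    antag <- .stage("antagonism",
                    antagonism_screen(hel, candidates, alpha = cfg$alpha,
                                      adjust = cfg$adjust))
    put("antagonism", write_correlation_tsv(antag,
                                            file.path(cfg$out_dir,
                                                      "antagonism.tsv")))
  }
  screen <- .stage("spearman_screen",
                   spearman_screen(hel, top_k = cfg$top_k,
                                   alpha = cfg$alpha, adjust = cfg$adjust))
  put("correlations", write_correlation_tsv(screen,
                                            file.path(cfg$out_dir,
                                                      "correlations.tsv")))

  # --- guilds and set algebra --------------------------------------------
  assignments <- .stage("guilds", assign_guilds(table, guild_db))
  put("guilds", .write_tsv(assignments,
                           file.path(cfg$out_dir, "guild_assignments.tsv")))
  grp_list <- split(metadata$sample_id, metadata[[cfg$group_by]])
  prof <- .stage("trophic_profile",
                 trophic_mode_profile(assignments, table, grp_list,
                                      weight = "taxa"))
  put("trophic_profile", .write_tsv(prof,
                                    file.path(cfg$out_dir,
                                              "trophic_profile.tsv")))
  venn <- NULL
  core_sets <- lapply(cores$cores, `[[`, "members")
  core_sets <- core_sets[lengths(core_sets) > 0]
  if (length(core_sets) >= 2L) {
    core_sets <- core_sets[seq_len(min(5L, length(core_sets)))]
    venn <- .stage("venn", venn_partition(core_sets))
    put("venn_cores", write_venn_tsv(venn,
                                     file.path(cfg$out_dir,
                                               "venn_cores.tsv")))
  }

  # --- provenance --------------------------------------------------------
  cfg_json <- file.path(cfg$out_dir, "config.json")
  cfg_out <- cfg
  cfg_out$synth_config <- unclass(cfg_out$synth_config)
  cfg_out$table <- if (is.character(cfg$table)) cfg$table else "<in-memory>"
  cfg_out$metadata <- if (is.character(cfg$metadata)) cfg$metadata
                      else "<in-memory>"
  cfg_out$guild_db <- if (is.character(cfg$guild_db)) cfg$guild_db
                      else "<in-memory>"
  jsonlite::write_json(unclass(cfg_out), cfg_json, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null",
                       force = TRUE)
  put("config", cfg_json)
  log_path <- file.path(cfg$out_dir, "run_log.txt")
  writeLines(c(
    paste0("timestamp: ", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    paste0("config_md5: ", unname(tools::md5sum(cfg_json))),
    paste0("permdisp_seed: ", cfg$permdisp_seed),
    paste0("modularity_seed: ", cfg$modularity_seed),
    paste0("synth_seed: ", if (is.null(cfg$synth_seed)) "NA"
           else cfg$synth_seed),
    paste0("n_taxa: ", nrow(table$counts)),
    paste0("n_samples: ", ncol(table$counts))), log_path)
  put("run_log", log_path)

  structure(list(table = table, metadata = metadata, truth = truth,
                 composition = comp, permdisp = disp, critical = crit,
                 partition = part, cores = cores, antagonism = antag,
                 screen = screen, assignments = assignments,
                 trophic_profile = prof, venn = venn, files = files,
                 config = cfg),
            class = "report_bundle")
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("report_bundle:", length(x$files), "files in",
      x$config$out_dir, "\n")
  invisible(x)
}
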