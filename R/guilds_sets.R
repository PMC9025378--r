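# Trophic-mode/guild assignment from taxonomy against a local lookup
# table, per-group trophic profiles, and Venn-style set algebra for
# shared/unique comparisons.

.GUILD_MATCH_ORDER <- c("species", "genus", "family", "order", "class",
                        "phylum")

#' Assign a trophic mode and guild to one taxon
#'
#' Matches the taxon's names against the lookup table at the most specific
#' rank available, preferring species > genus > family > order > class >
#' phylum. No match at any rank yields an unassigned record (a value, not
#' an error).
#'
#' @param tax one taxonomy record: named list or one-row data.frame with
#'   the seven rank fields.
#' @param db a validated `guild_db`.
#' @return List: `matched_name`, `matched_rank`, `trophic_modes`
#'   (character vector, or `"unassigned"`), `guild`, `confidence`.
#' @export
assign_guild <- function(tax, db) {
  if (nrow(db) == 0L) stop("guild db is empty")
  for (rank in .GUILD_MATCH_ORDER) {
    nm <- tax[[rank]]
    if (is.null(nm) || is.na(nm) || !nzchar(nm)) next
    hit <- which(db$taxon == nm & db$rank == rank)
    if (length(hit)) {
      hit <- hit[1L]  # (taxon, rank) unique by guild_db invariant
      return(list(matched_name = nm, matched_rank = rank,
                  trophic_modes = parse_trophic_modes(
                    db$trophic_mode[hit])[[1L]],
                  guild = db$guild[hit], confidence = db$confidence[hit]))
    }
  }
  list(matched_name = NA_character_, matched_rank = NA_character_,
       trophic_modes = "unassigned", guild = "unassigned",
       confidence = NA_character_)
}

.mode_label <- function(modes) {
  if (identical(modes, "unassigned") || !length(modes)) return("unassigned")
  paste(sort(modes), collapse = "-")
}

#' Assign guilds to every taxon of an abundance table
#'
#' Vectorized [assign_guild()]; deterministic and total — every taxon is
#' either matched or unassigned.
#'
#' @param table an `abundance_table`.
#' @param db a validated `guild_db`.
#' @return data.frame: `taxon_id`, `matched_name`, `matched_rank`,
#'   `trophic_mode` (combination label such as `"pathotroph-saprotroph"`,
#'   or `"unassigned"`), `guild`, `confidence`.
#' @export
assign_guilds <- function(table, db) {
  tax <- table$taxonomy
  rows <- lapply(seq_len(nrow(tax)), function(i)
    assign_guild(as.list(tax[i, ]), db))
  data.frame(
    taxon_id = tax$taxon_id,
    matched_name = vapply(rows, `[[`, character(1), "matched_name"),
    matched_rank = vapply(rows, `[[`, character(1), "matched_rank"),
    trophic_mode = vapply(rows, function(r) .mode_label(r$trophic_modes),
                          character(1)),
    guild = vapply(rows, `[[`, character(1), "guild"),
    confidence = vapply(rows, `[[`, character(1), "confidence"),
    stringsAsFactors = FALSE)
}

#' Per-group trophic-mode profile
#'
#' For every sample group, the proportion of taxa (present in the group)
#' or of reads per trophic-mode combination, including `"unassigned"`.
#' Proportions over all categories sum to 1 per group.
#'
#' @param assignments output of [assign_guilds()].
#' @param table the matching `abundance_table`.
#' @param groups named list: group name -> sample ids.
#' @param weight `"taxa"` (count present taxa) or `"reads"` (sum reads).
#' @return data.frame: `group`, `trophic_mode`, `proportion`.
#' @export
trophic_mode_profile <- function(assignments, table, groups,
                                 weight = c("taxa", "reads")) {
  weight <- match.arg(weight)
  stopifnot(identical(assignments$taxon_id, taxon_ids(table)))
  out <- lapply(names(groups), function(g) {
    s <- groups[[g]]
    miss <- setdiff(s, sample_ids(table))
    if (length(miss)) stop("unknown samples in group '", g, "'")
    sub <- table$counts[, s, drop = FALSE]
    w <- if (weight == "taxa") as.numeric(rowSums(sub) > 0)
         else rowSums(sub)
    tot <- sum(w)
    if (tot == 0) stop("group '", g, "' has no reads")
    prop <- tapply(w, assignments$trophic_mode, sum) / tot
    data.frame(group = g, trophic_mode = names(prop),
               proportion = as.numeric(prop), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Venn partition of 2-5 named sets
#'
#' Enumerates all 2^k - 1 inclusion/exclusion regions with exact
#' memberships. Labels are cleaned by `normalizer` (default: trim
#' whitespace, case preserved) before comparison. Region counts sum to
#' the size of the union and memberships are disjoint across regions.
#'
#' @param sets named list of 2-5 character vectors.
#' @param normalizer label-cleaning function applied to every element.
#' @return `venn_summary`: `set_names` and `regions`, a named list keyed
#'   by `"A&B"`-style region labels, each `list(sets, bitmask, count,
#'   members)`.
#' @export
venn_partition <- function(sets, normalizer = trimws) {
  k <- length(sets)
  if (k < 2L || k > 5L) stop("need between 2 and 5 sets")
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stop("sets must have unique names")
  sets <- lapply(sets, function(s) unique(normalizer(as.character(s))))
  universe <- unique(unlist(sets, use.names = FALSE))
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1L,
                                               dimnames = list(NULL, names(sets)))
  sig <- apply(member, 1L, function(b) paste(as.integer(b), collapse = ""))
  regions <- list()
  for (code in seq_len(2^k - 1L)) {
    incl <- as.logical(bitwAnd(code, 2^(seq_len(k) - 1L)))
    bitmask <- paste(as.integer(incl), collapse = "")
    key <- paste(names(sets)[incl], collapse = "&")
    members <- sort(universe[sig == bitmask])
    regions[[key]] <- list(sets = names(sets)[incl], bitmask = bitmask,
                           count = length(members), members = members)
  }
  structure(list(set_names = names(sets), regions = regions),
            class = "venn_summary")
}

#' @export
print.venn_summary <- function(x, ...) {
  cat("venn_summary over {", paste(x$set_names, collapse = ", "), "}\n")
  for (key in names(x$regions))
    cat(sprintf("  %-30s %d\n", key, x$regions[[key]]$count))
  invisible(x)
}

#' Flatten a Venn summary to a data.frame
#'
#' @param x a `venn_summary`.
#' @param ... unused.
#' @return data.frame: `region`, `bitmask`, `count`, `members`
#'   (comma-joined).
#' @export
as.data.frame.venn_summary <- function(x, ...) {
  data.frame(
    region = names(x$regions),
    bitmask = vapply(x$regions, `[[`, character(1), "bitmask"),
    count = vapply(x$regions, function(r) as.integer(r$count), integer(1)),
    members = vapply(x$regions, function(r)
      paste(r$members, collapse = ","), character(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Write a Venn summary to TSV
#'
#' @param x a `venn_summary`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_venn_tsv <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
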