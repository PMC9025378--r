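# Tabular inputs and the shared data model: OTU abundance tables with
# taxonomy, sample metadata, and the guild lookup table. All files are
# plain TSV (tab-separated, UTF-8, header row); tabs inside fields are
# rejected rather than quoted.

#' The seven canonical taxonomic ranks
#'
#' Rank names used throughout the package, ordered from most to least
#' inclusive.
#'
#' @export
TAXONOMY_RANKS <- c("kingdom", "phylum", "class", "order", "family",
                    "genus", "species")

.rank_prefixes <- c(k = "kingdom", p = "phylum", c = "class", o = "order",
                    f = "family", g = "genus", s = "species")

#' Construct an abundance table
#'
#' An abundance table couples an integer read-count matrix (taxa as rows,
#' samples as columns) with one taxonomy record per taxon. This is the
#' universal input of the pipeline.
#'
#' @param counts integer matrix, taxa x samples, with unique dimnames.
#' @param taxonomy data.frame with columns `taxon_id`, the seven rank
#'   columns (`NA` = unknown) and `source_string`; one row per taxon, in
#'   the row order of `counts`. If `NULL`, all-unknown records are created.
#' @return An object of class `abundance_table`.
#' @export
abundance_table <- function(counts, taxonomy = NULL) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have taxon rownames and sample colnames")
  if (is.null(taxonomy)) {
    taxonomy <- parse_taxonomy_table(rownames(counts),
                                     rep(NA_character_, nrow(counts)))
  }
  out <- structure(list(counts = counts, taxonomy = taxonomy),
                   class = "abundance_table")
  validate_abundance_table(out)
  out
}

#' Validate an abundance table
#'
#' Checks the structural invariants: matching dimensions, unique ids,
#' non-negative integer counts, and full taxonomy coverage.
#'
#' @param x an `abundance_table`.
#' @return `x`, invisibly; errors describe the first violated invariant.
#' @export
validate_abundance_table <- function(x) {
  stopifnot(inherits(x, "abundance_table"))
  cnt <- x$counts
  dup_t <- rownames(cnt)[duplicated(rownames(cnt))]
  if (length(dup_t))
    stop("duplicated taxon ids: ", paste(unique(dup_t), collapse = ", "))
  dup_s <- colnames(cnt)[duplicated(colnames(cnt))]
  if (length(dup_s))
    stop("duplicated sample ids: ", paste(unique(dup_s), collapse = ", "))
  if (anyNA(cnt) || any(cnt < 0) || any(cnt != floor(cnt)))
    stop("counts must be non-negative integers")
  if (!identical(x$taxonomy$taxon_id, rownames(cnt)))
    stop("taxonomy rows must match counts rows (one record per taxon)")
  invisible(x)
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table: %d taxa x %d samples, %s reads\n",
              nrow(x$counts), ncol(x$counts),
              format(sum(x$counts), big.mark = ",")))
  invisible(x)
}

#' Taxon and sample identifiers
#'
#' @param x an `abundance_table`.
#' @return Character vector of ids in table order.
#' @export
taxon_ids <- function(x) rownames(x$counts)

#' @rdname taxon_ids
#' @export
sample_ids <- function(x) colnames(x$counts)

#' Parse a taxonomy string into rank fields
#'
#' Understands UNITE-style labels (`"k__Fungi;p__Basidiomycota;...;g__Meira"`),
#' plain binomials (`"Meira argovae"` fills genus and species), and bare
#' genus names. Placeholder labels such as `"Ascomycota sp. 52-1"` are kept
#' opaque: every rank is unknown and the source string is preserved verbatim,
#' so such labels survive a write/read round trip unchanged.
#'
#' @param source non-empty taxonomy string.
#' @return Named list with the seven ranks (`NA` when unknown) and
#'   `source_string`.
#' @export
parse_taxonomy <- function(source) {
  if (!is.character(source) || length(source) != 1L || is.na(source) ||
      !nzchar(trimws(source)))
    stop("taxonomy source must be a non-empty string")
  src <- trimws(source)
  ranks <- stats::setNames(rep(NA_character_, 7L), TAXONOMY_RANKS)
  if (grepl("__", src, fixed = TRUE)) {
    for (tok in trimws(strsplit(src, ";", fixed = TRUE)[[1]])) {
      m <- regmatches(tok, regexec("^([kpcofgs])__(.*)$", tok))[[1]]
      if (length(m) == 3L && nzchar(trimws(m[3]))) {
        nm <- gsub("_", " ", trimws(m[3]))
        ranks[[.rank_prefixes[[m[2]]]]] <- nm
      }
    }
  } else {
    toks <- strsplit(src, "[[:space:]]+")[[1]]
    if (length(toks) == 1L && grepl("^[A-Za-z][A-Za-z-]*$", toks)) {
      ranks[["genus"]] <- toks
    } else if (length(toks) == 2L &&
               grepl("^[A-Z][A-Za-z-]*$", toks[1]) &&
               grepl("^[a-z][a-z-]*$", toks[2])) {
      ranks[["genus"]] <- toks[1]
      ranks[["species"]] <- paste(toks, collapse = " ")
    }
    # anything else ("Ascomycota sp. 52-1") stays fully unknown
  }
  c(as.list(ranks), list(source_string = source))
}

# vectorized helper building the taxonomy data.frame used inside tables
parse_taxonomy_table <- function(taxon_id, sources) {
  sources <- ifelse(is.na(sources) | !nzchar(trimws(sources)),
                    NA_character_, sources)
  recs <- lapply(sources, function(s) {
    if (is.na(s)) c(stats::setNames(as.list(rep(NA_character_, 7L)),
                                    TAXONOMY_RANKS),
                    list(source_string = NA_character_))
    else parse_taxonomy(s)
  })
  out <- data.frame(taxon_id = taxon_id, stringsAsFactors = FALSE)
  for (r in TAXONOMY_RANKS)
    out[[r]] <- vapply(recs, function(x) x[[r]], character(1))
  out$source_string <- vapply(recs, function(x) x$source_string, character(1))
  rownames(out) <- NULL
  out
}

.read_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                    check.names = FALSE, colClasses = "character",
                    stringsAsFactors = FALSE)
}

.no_tabs <- function(x, what) {
  if (any(grepl("\t", x, fixed = TRUE)))
    stop(what, " may not contain tab characters (TSV fields are unquoted)")
  invisible(x)
}

#' Read an OTU abundance table from TSV
#'
#' The first column holds taxon ids; one column (default `"taxonomy"`) holds
#' the taxonomy string; every remaining column is an integer read-count
#' vector for one sample. Row and column order are preserved. Files with
#' samples as rows can be read with `transpose = TRUE` (no taxonomy column
#' in that orientation).
#'
#' @param path TSV file path.
#' @param taxonomy_col name of the taxonomy column, or `NULL` if absent.
#' @param transpose set `TRUE` when the file stores samples as rows.
#' @return An `abundance_table`.
#' @export
read_abundance_table <- function(path, taxonomy_col = "taxonomy",
                                 transpose = FALSE) {
  raw <- .read_tsv(path)
  hdr <- names(raw)
  dup <- unique(hdr[duplicated(hdr)])
  if (length(dup))
    stop("duplicated column headers: ", paste(dup, collapse = ", "))
  if (ncol(raw) < 2L) stop("need at least one id column and one sample column")
  ids <- raw[[1L]]
  if (anyDuplicated(ids))
    stop("duplicated ids in first column: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  tax_src <- NULL
  if (!transpose && !is.null(taxonomy_col) && taxonomy_col %in% hdr)
    tax_src <- raw[[taxonomy_col]]
  value_cols <- setdiff(hdr[-1L], if (!transpose) taxonomy_col else NULL)
  mat <- matrix(0L, nrow = nrow(raw), ncol = length(value_cols),
                dimnames = list(ids, value_cols))
  for (j in seq_along(value_cols)) {
    col <- raw[[value_cols[j]]]
    bad <- which(!grepl("^[0-9]+$", col))
    if (length(bad))
      stop(sprintf(
        "non-integer or negative count '%s' at row '%s', column '%s'",
        col[bad[1]], ids[bad[1]], value_cols[j]))
    mat[, j] <- as.integer(col)
  }
  if (transpose) mat <- t(mat)
  taxonomy <- if (is.null(tax_src)) NULL else
    parse_taxonomy_table(rownames(mat), tax_src)
  abundance_table(mat, taxonomy)
}

#' Write an abundance table to TSV
#'
#' Inverse of [read_abundance_table()]: `taxon_id`, `taxonomy` (verbatim
#' source strings), then one column per sample. Writing then reading gives
#' back an identical table.
#'
#' @param table an `abundance_table`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_abundance_table <- function(table, path) {
  validate_abundance_table(table)
  .no_tabs(taxon_ids(table), "taxon ids")
  .no_tabs(sample_ids(table), "sample ids")
  tax <- table$taxonomy$source_string
  tax[is.na(tax)] <- ""
  .no_tabs(tax, "taxonomy strings")
  df <- data.frame(taxon_id = taxon_ids(table), taxonomy = tax,
                   check.names = FALSE, stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(table$counts, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Filter taxa by total read count
#'
#' Keeps taxa whose reads summed over all samples are strictly greater than
#' `min_total_reads` (e.g. the display convention "more than 100 reads").
#' The sample set is unchanged; the operation is idempotent and monotone in
#' the threshold.
#'
#' @param table an `abundance_table`.
#' @param min_total_reads non-negative integer threshold.
#' @return The filtered `abundance_table` (possibly with zero taxa).
#' @export
filter_taxa_by_total <- function(table, min_total_reads) {
  stopifnot(length(min_total_reads) == 1L, min_total_reads >= 0)
  keep <- rowSums(table$counts) > min_total_reads
  structure(list(counts = table$counts[keep, , drop = FALSE],
                 taxonomy = table$taxonomy[keep, , drop = FALSE]),
            class = "abundance_table")
}

#' Read sample metadata from TSV
#'
#' Requires columns `sample_id`, `site`, `stage`, `tree`; `leaf` is
#' optional. Stage is restricted to `adult`/`plantlet`; sample ids and
#' (tree, leaf) pairs must be unique.
#'
#' @param path TSV file path.
#' @return A validated metadata `data.frame`.
#' @export
read_metadata <- function(path) {
  meta <- .read_tsv(path)
  validate_metadata(meta)
}

#' Validate sample metadata
#'
#' @param meta data.frame with `sample_id`, `site`, `stage`, `tree` and
#'   optionally `leaf`.
#' @return `meta` with a `leaf` column (NA when absent), invisibly usable.
#' @export
validate_metadata <- function(meta) {
  need <- c("sample_id", "site", "stage", "tree")
  miss <- setdiff(need, names(meta))
  if (length(miss))
    stop("metadata missing columns: ", paste(miss, collapse = ", "))
  if (!"leaf" %in% names(meta)) meta$leaf <- NA_character_
  dup <- meta$sample_id[duplicated(meta$sample_id)]
  if (length(dup))
    stop("duplicated sample ids in metadata: ",
         paste(unique(dup), collapse = ", "))
  bad <- setdiff(unique(meta$stage), c("adult", "plantlet"))
  if (length(bad))
    stop("stage must be 'adult' or 'plantlet', found: ",
         paste(bad, collapse = ", "))
  key <- paste(meta$tree, meta$leaf, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicated (tree, leaf) pairs in metadata")
  meta
}

#' Check that metadata covers every table sample
#'
#' @param table an `abundance_table`.
#' @param meta metadata data.frame.
#' @return Invisibly `TRUE`; errors listing the missing sample ids.
#' @export
check_metadata_covers <- function(table, meta) {
  miss <- setdiff(sample_ids(table), meta$sample_id)
  if (length(miss))
    stop("metadata is missing table samples: ", paste(miss, collapse = ", "))
  invisible(TRUE)
}

#' Write sample metadata to TSV
#'
#' @param meta metadata data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

.VALID_MODES <- c("saprotroph", "pathotroph", "symbiotroph")

#' Read a guild lookup table from TSV
#'
#' A local, static stand-in for an online guild database. Columns:
#' `taxon` (name at some rank), `rank` (one of the seven ranks),
#' `trophic_mode` (semicolon-joined subset of
#' saprotroph/pathotroph/symbiotroph), `guild` (free text), `confidence`.
#' (taxon, rank) pairs must be unique and every record must carry at least
#' one trophic mode.
#'
#' @param path TSV file path.
#' @return A validated `data.frame` of class `guild_db`.
#' @export
read_guild_db <- function(path) {
  db <- .read_tsv(path)
  validate_guild_db(db)
}

#' Validate a guild lookup table
#'
#' @param db data.frame with columns `taxon`, `rank`, `trophic_mode`,
#'   `guild`, `confidence`.
#' @return `db` with class `guild_db` prepended.
#' @export
validate_guild_db <- function(db) {
  need <- c("taxon", "rank", "trophic_mode", "guild", "confidence")
  miss <- setdiff(need, names(db))
  if (length(miss))
    stop("guild db missing columns: ", paste(miss, collapse = ", "))
  bad_rank <- setdiff(unique(db$rank), TAXONOMY_RANKS)
  if (length(bad_rank))
    stop("guild db has invalid ranks: ", paste(bad_rank, collapse = ", "))
  modes <- parse_trophic_modes(db$trophic_mode)
  empty <- which(lengths(modes) == 0L)
  if (length(empty))
    stop("guild db rows with empty/invalid trophic_mode: row ",
         paste(empty, collapse = ", "))
  key <- paste(db$taxon, db$rank, sep = "\r")
  if (anyDuplicated(key))
    stop("guild db has duplicated (taxon, rank) pairs: ",
         paste(unique(db$taxon[duplicated(key)]), collapse = ", "))
  class(db) <- c("guild_db", class(db))
  db
}

#' Parse semicolon-joined trophic-mode strings
#'
#' @param x character vector like `"Pathotroph;Saprotroph"`.
#' @return List of lowercase mode vectors; invalid tokens are dropped.
#' @export
parse_trophic_modes <- function(x) {
  lapply(strsplit(tolower(trimws(x)), "[;-]"), function(m) {
    m <- trimws(m)
    sort(unique(m[m %in% .VALID_MODES]))
  })
}

#' Write a guild lookup table to TSV
#'
#' @param db a `guild_db` data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_guild_db <- function(db, path) {
  utils::write.table(as.data.frame(db), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a square distance or similarity matrix to TSV
#'
#' @param m square matrix with dimnames.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_square_tsv <- function(m, path) {
  df <- data.frame(id = rownames(m), check.names = FALSE,
                   stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(m, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
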