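#' Canonical taxonomic ranks, highest to lowest
#'
#' Order matters: a filled rank implies all higher (earlier) ranks are filled.
#' @export
CANONICAL_RANKS <- c("kingdom", "phylum", "class", "order", "family",
                     "genus", "species")

#' Herbivore species and season levels used throughout the study design
#' @rdname study-levels
#' @export
DIET_SPECIES <- c("sika_deer", "reeves_muntjac", "chinese_hare")

#' @rdname study-levels
#' @export
DIET_SEASONS <- c("spring", "summer", "fall", "winter")

# season labels accepted on input (case-insensitive); "autumn" is the
# September-November season, i.e. fall
.season_aliases <- c(autumn = "fall")

#' Construct and validate an OTU count table
#'
#' The central container of the pipeline: a samples x OTUs matrix of
#' non-negative integer read counts with unique sample and OTU identifiers.
#'
#' @param counts numeric matrix, samples in rows, OTUs in columns. Must be
#'   whole non-negative numbers.
#' @param sample_ids,otu_ids character vectors; taken from `dimnames(counts)`
#'   when `NULL`.
#' @return An object of class `otu_table`: the validated integer matrix with
#'   sample ids as rownames and OTU ids as colnames.
#' @export
otu_table <- function(counts, sample_ids = NULL, otu_ids = NULL) {
  counts <- as.matrix(counts)
  if (is.null(sample_ids)) sample_ids <- rownames(counts)
  if (is.null(otu_ids)) otu_ids <- colnames(counts)
  if (is.null(sample_ids) || is.null(otu_ids))
    stop("otu_table requires sample and OTU identifiers")
  sample_ids <- as.character(sample_ids)
  otu_ids <- as.character(otu_ids)
  if (anyDuplicated(sample_ids))
    stop("duplicate sample id: ", sample_ids[duplicated(sample_ids)][1L])
  if (anyDuplicated(otu_ids))
    stop("duplicate OTU id: ", otu_ids[duplicated(otu_ids)][1L])
  if (length(sample_ids) != nrow(counts) || length(otu_ids) != ncol(counts))
    stop("identifier lengths do not match count matrix dimensions")
  if (anyNA(counts) || !is.numeric(counts))
    stop("counts must be numeric and complete")
  bad <- which(counts < 0 | abs(counts - round(counts)) > 1e-8, arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("invalid count at sample '%s', OTU '%s': %s",
                 sample_ids[bad[1L, 1L]], otu_ids[bad[1L, 2L]],
                 format(counts[bad[1L, , drop = FALSE]])))
  storage.mode(counts) <- "integer"
  empty <- rowSums(counts) == 0L
  if (any(empty))
    stop("sample with zero total reads: ", sample_ids[empty][1L])
  dimnames(counts) <- list(sample_ids, otu_ids)
  class(counts) <- c("otu_table", "matrix", "array")
  counts
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("OTU table: %d samples x %d OTUs, %s reads total\n",
              nrow(x), ncol(x), format(sum(as.numeric(x)), big.mark = ",")))
  invisible(x)
}

#' Read an OTU count table from TSV
#'
#' One header row, first column holds identifiers; UTF-8, tab-separated.
#'
#' @param path file path.
#' @param orientation `"samples_as_rows"` (default) or `"otus_as_rows"`;
#'   the returned table is always samples x OTUs.
#' @return An [otu_table()].
#' @export
read_otu_table <- function(path,
                           orientation = c("samples_as_rows", "otus_as_rows")) {
  orientation <- match.arg(orientation)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("OTU table needs an id column and >=1 count column")
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(matrix(as.numeric(m), nrow(m)))) &
                   !is.na(m), arr.ind = TRUE)
    if (nrow(bad) > 0L)
      stop(sprintf("non-numeric cell at row '%s', column '%s'",
                   ids[bad[1L, 1L]], colnames(m)[bad[1L, 2L]]))
    storage.mode(m) <- "numeric"
  }
  rownames(m) <- ids
  if (orientation == "otus_as_rows") m <- t(m)
  otu_table(m)
}

#' Write an OTU table as TSV (samples as rows)
#'
#' @param x an [otu_table()].
#' @param path output file path.
#' @param id_column header name for the identifier column.
#' @export
write_otu_table <- function(x, path, id_column = "sample_id") {
  df <- data.frame(rownames(x), unclass(x)[, , drop = FALSE],
                   check.names = FALSE)
  names(df)[1L] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata (sample_id, species, season)
#'
#' Species and season labels are matched case-insensitively; "autumn" is
#' accepted as an alias for fall. Samples present in the metadata but absent
#' from `otu` (when given) raise a warning; samples in `otu` without metadata
#' raise an error downstream where grouping is required.
#'
#' @param path TSV with columns sample_id, species, season.
#' @param otu optional [otu_table()] to cross-check sample ids against.
#' @return data.frame of class `sample_metadata` with factor columns
#'   `species` (levels [DIET_SPECIES]) and `season` (levels [DIET_SEASONS]).
#' @export
read_metadata <- function(path, otu = NULL) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("sample_id", "species", "season")
  if (!all(need %in% names(df)))
    stop("metadata must have columns: ", paste(need, collapse = ", "))
  sample_metadata(df$sample_id, df$species, df$season, otu = otu)
}

#' Construct validated sample metadata
#'
#' @param sample_id,species,season character vectors of equal length.
#' @param otu optional [otu_table()] for id cross-checking.
#' @export
sample_metadata <- function(sample_id, species, season, otu = NULL) {
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id))
    stop("duplicate sample_id in metadata: ",
         sample_id[duplicated(sample_id)][1L])
  sp <- tolower(trimws(as.character(species)))
  bad <- setdiff(unique(sp), DIET_SPECIES)
  if (length(bad) > 0L)
    stop("unknown species label: ", bad[1L])
  se <- tolower(trimws(as.character(season)))
  alias <- .season_aliases[se]
  se[!is.na(alias)] <- alias[!is.na(alias)]
  bad <- setdiff(unique(se), DIET_SEASONS)
  if (length(bad) > 0L)
    stop("unknown season label: ", bad[1L])
  out <- data.frame(sample_id = sample_id,
                    species = factor(sp, levels = DIET_SPECIES),
                    season = factor(se, levels = DIET_SEASONS),
                    stringsAsFactors = FALSE)
  if (!is.null(otu)) {
    extra <- setdiff(out$sample_id, rownames(otu))
    if (length(extra) > 0L)
      warning("metadata samples absent from OTU table: ",
              paste(utils::head(extra, 5L), collapse = ", "))
    missing <- setdiff(rownames(otu), out$sample_id)
    if (length(missing) > 0L)
      stop("OTU-table samples without metadata: ",
           paste(utils::head(missing, 5L), collapse = ", "))
  }
  class(out) <- c("sample_metadata", "data.frame")
  out
}

#' Write sample metadata as TSV
#' @param x a `sample_metadata` data.frame.
#' @param path output file path.
#' @export
write_metadata <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read OTU taxonomy assignments
#'
#' Consumes BLAST/classifier-style output: `otu_id<TAB>lineage`, where the
#' lineage is a semicolon-separated path of taxon names ordered from the
#' highest to the lowest assigned rank. Names map positionally onto `ranks`;
#' a lineage shorter than `ranks` is truncated at its deepest assigned rank
#' (missing lower ranks), never in the middle. Multiple rows with the same
#' otu_id become multiple candidate lineages for that OTU; an empty lineage
#' marks the OTU unassigned.
#'
#' @param path TSV file path (no header required; a header row whose first
#'   field is "otu_id" is skipped).
#' @param ranks character vector naming the rank of each lineage position,
#'   highest first. Default [CANONICAL_RANKS].
#' @return A `taxon_assignments` object: a named list (one element per OTU)
#'   of candidate lineages, each a named character vector (names = ranks),
#'   with attribute `ranks`.
#' @export
read_taxonomy <- function(path, ranks = CANONICAL_RANKS) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) > 0L && grepl("^otu_id\t", lines[1L]))
    lines <- lines[-1L]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  otus <- vapply(parts, `[`, character(1L), 1L)
  lineage_str <- vapply(parts, function(p)
    if (length(p) >= 2L) p[2L] else "", character(1L))
  cands <- lapply(lineage_str, parse_lineage, ranks = ranks)
  out <- split(cands, factor(otus, levels = unique(otus)))
  out <- lapply(out, function(x) x[!vapply(x, is.null, logical(1L))])
  taxon_assignments(out, ranks = ranks)
}

#' @rdname read_taxonomy
#' @param x named list of candidate-lineage lists, as described above.
#' @export
taxon_assignments <- function(x, ranks = CANONICAL_RANKS) {
  if (is.null(names(x)) || anyDuplicated(names(x)))
    stop("taxon assignments need unique otu_id names")
  structure(x, ranks = ranks, class = "taxon_assignments")
}

# Parse one semicolon-delimited lineage string into a named character vector
# over `ranks`; "" -> NULL (unassigned candidate). An empty field followed by
# a filled one violates the ranked-path invariant.
parse_lineage <- function(s, ranks = CANONICAL_RANKS) {
  s <- trimws(s)
  if (!nzchar(s)) return(NULL)
  fields <- trimws(strsplit(s, ";", fixed = TRUE)[[1L]])
  if (length(fields) > length(ranks))
    stop("lineage deeper than rank vector: ", s)
  filled <- nzchar(fields)
  if (any(filled) && any(!filled[seq_len(max(which(filled)))]))
    stop("lineage has a filled rank below an empty one: ", s)
  fields <- fields[filled]
  if (length(fields) == 0L) return(NULL)
  names(fields) <- ranks[seq_along(fields)]
  fields
}

#' @export
print.taxon_assignments <- function(x, ...) {
  n_cand <- lengths(x)
  cat(sprintf(
    "Taxonomy for %d OTUs (%d unassigned, %d with multiple candidates)\n",
    length(x), sum(n_cand == 0L), sum(n_cand > 1L)))
  invisible(x)
}

#' Write taxonomy assignments as TSV
#' @param x a `taxon_assignments` object.
#' @param path output file path.
#' @export
write_taxonomy <- function(x, path) {
  rows <- unlist(lapply(names(x), function(id) {
    if (length(x[[id]]) == 0L) return(paste0(id, "\t"))
    vapply(x[[id]], function(l) paste0(id, "\t", paste(l, collapse = ";")),
           character(1L))
  }))
  writeLines(rows, path)
  invisible(path)
}

#' Read a growth-form trait map
#'
#' @param path TSV with columns taxon, growth_form (herb / shrub / arbor).
#' @return data.frame of class `growth_form_map`.
#' @export
read_growth_forms <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("taxon", "growth_form") %in% names(df)))
    stop("growth-form map must have columns taxon, growth_form")
  growth_form_map(df$taxon, df$growth_form)
}

#' @rdname read_growth_forms
#' @param taxon,growth_form character vectors of equal length.
#' @export
growth_form_map <- function(taxon, growth_form) {
  gf <- tolower(trimws(as.character(growth_form)))
  bad <- setdiff(unique(gf), c("herb", "shrub", "arbor"))
  if (length(bad) > 0L)
    stop("unknown growth form: ", bad[1L])
  taxon <- as.character(taxon)
  if (anyDuplicated(taxon))
    stop("taxon mapped to more than one growth form: ",
         taxon[duplicated(taxon)][1L])
  out <- data.frame(taxon = taxon, growth_form = gf,
                    stringsAsFactors = FALSE)
  class(out) <- c("growth_form_map", "data.frame")
  out
}

#' Write a growth-form map as TSV
#' @param x a `growth_form_map`.
#' @param path output file path.
#' @export
write_growth_forms <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
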