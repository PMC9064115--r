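# The profile table: a tibble with a `sample_id` column followed by one numeric
# column per taxon, values as fractions in [0, 1]. Taxon columns are named by
# their full pipe-delimited, rank-prefixed lineage string (or a bare name for
# unannotated data). The taxonomic rank of the table and whether it has been
# degraded to presence/absence travel as attributes.

RANK_PREFIXES <- c(
  kingdom = "k__", phylum = "p__", class = "c__", order = "o__",
  family = "f__", genus = "g__", species = "s__"
)

#' Construct a taxonomic profile table
#'
#' A profile table is a tibble whose first column is `sample_id` and whose
#' remaining columns hold per-taxon relative abundance as fractions in
#' \[0, 1\] (or 0/1 indicators after [binarize()]). Taxon columns are named by
#' pipe-delimited, rank-prefixed lineage strings such as
#' `"k__Bacteria|...|s__Roseburia_faecis"`.
#'
#' @param data A data frame with a `sample_id` column and numeric taxon
#'   columns.
#' @param rank Taxonomic rank of all taxa in the table, one of
#'   `"kingdom"`, `"phylum"`, `"class"`, `"order"`, `"family"`, `"genus"`,
#'   `"species"`.
#' @param binary Logical; `TRUE` if values are presence/absence indicators.
#'
#' @return A tibble of class `pa_profile` with attributes `rank` and `binary`.
#' @export
profile_table <- function(data, rank = "species", binary = FALSE) {
  data <- tibble::as_tibble(data)
  if (!"sample_id" %in% names(data)) {
    stop_input("A profile table needs a `sample_id` column.")
  }
  data <- dplyr::relocate(data, "sample_id")
  rank <- match.arg(rank, names(RANK_PREFIXES))
  ids <- as.character(data$sample_id)
  if (anyDuplicated(ids)) {
    stop_input(sprintf(
      "Duplicate sample identifier(s): %s",
      paste(unique(ids[duplicated(ids)]), collapse = ", ")
    ))
  }
  taxa <- setdiff(names(data), "sample_id")
  if (anyDuplicated(taxa)) {
    stop_input("Taxon identifiers must be unique within the table.")
  }
  vals <- as.matrix(data[taxa])
  if (length(vals) && !is.numeric(vals)) {
    stop_input("Taxon columns must be numeric.")
  }
  if (length(vals) && any(vals < 0 | vals > 1)) {
    stop_input("Relative abundances must lie in [0, 1].")
  }
  if (binary && length(vals) && !all(vals %in% c(0, 1))) {
    stop_input("A binary profile may contain only 0 and 1.")
  }
  structure(
    data,
    rank = rank, binary = binary,
    class = c("pa_profile", class(tibble::tibble()))
  )
}

#' @rdname profile_table
#' @param x A profile table.
#' @export
profile_rank <- function(x) attr(x, "rank") %||% "species"

#' @rdname profile_table
#' @export
profile_is_binary <- function(x) isTRUE(attr(x, "binary"))

#' @rdname profile_table
#' @export
profile_taxa <- function(x) setdiff(names(x), "sample_id")

#' Extract the sample-by-taxon numeric matrix from a profile table
#'
#' @param x A profile table.
#' @return A numeric matrix with sample ids as row names and taxon lineages as
#'   column names.
#' @export
profile_matrix <- function(x) {
  m <- as.matrix(x[setdiff(names(x), "sample_id")])
  rownames(m) <- as.character(x$sample_id)
  m
}

# Rebuild a pa_profile from a plain tibble, re-validating invariants.
as_profile <- function(data, rank, binary) profile_table(data, rank = rank, binary = binary)

#' Parse a pipe-delimited, rank-prefixed lineage string
#'
#' Splits a MetaPhlAn-style lineage such as
#' `"k__Bacteria|p__Firmicutes|...|s__Roseburia_faecis"` into a named vector of
#' taxon names keyed by rank. Strain-level (`t__`) components are dropped.
#' Ranks must be contiguous from kingdom down to the deepest populated rank.
#'
#' @param lineage A single lineage string.
#' @return Named character vector (names are ranks, deepest last).
#' @export
parse_lineage <- function(lineage) {
  if (!is.character(lineage) || length(lineage) != 1L || is.na(lineage)) {
    stop_input("`lineage` must be a single string.")
  }
  parts <- strsplit(lineage, "|", fixed = TRUE)[[1]]
  parts <- parts[!startsWith(parts, "t__")]
  if (!length(parts)) stop_input(sprintf("Empty lineage: '%s'", lineage))
  prefixes <- substr(parts, 1, 3)
  hit <- match(prefixes, RANK_PREFIXES)
  if (anyNA(hit)) {
    stop_input(sprintf("Malformed lineage component(s) in '%s'", lineage))
  }
  if (!identical(hit, seq_along(parts))) {
    stop_input(sprintf(
      "Lineage ranks must run contiguously from kingdom: '%s'", lineage
    ))
  }
  setNames(substring(parts, 4), names(RANK_PREFIXES)[hit])
}

# Deepest populated rank of each lineage string (vectorised, tolerant of
# malformed rows: returns NA so callers can name offenders). Strain-level
# rows report "strain" so they are never selected at any canonical rank.
deepest_rank <- function(lineages) {
  vapply(lineages, function(l) {
    out <- tryCatch(parse_lineage(l), error = function(e) NULL)
    if (is.null(out)) return(NA_character_)
    if (grepl("|t__", l, fixed = TRUE)) return("strain")
    names(out)[length(out)]
  }, character(1), USE.NAMES = FALSE)
}

# Truncate a lineage string at `rank`; NA if the rank is not populated.
truncate_lineage <- function(lineage, rank) {
  parsed <- parse_lineage(lineage)
  idx <- match(rank, names(parsed))
  if (is.na(idx)) return(NA_character_)
  paste0(RANK_PREFIXES[names(parsed)[seq_len(idx)]], parsed[seq_len(idx)],
         collapse = "|")
}
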