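#' @importFrom rlang .data %||%
NULL

mutation_table_cols <- c("individual_id", "cell_id", "position", "ref", "alt",
                         "abundance_pct", "coverage", "region")

#' Construct an allele identifier from position, ref and alt
#'
#' Uses the field's `"<position><ref>><alt>"` convention (e.g. `15468A>G`).
#'
#' @param position 1-based position.
#' @param ref,alt Reference and alternate allele strings.
#' @return Character vector of allele ids.
#' @export
allele_id <- function(position, ref, alt) paste0(position, ref, ">", alt)

#' Validate a long-format single-cell mutation table
#'
#' Checks the canonical schema: one row per detected mutation with columns
#' `individual_id`, `cell_id`, `position` (1-based bp), `ref`, `alt`,
#' `abundance_pct` (percent of mtDNA copies, in (0, 100]), `coverage`
#' (reads >= 1) and optional `region`. Undetected mutations are absent rows,
#' never zeros.
#'
#' @param table A data frame.
#' @param genome_length Optional genome length L; when given, positions must
#'   lie in `[1, L]`.
#' @return The validated table (as a tibble, canonical column order),
#'   invisibly usable in pipes. Errors mention offending row numbers.
#' @export
validate_mutation_table <- function(table, genome_length = NULL) {
  table <- tibble::as_tibble(table)
  required <- setdiff(mutation_table_cols, "region")
  missing <- setdiff(required, names(table))
  if (length(missing))
    stop("mutation table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (!"region" %in% names(table)) table$region <- NA_character_
  table <- table[mutation_table_cols]
  table$position <- as.integer(table$position)
  bad <- which(table$abundance_pct <= 0 | table$abundance_pct > 100)
  if (length(bad))
    stop("abundance_pct outside (0, 100] at row(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  bad <- which(is.na(table$position) | table$position < 1L |
                 (if (!is.null(genome_length)) table$position > genome_length
                  else FALSE))
  if (length(bad))
    stop("position outside [1, L] at row(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  bad <- which(is.na(table$coverage) | table$coverage < 1)
  if (length(bad))
    stop("coverage below 1 at row(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  key <- paste(table$individual_id, table$cell_id, table$position,
               table$ref, table$alt)
  dup <- which(duplicated(key))
  if (length(dup))
    stop("duplicate (individual, cell, position, ref, alt) at row(s): ",
         paste(utils::head(dup, 5), collapse = ", "), call. = FALSE)
  table
}

#' Read a single-cell mutation table from TSV
#'
#' Reads the canonical tab-delimited long format (UTF-8, `.` decimal) and
#' validates it against the schema and the species' genome length.
#'
#' @param path Path to a TSV file with the canonical header.
#' @param species `"mouse"` or `"human"` (sets the admissible position range),
#'   or `NULL` to skip the range check.
#' @return A validated tibble.
#' @export
read_mutation_table <- function(path, species = "mouse") {
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    individual_id = readr::col_character(),
    cell_id = readr::col_character(),
    position = readr::col_integer(),
    ref = readr::col_character(),
    alt = readr::col_character(),
    abundance_pct = readr::col_double(),
    coverage = readr::col_double(),
    region = readr::col_character()), progress = FALSE)
  L <- if (is.null(species)) NULL else species_preset(species)$genome_length
  validate_mutation_table(tbl, genome_length = L)
}

#' Write a single-cell mutation table to TSV
#'
#' Deterministic column order and formatting; a round trip through
#' [read_mutation_table()] is lossless and repeated writes of the same table
#' are byte-identical.
#'
#' @param table A mutation table (validated on the way out).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mutation_table <- function(table, path) {
  table <- tibble::as_tibble(table)
  if (!"region" %in% names(table)) table$region <- NA_character_
  if (nrow(table)) table <- validate_mutation_table(table)
  else table <- tibble::as_tibble(
    stats::setNames(rep(list(character(0)), length(mutation_table_cols)),
                    mutation_table_cols))
  readr::write_tsv(table[mutation_table_cols], path, progress = FALSE)
  invisible(path)
}

#' Read genomic intervals from a BED file
#'
#' BED files are 0-based half-open; the returned intervals are converted to
#' the 1-based closed convention used by mutation-table positions
#' (NC_005089 / NC_012920 numbering).
#'
#' @param path Path to a BED file.
#' @return A tibble with columns `start`, `end` (1-based, inclusive) and
#'   `name` (NA when the BED file has no name column).
#' @export
read_regions_bed <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("reading BED files requires the rtracklayer package", call. = FALSE)
  gr <- rtracklayer::import(path, format = "BED")
  df <- as.data.frame(gr)
  tibble::tibble(start = as.integer(df$start), end = as.integer(df$end),
                 name = if ("name" %in% names(df)) as.character(df$name)
                        else NA_character_)
}

in_regions <- function(position, regions) {
  if (is.null(regions) || !nrow(regions)) return(rep(FALSE, length(position)))
  if (any(regions$start > regions$end))
    stop("malformed region interval (start > end)", call. = FALSE)
  out <- rep(FALSE, length(position))
  for (i in seq_len(nrow(regions)))
    out <- out | (position >= regions$start[i] & position <= regions$end[i])
  out
}
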