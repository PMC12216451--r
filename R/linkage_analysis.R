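#' Minimum co-residence of two alleles on the same genomes
#'
#' Two alleles present at `a1`% and `a2`% of a cell's mtDNA copies must, by
#' the pigeonhole principle, co-occur on at least `max(0, a1 + a2 - 100)` % of
#' genomes. A pair of alleles both above 50% therefore demonstrates physical
#' linkage on at least some genomes without read-level phasing.
#'
#' @param a1,a2 Cellular abundances in percent, in `[0, 100]` (vectorised).
#' @return Minimum co-residence percent(s).
#' @examples
#' min_coresidence(80, 75)  # 55
#' min_coresidence(40, 50)  # 0
#' @export
min_coresidence <- function(a1, a2) {
  if (any(a1 < 0 | a1 > 100) || any(a2 < 0 | a2 > 100))
    stop("abundances must lie in [0, 100]", call. = FALSE)
  pmax(0, a1 + a2 - 100)
}

#' Per-cell maximum driver vs coding-allele abundances
#'
#' For every cell of a cohort, records the maximum abundance among detected
#' driver alleles and the maximum abundance among detected non-driver alleles
#' in coding regions (0 when none is detected). Cells where both maxima
#' exceed `threshold` (strictly; the "red square" at 50%) indicate
#' driver-passenger linkage, since two alleles above 50% necessarily
#' co-reside on some genomes.
#'
#' @param table A validated mutation table.
#' @param driver_alleles Character vector of driver allele ids (see
#'   [allele_id()]).
#' @param coding_regions Data frame of 1-based closed intervals (`start`,
#'   `end`) defining coding sequence; required and non-empty.
#' @param exclude_alleles Optional allele ids ignored in both maxima (e.g. an
#'   abundant clonal mutation).
#' @param threshold Red-square threshold in percent (default 50, strict).
#' @return A tibble with one row per cell: `individual_id`, `cell_id`,
#'   `max_driver_pct`, `max_coding_pct`, `in_red_square`.
#' @export
per_cell_max_table <- function(table, driver_alleles, coding_regions,
                               exclude_alleles = NULL, threshold = 50) {
  table <- validate_mutation_table(table)
  if (is.null(coding_regions) || !nrow(tibble::as_tibble(coding_regions)))
    stop("a non-empty coding-region definition is required", call. = FALSE)
  coding_regions <- tibble::as_tibble(coding_regions)
  ids <- allele_id(table$position, table$ref, table$alt)
  if (!is.null(exclude_alleles)) {
    keep <- !(ids %in% exclude_alleles)
    table <- table[keep, , drop = FALSE]
    ids <- ids[keep]
  }
  is_driver <- ids %in% driver_alleles
  is_coding <- in_regions(table$position, coding_regions) & !is_driver
  table$driver_ab <- ifelse(is_driver, table$abundance_pct, 0)
  table$coding_ab <- ifelse(is_coding, table$abundance_pct, 0)
  out <- table |>
    dplyr::group_by(.data$individual_id, .data$cell_id) |>
    dplyr::summarise(max_driver_pct = max(.data$driver_ab),
                     max_coding_pct = max(.data$coding_ab),
                     .groups = "drop") |>
    dplyr::mutate(in_red_square = .data$max_driver_pct > threshold &
                    .data$max_coding_pct > threshold)
  out
}
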