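#' Per-allele summary statistics across cells (C# and AAA)
#'
#' For every distinct allele (position/ref/alt) in a long-format mutation
#' table, computes the number of cells in which it was detected (C#) and its
#' average cellular abundance over detected cells only (AAA, percent).
#' Averaging over detected cells only is what separates selection (high AAA)
#' from mutation pressure (high C#) in the AAA-vs-C# plane.
#'
#' @param table A validated mutation table (see [validate_mutation_table()]).
#' @param by_individual Also group by `individual_id`, yielding per-individual
#'   summaries.
#' @return A tibble with one row per allele (or per allele x individual):
#'   `allele_id`, `position`, `ref`, `alt`, `region`, `c_number` (C#),
#'   `aaa` (mean percent abundance over detected cells), `max_abundance`,
#'   and - when summarising across individuals - `n_individuals` (number of
#'   individuals with at least one detection).
#' @export
summarize_alleles <- function(table, by_individual = FALSE) {
  table <- validate_mutation_table(table)
  if (!nrow(table)) {
    empty <- tibble::tibble(allele_id = character(), position = integer(),
                            ref = character(), alt = character(),
                            region = character(), c_number = integer(),
                            aaa = numeric(), max_abundance = numeric())
    if (by_individual) empty$individual_id <- character()
    else empty$n_individuals <- integer()
    return(empty)
  }
  table$allele_id <- allele_id(table$position, table$ref, table$alt)
  keys <- if (by_individual) c("individual_id", "allele_id") else "allele_id"
  out <- table |>
    dplyr::group_by(dplyr::across(dplyr::all_of(
      c(keys, "position", "ref", "alt")))) |>
    dplyr::summarise(
      region = .data$region[1],
      c_number = dplyr::n(),
      aaa = mean(.data$abundance_pct),
      max_abundance = max(.data$abundance_pct),
      n_individuals = dplyr::n_distinct(.data$individual_id),
      .groups = "drop") |>
    dplyr::arrange(.data$position, .data$ref, .data$alt)
  if (by_individual) out$n_individuals <- NULL
  out
}

#' Simulated neutral reference curve in the AAA-vs-C# plane
#'
#' For each mutation rate in `mu_grid`, simulates `n_cells` independent
#' neutral single-site runs, optionally applies detection masking, and
#' records the resulting (C#, AAA) point. Alleles whose abundance is governed
#' by mutation pressure alone trace this curve; positively selected alleles
#' sit above it at matched C#.
#'
#' @param params A [sim_params()] object supplying N, generations and seed;
#'   `s` is forced to 0 (the curve is a neutral prediction).
#' @param mu_grid Ascending vector of mutation rates.
#' @param n_cells Simulated cells per grid point.
#' @param detection Optional [detection_params()]; when supplied, each
#'   simulated cell is assigned a coverage and masked by its sensitivity
#'   cutoff before counting detections.
#' @return A tibble `mu`, `c_number`, `aaa` (`aaa` is NA where no cell
#'   detected the allele; such points are omitted from a plotted curve).
#' @export
neutral_reference_curve <- function(params, mu_grid, n_cells,
                                    detection = NULL) {
  stopifnot(inherits(params, "sim_params"))
  if (!length(mu_grid)) stop("`mu_grid` must be non-empty", call. = FALSE)
  if (is.unsorted(mu_grid))
    stop("`mu_grid` must be sorted ascending", call. = FALSE)
  run_seeded(params$seed, function() {
    rows <- lapply(mu_grid, function(mu) {
      p <- sim_params(n_genomes = params$n_genomes, mu = mu, s = 0,
                      genome_length = params$genome_length,
                      generations = params$generations)
      ab <- simulate_site_ensemble(p, n_cells)$replicates$final_abundance_pct
      if (!is.null(detection)) {
        cov <- sample_coverage(n_cells, detection)
        ab[ab < sensitivity_cutoff(cov, detection$min_reads)] <- 0
      }
      pos <- ab[ab > 0]
      tibble::tibble(mu = mu, c_number = length(pos),
                     aaa = if (length(pos)) mean(pos) else NA_real_)
    })
    dplyr::bind_rows(rows)
  })
}

#' Histogram of per-record mutation abundances
#'
#' Bins every detected mutation record (one per cell and allele) by its
#' cellular abundance, after removing excluded alleles (e.g. a clonal mutant)
#' and excluded position ranges (e.g. the OriL homopolymer, mouse positions
#' 5172-5182). Bins are `[b, b + width)` with the final bin closed at 100.
#'
#' @param table A validated mutation table.
#' @param bin_width Bin width in percent (> 0).
#' @param exclude_alleles Character vector of allele ids to drop.
#' @param exclude_positions Optional data frame of 1-based closed ranges
#'   (`start`, `end`) whose records are dropped.
#' @return A tibble `bin_start`, `bin_end`, `count`; counts sum to the number
#'   of retained records.
#' @export
abundance_histogram <- function(table, bin_width = 2, exclude_alleles = NULL,
                                exclude_positions = NULL) {
  if (bin_width <= 0) stop("`bin_width` must be > 0", call. = FALSE)
  table <- validate_mutation_table(table)
  if (!is.null(exclude_alleles) && nrow(table)) {
    ids <- allele_id(table$position, table$ref, table$alt)
    table <- table[!(ids %in% exclude_alleles), , drop = FALSE]
  }
  if (!is.null(exclude_positions) && nrow(table))
    table <- table[!in_regions(table$position,
                               tibble::as_tibble(exclude_positions)), ,
                   drop = FALSE]
  breaks <- seq(0, 100 + bin_width, by = bin_width)
  n_bins <- ceiling(100 / bin_width)
  idx <- findInterval(table$abundance_pct, breaks,
                      rightmost.closed = FALSE)
  idx[table$abundance_pct >= 100] <- n_bins
  counts <- tabulate(idx, nbins = n_bins)
  tibble::tibble(bin_start = breaks[seq_len(n_bins)],
                 bin_end = breaks[seq_len(n_bins) + 1L],
                 count = counts)
}
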