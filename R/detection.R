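#' Detection-sensitivity parameters for single-cell variant calling
#'
#' Single-cell mtDNA sequencing only detects a mutation when enough reads
#' support it. Detection is modelled by the sensitivity cutoff
#' `100 * min_reads / coverage` (percent): simulated or synthetic abundances
#' below a cell's cutoff are treated as undetected. Cells whose coverage falls
#' below `min_cell_coverage` are removed altogether, mirroring the exclusion
#' of low-coverage cells from the sequencing datasets.
#'
#' Coverage is either an empirical list of per-cell coverages (sampled from
#' with replacement, as cells of a simulated cohort are randomly assigned the
#' coverage of a sequenced cell) or, when no empirical list is supplied, a
#' log-normal sampler.
#'
#' @param min_reads Minimum number of reads supporting a mutation (default 5).
#' @param coverage Optional numeric vector of empirical per-cell coverages;
#'   takes precedence over the parametric sampler.
#' @param coverage_meanlog,coverage_sdlog Log-normal parameters of the
#'   parametric coverage sampler (defaults: median 2,000x, sdlog 0.6).
#' @param min_cell_coverage Cells with coverage below this are dropped
#'   (default 50).
#' @return An object of class `detection_params`.
#' @export
detection_params <- function(min_reads = 5, coverage = NULL,
                             coverage_meanlog = log(2000),
                             coverage_sdlog = 0.6,
                             min_cell_coverage = 50) {
  if (min_reads < 1) stop("`min_reads` must be >= 1", call. = FALSE)
  if (!is.null(coverage)) {
    coverage <- as.numeric(coverage)
    if (!length(coverage) || any(!is.finite(coverage)) || any(coverage <= 0))
      stop("empirical `coverage` values must be positive", call. = FALSE)
  }
  if (coverage_sdlog < 0) stop("`coverage_sdlog` must be >= 0", call. = FALSE)
  structure(list(min_reads = min_reads, coverage = coverage,
                 coverage_meanlog = coverage_meanlog,
                 coverage_sdlog = coverage_sdlog,
                 min_cell_coverage = min_cell_coverage),
            class = "detection_params")
}

#' Abundance sensitivity cutoff implied by sequencing coverage
#'
#' The smallest detectable cellular abundance at a site covered by `coverage`
#' reads, given that `min_reads` reads must support a mutation:
#' `100 * min_reads / coverage` percent, capped at 100.
#'
#' @param coverage Read coverage (> 0), possibly a vector.
#' @param min_reads Minimum supporting reads (default 5).
#' @return Cutoff(s) in percent.
#' @examples
#' sensitivity_cutoff(500)    # 1
#' sensitivity_cutoff(10000)  # 0.05
#' @export
sensitivity_cutoff <- function(coverage, min_reads = 5) {
  if (!is.numeric(coverage) || any(!is.finite(coverage)) || any(coverage <= 0))
    stop("`coverage` must be positive", call. = FALSE)
  pmin(100 * min_reads / coverage, 100)
}

#' Draw per-cell coverages
#'
#' Samples `n` coverages from the empirical list in `params` (with
#' replacement) or from the parametric log-normal sampler when no empirical
#' list is set.
#'
#' @param n Number of cells.
#' @param params A [detection_params()] object.
#' @param seed Optional integer seed.
#' @return Numeric vector of length `n`.
#' @export
sample_coverage <- function(n, params = detection_params(), seed = NULL) {
  stopifnot(inherits(params, "detection_params"))
  run_seeded(seed, function() {
    if (!is.null(params$coverage))
      sample(params$coverage, n, replace = TRUE)
    else
      stats::rlnorm(n, params$coverage_meanlog, params$coverage_sdlog)
  })
}

#' Mask a mutation table by detection sensitivity
#'
#' Applies the coverage-dependent sensitivity model to a long-format mutation
#' table: rows whose `abundance_pct` falls strictly below the sensitivity
#' cutoff of their `coverage` are undetected and removed (in long format an
#' absent row is the zero), rows at or above the cutoff are kept unchanged,
#' and all rows of cells whose coverage is below `min_cell_coverage` are
#' dropped. Masking is idempotent and monotone in coverage.
#'
#' An optional stochastic mode replaces the deterministic threshold with read
#' sampling: a mutation at fraction p with c reads is detected iff
#' `Binomial(c, p) >= min_reads`. This is off by default; the deterministic
#' rule is the one used throughout the analyses.
#'
#' @param table A data frame with at least `abundance_pct` and `coverage`
#'   columns; if `cell_id` (and optionally `individual_id`) columns are
#'   present the low-coverage filter is applied per cell.
#' @param params A [detection_params()] object.
#' @param stochastic Use binomial read-sampling detection instead of the
#'   deterministic cutoff.
#' @param seed Optional integer seed (stochastic mode only).
#' @return The masked table (same columns, possibly fewer rows).
#' @export
apply_detection <- function(table, params = detection_params(),
                            stochastic = FALSE, seed = NULL) {
  stopifnot(inherits(params, "detection_params"))
  table <- tibble::as_tibble(table)
  if (!all(c("abundance_pct", "coverage") %in% names(table)))
    stop("`table` must have `abundance_pct` and `coverage` columns",
         call. = FALSE)
  if (anyNA(table$coverage))
    stop("missing coverage for one or more rows", call. = FALSE)
  if (any(table$abundance_pct < 0 | table$abundance_pct > 100))
    stop("abundances must lie in [0, 100]", call. = FALSE)
  if (!nrow(table)) return(table)
  detected <- if (stochastic) {
    run_seeded(seed, function() {
      stats::rbinom(nrow(table), round(table$coverage),
                    table$abundance_pct / 100) >= params$min_reads
    })
  } else {
    table$abundance_pct >= sensitivity_cutoff(table$coverage, params$min_reads)
  }
  table <- table[detected & table$abundance_pct > 0, , drop = FALSE]
  if ("cell_id" %in% names(table) && nrow(table)) {
    key <- if ("individual_id" %in% names(table))
      paste(table$individual_id, table$cell_id) else table$cell_id
    cell_cov <- tapply(table$coverage, key, mean)
    table <- table[cell_cov[key] >= params$min_cell_coverage, , drop = FALSE]
  } else if (nrow(table)) {
    table <- table[table$coverage >= params$min_cell_coverage, , drop = FALSE]
  }
  table
}
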