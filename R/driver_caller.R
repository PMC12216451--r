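#' Cohort threshold rules for calling driver alleles
#'
#' Driver (selfish replicative-drive) alleles are called by recurrence of
#' high cellular abundance across cells and individuals, which excludes both
#' neutral alleles (rarely abundant) and clonal expansions (confined to one
#' individual). Three rule kinds are provided:
#'
#' * `mouse_wt` - abundance strictly above 20% in at least `min_cells` (1)
#'   cell in at least `min_individuals` (3) of the examined mice (cohorts of
#'   5 in the WT mouse analysis; the denominator is whatever cohort is
#'   supplied).
#' * `mouse_mutator` - at least `min_cells` (3) qualifying cells in every
#'   examined individual; thresholds are higher than for WT because of the
#'   elevated mutation rate. By default qualifying cells must each exceed the
#'   abundance threshold (`cells_must_exceed_threshold = TRUE`); the laxer
#'   reading (any 3 detections, at least one above threshold) is available by
#'   setting it to `FALSE`.
#' * `human` - within a single individual: detected in at least `min_cells`
#'   (10) cells at abundance at or above 50%, with strictly more cells at or
#'   above 50% than below it (the majority clause; ties fail).
#'
#' The 20% mouse threshold is strict (`> 20`), the 50% human threshold
#' inclusive (`>= 50`).
#'
#' @param kind One of `"mouse_wt"`, `"mouse_mutator"`, `"human"`.
#' @param abundance_threshold Percent threshold (default 20 for mouse rules,
#'   50 for human).
#' @param min_cells Minimum qualifying cells per individual.
#' @param min_individuals Minimum number of individuals that must qualify;
#'   `NULL` means all individuals in the cohort (the mutator default) or 1
#'   (the human default).
#' @param cells_must_exceed_threshold Mutator rule only; see above.
#' @return An object of class `driver_rule`.
#' @export
driver_rule <- function(kind = c("mouse_wt", "mouse_mutator", "human"),
                        abundance_threshold = NULL, min_cells = NULL,
                        min_individuals = NULL,
                        cells_must_exceed_threshold = TRUE) {
  kind <- match.arg(kind)
  defaults <- switch(kind,
    mouse_wt = list(threshold = 20, min_cells = 1, min_individuals = 3,
                    strict = TRUE),
    mouse_mutator = list(threshold = 20, min_cells = 3,
                         min_individuals = NULL, strict = TRUE),
    human = list(threshold = 50, min_cells = 10, min_individuals = 1,
                 strict = FALSE))
  threshold <- abundance_threshold %||% defaults$threshold
  min_cells <- min_cells %||% defaults$min_cells
  if (threshold <= 0 || threshold > 100)
    stop("`abundance_threshold` must lie in (0, 100]", call. = FALSE)
  if (min_cells < 1) stop("`min_cells` must be >= 1", call. = FALSE)
  if (is.null(min_individuals)) min_individuals <- defaults$min_individuals
  structure(list(kind = kind, abundance_threshold = threshold,
                 min_cells = min_cells, min_individuals = min_individuals,
                 strict_threshold = defaults$strict,
                 cells_must_exceed_threshold = cells_must_exceed_threshold),
            class = "driver_rule")
}

#' @export
print.driver_rule <- function(x, ...) {
  cmp <- if (x$strict_threshold) ">" else ">="
  cat(sprintf("driver rule `%s`: %s %g%% abundance, >= %d cell(s)/individual",
              x$kind, cmp, x$abundance_threshold, x$min_cells))
  if (x$kind == "human") cat(", majority clause")
  cat(sprintf(", >= %s individual(s)\n",
              if (is.null(x$min_individuals)) "all" else x$min_individuals))
  invisible(x)
}

#' Classify alleles as drivers under a cohort rule
#'
#' Applies a [driver_rule()] to a multi-individual single-cell mutation
#' table. Every allele detected anywhere in the cohort receives a call; the
#' pass flag is fully determined by the rule and the per-individual
#' qualifying-cell counts, and raising any cell's abundance can never turn a
#' driver into a non-driver.
#'
#' @param table A validated mutation table covering the whole cohort.
#' @param rule A [driver_rule()] object.
#' @return A tibble with one row per allele: `allele_id`, `position`, `ref`,
#'   `alt`, `rule`, `pass`, `n_individuals_qualifying`,
#'   `total_qualifying_cells`. The per-individual supporting counts are
#'   attached as attribute `"per_individual"` (a tibble: `allele_id`,
#'   `individual_id`, `n_detected`, `n_qualifying`, `n_below`, `qualifies`).
#' @export
call_drivers <- function(table, rule) {
  stopifnot(inherits(rule, "driver_rule"))
  table <- validate_mutation_table(table)
  if (!nrow(table))
    stop("cannot call drivers from an empty cohort table", call. = FALSE)
  individuals <- unique(table$individual_id)
  n_ind <- length(individuals)
  need_ind <- rule$min_individuals %||% n_ind
  if (need_ind > n_ind)
    stop(sprintf(
      "rule `%s` requires %d qualifying individuals but the cohort has %d",
      rule$kind, need_ind, n_ind), call. = FALSE)
  thr <- rule$abundance_threshold
  above <- if (rule$strict_threshold) table$abundance_pct > thr
           else table$abundance_pct >= thr
  table$above <- above
  per_ind <- table |>
    dplyr::mutate(allele_id = allele_id(.data$position, .data$ref, .data$alt)) |>
    dplyr::group_by(.data$allele_id, .data$position, .data$ref, .data$alt,
                    .data$individual_id) |>
    dplyr::summarise(n_detected = dplyr::n(),
                     n_above = sum(.data$above),
                     n_below = sum(!.data$above),
                     .groups = "drop")
  per_ind$n_qualifying <- switch(rule$kind,
    mouse_wt = ,
    human = per_ind$n_above,
    mouse_mutator = if (rule$cells_must_exceed_threshold) per_ind$n_above
                    else per_ind$n_detected)
  per_ind$qualifies <- switch(rule$kind,
    mouse_wt = per_ind$n_above >= rule$min_cells,
    mouse_mutator = if (rule$cells_must_exceed_threshold)
        per_ind$n_above >= rule$min_cells
      else per_ind$n_detected >= rule$min_cells & per_ind$n_above >= 1,
    human = per_ind$n_above >= rule$min_cells &
      per_ind$n_above > per_ind$n_below)
  calls <- per_ind |>
    dplyr::group_by(.data$allele_id, .data$position, .data$ref, .data$alt) |>
    dplyr::summarise(n_individuals_qualifying = sum(.data$qualifies),
                     total_qualifying_cells = sum(.data$n_qualifying),
                     .groups = "drop") |>
    dplyr::mutate(rule = rule$kind,
                  pass = .data$n_individuals_qualifying >= need_ind) |>
    dplyr::select("allele_id", "position", "ref", "alt", "rule", "pass",
                  "n_individuals_qualifying", "total_qualifying_cells") |>
    dplyr::arrange(.data$position, .data$ref, .data$alt)
  attr(calls, "per_individual") <-
    per_ind[c("allele_id", "individual_id", "n_detected", "n_qualifying",
              "n_below", "qualifies")]
  calls
}
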