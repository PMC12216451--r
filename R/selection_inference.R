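#' Parameter grid for (mutation rate, selection coefficient) inference
#'
#' The default grid spans mutation rates from 1e-9 to 1e-2 in half-log steps
#' (15 values) and selection coefficients from -0.5 to +0.5 in steps of 0.05
#' (21 values): 315 models in all. Each model is simulated for `n_cells`
#' single-site runs of `generations` turnover cycles at population size
#' `n_genomes`, masked by detection sensitivity, filtered on positive-cell
#' count, and scored against the observed abundance distribution by a
#' permutation test.
#'
#' @param mu Ascending vector of mutation rates.
#' @param s Ascending vector of selection coefficients.
#' @param n_cells Simulated cells per model (9,833 to match the sequenced
#'   mutator-mouse cohort; scale down for desk-sized runs).
#' @param generations Turnover cycles per run (default 40, the aged-mouse
#'   scale).
#' @param n_genomes mtDNA copies per cell (default 10,000).
#' @param n_perm Permutations for the p-value (default 1,000).
#' @param seed Optional integer seed; the full grid fit is bit-reproducible
#'   given the seed.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(mu = 10^seq(-9, -2, by = 0.5),
                      s = seq(-0.5, 0.5, by = 0.05),
                      n_cells = 9833, generations = 40, n_genomes = 10000,
                      n_perm = 1000, seed = NULL) {
  if (!length(mu) || !length(s))
    stop("`mu` and `s` grids must be non-empty", call. = FALSE)
  if (is.unsorted(mu) || is.unsorted(s))
    stop("`mu` and `s` grids must be sorted ascending", call. = FALSE)
  if (any(mu < 0 | mu > 1)) stop("`mu` values must lie in [0, 1]", call. = FALSE)
  if (any(s <= -1)) stop("`s` values must be greater than -1", call. = FALSE)
  if (n_cells < 1 || n_perm < 1)
    stop("`n_cells` and `n_perm` must be >= 1", call. = FALSE)
  structure(list(mu = mu, s = s, n_cells = as.integer(n_cells),
                 generations = as.integer(generations),
                 n_genomes = as.integer(n_genomes),
                 n_perm = as.integer(n_perm), seed = seed),
            class = "grid_spec")
}

perm_stat <- function(x, n1) abs(mean(x[seq_len(n1)]) - mean(x[-seq_len(n1)]))

# Positive-cell filter: a model survives iff it produced no more than twice
# and no fewer than half the observed number of positive cells (inclusive).
positive_filter <- function(n_sim, n_obs) n_sim >= n_obs / 2 & n_sim <= 2 * n_obs

#' Permutation test for a difference in abundance means
#'
#' Tests whether the mean abundance of observed positive cells differs from
#' that of simulated positive cells. The statistic is the absolute difference
#' in means; group labels are permuted and the p-value uses the add-one
#' estimator `p = (1 + #{permuted >= observed}) / (n_perm + 1)`, so p is
#' never exactly zero. With `exact = TRUE` all label splits are enumerated
#' and the p-value is the exact proportion of splits whose statistic is at
#' least the observed one (the identity split included).
#'
#' @param observed,simulated Non-empty numeric vectors of positive-cell
#'   abundances (percent).
#' @param n_perm Number of random permutations.
#' @param exact Enumerate all `choose(n1 + n2, n1)` splits instead of
#'   sampling (only sensible for small samples).
#' @param seed Optional integer seed.
#' @return The p-value, in `[1 / (n_perm + 1), 1]`.
#' @export
permutation_pvalue <- function(observed, simulated, n_perm = 1000,
                               exact = FALSE, seed = NULL) {
  if (!length(observed) || !length(simulated))
    stop("`observed` and `simulated` must be non-empty (positive cells only)",
         call. = FALSE)
  pooled <- c(observed, simulated)
  n1 <- length(observed)
  stat_obs <- perm_stat(pooled, n1)
  if (exact) {
    n <- length(pooled)
    if (choose(n, n1) > 2e5)
      stop("too many splits to enumerate; use random permutations",
           call. = FALSE)
    splits <- utils::combn(n, n1)
    stats_all <- apply(splits, 2, function(idx)
      abs(mean(pooled[idx]) - mean(pooled[-idx])))
    return(mean(stats_all >= stat_obs))
  }
  run_seeded(seed, function() {
    exceed <- 0L
    for (i in seq_len(n_perm)) {
      stat_i <- perm_stat(sample(pooled), n1)
      if (stat_i >= stat_obs) exceed <- exceed + 1L
    }
    (1 + exceed) / (n_perm + 1)
  })
}

#' Grid-search inference of mutation rate and selection coefficient
#'
#' For each (mu, s) model in the grid: simulate `n_cells` independent
#' single-site runs, randomly assign each simulated cell a coverage, zero
#' abundances below the cell's sensitivity cutoff, and count positive
#' (detected) cells. Models producing more than twice or fewer than half the
#' observed number of positive cells are excluded (boundaries inclusive).
#' Surviving models are scored by [permutation_pvalue()] between observed and
#' simulated positive-cell abundances; the models with the highest p-value
#' match the data best.
#'
#' @param observed Numeric vector of observed positive-cell abundances
#'   (percent); its length is the observed positive-cell count.
#' @param grid A [grid_spec()] object.
#' @param detection A [detection_params()] object used for coverage
#'   assignment and masking.
#' @return An object of class `grid_fit`: a tibble with one row per model
#'   (`mu`, `s`, `n_positive`, `pass_filter`, `p_value`; `p_value` is NA for
#'   filtered-out models) carrying attributes `observed_n_positive` and
#'   `best` (the rows attaining the maximal p-value, empty when every model
#'   was filtered out, in which case a warning is issued).
#' @export
fit_grid <- function(observed, grid = grid_spec(),
                     detection = detection_params()) {
  stopifnot(inherits(grid, "grid_spec"),
            inherits(detection, "detection_params"))
  observed <- as.numeric(observed)
  if (!length(observed))
    stop("at least one observed positive cell is required", call. = FALSE)
  if (any(observed <= 0 | observed > 100))
    stop("observed abundances must lie in (0, 100]", call. = FALSE)
  n_obs <- length(observed)
  models <- expand.grid(s = grid$s, mu = grid$mu,
                        KEEP.OUT.ATTRS = FALSE)[, c("mu", "s")]
  res <- run_seeded(grid$seed, function() {
    n_pos <- integer(nrow(models))
    p_val <- rep(NA_real_, nrow(models))
    pass <- logical(nrow(models))
    for (i in seq_len(nrow(models))) {
      p <- sim_params(n_genomes = grid$n_genomes, mu = models$mu[i],
                      s = models$s[i], generations = grid$generations)
      ab <- simulate_site_ensemble(p, grid$n_cells)$replicates$final_abundance_pct
      cov <- sample_coverage(grid$n_cells, detection)
      ab[ab < sensitivity_cutoff(cov, detection$min_reads)] <- 0
      pos <- ab[ab > 0]
      n_pos[i] <- length(pos)
      pass[i] <- positive_filter(n_pos[i], n_obs)
      if (pass[i] && n_pos[i] > 0)
        p_val[i] <- permutation_pvalue(observed, pos, n_perm = grid$n_perm)
    }
    tibble::tibble(mu = models$mu, s = models$s, n_positive = n_pos,
                   pass_filter = pass, p_value = p_val)
  })
  attr(res, "observed_n_positive") <- n_obs
  if (any(!is.na(res$p_value))) {
    best <- res[!is.na(res$p_value) &
                  res$p_value == max(res$p_value, na.rm = TRUE), ]
  } else {
    warning("every model was excluded by the positive-cell filter",
            call. = FALSE)
    best <- res[0, ]
  }
  attr(res, "best") <- best
  class(res) <- c("grid_fit", class(res))
  res
}

#' @export
print.grid_fit <- function(x, ...) {
  cat(sprintf("(mu, s) grid fit: %d models, %d passing the positive-cell filter\n",
              nrow(x), sum(x$pass_filter)))
  cat(sprintf("  observed positive cells: %d\n",
              attr(x, "observed_n_positive")))
  best <- attr(x, "best")
  if (nrow(best)) {
    cat("  best-fitting model(s):\n")
    for (i in seq_len(nrow(best)))
      cat(sprintf("    mu = %.3g, s = %.3g (p = %.3g, %d positive cells)\n",
                  best$mu[i], best$s[i], best$p_value[i], best$n_positive[i]))
  } else cat("  no model passed the filter\n")
  invisible(x)
}
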