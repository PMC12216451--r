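#' Tissue-level accumulation trajectory of an allele
#'
#' Simulates the allele in many independent single cells and records, at each
#' requested generation, its mean abundance across all simulated cells - the
#' quantity a bulk-tissue assay measures. A neutral allele accumulates
#' linearly in tissue (mean fraction `1 - (1 - mu)^t`, about `mu * t`),
#' whereas a positively selected allele accumulates at an accelerating rate.
#'
#' @param params A [sim_params()] object (its `generations` bounds the
#'   trajectory).
#' @param n_cells Number of independent simulated cells (>= 1).
#' @param timepoints Generations at which to record the tissue mean; defaults
#'   to every generation from 0 to `params$generations`.
#' @return An object of class `tissue_trajectory`: a tibble `generation`,
#'   `mean_abundance_pct`, `n_cells`.
#' @export
simulate_tissue_mean <- function(params, n_cells, timepoints = NULL) {
  stopifnot(inherits(params, "sim_params"))
  n_cells <- as.integer(n_cells)
  if (is.na(n_cells) || n_cells < 1L)
    stop("`n_cells` must be a positive integer", call. = FALSE)
  timepoints <- as.integer(timepoints %||% 0:params$generations)
  if (any(is.na(timepoints)) || any(timepoints < 0L) ||
      any(timepoints > params$generations))
    stop("`timepoints` must lie in [0, generations]", call. = FALSE)
  if (is.unsorted(timepoints, strictly = TRUE))
    stop("`timepoints` must be strictly increasing", call. = FALSE)
  out <- run_seeded(params$seed, function() {
    k <- integer(n_cells)
    means <- numeric(length(timepoints))
    ti <- 1L
    if (timepoints[1L] == 0L) {
      means[1L] <- 0
      ti <- 2L
    }
    for (g in seq_len(max(timepoints))) {
      k <- wf_step(k, params$n_genomes, params$s, params$mu)$count
      if (ti <= length(timepoints) && g == timepoints[ti]) {
        means[ti] <- 100 * mean(k) / params$n_genomes
        ti <- ti + 1L
      }
    }
    means
  })
  structure(tibble::tibble(generation = timepoints,
                           mean_abundance_pct = out,
                           n_cells = n_cells),
            class = c("tissue_trajectory", "tbl_df", "tbl", "data.frame"))
}

#' Fit linear and power-function growth to an accumulation curve
#'
#' Fits both a straight line `y = a + b t` (ordinary least squares) and a
#' power function `y = a t^b` (nonlinear least squares in natural space, so
#' early zero abundances are handled) to (time, abundance) measurements, and
#' prefers the model with the lower AIC. Neutral accumulation is expected to
#' fit the line (power exponent near 1); replicative drive produces an
#' accelerating curve with exponent above 1. Works equally on simulated
#' tissue trajectories and bulk measurements such as allele-specific ddPCR
#' time courses.
#'
#' @param time Numeric vector of times (generations or age units); strictly
#'   positive times are required for the power fit. May also be a data frame
#'   with columns `time`/`generation` and `abundance`/`mean_abundance_pct`.
#' @param abundance Numeric vector of abundances (ignored when `time` is a
#'   data frame).
#' @param intercept_power Add an intercept to the power form
#'   (`y = c + a t^b`); off by default.
#' @return An object of class `growth_fit`: a list with `linear` (the `lm`
#'   fit), `power` (the `nls` fit), `aic` (named vector), `preferred`
#'   (`"linear"` or `"power"`), `linear_coef` (intercept, slope) and
#'   `power_coef` (scale, exponent and optionally intercept).
#' @export
fit_growth <- function(time, abundance = NULL, intercept_power = FALSE) {
  if (is.data.frame(time)) {
    df <- time
    tcol <- intersect(c("time", "generation", "age"), names(df))[1]
    ycol <- intersect(c("abundance", "abundance_pct", "mean_abundance_pct"),
                      names(df))[1]
    if (is.na(tcol) || is.na(ycol))
      stop("data frame must carry time and abundance columns", call. = FALSE)
    time <- df[[tcol]]
    abundance <- df[[ycol]]
  }
  if (length(time) != length(abundance))
    stop("`time` and `abundance` lengths differ", call. = FALSE)
  if (length(time) < 3)
    stop("at least 3 points are required", call. = FALSE)
  if (any(time <= 0))
    stop("power fitting requires strictly positive times", call. = FALSE)
  dat <- data.frame(t = as.numeric(time), y = as.numeric(abundance))
  linear <- stats::lm(y ~ t, data = dat)
  # starting values from a log-log regression on the positive points
  pos <- dat$y > 0
  if (sum(pos) >= 2) {
    ll <- stats::lm(log(y) ~ log(t), data = dat[pos, ])
    start <- list(a = exp(stats::coef(ll)[[1]]), b = stats::coef(ll)[[2]])
  } else {
    start <- list(a = max(dat$y, 1e-6) / max(dat$t), b = 1)
  }
  power <- if (intercept_power) {
    minpack.lm::nlsLM(y ~ c0 + a * t^b, data = dat,
                      start = c(start, list(c0 = min(dat$y))),
                      control = minpack.lm::nls.lm.control(maxiter = 200))
  } else {
    minpack.lm::nlsLM(y ~ a * t^b, data = dat, start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200))
  }
  aic <- c(linear = stats::AIC(linear), power = stats::AIC(power))
  structure(list(linear = linear, power = power, aic = aic,
                 preferred = names(aic)[which.min(aic)],
                 linear_coef = stats::coef(linear),
                 power_coef = stats::coef(power)),
            class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat("growth fit (linear vs power)\n")
  cat(sprintf("  linear: intercept %.4g, slope %.4g (AIC %.2f)\n",
              x$linear_coef[[1]], x$linear_coef[[2]], x$aic[["linear"]]))
  cat(sprintf("  power:  scale %.4g, exponent %.4g (AIC %.2f)\n",
              x$power_coef[["a"]], x$power_coef[["b"]], x$aic[["power"]]))
  cat(sprintf("  preferred: %s\n", x$preferred))
  invisible(x)
}
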