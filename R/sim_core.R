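#' Parameters for the intracellular mtDNA population model
#'
#' A cell's mtDNA copies are treated as a haploid population of constant size
#' that is completely replaced once per "Generation" (two half-lives of mtDNA,
#' 18.8 days). Each Generation, `n_genomes` offspring genomes are resampled
#' from the current population with a mutant genome weighted `1 + s` relative
#' to wild type, after which each wild-type offspring mutates with probability
#' `mu` per site per replication. There is no back-mutation and no cell
#' division.
#'
#' @param n_genomes mtDNA copies per cell (population size N). Defaults to the
#'   mouse hepatocyte copy number of 10,000; use 5,000 for human hepatocytes
#'   (see [species_preset()]).
#' @param mu Mutation probability per base pair per replication cycle, in
#'   `[0, 1]`. Default `2e-8`.
#' @param s Selection coefficient of the mutant genome: `s = 0` neutral,
#'   `s > 0` positive selection (replicative drive), `-1 < s < 0` negative
#'   selection.
#' @param genome_length Genome length L in bp (mouse mtDNA: 16,299). Only used
#'   by whole-genome simulation.
#' @param generations Number of complete mtDNA turnover cycles t.
#' @param seed Optional integer seed; when supplied every simulation run from
#'   these parameters is reproducible.
#' @return An object of class `sim_params`.
#' @examples
#' sim_params(generations = 40)
#' @export
sim_params <- function(n_genomes = 10000, mu = 2e-8, s = 0,
                       genome_length = 16299, generations = 40, seed = NULL) {
  n_genomes <- as.integer(n_genomes)
  genome_length <- as.integer(genome_length)
  generations <- as.integer(generations)
  if (is.na(n_genomes) || n_genomes < 1L)
    stop("`n_genomes` must be a positive integer", call. = FALSE)
  if (!is.numeric(mu) || is.na(mu) || mu < 0 || mu > 1)
    stop("`mu` must lie in [0, 1]", call. = FALSE)
  if (!is.numeric(s) || is.na(s) || s <= -1)
    stop("`s` must be greater than -1 (fitness 1 + s must be positive)",
         call. = FALSE)
  if (is.na(genome_length) || genome_length < 1L)
    stop("`genome_length` must be a positive integer", call. = FALSE)
  if (is.na(generations) || generations < 0L)
    stop("`generations` must be a non-negative integer", call. = FALSE)
  if (!is.null(seed)) seed <- as.integer(seed)
  structure(
    list(n_genomes = n_genomes, mu = mu, s = s,
         genome_length = genome_length, generations = generations,
         seed = seed),
    class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat("mtDNA population model parameters\n")
  cat(sprintf("  N (genomes/cell): %d\n", x$n_genomes))
  cat(sprintf("  mu (/bp/replication): %g\n", x$mu))
  cat(sprintf("  s: %g\n", x$s))
  cat(sprintf("  genome length (bp): %d\n", x$genome_length))
  cat(sprintf("  generations: %d\n", x$generations))
  if (!is.null(x$seed)) cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

#' Species presets for mtDNA copy number and genome length
#'
#' @param species `"mouse"` (N = 10,000 genomes/cell, L = 16,299 bp) or
#'   `"human"` (N = 5,000 genomes/cell, L = 16,569 bp).
#' @return A list with elements `n_genomes` and `genome_length`.
#' @export
species_preset <- function(species = c("mouse", "human")) {
  species <- match.arg(species)
  switch(species,
         mouse = list(n_genomes = 10000L, genome_length = 16299L),
         human = list(n_genomes = 5000L, genome_length = 16569L))
}

# One Wright-Fisher turnover for a biallelic site, vectorised over replicates.
# k: current mutant counts. Offspring pick a mutant parent with probability
# proportional to k*(1+s); wild-type offspring then mutate with probability mu.
# Returns the new counts and the number of de novo emergence events.
wf_step <- function(k, n_genomes, s, mu) {
  w <- k * (1 + s)
  p <- w / (w + (n_genomes - k))
  k1 <- stats::rbinom(length(k), n_genomes, p)
  emerged <- if (mu > 0) stats::rbinom(length(k), n_genomes - k1, mu)
             else integer(length(k))
  list(count = k1 + emerged, emerged = emerged)
}

run_seeded <- function(seed, expr) {
  if (is.null(seed)) expr() else withr::with_seed(seed, expr())
}

site_outcome <- function(count, n_genomes) {
  ifelse(count == 0L, "lost", ifelse(count == n_genomes, "fixed", "segregating"))
}

#' Simulate the trajectory of a single mtDNA site within one cell
#'
#' Tracks the mutant copy count of one site through `generations` turnover
#' cycles of Wright-Fisher resampling with selection, with recurrent de novo
#' mutation of wild-type offspring at rate `mu` and no back-mutation. Fixation
#' (count = N) is absorbing; a lost allele (count = 0) can only reappear
#' through a new emergence event.
#'
#' @param params A [sim_params()] object.
#' @param init_count Initial mutant copy count, in `[0, N]`.
#' @return An object of class `site_trajectory`: a list with `counts`
#'   (length `generations + 1`, starting at `init_count`),
#'   `abundance_pct` (the same trajectory as percent of N),
#'   `emergence_events` (number of de novo wild-type-to-mutant events during
#'   the run) and `outcome` (`"lost"`, `"segregating"` or `"fixed"`).
#' @examples
#' p <- sim_params(n_genomes = 1000, mu = 0, generations = 50, seed = 1)
#' simulate_site(p, init_count = 100)$outcome
#' @export
simulate_site <- function(params, init_count = 0L) {
  stopifnot(inherits(params, "sim_params"))
  init_count <- as.integer(init_count)
  if (is.na(init_count) || init_count < 0L || init_count > params$n_genomes)
    stop("`init_count` must lie in [0, n_genomes]", call. = FALSE)
  run_seeded(params$seed, function() {
    t <- params$generations
    counts <- integer(t + 1L)
    counts[1L] <- init_count
    emergence <- 0L
    k <- init_count
    for (g in seq_len(t)) {
      st <- wf_step(k, params$n_genomes, params$s, params$mu)
      k <- st$count
      emergence <- emergence + st$emerged
      counts[g + 1L] <- k
    }
    structure(
      list(counts = counts,
           abundance_pct = 100 * counts / params$n_genomes,
           emergence_events = as.integer(emergence),
           outcome = site_outcome(k, params$n_genomes),
           init_count = init_count,
           params = params),
      class = "site_trajectory")
  })
}

#' Simulate an ensemble of independent single-site runs
#'
#' Runs `n_reps` independent replicates of the single-site model (one
#' replicate per simulated cell) and summarises their final states. All
#' replicates are advanced jointly, one vectorised Wright-Fisher turnover per
#' generation, from a single RNG stream seeded by `params$seed`.
#'
#' @param params A [sim_params()] object.
#' @param n_reps Number of independent replicate cells (>= 1).
#' @param init_count Initial mutant copy count shared by all replicates.
#' @param threshold_pct Optional abundance threshold (percent); when given,
#'   the summary reports how many replicates end at or above it.
#' @return An object of class `site_ensemble`: a list with `replicates`
#'   (a tibble: `rep`, `final_count`, `final_abundance_pct`,
#'   `emergence_events`, `outcome`), `total_emergence`, `n_lost`,
#'   `n_segregating`, `n_fixed`, `n_persisting` (final count > 0) and, when
#'   requested, `n_above_threshold`.
#' @examples
#' p <- sim_params(mu = 2e-8, generations = 1600, seed = 7)
#' ens <- simulate_site_ensemble(p, n_reps = 250)
#' ens$total_emergence
#' @export
simulate_site_ensemble <- function(params, n_reps, init_count = 0L,
                                   threshold_pct = NULL) {
  stopifnot(inherits(params, "sim_params"))
  n_reps <- as.integer(n_reps)
  if (is.na(n_reps) || n_reps < 1L)
    stop("`n_reps` must be a positive integer", call. = FALSE)
  init_count <- as.integer(init_count)
  if (is.na(init_count) || init_count < 0L || init_count > params$n_genomes)
    stop("`init_count` must lie in [0, n_genomes]", call. = FALSE)
  run_seeded(params$seed, function() {
    k <- rep.int(init_count, n_reps)
    emergence <- integer(n_reps)
    for (g in seq_len(params$generations)) {
      st <- wf_step(k, params$n_genomes, params$s, params$mu)
      k <- st$count
      emergence <- emergence + st$emerged
    }
    outcome <- site_outcome(k, params$n_genomes)
    reps <- tibble::tibble(
      rep = seq_len(n_reps),
      final_count = as.integer(k),
      final_abundance_pct = 100 * k / params$n_genomes,
      emergence_events = as.integer(emergence),
      outcome = outcome)
    out <- list(replicates = reps,
                total_emergence = sum(emergence),
                n_lost = sum(outcome == "lost"),
                n_segregating = sum(outcome == "segregating"),
                n_fixed = sum(outcome == "fixed"),
                n_persisting = sum(k > 0L),
                params = params)
    if (!is.null(threshold_pct))
      out$n_above_threshold <- sum(100 * k / params$n_genomes >= threshold_pct)
    structure(out, class = "site_ensemble")
  })
}

#' @export
print.site_ensemble <- function(x, ...) {
  n <- nrow(x$replicates)
  cat(sprintf("Single-site ensemble: %d replicate cells, %d generations\n",
              n, x$params$generations))
  cat(sprintf("  emergence events: %d; persisting: %d; fixed: %d\n",
              x$total_emergence, x$n_persisting, x$n_fixed))
  invisible(x)
}

plant_table <- function(planted, genome_length, n_genomes) {
  if (is.null(planted))
    return(tibble::tibble(site = integer(), s = numeric(),
                          init_count = integer()))
  planted <- tibble::as_tibble(planted)
  if (!all(c("site", "s", "init_count") %in% names(planted)))
    stop("`planted` needs columns site, s, init_count", call. = FALSE)
  planted$site <- as.integer(planted$site)
  planted$init_count <- as.integer(planted$init_count)
  if (any(planted$site < 1L | planted$site > genome_length))
    stop("planted site outside [1, genome_length]", call. = FALSE)
  if (anyDuplicated(planted$site))
    stop("planted sites must be unique", call. = FALSE)
  if (any(planted$s <= -1))
    stop("planted `s` must be greater than -1", call. = FALSE)
  if (any(planted$init_count < 0L | planted$init_count > n_genomes))
    stop("planted `init_count` outside [0, n_genomes]", call. = FALSE)
  planted
}

#' Simulate whole-genome mutation accumulation in one cell
#'
#' Simulates all sites of an mtDNA genome of length L through `generations`
#' turnover cycles. New mutations arise during replication as a Poisson
#' process with expectation `N * L * mu` events per generation, each landing
#' at a uniformly drawn position on a uniformly drawn genome; repeat hits at a
#' segregating site add a copy to the existing allele (no triallelic
#' tracking).
#'
#' Two modes are available. `"marginal"` tracks each segregating site
#' independently by binomial resampling; this is exact in law under
#' neutrality and is the fast path for large cohorts, but refuses non-neutral
#' planted alleles. `"linked"` tracks whole genotypes (sets of mutations per
#' genome) with multiplicative fitness across carried mutations and
#' multinomial resampling, with zero recombination, and supports planted
#' alleles with `s != 0`.
#'
#' @param params A [sim_params()] object; `params$s` is ignored here
#'   (per-site selection enters through `planted`).
#' @param mode `"marginal"` or `"linked"`.
#' @param planted Optional data frame with columns `site`, `s`, `init_count`:
#'   alleles present (or destined to recur) from generation 0.
#' @return An object of class `cell_genome`: a list with `mutations` (tibble
#'   `site`, `count`, `abundance_pct` of all mutations present at >= 1 copy at
#'   the final generation) and `mode`.
#' @examples
#' p <- sim_params(mu = 2e-8, generations = 40, seed = 11)
#' simulate_genome(p)$mutations
#' @export
simulate_genome <- function(params, mode = c("marginal", "linked"),
                            planted = NULL) {
  stopifnot(inherits(params, "sim_params"))
  mode <- match.arg(mode)
  planted <- plant_table(planted, params$genome_length, params$n_genomes)
  if (mode == "marginal" && any(planted$s != 0))
    stop("marginal mode requires all planted fitness effects to be 0; ",
         "use mode = \"linked\" for selected alleles", call. = FALSE)
  run_seeded(params$seed, function() {
    mut <- if (mode == "marginal") genome_marginal(params, planted)
           else genome_linked(params, planted)
    structure(list(mutations = mut, mode = mode, params = params),
              class = "cell_genome")
  })
}

genome_marginal <- function(params, planted) {
  N <- params$n_genomes
  L <- params$genome_length
  sites <- planted$site
  counts <- planted$init_count
  lambda_new <- N * L * params$mu   # expected mutation events per turnover
  for (g in seq_len(params$generations)) {
    if (length(counts)) {
      counts <- stats::rbinom(length(counts), N, counts / N)
      keep <- counts > 0L
      sites <- sites[keep]
      counts <- counts[keep]
    }
    n_new <- stats::rpois(1L, lambda_new)
    if (n_new > 0L) {
      pos <- sample.int(L, n_new, replace = TRUE)
      for (p in pos) {
        idx <- match(p, sites)
        if (is.na(idx)) {
          sites <- c(sites, p)
          counts <- c(counts, 1L)
        } else if (stats::runif(1) < (N - counts[idx]) / N) {
          # a repeat hit only creates a new mutant copy on a wild-type genome
          counts[idx] <- counts[idx] + 1L
        }
      }
    }
  }
  keep <- counts > 0L
  sites <- sites[keep]
  counts <- counts[keep]
  ord <- order(sites)
  tibble::tibble(site = as.integer(sites[ord]),
                 count = as.integer(counts[ord]),
                 abundance_pct = 100 * counts[ord] / N)
}

genome_linked <- function(params, planted) {
  N <- params$n_genomes
  L <- params$genome_length
  s_of_site <- structure(planted$s, names = as.character(planted$site))
  site_fitness <- function(site) {
    s <- s_of_site[as.character(site)]
    ifelse(is.na(s), 1, 1 + s)
  }
  # genotype -> count map; genotypes are sorted integer vectors of sites
  genos <- list(integer(0))
  counts <- N
  fits <- 1
  for (i in seq_len(nrow(planted))) {
    if (planted$init_count[i] > 0L) {
      genos <- c(genos, list(planted$site[i]))
      counts <- c(counts, planted$init_count[i])
      counts[1L] <- counts[1L] - planted$init_count[i]
      fits <- c(fits, site_fitness(planted$site[i]))
    }
  }
  if (counts[1L] < 0L)
    stop("planted initial counts exceed n_genomes", call. = FALSE)
  p_mut <- 1 - (1 - params$mu)^L  # P(an offspring genome gains a new mutation)
  for (g in seq_len(params$generations)) {
    w <- counts * fits
    counts <- as.vector(stats::rmultinom(1L, N, w / sum(w)))
    n_mut <- stats::rbinom(length(counts), counts, p_mut)
    if (any(n_mut > 0L)) {
      for (i in which(n_mut > 0L)) {
        for (j in seq_len(n_mut[i])) {
          repeat {
            new_site <- sample.int(L, 1L)
            if (!(new_site %in% genos[[i]])) break
          }
          genos <- c(genos, list(sort(c(genos[[i]], new_site))))
          fits <- c(fits, fits[i] * site_fitness(new_site))
          counts <- c(counts, 1L)
        }
        counts[i] <- counts[i] - n_mut[i]
      }
    }
    keep <- counts > 0L | lengths(genos) == 0L   # always keep the WT class
    genos <- genos[keep]
    fits <- fits[keep]
    counts <- counts[keep]
  }
  per_site <- tapply(rep(counts, lengths(genos)), unlist(genos), sum)
  if (is.null(per_site) || !length(per_site))
    return(tibble::tibble(site = integer(), count = integer(),
                          abundance_pct = numeric()))
  sites <- as.integer(names(per_site))
  cnt <- as.integer(per_site)
  ord <- order(sites)
  tibble::tibble(site = sites[ord], count = cnt[ord],
                 abundance_pct = 100 * cnt[ord] / N)
}

#' Expected mutant fraction under neutral recurrent mutation
#'
#' Closed form of the recursion `E[p_{t+1}] = E[p_t] + mu (1 - E[p_t])`
#' starting from `p_0 = 0`, i.e. `1 - (1 - mu)^t`. Drift does not change the
#' expectation, so this is also the expected across-cell (tissue) abundance
#' of a neutral allele after `t` turnover cycles.
#'
#' @param mu Mutation probability per replication, in `[0, 1]`.
#' @param t Number of generations (>= 0), possibly a vector.
#' @return Expected mutant fraction(s) in `[0, 1]`.
#' @export
neutral_expectation <- function(mu, t) {
  if (!is.numeric(mu) || any(mu < 0 | mu > 1))
    stop("`mu` must lie in [0, 1]", call. = FALSE)
  if (!is.numeric(t) || any(t < 0))
    stop("`t` must be non-negative", call. = FALSE)
  1 - (1 - mu)^t
}

#' Deterministic (infinite-N) abundance trajectory under selection
#'
#' Iterates the infinite-population limit of one turnover cycle: selection
#' `p' = p (1 + s) / (1 + s p)` followed by recurrent mutation
#' `p'' = p' + mu (1 - p')`. Useful as a law-of-large-numbers oracle for the
#' stochastic simulator and for reasoning about driver growth rates.
#'
#' @param p0 Initial mutant fraction in `[0, 1]`.
#' @param s Selection coefficient (> -1).
#' @param mu Mutation probability per replication, in `[0, 1]`.
#' @param t Number of generations (>= 0).
#' @return Numeric vector of length `t + 1` (fractions, starting at `p0`);
#'   monotone non-decreasing whenever `s >= 0` and `mu >= 0`.
#' @export
selection_trajectory <- function(p0, s, mu, t) {
  if (!is.numeric(p0) || p0 < 0 || p0 > 1)
    stop("`p0` must lie in [0, 1]", call. = FALSE)
  if (s <= -1) stop("`s` must be greater than -1", call. = FALSE)
  if (mu < 0 || mu > 1) stop("`mu` must lie in [0, 1]", call. = FALSE)
  t <- as.integer(t)
  if (is.na(t) || t < 0) stop("`t` must be non-negative", call. = FALSE)
  p <- numeric(t + 1L)
  p[1L] <- p0
  for (g in seq_len(t)) {
    ps <- p[g] * (1 + s) / (1 + s * p[g])
    p[g + 1L] <- ps + mu * (1 - ps)
  }
  p
}

#' Model-clock and bookkeeping helpers
#'
#' `generation_days()` converts the mtDNA half-life into the length of one
#' model Generation (one complete population replacement, i.e. two
#' half-lives). `generations_at_age()` converts an age in years into a whole
#' number of Generations. `n_possible_substitutions()` counts the single-base
#' substitution alleles a genome of length L can produce (three per bp).
#' `fold_amplification()` expresses a rise from a single founding copy among
#' `n_genomes` to a final cellular fraction as a fold change.
#'
#' @param half_life_days mtDNA half-life in days (rat liver estimate: 9.4).
#' @param age_years Age in years.
#' @param genome_length Genome length in bp.
#' @param n_genomes mtDNA copies per cell.
#' @param final_fraction Final cellular abundance as a fraction in `[0, 1]`.
#' @return A number (days, Generations, allele count, or fold change).
#' @examples
#' generation_days()             # 18.8
#' generations_at_age(2)         # 39
#' generations_at_age(81)        # 1573
#' n_possible_substitutions(16299)
#' fold_amplification(5000, 0.5) # 2500
#' @name model_clock
NULL

#' @rdname model_clock
#' @export
generation_days <- function(half_life_days = 9.4) 2 * half_life_days

#' @rdname model_clock
#' @export
generations_at_age <- function(age_years, half_life_days = 9.4) {
  if (any(age_years < 0)) stop("`age_years` must be non-negative", call. = FALSE)
  round(age_years * 365 / generation_days(half_life_days))
}

#' @rdname model_clock
#' @export
n_possible_substitutions <- function(genome_length) {
  if (any(genome_length < 1)) stop("`genome_length` must be positive", call. = FALSE)
  3 * genome_length
}

#' @rdname model_clock
#' @export
fold_amplification <- function(n_genomes, final_fraction) {
  if (any(n_genomes < 1)) stop("`n_genomes` must be positive", call. = FALSE)
  if (any(final_fraction < 0 | final_fraction > 1))
    stop("`final_fraction` must lie in [0, 1]", call. = FALSE)
  final_fraction * n_genomes
}
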