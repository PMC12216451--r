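#' Configuration of a synthetic single-cell mtDNA cohort
#'
#' Describes a multi-individual single-cell mutation dataset with the
#' statistical structure the downstream analyses assume: a neutral
#' whole-genome mutation background, hypermutable homopolymer alleles (the
#' OriL indel hotspot, mouse positions 5172-5182), clonal alleles confined to
#' single individuals, positively selected NCR driver alleles, passengers
#' physically linked to drivers, coverage-limited detection and near-100%
#' attenuation ("leakage") of fixed alleles.
#'
#' The defaults encode the aged wild-type mouse liver setting: mouse copy
#' number and genome length, background mutation rate 2e-8 per bp per
#' replication, 40 turnover generations, one recurrent NCR driver
#' (position 15468, s = 0.2, mu = 1e-7, with a linked coding passenger at
#' position 12040) and one OriL hypermutable allele.
#'
#' @param n_individuals Number of individuals (default 5, a WT mouse cohort).
#' @param cells_per_individual Cells sequenced per individual.
#' @param species `"mouse"` or `"human"` (sets N and L; positions are
#'   preset-specific).
#' @param background_mu Neutral genome-wide mutation rate per bp per
#'   replication (default 2e-8).
#' @param generations Turnover generations (40 for an aged mouse, 1600 for an
#'   aged human).
#' @param drivers Data frame of planted drivers: `position`, `s`, `mu`,
#'   optional `region` (default `"NCR"`), optional `passenger_position` and
#'   `passenger_region` (NA for none).
#' @param hypermutable Data frame of hypermutable neutral alleles:
#'   `position`, `mu`, optional `region` (default `"OriL"`).
#' @param clonal Data frame of clonal alleles: `position`, `abundance_pct`
#'   (initial cellular abundance), `cell_fraction` (fraction of cells
#'   carrying), optional `individual` (index; each clone belongs to a single
#'   individual, drawn at random when omitted).
#' @param passenger_rate Probability that a driver's emergence in a cell
#'   occurs on a genome carrying its passenger mutation (realised as the
#'   fraction of cells simulated through the linked driver-passenger path).
#' @param leakage_ceiling Maximum reported abundance in percent (default 99):
#'   fixed alleles read out just below 100% because wild-type signal leaks
#'   between cells.
#' @param detection A [detection_params()] object.
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_individuals = 5,
                          cells_per_individual = 1000,
                          species = c("mouse", "human"),
                          background_mu = 2e-8,
                          generations = 40,
                          drivers = data.frame(position = 15468, s = 0.2,
                                               mu = 1e-7, region = "NCR",
                                               passenger_position = 12040,
                                               passenger_region = "coding"),
                          hypermutable = data.frame(position = 5177,
                                                    mu = 1e-4,
                                                    region = "OriL"),
                          clonal = NULL,
                          passenger_rate = 0.1,
                          leakage_ceiling = 99,
                          detection = detection_params(),
                          seed = 1L) {
  species <- match.arg(species)
  preset <- species_preset(species)
  L <- preset$genome_length
  norm <- function(df, cols, defaults = list()) {
    if (is.null(df) || !nrow(tibble::as_tibble(df)))
      return(tibble::as_tibble(c(
        stats::setNames(rep(list(numeric(0)), length(cols)), cols), defaults)[
          unique(c(cols, names(defaults)))])[0, ])
    df <- tibble::as_tibble(df)
    for (nm in names(defaults))
      if (!nm %in% names(df)) df[[nm]] <- defaults[[nm]]
    df
  }
  drivers <- norm(drivers, c("position", "s", "mu"),
                  list(region = "NCR", passenger_position = NA_real_,
                       passenger_region = "coding"))
  hypermutable <- norm(hypermutable, c("position", "mu"),
                       list(region = "OriL"))
  clonal <- norm(clonal, c("position", "abundance_pct", "cell_fraction"),
                 list(individual = NA_integer_))
  if (n_individuals < 1 || cells_per_individual < 1)
    stop("cohort must have >= 1 individual and >= 1 cell", call. = FALSE)
  if (background_mu < 0 || background_mu > 1)
    stop("`background_mu` must lie in [0, 1]", call. = FALSE)
  if (passenger_rate < 0 || passenger_rate > 1)
    stop("`passenger_rate` must lie in [0, 1]", call. = FALSE)
  if (leakage_ceiling <= 0 || leakage_ceiling > 100)
    stop("`leakage_ceiling` must lie in (0, 100]", call. = FALSE)
  planted_pos <- c(drivers$position, drivers$passenger_position[
    !is.na(drivers$passenger_position)], hypermutable$position,
    clonal$position)
  if (length(planted_pos)) {
    if (any(planted_pos < 1 | planted_pos > L))
      stop("planted position outside [1, L] for the chosen species",
           call. = FALSE)
    if (anyDuplicated(planted_pos))
      stop("conflicting planted positions across allele classes",
           call. = FALSE)
  }
  if (nrow(clonal) && any(clonal$abundance_pct < 0 | clonal$abundance_pct > 100))
    stop("clonal `abundance_pct` must lie in [0, 100]", call. = FALSE)
  if (nrow(clonal) && any(clonal$cell_fraction < 0 | clonal$cell_fraction > 1))
    stop("clonal `cell_fraction` must lie in [0, 1]", call. = FALSE)
  if (nrow(drivers) && any(drivers$mu < 0 | drivers$mu > 1))
    stop("driver `mu` must lie in [0, 1]", call. = FALSE)
  if (nrow(drivers) && any(drivers$s <= -1))
    stop("driver `s` must be greater than -1", call. = FALSE)
  if (nrow(hypermutable) && any(hypermutable$mu < 0 | hypermutable$mu > 1))
    stop("hypermutable `mu` must lie in [0, 1]", call. = FALSE)
  stopifnot(inherits(detection, "detection_params"))
  structure(list(n_individuals = as.integer(n_individuals),
                 cells_per_individual = as.integer(cells_per_individual),
                 species = species, n_genomes = preset$n_genomes,
                 genome_length = L, background_mu = background_mu,
                 generations = as.integer(generations),
                 drivers = drivers, hypermutable = hypermutable,
                 clonal = clonal, passenger_rate = passenger_rate,
                 leakage_ceiling = leakage_ceiling, detection = detection,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# Final mutant counts of n independent single-site WF runs (current RNG
# stream; no per-run reseeding).
ensemble_final_counts <- function(n, n_genomes, mu, s, t, init = 0L) {
  k <- rep.int(as.integer(init), n)
  for (g in seq_len(t)) k <- wf_step(k, n_genomes, s, mu)$count
  k
}

# Linked driver-passenger realisation in one cell: the passenger is planted
# first (one copy at generation 0), the driver is injected onto a surviving
# passenger-carrying genome at a random generation, and the three genotype
# classes (WT / passenger / passenger+driver) are resampled multinomially
# with the driver class weighted 1 + s. Returns final (driver, passenger)
# copy counts.
linked_pair_counts <- function(n_genomes, s, t) {
  cls <- c(n_genomes - 1L, 1L, 0L)     # WT, P, P+D
  w <- c(1, 1, 1 + s)
  g_inject <- sample.int(t, 1L)
  for (g in seq_len(t)) {
    if (g == g_inject && cls[2L] > 0L) {
      cls[2L] <- cls[2L] - 1L
      cls[3L] <- cls[3L] + 1L
    }
    wt <- cls * w
    cls <- as.vector(stats::rmultinom(1L, n_genomes, wt / sum(wt)))
  }
  c(driver = cls[3L], passenger = cls[2L] + cls[3L])
}

#' Generate a synthetic single-cell cohort with ground truth
#'
#' Simulates every cell of a [cohort_config()]: neutral background mutations
#' from the marginal whole-genome model, planted drivers and hypermutable
#' alleles from the single-site model with their own (mu, s), driver
#' passengers through a linked three-genotype model so that passenger
#' abundance tracks its driver within a cell, and clonal alleles seeded at
#' their initial abundance in a fraction of one individual's cells and
#' drifted neutrally. Fixed alleles are capped at the leakage ceiling and
#' detection masking is applied last.
#'
#' @param config A [cohort_config()] object.
#' @return An object of class `mt_cohort`: a list with `table` (a validated
#'   mutation table), `truth` (one row per planted allele: `allele_id`,
#'   `position`, `ref`, `alt`, `role` in driver/passenger/hypermutable/
#'   clonal, `s`, `mu`, `partner_position`, `individual`) and `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  N <- config$n_genomes
  L <- config$genome_length
  t <- config$generations
  run_seeded(config$seed, function() {
    bases <- c("A", "C", "G", "T")
    ref_of <- sample(4L, L, replace = TRUE)
    alt_of <- ((ref_of - 1L + sample.int(3L, L, replace = TRUE)) %% 4L) + 1L
    planted_pos <- c(config$drivers$position,
                     config$drivers$passenger_position,
                     config$hypermutable$position, config$clonal$position)
    planted_pos <- planted_pos[!is.na(planted_pos)]
    clonal <- config$clonal
    if (nrow(clonal)) {
      miss <- is.na(clonal$individual)
      clonal$individual[miss] <- sample.int(config$n_individuals, sum(miss),
                                            replace = TRUE)
    }
    empty_plant <- plant_table(NULL, L, N)
    bg_params <- sim_params(n_genomes = N, mu = config$background_mu, s = 0,
                            genome_length = L, generations = t)
    rows <- list()
    add_rows <- function(individual, cell, position, count, region) {
      rows[[length(rows) + 1L]] <<- tibble::tibble(
        individual_id = individual, cell_id = cell,
        position = as.integer(position), count = as.integer(count),
        region = region)
    }
    for (i in seq_len(config$n_individuals)) {
      ind <- sprintf("ind%02d", i)
      n_c <- config$cells_per_individual
      cells <- sprintf("c%05d", seq_len(n_c))
      if (config$background_mu > 0) {
        for (j in seq_len(n_c)) {
          m <- genome_marginal(bg_params, empty_plant)
          if (nrow(m)) {
            keep <- !(m$site %in% planted_pos)
            if (any(keep))
              add_rows(ind, cells[j], m$site[keep], m$count[keep],
                       NA_character_)
          }
        }
      }
      for (d in seq_len(nrow(config$drivers))) {
        drv <- config$drivers[d, ]
        has_pass <- !is.na(drv$passenger_position) && config$passenger_rate > 0
        paired <- if (has_pass) stats::runif(n_c) < config$passenger_rate
                  else rep(FALSE, n_c)
        dcount <- integer(n_c)
        pcount <- integer(n_c)
        n_un <- sum(!paired)
        if (n_un)
          dcount[!paired] <- ensemble_final_counts(n_un, N, drv$mu, drv$s, t)
        for (j in which(paired)) {
          pair <- linked_pair_counts(N, drv$s, t)
          dcount[j] <- pair[["driver"]]
          pcount[j] <- pair[["passenger"]]
        }
        det <- dcount > 0L
        if (any(det))
          add_rows(ind, cells[det], rep(drv$position, sum(det)), dcount[det],
                   drv$region)
        det <- pcount > 0L
        if (any(det))
          add_rows(ind, cells[det], rep(drv$passenger_position, sum(det)),
                   pcount[det], drv$passenger_region)
      }
      for (h in seq_len(nrow(config$hypermutable))) {
        hm <- config$hypermutable[h, ]
        cnt <- ensemble_final_counts(n_c, N, hm$mu, 0, t)
        det <- cnt > 0L
        if (any(det))
          add_rows(ind, cells[det], rep(hm$position, sum(det)), cnt[det],
                   hm$region)
      }
      if (nrow(clonal)) {
        for (cl in which(clonal$individual == i)) {
          carrier <- stats::runif(n_c) < clonal$cell_fraction[cl]
          n_car <- sum(carrier)
          if (n_car) {
            init <- max(1L, round(clonal$abundance_pct[cl] / 100 * N))
            cnt <- ensemble_final_counts(n_car, N, 0, 0, t, init = init)
            det <- cnt > 0L
            if (any(det))
              add_rows(ind, cells[carrier][det],
                       rep(clonal$position[cl], sum(det)), cnt[det],
                       "clonal")
          }
        }
      }
    }
    tab <- if (length(rows)) dplyr::bind_rows(rows) else
      tibble::tibble(individual_id = character(), cell_id = character(),
                     position = integer(), count = integer(),
                     region = character())
    truth <- cohort_truth(config, clonal, ref_of, alt_of, bases)
    if (!nrow(tab)) {
      empty <- tibble::as_tibble(stats::setNames(
        list(character(), character(), integer(), character(), character(),
             numeric(), numeric(), character()), mutation_table_cols))
      return(structure(list(table = empty, truth = truth, config = config),
                       class = "mt_cohort"))
    }
    tab$ref <- bases[ref_of[tab$position]]
    tab$alt <- bases[alt_of[tab$position]]
    tab$abundance_pct <- pmin(100 * tab$count / N, config$leakage_ceiling)
    cell_key <- paste(tab$individual_id, tab$cell_id)
    covs <- sample_coverage(config$n_individuals * config$cells_per_individual,
                            config$detection)
    names(covs) <- as.vector(outer(
      sprintf("c%05d", seq_len(config$cells_per_individual)),
      sprintf("ind%02d", seq_len(config$n_individuals)),
      function(c, i) paste(i, c)))
    tab$coverage <- unname(covs[cell_key])
    tab <- tab[order(tab$individual_id, tab$cell_id, tab$position), ]
    tab <- apply_detection(tab[mutation_table_cols], config$detection)
    tab <- validate_mutation_table(tab, genome_length = L)
    structure(list(table = tab, truth = truth, config = config),
              class = "mt_cohort")
  })
}

cohort_truth <- function(config, clonal, ref_of, alt_of, bases) {
  truth_row <- function(position, role, s, mu, partner, individual) {
    position <- as.integer(position)
    tibble::tibble(
      allele_id = allele_id(position, bases[ref_of[position]],
                            bases[alt_of[position]]),
      position = position, ref = bases[ref_of[position]],
      alt = bases[alt_of[position]], role = role, s = s, mu = mu,
      partner_position = as.integer(partner),
      individual = as.integer(individual))
  }
  parts <- list()
  for (d in seq_len(nrow(config$drivers))) {
    drv <- config$drivers[d, ]
    parts[[length(parts) + 1L]] <-
      truth_row(drv$position, "driver", drv$s, drv$mu, NA, NA)
    if (!is.na(drv$passenger_position))
      parts[[length(parts) + 1L]] <-
        truth_row(drv$passenger_position, "passenger", 0, NA, drv$position,
                  NA)
  }
  for (h in seq_len(nrow(config$hypermutable)))
    parts[[length(parts) + 1L]] <-
      truth_row(config$hypermutable$position[h], "hypermutable", 0,
                config$hypermutable$mu[h], NA, NA)
  for (cl in seq_len(nrow(clonal)))
    parts[[length(parts) + 1L]] <-
      truth_row(clonal$position[cl], "clonal", 0, NA, NA,
                clonal$individual[cl])
  if (!length(parts))
    return(tibble::tibble(allele_id = character(), position = integer(),
                          ref = character(), alt = character(),
                          role = character(), s = numeric(), mu = numeric(),
                          partner_position = integer(),
                          individual = integer()))
  dplyr::bind_rows(parts)
}

#' @export
print.mt_cohort <- function(x, ...) {
  cat(sprintf(
    "synthetic mtDNA cohort (%s): %d individuals x %d cells, %d detected mutation records\n",
    x$config$species, x$config$n_individuals, x$config$cells_per_individual,
    nrow(x$table)))
  cat(sprintf("  planted alleles: %d (%s)\n", nrow(x$truth),
              paste(unique(x$truth$role), collapse = ", ")))
  invisible(x)
}
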