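test_that("an empty configuration yields an empty, well-typed table", {
  cfg <- cohort_config(n_individuals = 2, cells_per_individual = 10,
                       background_mu = 0, drivers = NULL,
                       hypermutable = NULL, seed = 1)
  coh <- generate_cohort(cfg)
  expect_identical(nrow(coh$table), 0L)
  expect_identical(nrow(coh$truth), 0L)
  expect_named(coh$table, c("individual_id", "cell_id", "position", "ref",
                            "alt", "abundance_pct", "coverage", "region"))
})

test_that("cohorts are reproducible from their seed", {
  cfg <- cohort_config(n_individuals = 2, cells_per_individual = 50,
                       seed = 42)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$table, b$table)
  expect_identical(a$truth, b$truth)
})

test_that("configuration invariants are enforced", {
  expect_error(cohort_config(drivers = data.frame(position = 20000, s = 0.2,
                                                  mu = 1e-7)),
               "position")
  expect_error(cohort_config(
    drivers = data.frame(position = 5177, s = 0.2, mu = 1e-7)),
    "conflicting")  # collides with the default OriL hypermutable site
  expect_error(cohort_config(passenger_rate = 2), "passenger_rate")
  expect_error(cohort_config(leakage_ceiling = 0), "leakage_ceiling")
  expect_error(cohort_config(
    clonal = data.frame(position = 9000, abundance_pct = 150,
                        cell_fraction = 0.5)), "abundance_pct")
})

test_that("reported abundances respect detection cutoffs and the leakage ceiling", {
  cfg <- cohort_config(n_individuals = 2, cells_per_individual = 300,
                       generations = 60,
                       clonal = data.frame(position = 9000,
                                           abundance_pct = 99.5,
                                           cell_fraction = 0.5,
                                           individual = 1),
                       leakage_ceiling = 99, seed = 7)
  coh <- generate_cohort(cfg)
  tab <- coh$table
  expect_true(all(tab$abundance_pct > 0 & tab$abundance_pct <= 99))
  cutoffs <- sensitivity_cutoff(tab$coverage, cfg$detection$min_reads)
  expect_true(all(tab$abundance_pct >= cutoffs))
  # drifted clonal copies that fix are reported at the ceiling, never 100
  clonal_rows <- tab[tab$position == 9000, ]
  expect_gt(nrow(clonal_rows), 0)
  expect_lte(max(clonal_rows$abundance_pct), 99)
})

test_that("every planted allele in the table is labelled in the ground truth", {
  cfg <- cohort_config(n_individuals = 3, cells_per_individual = 200,
                       clonal = data.frame(position = 9000,
                                           abundance_pct = 40,
                                           cell_fraction = 0.2),
                       seed = 11)
  coh <- generate_cohort(cfg)
  expect_identical(anyDuplicated(coh$truth$allele_id), 0L)
  planted_in_table <- unique(coh$table$position[!is.na(coh$table$region)])
  expect_true(all(planted_in_table %in% coh$truth$position))
  expect_setequal(
    coh$truth$role,
    c("driver", "passenger", "hypermutable", "clonal"))
})

test_that("a planted driver sits above the neutral AAA-vs-C# reference curve", {
  det <- detection_params()
  cfg <- cohort_config(n_individuals = 1, cells_per_individual = 3000,
                       background_mu = 0, hypermutable = NULL,
                       drivers = data.frame(position = 15468, s = 0.3,
                                            mu = 1e-7, region = "NCR",
                                            passenger_position = NA,
                                            passenger_region = NA),
                       detection = det, seed = 13)
  coh <- generate_cohort(cfg)
  s <- summarize_alleles(coh$table)
  driver_row <- s[s$position == 15468, ]
  expect_gte(nrow(driver_row), 1)
  curve <- neutral_reference_curve(
    sim_params(generations = 40, seed = 13), mu_grid = 1e-7,
    n_cells = 3000, detection = det)
  expect_gt(driver_row$aaa, curve$aaa)
})

test_that("passenger abundance tracks its driver within cells; controls do not", {
  cfg <- cohort_config(
    n_individuals = 1, cells_per_individual = 4000, background_mu = 0,
    drivers = data.frame(position = 15468, s = 0.3, mu = 2e-7,
                         region = "NCR", passenger_position = 12040,
                         passenger_region = "coding"),
    hypermutable = data.frame(position = 5177, mu = 1e-4, region = "OriL"),
    passenger_rate = 0.5, seed = 17)
  coh <- generate_cohort(cfg)
  tab <- coh$table
  wide <- tidyr_lite(tab, c(15468L, 12040L, 5177L))
  both <- wide[wide$p15468 > 0 & wide$p12040 > 0, ]
  expect_gt(nrow(both), 5)
  rho_linked <- stats::cor(both$p15468, both$p12040, method = "spearman")
  expect_gt(rho_linked, 0)
  ctrl <- wide[wide$p15468 > 0 & wide$p5177 > 0, ]
  if (nrow(ctrl) > 5) {
    rho_ctrl <- stats::cor(ctrl$p15468, ctrl$p5177, method = "spearman")
    expect_gt(rho_linked, rho_ctrl)
  }
})
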