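test_that("pigeonhole co-residence bound matches hand-derived cases", {
  expect_equal(min_coresidence(60, 60), 20)
  expect_equal(min_coresidence(80, 75), 55)
  expect_equal(min_coresidence(40, 50), 0)
  expect_equal(min_coresidence(100, 100), 100)
  expect_error(min_coresidence(120, 10), "abundances")
})

test_that("co-residence bound is symmetric, zero below saturation, 100 only at (100,100)", {
  withr::with_seed(1, {
    a <- stats::runif(200, 0, 100)
    b <- stats::runif(200, 0, 100)
    expect_equal(min_coresidence(a, b), min_coresidence(b, a))
    low <- a + b <= 100
    expect_true(all(min_coresidence(a, b)[low] == 0))
    expect_true(all(min_coresidence(a, b) < 100))
  })
})

test_that("per-cell maxima and the red square are computed as defined", {
  coding <- data.frame(start = 2751, end = 15288)
  tbl <- dplyr::bind_rows(
    make_table(cell = "cellA", position = 16100L, abundance = 80),  # driver
    make_table(cell = "cellA", position = 12000L, ref = "T", alt = "C",
               abundance = 75),                                      # coding
    make_table(cell = "cellB", position = 12000L, ref = "T", alt = "C",
               abundance = 60),                                      # no driver
    make_table(cell = "cellC", position = 16100L, abundance = 55))   # no coding
  pts <- per_cell_max_table(tbl, driver_alleles = allele_id(16100, "A", "G"),
                            coding_regions = coding)
  a <- pts[pts$cell_id == "cellA", ]
  expect_equal(a$max_driver_pct, 80)
  expect_equal(a$max_coding_pct, 75)
  expect_true(a$in_red_square)
  expect_equal(pts$max_driver_pct[pts$cell_id == "cellB"], 0)
  expect_false(any(pts$in_red_square[pts$cell_id != "cellA"]))
  # red-square membership forces a positive co-residence bound
  red <- pts[pts$in_red_square, ]
  expect_true(all(min_coresidence(red$max_driver_pct, red$max_coding_pct) > 0))
  expect_error(per_cell_max_table(tbl, "x", data.frame()), "coding-region")
})

test_that("excluded alleles are ignored in per-cell maxima", {
  coding <- data.frame(start = 2751, end = 15288)
  tbl <- dplyr::bind_rows(
    make_table(cell = "cellA", position = 16100L, abundance = 80),
    make_table(cell = "cellA", position = 9000L, ref = "C", alt = "A",
               abundance = 90),
    make_table(cell = "cellA", position = 12000L, ref = "T", alt = "C",
               abundance = 30))
  pts <- per_cell_max_table(tbl, allele_id(16100, "A", "G"), coding,
                            exclude_alleles = allele_id(9000, "C", "A"))
  expect_equal(pts$max_coding_pct, 30)
})

test_that("linked cohorts fill the red square more than unlinked controls", {
  drivers <- data.frame(position = 15468, s = 0.35, mu = 3e-7,
                        region = "NCR", passenger_position = 12040,
                        passenger_region = "coding")
  base <- list(n_individuals = 2, cells_per_individual = 2000,
               background_mu = 0, hypermutable = NULL)
  linked <- generate_cohort(do.call(cohort_config, c(
    base, list(drivers = drivers, passenger_rate = 0.5, seed = 23))))
  unlinked <- generate_cohort(do.call(cohort_config, c(
    base, list(drivers = drivers, passenger_rate = 0, seed = 23))))
  coding <- data.frame(start = 2751, end = 15288)
  drv_ids <- linked$truth$allele_id[linked$truth$role == "driver"]
  red_frac <- function(coh) {
    pts <- per_cell_max_table(coh$table, drv_ids, coding)
    # denominator: all simulated cells, not just cells with detections
    sum(pts$in_red_square) / (2 * 2000)
  }
  expect_gt(red_frac(linked), red_frac(unlinked))
})
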