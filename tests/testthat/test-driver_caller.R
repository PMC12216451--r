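test_that("WT mouse rule: >20% in >=1 cell in >=3 of 5 mice", {
  rule <- driver_rule("mouse_wt")
  # abundant in exactly three mice -> driver
  tbl <- allele_cohort_table(list(m1 = 25, m2 = 30, m3 = 21, m4 = numeric(0),
                                  m5 = numeric(0)))
  calls <- call_drivers(tbl, rule)
  expect_true(calls$pass[calls$position == 16100])

  # abundant in only two mice -> not a driver
  tbl2 <- allele_cohort_table(list(m1 = 25, m2 = 30, m3 = numeric(0),
                                   m4 = numeric(0), m5 = numeric(0)))
  expect_false(call_drivers(tbl2, rule)$pass[1])

  # the 20% threshold is strict: 20.0% does not qualify
  tbl3 <- allele_cohort_table(list(m1 = 20, m2 = 20, m3 = 20, m4 = 20,
                                   m5 = 20))
  calls3 <- call_drivers(tbl3, rule)
  expect_false(calls3$pass[calls3$position == 16100])

  # the decoy allele is called (negatively) too: every allele gets a call
  expect_setequal(calls$position, c(16100L, 200L))
  expect_false(calls$pass[calls$position == 200])
})

test_that("mutator rule: qualifying cells in every examined individual", {
  rule <- driver_rule("mouse_mutator")
  # >=3 cells above 20% in all three mice -> driver
  tbl <- allele_cohort_table(list(m1 = c(25, 30, 40), m2 = c(21, 22, 23),
                                  m3 = c(50, 60, 70)))
  expect_true(call_drivers(tbl, rule)$pass[2])

  # one mouse with only 2 qualifying cells -> fails
  tbl2 <- allele_cohort_table(list(m1 = c(25, 30, 40), m2 = c(21, 22),
                                   m3 = c(50, 60, 70)))
  expect_false(call_drivers(tbl2, rule)$pass[2])

  # lax reading: three detections suffice if at least one exceeds threshold
  lax <- driver_rule("mouse_mutator", cells_must_exceed_threshold = FALSE)
  tbl3 <- allele_cohort_table(list(m1 = c(25, 3, 4), m2 = c(21, 1, 2),
                                   m3 = c(50, 5, 6)))
  expect_false(call_drivers(tbl3, rule)$pass[2])
  expect_true(call_drivers(tbl3, lax)$pass[2])
})

test_that("human rule: >=10 cells at >=50% with a strict majority above 50%", {
  rule <- driver_rule("human")
  tbl <- allele_cohort_table(list(h1 = c(rep(60, 12), rep(10, 5))))
  expect_true(call_drivers(tbl, rule)$pass[2])

  # majority clause fails: 12 cells >=50% but 15 below
  tbl2 <- allele_cohort_table(list(h1 = c(rep(60, 12), rep(10, 15))))
  expect_false(call_drivers(tbl2, rule)$pass[2])

  # the 50% threshold is inclusive, and ties fail the strict majority
  tbl3 <- allele_cohort_table(list(h1 = c(rep(50, 10), rep(10, 10))))
  expect_false(call_drivers(tbl3, rule)$pass[2])
  tbl4 <- allele_cohort_table(list(h1 = c(rep(50, 10), rep(10, 9))))
  expect_true(call_drivers(tbl4, rule)$pass[2])
})

test_that("rule/cohort mismatches and empty cohorts are usage errors", {
  tbl <- allele_cohort_table(list(m1 = 25, m2 = 30))
  expect_error(call_drivers(tbl, driver_rule("mouse_wt")), "individuals")
  expect_error(call_drivers(make_table()[0, ], driver_rule("human")), "empty")
  expect_error(driver_rule("human", abundance_threshold = 0), "threshold")
  expect_error(driver_rule("mouse_wt", min_cells = 0), "min_cells")
})

test_that("raising any cell's abundance never turns a driver into a non-driver", {
  rules <- list(driver_rule("mouse_wt", min_individuals = 2),
                driver_rule("mouse_mutator"),
                driver_rule("human"))
  withr::with_seed(61, {
    for (rep in 1:15) {
      tbl <- allele_cohort_table(list(
        m1 = stats::runif(sample(1:15, 1), 1, 95),
        m2 = stats::runif(sample(1:15, 1), 1, 95),
        m3 = stats::runif(sample(1:15, 1), 1, 95)))
      for (rule in rules) {
        before <- call_drivers(tbl, rule)
        bumped <- tbl
        i <- sample(nrow(tbl), 1)
        bumped$abundance_pct[i] <-
          min(100, bumped$abundance_pct[i] + stats::runif(1, 0, 60))
        after <- call_drivers(bumped, rule)
        idx <- match(before$allele_id, after$allele_id)
        expect_true(all(!before$pass | after$pass[idx]))
      }
    }
  })
})

test_that("planted strong drivers are recovered from a synthetic cohort", {
  cfg <- cohort_config(
    n_individuals = 5, cells_per_individual = 3000,
    drivers = data.frame(position = c(15468, 16012, 15417), s = 0.3,
                         mu = 1e-7, region = "NCR",
                         passenger_position = c(12040, NA, NA),
                         passenger_region = "coding"),
    clonal = data.frame(position = 9000, abundance_pct = 60,
                        cell_fraction = 0.3, individual = 2),
    seed = 101)
  coh <- generate_cohort(cfg)
  calls <- call_drivers(coh$table, driver_rule("mouse_wt"))
  planted_drivers <- coh$truth$allele_id[coh$truth$role == "driver"]
  called <- calls$allele_id[calls$pass]
  expect_gte(mean(planted_drivers %in% called), 0.8)     # sensitivity
  # no neutral background allele is flagged, and specificity on all
  # non-driver alleles stays above 0.99
  background <- setdiff(calls$allele_id, coh$truth$allele_id)
  expect_length(intersect(background, called), 0)
  negatives <- setdiff(calls$allele_id, planted_drivers)
  expect_gte(1 - length(intersect(negatives, called)) / length(negatives),
             0.99)
  # the clonal expansion is confined to one individual and never called
  clonal_id <- coh$truth$allele_id[coh$truth$role == "clonal"]
  expect_false(clonal_id %in% called)
})
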