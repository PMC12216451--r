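test_that("degenerate single-site runs behave as forced", {
  p <- sim_params(n_genomes = 500, mu = 0, s = 0.1, generations = 40, seed = 1)
  tr <- simulate_site(p, init_count = 0L)
  expect_identical(tr$counts, integer(41))
  expect_identical(tr$emergence_events, 0L)
  expect_identical(tr$outcome, "lost")

  p0 <- sim_params(n_genomes = 500, mu = 0, s = 0, generations = 40, seed = 2)
  tr <- simulate_site(p0, init_count = 500L)
  expect_true(all(tr$counts == 500L))
  expect_identical(tr$outcome, "fixed")

  # fixation is absorbing even under recurrent mutation (no back-mutation)
  pm <- sim_params(n_genomes = 200, mu = 1e-3, s = 0, generations = 100,
                   seed = 3)
  tr <- simulate_site(pm, init_count = 200L)
  expect_true(all(tr$counts == 200L))
})

test_that("parameter validation rejects out-of-domain inputs", {
  expect_error(sim_params(mu = -0.1), "mu")
  expect_error(sim_params(mu = 1.5), "mu")
  expect_error(sim_params(s = -1), "s")
  expect_error(sim_params(n_genomes = 0), "n_genomes")
  expect_error(sim_params(generations = -1), "generations")
  p <- sim_params(n_genomes = 100, generations = 5)
  expect_error(simulate_site(p, init_count = -1), "init_count")
  expect_error(simulate_site(p, init_count = 101), "init_count")
  expect_error(simulate_site_ensemble(p, 0), "n_reps")
  expect_error(neutral_expectation(-1e-3, 10), "mu")
  expect_error(selection_trajectory(0.5, -1, 0, 10), "s")
  expect_error(selection_trajectory(1.2, 0, 0, 10), "p0")
})

test_that("identical parameters and seed reproduce trajectories bit-identically", {
  p <- sim_params(n_genomes = 1000, mu = 1e-4, s = 0.05, generations = 60,
                  seed = 99)
  a <- simulate_site(p, init_count = 10L)
  b <- simulate_site(p, init_count = 10L)
  expect_identical(a$counts, b$counts)
  expect_identical(a$emergence_events, b$emergence_events)
  ea <- simulate_site_ensemble(p, 50)
  eb <- simulate_site_ensemble(p, 50)
  expect_identical(ea$replicates, eb$replicates)
  g1 <- simulate_genome(sim_params(mu = 1e-6, generations = 40, seed = 5))
  g2 <- simulate_genome(sim_params(mu = 1e-6, generations = 40, seed = 5))
  expect_identical(g1$mutations, g2$mutations)
})

test_that("counts stay within [0, N] and trajectories respect absorption", {
  p <- sim_params(n_genomes = 50, mu = 5e-3, s = 0.2, generations = 200,
                  seed = 7)
  tr <- simulate_site(p, init_count = 1L)
  expect_true(all(tr$counts >= 0 & tr$counts <= 50))
  hit_fix <- which(tr$counts == 50)
  if (length(hit_fix))
    expect_true(all(tr$counts[seq(min(hit_fix), length(tr$counts))] == 50))
})

test_that("neutral drift is a martingale in the mean", {
  p <- sim_params(n_genomes = 200, mu = 0, s = 0, generations = 50, seed = 11)
  ens <- simulate_site_ensemble(p, 20000, init_count = 60L)
  final <- ens$replicates$final_count
  se <- stats::sd(final) / sqrt(length(final))
  expect_lt(abs(mean(final) - 60), 3 * se)
})

test_that("neutral fixation probability matches the exact Markov-chain oracle", {
  N <- 10L
  exact <- wf_fixation_prob_exact(N, init = 1L, n_iter = 1000)
  expect_equal(exact, 1 / N, tolerance = 1e-8)  # martingale cross-check
  p <- sim_params(n_genomes = N, mu = 0, s = 0, generations = 400, seed = 13)
  ens <- simulate_site_ensemble(p, 40000, init_count = 1L)
  expect_identical(ens$n_segregating, 0L)  # fully absorbed by t = 400
  frac_fixed <- ens$n_fixed / 40000
  sd3 <- 3 * sqrt(exact * (1 - exact) / 40000)
  expect_lt(abs(frac_fixed - exact), sd3)
})

test_that("heterozygosity decays as (1 - 1/N)^t under neutral drift", {
  N <- 50L
  t <- 20L
  p0 <- 0.3
  p <- sim_params(n_genomes = N, mu = 0, s = 0, generations = t, seed = 17)
  ens <- simulate_site_ensemble(p, 20000, init_count = as.integer(N * p0))
  pf <- ens$replicates$final_count / N
  h <- pf * (1 - pf)
  expected <- p0 * (1 - p0) * (1 - 1 / N)^t
  se <- stats::sd(h) / sqrt(length(h))
  expect_lt(abs(mean(h) - expected), 3 * se)
})

test_that("emergence events are Poisson-thinned at rate N*mu per generation", {
  p <- sim_params(n_genomes = 10000, mu = 1e-5, s = 0, generations = 20,
                  seed = 19)
  ens <- simulate_site_ensemble(p, 500)
  lambda <- 500 * 20 * 10000 * 1e-5
  expect_lt(abs(ens$total_emergence - lambda), 3 * sqrt(lambda))
  pz <- sim_params(n_genomes = 10000, mu = 0, s = 0, generations = 100,
                   seed = 20)
  expect_identical(simulate_site_ensemble(pz, 100)$total_emergence, 0L)
})

test_that("ensemble mean under recurrent neutral mutation matches 1-(1-mu)^t", {
  mu <- 1e-4
  t <- 40L
  p <- sim_params(n_genomes = 10000, mu = mu, s = 0, generations = t,
                  seed = 23)
  ens <- simulate_site_ensemble(p, 10000)
  frac <- ens$replicates$final_count / 10000
  se <- stats::sd(frac) / sqrt(length(frac))
  expect_lt(abs(mean(frac) - neutral_expectation(mu, t)), 3 * se)
})

test_that("stochastic means track the deterministic selection recursion", {
  N <- 100000L
  t <- 30L
  s <- 0.2
  expected <- selection_trajectory(0.01, s, 0, t)
  p <- sim_params(n_genomes = N, mu = 0, s = s, generations = t)
  traj <- withr::with_seed(29, {
    m <- matrix(0L, nrow = t + 1, ncol = 300)
    for (r in seq_len(300)) {
      tr <- simulate_site(p, init_count = as.integer(0.01 * N))
      m[, r] <- tr$counts
    }
    m
  })
  frac <- traj / N
  for (g in c(5, 15, 30) + 1) {
    se <- stats::sd(frac[g, ]) / sqrt(ncol(frac))
    expect_lt(abs(mean(frac[g, ]) - expected[g]), 3 * se + 1e-9)
  }
})

test_that("selection_trajectory honours its closed-form limits", {
  expect_equal(selection_trajectory(0.25, 0, 0, 10), rep(0.25, 11))
  expect_equal(selection_trajectory(1, 0.3, 1e-4, 5), rep(1, 6))
  expect_equal(neutral_expectation(0.5, 0), 0)
  expect_equal(neutral_expectation(1, 1), 1)
  tr <- selection_trajectory(0.001, 0.2, 1e-6, 50)
  expect_true(all(diff(tr) >= 0))
})

test_that("whole-genome simulation honours its contracts", {
  p0 <- sim_params(mu = 2e-8, generations = 0, seed = 31)
  expect_identical(nrow(simulate_genome(p0)$mutations), 0L)

  p <- sim_params(n_genomes = 5000, mu = 1e-7, generations = 40, seed = 37)
  g <- simulate_genome(p)
  expect_true(all(g$mutations$count >= 1 & g$mutations$count <= 5000))
  expect_true(all(g$mutations$site >= 1 & g$mutations$site <= 16299))
  expect_false(anyDuplicated(g$mutations$site) > 0)

  expect_error(
    simulate_genome(p, mode = "marginal",
                    planted = data.frame(site = 5, s = 0.2, init_count = 1)),
    "linked")
  expect_error(
    simulate_genome(p, planted = data.frame(site = 20000, s = 0,
                                            init_count = 1)),
    "site")
})

test_that("marginal and linked genome modes agree in law under neutrality", {
  p <- sim_params(n_genomes = 2000, mu = 1e-6, generations = 40)
  counts <- withr::with_seed(41, {
    nm <- replicate(150, nrow(simulate_genome(p, "marginal")$mutations))
    nl <- replicate(150, nrow(simulate_genome(p, "linked")$mutations))
    list(nm = nm, nl = nl)
  })
  se <- sqrt(stats::var(counts$nm) / 150 + stats::var(counts$nl) / 150)
  expect_lt(abs(mean(counts$nm) - mean(counts$nl)), 3 * se)
})

test_that("linked mode carries a planted beneficial allele upward on average", {
  p <- sim_params(n_genomes = 1000, mu = 0, generations = 30)
  finals <- withr::with_seed(43, {
    replicate(200, {
      g <- simulate_genome(p, "linked",
                           planted = data.frame(site = 100, s = 0.3,
                                                init_count = 50))
      if (nrow(g$mutations)) g$mutations$count[g$mutations$site == 100] else 0
    })
  })
  # deterministic growth from 5% at s = 0.3 over 30 generations approaches 1
  expect_gt(mean(finals) / 1000, 0.5)
})

test_that("model clock and bookkeeping helpers compute the printed quantities", {
  expect_equal(generation_days(9.4), 18.8)
  expect_equal(generations_at_age(2), 39)
  expect_equal(generations_at_age(81), 1573)
  expect_equal(n_possible_substitutions(16299), 48897)
  expect_equal(fold_amplification(5000, 0.5), 2500)
  expect_error(fold_amplification(5000, 1.5), "final_fraction")
})
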