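test_that("percent undivided matches the precursor-cohort oracle exactly", {
  # hand cases frozen from the oracle: X = n_g * 2^(g-1)
  expect_equal(percent_undivided(c(100)), 100)
  expect_equal(percent_undivided(c(50, 50)), 100 * 50 / 75)
  expect_equal(percent_undivided(c(40, 30, 20, 10)),
               100 * 40 / (40 + 15 + 5 + 1.25))
  # random cohorts: build precursors, derive event frequencies, compare
  set.seed(21)
  for (i in 1:50) {
    n_g <- rgamma(sample(1:10, 1), 2)
    X <- oracle_events_from_precursors(n_g)
    expect_equal(percent_undivided(X), oracle_phi1_from_precursors(n_g),
                 tolerance = 1e-12)
  }
  expect_error(percent_undivided(c(0, 0)), "all zero")
})

test_that("phi series equals truncated re-application and is scale-free", {
  X <- c(40, 30, 20, 10)
  phi <- phi_series(X)
  expect_equal(phi[2], 100 * 30 / (30 + 10 + 2.5))
  expect_equal(phi[4], 100)
  for (k in seq_along(X))
    expect_equal(phi[k], percent_undivided(X[k:4]))
  expect_equal(phi_series(X * 7), phi)
  expect_equal(phi_series(X / 100), phi)
  # theta is the exact complement
  expect_equal(theta_series(X), 100 - phi)
  expect_equal(theta_series(c(100)), 0)
  expect_equal(theta_series(c(50, 50))[1], 100 - 100 * 50 / 75)
})

test_that("cohort indices satisfy their identities", {
  i1 <- proliferation_indices(c(100))
  expect_equal(i1$division_index, 0)
  expect_equal(i1$expansion_index, 1)
  i2 <- proliferation_indices(c(50, 50))  # precursors 50, 25
  expect_equal(i2$division_index, 25 / 75)
  expect_equal(i2$proliferation_index, 1)
  expect_equal(i2$expansion_index, 100 / 75)
  i3 <- proliferation_indices(c(0, 100))
  expect_equal(i3$division_index, 1)
  expect_equal(i3$proliferation_index, 1)
  expect_equal(i3$expansion_index, 2)
  set.seed(22)
  for (i in 1:25) {
    X <- random_simplex(sample(2:10, 1)) * 100
    idx <- proliferation_indices(X)
    expect_lte(idx$division_index, idx$proliferation_index + 1e-12)
    expect_gte(idx$expansion_index, 1 - 1e-12)
  }
})

test_that("proliferation summaries are internally consistent", {
  s <- proliferation_summary(c(40, 30, 20, 10), sample_id = "w1")
  expect_identical(s$D, 3L)
  expect_equal(s$Phi + s$Theta, rep(100, 4))
  expect_true(all(s$Phi >= 0 & s$Phi <= 100))
  expect_equal(s$Phi[4], 100)
  expect_equal(sum(s$bins), 100)
})

test_that("Holm-Sidak closed form matches the step-down oracle", {
  expect_equal(holm_sidak(c(0.01, 0.04)),
               c(1 - (1 - 0.01)^2, 0.04), tolerance = 1e-9)
  expect_equal(holm_sidak(0.3), 0.3)  # m = 1: identity
  set.seed(23)
  for (m in 2:6) {
    for (rep in 1:10) {
      p <- runif(m)
      adj <- holm_sidak(p)
      expect_equal(adj, oracle_holm_sidak(p), tolerance = 1e-9)
      expect_true(all(adj >= p - 1e-12))
      expect_true(all(adj <= 1))
      # monotone in the raw p ordering
      expect_true(all(diff(adj[order(p)]) >= -1e-12))
    }
  }
})

make_summaries <- function(phi1s, tail = c(30, 20, 10), jitter = 0,
                           seed = 1) {
  set.seed(seed)
  lapply(seq_along(phi1s), function(i) {
    # build a frequency vector whose Phi_1 is close to the requested value
    x1 <- phi1s[i] + rnorm(1, 0, jitter)
    proliferation_summary(c(x1, tail * (100 - x1) / sum(tail)),
                          sample_id = paste0("s", i))
  })
}

test_that("condition comparison reports the stated effect metric", {
  # treated mean Phi_1 = 60, control = 20 -> +200%
  tr <- lapply(c(60, 60), function(x)
    structure(list(sample_id = "t", X = c(x, 100 - x), D = 1L,
                   Phi = c(x, 100), Theta = c(100 - x, 0),
                   indices = proliferation_indices(c(x, 100 - x)),
                   bins = bin_generations(c(x, 100 - x))),
              class = "proliferation_summary"))
  ct <- lapply(c(20, 20), function(x)
    structure(list(sample_id = "c", X = c(x, 100 - x), D = 1L,
                   Phi = c(x, 100), Theta = c(100 - x, 0),
                   indices = proliferation_indices(c(x, 100 - x)),
                   bins = bin_generations(c(x, 100 - x))),
              class = "proliferation_summary"))
  res <- compare_conditions(tr, ct)
  expect_equal(res$effect_percent_increase_undivided, 200)
  # identical arms: 0% effect, degenerate variances flagged
  res0 <- compare_conditions(tr, tr)
  expect_equal(res0$effect_percent_increase_undivided, 0)
  expect_true(all(res0$per_generation$flag[1] == "degenerate_variance"))
  expect_true(all(is.na(res0$per_generation$p_raw[
    res0$per_generation$flag == "degenerate_variance"])))
})

test_that("per-generation tests are adjusted and medians compared", {
  # control cultures divide further (longer tails -> larger D)
  tr <- c(make_summaries(c(55, 60), jitter = 2, seed = 31),
          make_summaries(c(58, 62), tail = c(30, 20, 10, 5), jitter = 2,
                         seed = 33))
  ct <- c(make_summaries(c(20, 22), tail = c(30, 20, 10, 8, 5), jitter = 2,
                         seed = 32),
          make_summaries(c(19, 24), tail = c(30, 20, 10, 8, 5, 3),
                         jitter = 2, seed = 34))
  res <- compare_conditions(tr, ct)
  pg <- res$per_generation
  tested <- !is.na(pg$p_raw)
  expect_true(any(tested))
  expect_true(all(pg$p_adj[tested] >= pg$p_raw[tested] - 1e-12))
  expect_equal(pg$p_adj[tested], holm_sidak(pg$p_raw[tested]))
  expect_true(is.finite(res$mann_whitney_p))
  # welch vs pooled give different p in general
  res_p <- compare_conditions(tr, ct, method = "pooled")
  expect_s3_class(res_p, "comparison_result")
})

test_that("multi-condition ANOVA wrapper runs on Phi_1", {
  conds <- list(a = make_summaries(c(20, 22, 21), seed = 1),
                b = make_summaries(c(40, 42, 41), seed = 2),
                c = make_summaries(c(60, 62, 61), seed = 3))
  out <- anova_conditions(conds)
  expect_lt(out$p, 0.01)
})

test_that("simulate -> deconvolve -> Phi_1 recovers truth within 2 pp", {
  lm <- labeling_model(log10_initial_sd = 0.06, instrument_cv_log10 = 0,
                       autofluorescence_floor = -Inf)
  set.seed(41)
  for (i in 1:5) {
    prof <- random_recovery_profile(sample(3:8, 1))
    et <- simulate_cohort(prof, 10000, lm, seed = 500 + i)
    phi1 <- percent_undivided(fit_generations(et))
    expect_lt(abs(phi1 - 100 * prof[1]), 2)
  }
})

test_that("estimated Phi_1 increases monotonically with true p_1", {
  lm <- labeling_model(log10_initial_sd = 0.06, instrument_cv_log10 = 0,
                       autofluorescence_floor = -Inf)
  p1s <- c(0.1, 0.25, 0.4, 0.55, 0.7)
  phi <- vapply(seq_along(p1s), function(i) {
    rest <- c(0.4, 0.3, 0.2, 0.1) * (1 - p1s[i])
    et <- simulate_cohort(division_profile(c(p1s[i], rest)), 20000, lm,
                          seed = 600 + i)
    percent_undivided(fit_generations(et))
  }, numeric(1))
  expect_true(all(diff(phi) > 0))
})
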