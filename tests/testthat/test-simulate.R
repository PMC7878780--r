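# synthetic-cohort generator: distributional oracles and structure

test_that("trajectory simulation respects degenerate inputs", {
  p0 <- intensity_params()
  tr <- simulate_trajectory(2, 50, "female", p0, horizon = 5)
  expect_equal(tr, data.frame(time = 0, state = 2L), ignore_attr = TRUE)
  expect_error(simulate_trajectory(2, 50, "female", p0, horizon = -1),
               "horizon")
  expect_error(simulate_trajectory(5, 50, "female", p0, horizon = 1))
})

test_that("single-exit jump times are exponential with the right mean", {
  lam <- 0.4
  p <- toy_params(lam)
  set.seed(21)
  jumps <- replicate(10000, {
    tr <- simulate_trajectory(1, 50, "female", p, horizon = 100)
    if (nrow(tr) > 1) tr$time[2] else NA_real_
  })
  jumps <- jumps[!is.na(jumps)]
  se <- (1 / lam) / sqrt(length(jumps))
  expect_lt(abs(mean(jumps) - 1 / lam), 3 * se)
})

test_that("cohort state occupancy matches matrix-exponential predictions", {
  # the central oracle binding the simulator to the model: empirical
  # occupancy at t = 2 over 50,000 trajectories vs P(2) cell by cell
  n <- 50000
  p <- default_intensity_params(covariates = FALSE)
  set.seed(33)
  state0 <- sample(1:3, n, replace = TRUE, prob = c(0.3555, 0.4733, 0.1712))
  jumps <- metsmarkov:::simulate_cohort_trajectories(
    state0, rep(50, n), rep(0, n), p, horizon = 2)
  emp <- occupancy_at(state0, jumps, 2, n)
  Q <- build_generator(p, 50, "female")
  P <- transition_probability(Q, 2)
  pred <- as.vector(c(0.3555, 0.4733, 0.1712, 0, 0, 0) %*% P)
  for (s in 1:6) {
    se <- sqrt(pred[s] * (1 - pred[s]) / n)
    expect_lt(abs(emp[s] - pred[s]), 3 * se + 2 / n)
  }
})

test_that("age-refreshed occupancy matches the piecewise product of P matrices", {
  # with covariates active the simulator refreshes age yearly; the
  # analytic prediction is the product of one-year transition matrices
  n <- 50000
  p <- default_intensity_params()
  set.seed(34)
  jumps <- metsmarkov:::simulate_cohort_trajectories(
    rep(2L, n), rep(60, n), rep(1, n), p, horizon = 2)
  emp <- occupancy_at(rep(2L, n), jumps, 2, n)
  P2 <- transition_probability(build_generator(p, 60, "male"), 1) %*%
    transition_probability(build_generator(p, 61, "male"), 1)
  pred <- P2[2, ]
  for (s in 1:6) {
    se <- sqrt(pred[s] * (1 - pred[s]) / n)
    expect_lt(abs(emp[s] - pred[s]), 3 * se + 2 / n)
  }
})

test_that("observation scheme emits the expected records", {
  # absorbed by other-cause death before the first follow-up screen
  traj <- data.frame(time = c(0, 0.4), state = c(1L, 6L))
  h <- observe_panel(traj, screen_times = 0:4, horizon = 4, age0 = 50,
                     sex = "female")
  expect_equal(h$obs_kind, c("panel", "exact_event"))
  expect_equal(h$state, c(1L, 6L))
  expect_equal(h$time, c(0, 0.4))

  # no events, annual screens all attended: one screen per year, no censor
  traj <- data.frame(time = 0, state = 2L)
  h <- observe_panel(traj, 0:4, 4, 50, "male")
  expect_equal(nrow(h), 5L)
  expect_true(all(h$obs_kind == "panel"))

  # missed final screens leave a censor record at the horizon
  h <- observe_panel(traj, 0:4, 4, 50, "male",
                     attended = c(TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_equal(utils::tail(h$obs_kind, 1), "censor")
  expect_equal(utils::tail(h$time, 1), 4)

  # CVD onset stops screening; survival to horizon is censored from CVD
  traj <- data.frame(time = c(0, 1.5), state = c(3L, 4L))
  h <- observe_panel(traj, 0:4, 4, 55, "male")
  expect_equal(h$obs_kind, c("panel", "panel", "exact_event", "censor"))
  expect_equal(h$state, c(3L, 3L, 4L, NA))
})

test_that("generated cohorts are reproducible and structurally valid", {
  spec <- cohort_spec(n_subjects = 300, seed = 2024)
  s1 <- simulate_cohort(spec)
  s2 <- simulate_cohort(spec)
  expect_identical(s1$panel, s2$panel)

  # validation runs clean on everything the generator emits (irregular
  # schedule and missed screens included)
  spec2 <- cohort_spec(n_subjects = 300, screen_schedule = "irregular",
                       attendance_prob = 0.8, followup_years = 6, seed = 7)
  s3 <- simulate_cohort(spec2)
  expect_s3_class(s3$panel, "msm6_panel")

  # absorbing states never lose members across screen times
  for (t in 1:4) {
    n5 <- function(sim, tt) sum(sim$panel$state == 5 & sim$panel$time <= tt,
                                na.rm = TRUE)
    expect_gte(n5(s1, t), n5(s1, t - 1))
  }
})

test_that("baseline mix, sex mix and written outputs follow the spec", {
  spec <- cohort_spec(n_subjects = 8000, seed = 99)
  dir <- withr::local_tempdir()
  sim <- generate_cohort(spec, out_csv = file.path(dir, "panel.csv"),
                         truth_yaml = file.path(dir, "truth.yaml"))
  mix <- sim$summary$baseline_mix
  for (k in 1:3) {
    pk <- spec$baseline_state_probs[k]
    expect_lt(abs(mix[k] - pk), 3 * sqrt(pk * (1 - pk) / 8000))
  }
  expect_lt(abs(sim$summary$prop_female - 0.60), 3 * sqrt(0.6 * 0.4 / 8000))

  back <- read_panel(file.path(dir, "panel.csv"))
  expect_equal(nrow(back), nrow(sim$panel))
  truth <- read_params(file.path(dir, "truth.yaml"))
  expect_identical(truth$lambda0, spec$params$lambda0)

  # with full annual attendance every living subject has >= 2 observations
  tab <- table(sim$panel$subject_id)
  expect_true(all(tab >= 2 | tapply(sim$panel$time, sim$panel$subject_id, max) < 1))
})

test_that("invalid cohort specifications are rejected", {
  expect_error(cohort_spec(baseline_state_probs = c(0.5, 0.6, 0.2)),
               "probability vector")
  expect_error(cohort_spec(followup_years = 0))
  expect_error(cohort_spec(attendance_prob = 0))
})
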