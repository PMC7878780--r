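# interval and cohort likelihood against closed-form oracles

test_that("panel validation enforces the observation scheme", {
  ok <- make_history(c(0, 1, 2), c(1, 2, 2), rep("panel", 3))
  expect_s3_class(validate_panel(ok), "msm6_panel")

  expect_error(validate_panel(ok[, -2]), "lacks column")
  bad_first <- make_history(c(0, 1), c(4, 5), c("exact_event", "exact_event"))
  expect_error(validate_panel(bad_first), "first observation")
  dup_time <- make_history(c(0, 0), c(1, 2), c("panel", "panel"))
  expect_error(validate_panel(dup_time), "strictly increasing")
  death_mid <- make_history(c(0, 1, 2), c(1, 6, 1),
                            c("panel", "exact_event", "panel"))
  expect_error(validate_panel(death_mid), "after a death")
  cvd_death_alone <- make_history(c(0, 1), c(1, 5), c("panel", "exact_event"))
  expect_error(validate_panel(cvd_death_alone), "preceding CVD onset")
  panel_after_cvd <- make_history(c(0, 1, 2), c(1, 4, 1),
                                  c("panel", "exact_event", "panel"))
  expect_error(validate_panel(panel_after_cvd), "after CVD onset")
  state_as_panel <- make_history(c(0, 1), c(1, 4), c("panel", "panel"))
  expect_error(validate_panel(state_as_panel), "state 1, 2 or 3")
})

test_that("regression out of MetS is carried forward or rejected", {
  reg <- make_history(c(0, 1, 2), c(3, 2, 1), rep("panel", 3))
  cf <- validate_panel(reg)  # carry-forward is the default
  expect_equal(cf$state, c(3L, 3L, 3L))
  expect_equal(attr(cf, "n_carry_forward"), 2L)
  expect_error(validate_panel(reg, carry_forward = FALSE), "regress out of MetS")
})

test_that("two-state toy interval likelihoods match closed forms", {
  lam <- 0.3
  p <- toy_params(lam)
  h <- make_history(c(0, 1.7), c(1, 1), c("panel", "panel"))
  # staying in a single-exit state: survival exp(-lambda dt)
  expect_equal(interval_loglik(h[1, ], h[2, ], p), -lam * 1.7)
  # observed move 1 -> 2 with no onward exits: 1 - exp(-lambda dt)
  h2 <- make_history(c(0, 2), c(1, 2), c("panel", "panel"))
  expect_equal(interval_loglik(h2[1, ], h2[2, ], p),
               log(1 - exp(-lam * 2)))
})

test_that("exactly-dated CVD death is the exponential density", {
  mu <- 0.2
  p <- intensity_params(lambda0 = c("4-5" = mu))
  prev <- list(time = 1, state = 4, obs_kind = "exact_event", age = 52,
               sex = "female")
  nxt <- list(time = 3.4, state = 5, obs_kind = "exact_event", age = 54.4,
              sex = "female")
  expect_equal(interval_loglik(prev, nxt, p), -mu * 2.4 + log(mu))
})

test_that("impossible intervals yield -Inf diagnostics, bad input errors", {
  p <- default_intensity_params()
  prev <- list(time = 0, state = 3, obs_kind = "panel", age = 50, sex = "female")
  nxt <- list(time = 1, state = 1, obs_kind = "panel", age = 51, sex = "female")
  ll <- interval_loglik(prev, nxt, p)
  expect_identical(unclass(ll)[1], -Inf)
  expect_true(attr(ll, "impossible"))

  dead <- list(time = 0, state = 5, obs_kind = "exact_event", age = 50,
               sex = "female")
  expect_error(interval_loglik(dead, nxt, p), "absorbing")
  expect_error(interval_loglik(prev, utils::modifyList(nxt, list(time = 0)), p),
               "non-positive")
})

test_that("cohort likelihood is additive and zero for no intervals", {
  set.seed(11)
  spec <- cohort_spec(n_subjects = 150, seed = 5)
  sim <- simulate_cohort(spec)
  p <- default_intensity_params()
  ll1 <- cohort_loglik(sim$panel, p)
  # duplicated cohort doubles the log-likelihood exactly
  pan2 <- sim$panel
  pan2$subject_id <- pan2$subject_id + 10000L
  both <- validate_panel(rbind(as.data.frame(sim$panel), as.data.frame(pan2)))
  expect_equal(cohort_loglik(both, p), 2 * ll1, tolerance = 1e-10)

  single <- validate_panel(make_history(0, 1, "panel"))
  expect_equal(cohort_loglik(single, p), 0)
  expect_error(cohort_loglik(data.frame()), "empty|lacks")
})

test_that("fast vectorized likelihood equals the per-interval reference", {
  spec <- cohort_spec(n_subjects = 250, seed = 77)
  sim <- simulate_cohort(spec)
  p <- default_intensity_params()
  pan <- sim$panel
  ll_fast <- cohort_loglik(pan, p)
  id <- pan$subject_id
  ll_ref <- 0
  for (i in which(id[-1] == id[-nrow(pan)])) {
    ll_ref <- ll_ref + interval_loglik(pan[i, ], pan[i + 1, ], p)
  }
  # the fast path keys interval lengths at 1/365-year resolution
  expect_equal(ll_fast, ll_ref, tolerance = 1e-5)
})

test_that("panel likelihood is row-stochastic when metabolic states have no exits", {
  # with CVD and death switched off the three metabolic states form a
  # closed system, so next-state probabilities must sum to one
  p <- intensity_params(lambda0 = c("1-2" = 0.45, "2-1" = 0.29, "2-3" = 0.06))
  for (r in 1:3) {
    tot <- 0
    for (s in 1:3) {
      h <- make_history(c(0, 2), c(r, s), c("panel", "panel"))
      ll <- suppressWarnings(interval_loglik(h[1, ], h[2, ], p))
      tot <- tot + exp(as.numeric(ll))
    }
    expect_equal(tot, 1, tolerance = 1e-10)
  }
})

test_that("likelihood is invariant to time-origin shifts and subject order", {
  spec <- cohort_spec(n_subjects = 120, seed = 9)
  sim <- simulate_cohort(spec)
  p <- default_intensity_params()
  pan <- as.data.frame(sim$panel)
  ll <- cohort_loglik(validate_panel(pan), p)

  shifted <- pan
  shifted$time <- shifted$time + 7  # same ages, same gaps
  expect_equal(cohort_loglik(validate_panel(shifted), p), ll, tolerance = 1e-9)

  perm <- pan[sample(nrow(pan)), ]
  perm$subject_id <- paste0("S", perm$subject_id)
  expect_equal(cohort_loglik(validate_panel(perm), p), ll, tolerance = 1e-9)
})

test_that("panel CSV round-trips through read/write", {
  spec <- cohort_spec(n_subjects = 40, seed = 13)
  sim <- simulate_cohort(spec)
  f <- withr::local_tempfile(fileext = ".csv")
  write_panel(sim$panel, f)
  back <- read_panel(f)
  expect_equal(nrow(back), nrow(sim$panel))
  expect_equal(back$time, sim$panel$time)
  expect_equal(back$state, sim$panel$state)
  expect_equal(cohort_loglik(back, default_intensity_params()),
               cohort_loglik(sim$panel, default_intensity_params()))
})
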