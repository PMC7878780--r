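# shared fixtures for the test suite; everything is generated in code

# parameter set with every transition moderately common, so that small
# simulated cohorts have events in all cells (used for coverage and
# property tests, not as a portrait of any real population)
dense_params <- function() {
  intensity_params(lambda0 = c(
    "1-2" = 0.45, "2-1" = 0.29, "2-3" = 0.10,
    "1-4" = 0.05, "2-4" = 0.08, "3-4" = 0.20,
    "4-5" = 0.15, "1-6" = 0.02, "2-6" = 0.03, "3-6" = 0.04, "4-6" = 0.05
  ))
}

# two-state toy: FMD -> MMD at rate lam, nothing else
toy_params <- function(lam = 0.3) {
  intensity_params(lambda0 = c("1-2" = lam))
}

# one-subject panel history from (time, state, obs_kind) triples
make_history <- function(times, states, kinds, age0 = 50, sex = "female",
                         id = 1L) {
  data.frame(subject_id = id, time = times, state = states, obs_kind = kinds,
             age = age0 + times, sex = sex)
}

# random valid intensity parameters for property tests
random_params <- function(covariates = FALSE) {
  lam <- stats::runif(11, 0.001, 0.5)
  names(lam) <- rownames(msm6_topology())
  if (!covariates) return(intensity_params(lambda0 = lam))
  ba <- stats::runif(8, -0.05, 0.05)
  bs <- stats::runif(8, -0.7, 0.7)
  names(ba) <- names(bs) <- c("1-2", "2-1", "2-3", "1-4", "2-4", "3-4", "4-5", "ocd")
  intensity_params(lambda0 = lam, beta_age = ba, beta_sex = bs)
}

# empirical state distribution at a time point from a jump log
occupancy_at <- function(state0, jumps, t, n) {
  st <- state0
  if (nrow(jumps)) {
    keep <- jumps$time <= t
    if (any(keep)) {
      j <- jumps[keep, ]
      last <- j[!duplicated(j$id, fromLast = TRUE), ]
      st[last$id] <- last$state
    }
  }
  tabulate(st, 6) / n
}
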