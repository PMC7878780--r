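#' Specification of a synthetic screening cohort
#'
#' Describes the cohort the simulator generates: continuous-time
#' six-state trajectories under covariate-modulated intensities,
#' observed at screening visits with registry-style exactly-dated CVD
#' onsets and deaths. The defaults emulate a large community-based
#' screening population: baseline metabolic mix 35.55% FMD / 47.33% MMD
#' / 17.12% MetS, 60% female, ages drawn from six 10-year bands with
#' screening-population weights, annual screens over four years of
#' follow-up with full attendance.
#'
#' @param n_subjects Number of subjects.
#' @param baseline_state_probs Probabilities of starting in FMD, MMD,
#'   MetS (must sum to 1).
#' @param age_bands Matrix-like with columns `lo`, `hi`, `weight`: ages
#'   are drawn by band, uniformly over whole years within the band.
#' @param prop_female Fraction of women.
#' @param params Generating truth, an [intensity_params()] object.
#' @param screen_schedule `"annual"` or `"irregular"` (inter-screen gaps
#'   uniform on 1--4 whole years, emulating irregular re-attendance).
#' @param followup_years Administrative end of follow-up (years).
#' @param attendance_prob Probability that each post-baseline screen is
#'   attended (baseline is always observed).
#' @param seed Optional seed; all random streams derive from it.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 5000L,
                        baseline_state_probs = c(0.3555, 0.4733, 0.1712),
                        age_bands = default_age_bands(),
                        prop_female = 0.60,
                        params = default_intensity_params(),
                        screen_schedule = c("annual", "irregular"),
                        followup_years = 4,
                        attendance_prob = 1,
                        seed = NULL) {
  screen_schedule <- match.arg(screen_schedule)
  baseline_state_probs <- as.numeric(baseline_state_probs)
  if (length(baseline_state_probs) != 3L || any(baseline_state_probs < 0) ||
      abs(sum(baseline_state_probs) - 1) > 1e-8) {
    stop("baseline_state_probs must be a probability vector over FMD, MMD, MetS",
         call. = FALSE)
  }
  stopifnot(n_subjects >= 1L, followup_years > 0,
            attendance_prob > 0, attendance_prob <= 1,
            prop_female >= 0, prop_female <= 1,
            inherits(params, "intensity_params"))
  structure(list(n_subjects = as.integer(n_subjects),
                 baseline_state_probs = baseline_state_probs,
                 age_bands = as.data.frame(age_bands),
                 prop_female = prop_female, params = params,
                 screen_schedule = screen_schedule,
                 followup_years = followup_years,
                 attendance_prob = attendance_prob, seed = seed),
            class = "cohort_spec")
}

#' @rdname cohort_spec
#' @export
default_age_bands <- function() {
  # 10-year bands with weights proportional to a community screening
  # population (band counts 4775 / 11788 / 13493 / 8511 / 5938 / 2990)
  data.frame(lo = c(20, 30, 40, 50, 60, 70),
             hi = c(29, 39, 49, 59, 69, 79),
             weight = c(4775, 11788, 13493, 8511, 5938, 2990) / 47495)
}

# per-state exit intensities at given covariates; rows: origin 1..4
exit_rates <- function(params, age, male) {
  lb <- living_block(params, age, male)
  l45 <- intensity_for(params, "4-5", age, male)
  l46 <- intensity_for(params, "4-6", age, male)
  list(
    # destination rates per origin state
    `1` = c(`2` = lb$B[1, 2], `4` = lb$to_cvd[1], `6` = lb$to_ocd[1]),
    `2` = c(`1` = lb$B[2, 1], `3` = lb$B[2, 3], `4` = lb$to_cvd[2], `6` = lb$to_ocd[2]),
    `3` = c(`4` = lb$to_cvd[3], `6` = lb$to_ocd[3]),
    `4` = c(`5` = l45, `6` = l46)
  )
}

#' Simulate one continuous-time trajectory
#'
#' Competing-exponentials event simulation of the six-state process for
#' a single subject: at each jump the waiting time is exponential with
#' the total exit rate and the destination is drawn proportionally to
#' the destination intensities. While the subject is in a metabolic
#' state the covariate age (and hence the intensities) refreshes at
#' integer multiples of `age_refresh` years since entry; after CVD
#' onset the intensities are frozen at their onset values, matching the
#' interval-start piecewise-constant age convention of the likelihood.
#'
#' @param state0 Starting state (1, 2 or 3).
#' @param age0 Age at entry (years).
#' @param sex `"male"` or `"female"`.
#' @param params Generating [intensity_params()].
#' @param horizon End of simulation (years, > 0).
#' @param age_refresh Refresh interval for the covariate age (years,
#'   default 1).
#' @return Data frame with columns `time`, `state`: the entry row
#'   `(0, state0)` followed by one row per jump (the process stays in
#'   the last state until `horizon` if unabsorbed).
#' @export
simulate_trajectory <- function(state0, age0, sex, params, horizon,
                                age_refresh = 1) {
  stopifnot(state0 %in% 1:3)
  if (!is.numeric(horizon) || horizon <= 0) {
    stop("horizon must be positive", call. = FALSE)
  }
  male <- sex_to_male(sex)
  t <- 0
  st <- as.integer(state0)
  times <- 0
  states <- st
  onset_rates <- NULL
  while (st %in% 1:4 && t < horizon) {
    if (st == 4L) {
      rates <- onset_rates
      boundary <- horizon
    } else {
      age <- age0 + floor(t / age_refresh) * age_refresh
      rates <- exit_rates(params, age, male)[[as.character(st)]]
      boundary <- min((floor(t / age_refresh) + 1) * age_refresh, horizon)
    }
    tot <- sum(rates)
    wait <- if (tot > 0) stats::rexp(1L, tot) else Inf
    if (t + wait < boundary) {
      t <- t + wait
      st <- as.integer(names(rates)[sample.int(length(rates), 1L, prob = rates)])
      times <- c(times, t)
      states <- c(states, st)
      if (st == 4L) {
        onset_rates <- exit_rates(params, age0 + t, male)[["4"]]
      }
    } else {
      t <- boundary
    }
  }
  data.frame(time = times, state = states)
}

# Vectorized trajectory simulation for a whole cohort; same process as
# simulate_trajectory, advancing all subjects in lock-step between
# events and refresh boundaries. Returns the jump log in long form.
simulate_cohort_trajectories <- function(state0, age0, male, params, horizon) {
  n <- length(state0)
  t <- numeric(n)
  st <- as.integer(state0)
  onset_age <- rep(NA_real_, n)
  log_id <- vector("list", 64L); log_t <- vector("list", 64L)
  log_s <- vector("list", 64L); nlog <- 0L

  repeat {
    active <- which(st %in% 1:4 & t < horizon)
    if (!length(active)) break
    ta <- t[active]
    sa <- st[active]
    met <- sa %in% 1:3
    age <- ifelse(met, age0[active] + floor(ta), onset_age[active])
    ma <- male[active]

    # destination intensity matrix (active x 6)
    R <- matrix(0, length(active), 6L)
    for (spec in list(c("1-2", 1, 2), c("2-1", 2, 1), c("2-3", 2, 3),
                      c("1-4", 1, 4), c("2-4", 2, 4), c("3-4", 3, 4),
                      c("4-5", 4, 5), c("1-6", 1, 6), c("2-6", 2, 6),
                      c("3-6", 3, 6), c("4-6", 4, 6))) {
      origin <- as.integer(spec[2]); dest <- as.integer(spec[3])
      sel <- sa == origin
      if (any(sel)) R[sel, dest] <- intensity_for(params, spec[1], age[sel], ma[sel])
    }
    tot <- rowSums(R)
    wait <- ifelse(tot > 0, stats::rexp(length(active)) / tot, Inf)
    boundary <- ifelse(met, pmin(floor(ta) + 1, horizon), horizon)
    jump <- ta + wait < boundary

    # advance non-jumpers to their boundary
    t[active[!jump]] <- boundary[!jump]
    if (any(jump)) {
      ji <- active[jump]
      tj <- ta[jump] + wait[jump]
      Pj <- R[jump, , drop = FALSE] / tot[jump]
      u <- stats::runif(length(ji))
      cum <- t(apply(Pj, 1L, cumsum))
      dest <- max.col(cum >= u, ties.method = "first")
      t[ji] <- tj
      newly4 <- dest == 4L
      onset_age[ji[newly4]] <- age0[ji[newly4]] + tj[newly4]
      st[ji] <- dest
      nlog <- nlog + 1L
      if (nlog > length(log_id)) {
        length(log_id) <- length(log_t) <- length(log_s) <- 2L * nlog
      }
      log_id[[nlog]] <- ji; log_t[[nlog]] <- tj; log_s[[nlog]] <- dest
    }
  }
  if (nlog == 0L) {
    return(data.frame(id = integer(0), time = numeric(0), state = integer(0)))
  }
  jumps <- data.frame(id = unlist(log_id[seq_len(nlog)]),
                      time = unlist(log_t[seq_len(nlog)]),
                      state = unlist(log_s[seq_len(nlog)]))
  jumps[order(jumps$id, jumps$time), , drop = FALSE]
}

#' Observe a trajectory through the screening and registry scheme
#'
#' Converts one simulated trajectory into the panel record the analysis
#' sees: metabolic states sampled at the screening times actually
#' attended, CVD onset and deaths emitted as exactly-dated events,
#' and a censor row at the horizon for subjects still alive whose last
#' record precedes it. Screens falling after CVD onset or death are
#' dropped (post-onset follow-up is through the registry only). The
#' retain-as-MetS carry-forward is applied to the observed states.
#'
#' @param trajectory Data frame from [simulate_trajectory()].
#' @param screen_times Screening times in years (must include 0).
#' @param horizon End of follow-up.
#' @param age0 Age at entry; `sex` the subject's sex.
#' @param subject_id Identifier for the output rows.
#' @param attended Logical vector matching `screen_times`; defaults to
#'   all attended (baseline is always kept).
#' @return Panel-format data frame (see [validate_panel()]).
#' @export
observe_panel <- function(trajectory, screen_times, horizon, age0, sex,
                          subject_id = 1L, attended = NULL) {
  stopifnot(is.data.frame(trajectory), nrow(trajectory) >= 1L,
            trajectory$time[1L] == 0)
  if (is.null(attended)) attended <- rep(TRUE, length(screen_times))
  attended[screen_times == 0] <- TRUE
  screen_times <- screen_times[attended]

  state_at <- function(tt) {
    trajectory$state[findInterval(tt, trajectory$time)]
  }
  scr_state <- state_at(screen_times)
  keep <- scr_state %in% 1:3
  rows <- data.frame(subject_id = subject_id,
                     time = screen_times[keep],
                     state = as.integer(scr_state[keep]),
                     obs_kind = "panel",
                     age = age0 + screen_times[keep],
                     sex = sex)
  ev <- trajectory[trajectory$state %in% 4:6, , drop = FALSE]
  ev <- ev[ev$time <= horizon, , drop = FALSE]
  if (nrow(ev)) {
    rows <- rbind(rows, data.frame(subject_id = subject_id, time = ev$time,
                                   state = as.integer(ev$state),
                                   obs_kind = "exact_event",
                                   age = age0 + ev$time, sex = sex))
  }
  rows <- rows[order(rows$time), , drop = FALSE]
  final <- utils::tail(trajectory$state, 1L)
  if (final %in% 1:4 && (nrow(rows) == 0L || max(rows$time) < horizon)) {
    rows <- rbind(rows, data.frame(subject_id = subject_id, time = horizon,
                                   state = NA_integer_, obs_kind = "censor",
                                   age = age0 + horizon, sex = sex))
  }
  # retain-as-MetS carry-forward on the observed panel states
  pan <- rows$obs_kind == "panel"
  if (any(pan)) {
    seen <- cummax(ifelse(pan & rows$state == 3L, 1L, 0L))
    rows$state[pan & seen == 1L] <- 3L
  }
  rownames(rows) <- NULL
  rows
}

#' Simulate a full observed cohort
#'
#' Draws baseline covariates and states from the cohort specification,
#' simulates latent trajectories under the generating intensities, and
#' observes them through the screening/registry scheme. Baseline ages
#' are drawn in whole years, as screening records report them.
#'
#' @param spec A [cohort_spec()].
#' @return List of class `cohort_sim`: `panel` (validated `msm6_panel`),
#'   `truth` (the generating parameters), `subjects` (baseline frame),
#'   and `summary` (baseline mix, sex mix, event counts).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  n <- spec$n_subjects
  horizon <- spec$followup_years

  male <- as.numeric(stats::runif(n) >= spec$prop_female)
  band <- sample.int(nrow(spec$age_bands), n, replace = TRUE,
                     prob = spec$age_bands$weight)
  lo <- spec$age_bands$lo[band]; hi <- spec$age_bands$hi[band]
  age0 <- lo + floor(stats::runif(n) * (hi - lo + 1))
  state0 <- sample.int(3L, n, replace = TRUE, prob = spec$baseline_state_probs)

  jumps <- simulate_cohort_trajectories(state0, age0, male, spec$params, horizon)

  # screening times per subject
  if (spec$screen_schedule == "annual") {
    k <- floor(horizon)
    stimes <- lapply(seq_len(n), function(i) 0:k)
  } else {
    stimes <- lapply(seq_len(n), function(i) {
      g <- cumsum(sample(1:4, ceiling(horizon), replace = TRUE))
      c(0, g[g <= horizon])
    })
  }

  sexchr <- ifelse(male == 1, "male", "female")
  panels <- vector("list", n)
  jidx <- split(seq_len(nrow(jumps)), factor(jumps$id, levels = seq_len(n)))
  for (i in seq_len(n)) {
    traj <- rbind(data.frame(time = 0, state = state0[i]),
                  jumps[jidx[[i]], c("time", "state"), drop = FALSE])
    sts <- stimes[[i]]
    att <- c(TRUE, stats::runif(length(sts) - 1L) <= spec$attendance_prob)
    panels[[i]] <- observe_panel(traj, sts, horizon, age0[i], sexchr[i],
                                 subject_id = i, attended = att)
  }
  panel <- do.call(rbind, panels)
  panel <- validate_panel(panel)

  summary <- list(
    n_subjects = n,
    baseline_mix = as.vector(table(factor(state0, 1:3))) / n,
    prop_female = mean(male == 0),
    n_cvd_onset = sum(panel$state == 4L, na.rm = TRUE),
    n_cvd_death = sum(panel$state == 5L, na.rm = TRUE),
    n_ocd = sum(panel$state == 6L, na.rm = TRUE),
    n_panel_obs = sum(panel$obs_kind == "panel"),
    n_censor = sum(panel$obs_kind == "censor")
  )
  structure(list(panel = panel, truth = spec$params,
                 subjects = data.frame(subject_id = seq_len(n), age0 = age0,
                                       sex = sexchr, state0 = state0),
                 summary = summary, spec = spec),
            class = "cohort_sim")
}

#' Generate a cohort and write it to disk
#'
#' Runs [simulate_cohort()] and writes the panel as CSV plus the
#' generating truth as a YAML sidecar, so simulated data and truth
#' travel together for recovery studies.
#'
#' @param spec A [cohort_spec()].
#' @param out_csv Path for the panel CSV (optional).
#' @param truth_yaml Path for the truth parameter file (optional).
#' @return The `cohort_sim` list, invisibly.
#' @export
generate_cohort <- function(spec, out_csv = NULL, truth_yaml = NULL) {
  sim <- simulate_cohort(spec)
  if (!is.null(out_csv)) write_panel(sim$panel, out_csv)
  if (!is.null(truth_yaml)) write_params(sim$truth, truth_yaml)
  invisible(sim)
}

# ---- biomarker-level synthesis ---------------------------------------------

#' Synthesize biomarkers consistent with metabolic states
#'
#' Optional layer that turns RMRC states into raw screen biomarkers so
#' the classifier can be tested end-to-end. The five criteria are drawn
#' as correlated binaries from a Gaussian copula with per-state marginal
#' prevalences typical of a screening population (conditional on MMD:
#' 27% central obesity, 21% high triglycerides, 21% low HDL, 54% high
#' blood pressure, 16% hyperglycemia; conditional on MetS: 76%, 73%,
#' 53%, 84%, 57%), rejected until the positive count matches the
#' state's class (0 / 1--2 / 3+). The joint distribution beyond these
#' margins is a modelling invention. Biomarker values are then placed
#' uniformly on the flagged side of each threshold.
#'
#' @param states Integer vector of RMRC states (1, 2, 3).
#' @param sex Character vector (`"male"`/`"female"`), recycled.
#' @param copula_cor Latent pairwise correlation of the copula
#'   (default 0.3).
#' @return Data frame with `sex`, the five biomarker columns, the three
#'   treatment flags (all `FALSE`) and the generating `state`.
#' @export
simulate_biomarkers <- function(states, sex, copula_cor = 0.3) {
  n <- length(states)
  sex <- rep_len(sex, n)
  male <- sex_to_male(sex)
  prev <- rbind(FMD = rep(0, 5),
                MMD = c(0.2696, 0.2141, 0.2140, 0.5423, 0.1624),
                MetS = c(0.7634, 0.7332, 0.5329, 0.8413, 0.5719))
  lohi <- function(state) if (state == 1L) c(0, 0) else if (state == 2L) c(1, 2) else c(3, 5)
  Sigma <- matrix(copula_cor, 5, 5); diag(Sigma) <- 1
  L <- chol(Sigma)
  flags <- matrix(FALSE, n, 5)
  for (i in seq_len(n)) {
    rng <- lohi(states[i])
    pm <- prev[states[i], ]
    if (states[i] == 1L) next
    repeat {
      z <- as.vector(matrix(stats::rnorm(5), 1) %*% L)
      f <- z < stats::qnorm(pm)
      if (sum(f) >= rng[1] && sum(f) <= rng[2]) { flags[i, ] <- f; break }
    }
  }
  thr <- RMRC_THRESHOLDS
  below <- function(cut, spread) cut * (1 - stats::runif(n, 0.05, spread))
  above <- function(cut, spread) cut * (1 + stats::runif(n, 0, spread))
  waist_cut <- ifelse(male == 1, thr$waist_male, thr$waist_female)
  hdl_cut <- ifelse(male == 1, thr$hdl_male, thr$hdl_female)
  out <- data.frame(
    sex = sex,
    waist = ifelse(flags[, 1], above(waist_cut, 0.3), below(waist_cut, 0.3)),
    triglycerides = ifelse(flags[, 2], above(thr$triglycerides, 1),
                           below(thr$triglycerides, 0.6)),
    hdl = ifelse(flags[, 3], below(hdl_cut, 0.5), above(hdl_cut, 0.6)),
    sbp = ifelse(flags[, 4], above(thr$sbp, 0.3), below(thr$sbp, 0.25)),
    dbp = ifelse(flags[, 4], above(thr$dbp, 0.3), below(thr$dbp, 0.25)),
    glucose = ifelse(flags[, 5], above(thr$glucose, 0.6), below(thr$glucose, 0.2)),
    on_hypertension_treatment = FALSE,
    on_diabetes_treatment = FALSE,
    on_hyperlipidemia_treatment = FALSE,
    state = as.integer(states)
  )
  out
}
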