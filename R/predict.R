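#' Cumulative risk of CVD or CVD death from a metabolic state
#'
#' Propagates the state-occupancy distribution forward from a living
#' metabolic state under the fitted (or specified) intensities and
#' reports the cumulative probability of the target outcome on a time
#' grid. For `target = "cvd"` the risk at time t is the probability of
#' ever having entered the CVD state by t (computed on an internally
#' expanded chain that separates other-cause deaths with and without
#' prior CVD, so the curve is a true cumulative incidence and
#' nondecreasing); with `include_death_in_cvd = FALSE` it is instead the
#' probability of currently living with CVD, a prevalence-style curve
#' that can decline as cases die. For `target = "cvd_death"` it is
#' `P[start,5](t)`. Age is handled piecewise-constant: the generator is
#' refreshed whenever the subject crosses an integer age on the grid.
#'
#' @param params An [intensity_params()] object (e.g. `fit$params_hat`).
#' @param start_state 1 (FMD), 2 (MMD) or 3 (MetS).
#' @param target `"cvd"` or `"cvd_death"`.
#' @param age,sex Covariates at time 0.
#' @param horizon Prediction horizon in years (> 0).
#' @param grid_step Grid resolution in years (default 0.1).
#' @param include_death_in_cvd Count CVD deaths as CVD events
#'   (default `TRUE`).
#' @return Data frame of class `risk_curve` with columns `time`, `risk`,
#'   and the full occupancy probabilities `p1`..`p6`.
#' @examples
#' rc <- cumulative_risk(default_intensity_params(), 3, "cvd_death",
#'                       age = 65, sex = "male", horizon = 10)
#' utils::tail(rc, 1)
#' @export
cumulative_risk <- function(params, start_state, target = c("cvd", "cvd_death"),
                            age, sex, horizon, grid_step = 0.1,
                            include_death_in_cvd = TRUE) {
  target <- match.arg(target)
  if (!start_state %in% 1:3) {
    stop("start_state must be a living metabolic state (1, 2 or 3)", call. = FALSE)
  }
  if (!is.numeric(horizon) || horizon <= 0) {
    stop("horizon must be positive", call. = FALSE)
  }
  times <- seq(0, horizon, by = grid_step)
  if (utils::tail(times, 1L) < horizon) times <- c(times, horizon)
  # expanded chain: 1-3 metabolic, 4 CVD, 5 CVD death, 6 OCD without
  # prior CVD, 7 OCD after CVD; ever-CVD = p4 + p5 + p7
  expand_generator <- function(cur_age) {
    Q <- build_generator(params, cur_age, sex)
    Q7 <- matrix(0, 7L, 7L)
    Q7[1:6, 1:6] <- Q
    Q7[4L, 7L] <- Q[4L, 6L]
    Q7[4L, 6L] <- 0
    Q7
  }
  p <- numeric(7L)
  p[start_state] <- 1
  occ <- matrix(0, length(times), 7L)
  occ[1L, ] <- p
  step_cache <- list()
  for (k in seq_len(length(times) - 1L)) {
    dt <- times[k + 1L] - times[k]
    cur_age <- floor(age + times[k])
    key <- sprintf("%d_%.6f", cur_age, dt)
    if (is.null(step_cache[[key]])) {
      step_cache[[key]] <- transition_probability(expand_generator(cur_age), dt)
    }
    p <- as.vector(p %*% step_cache[[key]])
    occ[k + 1L, ] <- p
  }
  risk <- switch(target,
                 cvd = if (include_death_in_cvd) {
                   occ[, 4L] + occ[, 5L] + occ[, 7L]
                 } else occ[, 4L],
                 cvd_death = occ[, 5L])
  out <- data.frame(time = times, risk = risk,
                    p1 = occ[, 1], p2 = occ[, 2], p3 = occ[, 3],
                    p4 = occ[, 4], p5 = occ[, 5], p6 = occ[, 6] + occ[, 7])
  attr(out, "start_state") <- start_state
  attr(out, "target") <- target
  attr(out, "covariates") <- list(age = age, sex = sex)
  class(out) <- c("risk_curve", "data.frame")
  out
}

#' @export
plot.risk_curve <- function(x, ...) {
  graphics::plot(x$time, 100 * x$risk, type = "l", xlab = "Years",
                 ylab = "Cumulative risk (%)",
                 main = sprintf("Cumulative risk of %s from %s",
                                attr(x, "target"),
                                STATE_LABELS[attr(x, "start_state")]), ...)
  invisible(x)
}

#' Estimation report in the style of a progression-rate table
#'
#' Formats a converged fit as two tables: transition rates in percent
#' per year with 95% confidence intervals (two decimals), and, when
#' covariates were fitted, age and sex rate ratios with intervals. Both
#' are returned as data frames and can be written as CSV.
#'
#' @param fit An `msm6_fit`.
#' @param rates_csv,rr_csv Optional output paths.
#' @return List with elements `rates` and (if available) `rate_ratios`.
#' @export
report_tables <- function(fit, rates_csv = NULL, rr_csv = NULL) {
  stopifnot(inherits(fit, "msm6_fit"))
  rt <- transition_rate_table(fit)
  labels <- c(
    "1-2" = "Transition rate from FMD to MMD",
    "2-1" = "Regression rate from MMD to FMD",
    "2-3" = "Transition rate from MMD to MetS",
    "1-4" = "Incidence rate of CVD from FMD",
    "2-4" = "Incidence rate of CVD from MMD",
    "3-4" = "Incidence rate of CVD from MetS",
    "cvd" = "Incidence rate of CVD (common)",
    "4-5" = "Hazard rate of CVD death",
    "1-6" = "Hazard rate of OCD from FMD",
    "2-6" = "Hazard rate of OCD from MMD",
    "3-6" = "Hazard rate of OCD from MetS",
    "4-6" = "Hazard rate of OCD from CVD"
  )
  rates <- data.frame(
    parameter = unname(labels[rt$transition]),
    estimate_pct = round(100 * rt$rate, 2),
    lcl_pct = round(100 * rt$lcl, 2),
    ucl_pct = round(100 * rt$ucl, 2)
  )
  out <- list(rates = rates)
  if (length(fit$info$grp_free)) {
    rr <- rate_ratio_table(fit)
    grp_labels <- c("1-2" = "Transition rate from FMD to MMD",
                    "2-1" = "Regression rate from MMD to FMD",
                    "2-3" = "Transition rate from MMD to MetS",
                    "1-4" = "Incidence rate of CVD from FMD",
                    "2-4" = "Incidence rate of CVD from MMD",
                    "3-4" = "Incidence rate of CVD from MetS",
                    "cvd" = "Incidence rate of CVD (common)",
                    "4-5" = "Hazard rate of CVD death",
                    "ocd" = "Hazard rate of OCD",
                    "4-6" = "Hazard rate of OCD from CVD")
    out$rate_ratios <- data.frame(
      parameter = unname(grp_labels[rr$group]),
      covariate = rr$covariate,
      rr = round(rr$rr, 2), lcl = round(rr$lcl, 2), ucl = round(rr$ucl, 2)
    )
  }
  if (!is.null(rates_csv)) utils::write.csv(out$rates, rates_csv, row.names = FALSE)
  if (!is.null(rr_csv) && !is.null(out$rate_ratios)) {
    utils::write.csv(out$rate_ratios, rr_csv, row.names = FALSE)
  }
  out
}

#' End-to-end pipeline: simulate, fit, report, predict
#'
#' Convenience driver binding the modules together: generates a cohort
#' from a specification, fits the full model, produces the report
#' tables and a set of cumulative-risk curves, optionally writing
#' everything into an output directory.
#'
#' @param spec A [cohort_spec()].
#' @param out_dir Optional directory for `panel.csv`, `truth.yaml`,
#'   `rates.csv`, `rate_ratios.csv` and `risk_curves.csv`.
#' @param fit_args Extra arguments passed to [fit_msm6()].
#' @param risk_age,risk_sex Covariates for the risk curves
#'   (default 65, male).
#' @param risk_horizon Risk-curve horizon in years (default 10).
#' @return List with `sim`, `fit`, `report`, `risk_curves`.
#' @export
run_pipeline <- function(spec, out_dir = NULL, fit_args = list(),
                         risk_age = 65, risk_sex = "male", risk_horizon = 10) {
  sim <- simulate_cohort(spec)
  fit <- do.call(fit_msm6, c(list(data = sim$panel), fit_args))
  rep <- report_tables(fit)
  curves <- lapply(1:3, function(s) {
    rbind(
      cbind(start = STATE_LABELS[s], target = "cvd",
            as.data.frame(cumulative_risk(fit$params_hat, s, "cvd", risk_age,
                                          risk_sex, risk_horizon))[, c("time", "risk")]),
      cbind(start = STATE_LABELS[s], target = "cvd_death",
            as.data.frame(cumulative_risk(fit$params_hat, s, "cvd_death", risk_age,
                                          risk_sex, risk_horizon))[, c("time", "risk")])
    )
  })
  curves <- do.call(rbind, curves)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_panel(sim$panel, file.path(out_dir, "panel.csv"))
    write_params(sim$truth, file.path(out_dir, "truth.yaml"))
    utils::write.csv(rep$rates, file.path(out_dir, "rates.csv"), row.names = FALSE)
    if (!is.null(rep$rate_ratios)) {
      utils::write.csv(rep$rate_ratios, file.path(out_dir, "rate_ratios.csv"),
                       row.names = FALSE)
    }
    utils::write.csv(curves, file.path(out_dir, "risk_curves.csv"), row.names = FALSE)
  }
  list(sim = sim, fit = fit, report = rep, risk_curves = curves)
}
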