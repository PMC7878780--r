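#' Counting-based starting values
#'
#' Crude initial intensities obtained by treating every observed panel
#' transition as a direct jump: for each allowed transition, the number
#' of observed moves divided by the person-years spent in the origin
#' state. Rates are floored at 1e-4 and capped at 2 per year;
#' covariate effects start at zero. The same idea underlies the
#' standard crude initializers for panel-observed multistate models.
#'
#' @param data Panel data (validated or raw).
#' @param ref_age,ref_sex Reference covariates for the returned
#'   parameter object.
#' @return An [intensity_params()] object.
#' @export
crude_inits <- function(data, ref_age = 50, ref_sex = "female") {
  itab <- if (is.list(data) && !is.data.frame(data) && !is.null(data$met)) data
          else interval_table(data)
  m <- itab$met
  py <- c(`1` = 0, `2` = 0, `3` = 0, `4` = 0)
  for (r in 1:3) py[r] <- sum(m$dt[m$r == r] * m$count[m$r == r])
  py[4] <- sum(itab$cvd$dt * itab$cvd$count)
  cnt <- function(sel) sum(m$count[sel])
  ev <- c(
    "1-2" = cnt(m$r == 1 & m$kind == "panel" & m$s == 2),
    "2-1" = cnt(m$r == 2 & m$kind == "panel" & m$s == 1),
    # observed 1 -> 3 over one interval implies a latent passage through 2
    "2-3" = cnt(m$r %in% 1:2 & m$kind == "panel" & m$s == 3),
    "1-4" = cnt(m$r == 1 & m$kind == "cvd_onset"),
    "2-4" = cnt(m$r == 2 & m$kind == "cvd_onset"),
    "3-4" = cnt(m$r == 3 & m$kind == "cvd_onset"),
    "4-5" = sum(itab$cvd$count[itab$cvd$kind == "cvd_death"]),
    "1-6" = cnt(m$r == 1 & m$kind == "ocd"),
    "2-6" = cnt(m$r == 2 & m$kind == "ocd"),
    "3-6" = cnt(m$r == 3 & m$kind == "ocd"),
    "4-6" = sum(itab$cvd$count[itab$cvd$kind == "ocd"])
  )
  from <- c(1, 2, 2, 1, 2, 3, 4, 1, 2, 3, 4)
  rate <- pmin(pmax(ev / pmax(py[from], 1e-8), 1e-4), 2)
  intensity_params(lambda0 = stats::setNames(rate, names(ev)),
                   ref_age = ref_age, ref_sex = ref_sex)
}

#' Fit the six-state model by maximum likelihood
#'
#' Maximizes the cohort log-likelihood over the baseline log-intensities
#' and (optionally) the proportional-hazards age and sex log rate-ratios
#' with a BFGS quasi-Newton search, optionally from multiple jittered
#' starting points to guard against local optima on the likelihood
#' ridge created by the FMD-MMD exchange. The `equal_cvd_risk` variant
#' ties the three CVD incidence baselines to a single rate (the reduced
#' model of the likelihood-ratio comparison); by default covariate
#' effects remain transition-specific so the reduction removes exactly
#' two free parameters.
#'
#' @param data Panel data frame (validated with [validate_panel()] if
#'   not already).
#' @param init Optional [intensity_params()] starting values; defaults
#'   to [crude_inits()].
#' @param variant `"full"` or `"equal_cvd_risk"`.
#' @param covariates If `FALSE`, fit a homogeneous model with all rate
#'   ratios fixed at 1.
#' @param tie_covariates For `equal_cvd_risk`, also tie the CVD
#'   covariate effects (reduction of six parameters instead of two).
#' @param multi_start Number of starting points (first is `init`, the
#'   rest are jittered; default 3).
#' @param compute_vcov Compute the observed-information variance matrix
#'   at the optimum (default `TRUE`; the numerical Hessian dominates the
#'   run time of large fits, so recovery loops may switch it off).
#' @param control List: `reltol` (default 1e-10), `maxit` (500),
#'   `jitter_sd` (0.25), `seed` (20210211, used only for the jitter),
#'   `grad_tol` (1e-3, per-interval scaled gradient check).
#' @param ref_age,ref_sex Reference covariates when `init` is not given.
#' @return An object of class `msm6_fit`: `params_hat`, `theta`
#'   (free-parameter vector), `vcov`, `loglik`, `n_subjects`,
#'   `n_intervals`, `converged`, `n_evals`, `ci_level`, plus the fit
#'   configuration.
#' @export
fit_msm6 <- function(data, init = NULL, variant = c("full", "equal_cvd_risk"),
                     covariates = TRUE, tie_covariates = FALSE,
                     multi_start = 3L, compute_vcov = TRUE, control = list(),
                     ref_age = 50, ref_sex = "female") {
  variant <- match.arg(variant)
  ctrl <- utils::modifyList(list(reltol = 1e-10, maxit = 500L,
                                 jitter_sd = 0.25, seed = 20210211,
                                 grad_tol = 1e-3), control)
  itab <- if (is.list(data) && !is.data.frame(data) && !is.null(data$met)) data
          else interval_table(data)
  if (is.null(init)) init <- crude_inits(itab, ref_age = ref_age, ref_sex = ref_sex)
  stopifnot(inherits(init, "intensity_params"))

  info <- free_param_info(init, variant, covariates, tie_covariates)
  theta0 <- pack_params(init, info)
  n_evals <- 0L
  negll <- function(theta) {
    n_evals <<- n_evals + 1L
    p <- tryCatch(unpack_params(theta, info, init), error = function(e) NULL)
    if (is.null(p)) return(1e12)
    ll <- tryCatch(cohort_loglik(itab, p), error = function(e) -Inf)
    if (!is.finite(ll)) return(1e12)
    -ll
  }

  starts <- list(theta0)
  if (multi_start > 1L) {
    old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(ctrl$seed)
    for (k in seq_len(multi_start - 1L)) {
      starts[[k + 1L]] <- theta0 + stats::rnorm(length(theta0), 0, ctrl$jitter_sd)
    }
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }

  best <- NULL
  for (th in starts) {
    opt <- stats::optim(th, negll, method = "BFGS",
                        control = list(maxit = ctrl$maxit, reltol = ctrl$reltol))
    if (is.null(best) || opt$value < best$value) best <- opt
  }

  theta_hat <- best$par
  names(theta_hat) <- info$names
  params_hat <- unpack_params(theta_hat, info, init)
  loglik <- -best$value

  # scaled gradient at the optimum (finite differences)
  gr <- numeric(length(theta_hat))
  h <- 1e-5
  f0 <- negll(theta_hat)
  for (k in seq_along(theta_hat)) {
    tp <- theta_hat; tp[k] <- tp[k] + h
    tm <- theta_hat; tm[k] <- tm[k] - h
    gr[k] <- (negll(tp) - negll(tm)) / (2 * h)
  }
  grad_max <- max(abs(gr)) / max(1, itab$n_intervals)
  converged <- best$convergence == 0L && grad_max < ctrl$grad_tol

  vc <- NULL
  vcov_ok <- FALSE
  if (compute_vcov) {
    H <- tryCatch(stats::optimHess(theta_hat, negll), error = function(e) NULL)
    if (!is.null(H)) {
      vc <- tryCatch(solve(H), error = function(e) NULL)
      if (!is.null(vc)) {
        vc <- (vc + t(vc)) / 2
        dimnames(vc) <- list(info$names, info$names)
        vcov_ok <- all(is.finite(vc)) && all(eigen(vc, only.values = TRUE)$values > -1e-8)
      }
    }
  }

  structure(list(params_hat = params_hat, theta = theta_hat,
                 vcov = if (vcov_ok) vc else NULL, vcov_ok = vcov_ok,
                 loglik = loglik, n_subjects = itab$n_subjects,
                 n_intervals = itab$n_intervals,
                 converged = converged, grad_max = grad_max,
                 n_evals = n_evals, ci_level = 0.95,
                 variant = variant, covariates = covariates,
                 tie_covariates = tie_covariates, info = info,
                 optim_convergence = best$convergence),
            class = "msm6_fit")
}

#' @export
print.msm6_fit <- function(x, ...) {
  cat(sprintf("Six-state Markov model fit (%s%s)\n", x$variant,
              if (x$covariates) ", age/sex covariates" else ""))
  cat(sprintf("  subjects: %d   intervals: %d   log-likelihood: %.2f\n",
              x$n_subjects, x$n_intervals, x$loglik))
  cat(sprintf("  converged: %s (scaled |grad| %.2e, %d evaluations)\n",
              x$converged, x$grad_max, x$n_evals))
  tab <- transition_rate_table(x)
  print(tab, digits = 4)
  invisible(x)
}

#' Estimated transition rates with confidence intervals
#'
#' Back-transforms the fitted baseline log-intensities to rates per year
#' with Wald confidence intervals computed on the log scale and
#' exponentiated, so the bounds are always positive and asymmetric
#' around the estimate (`delta_method = TRUE` instead applies the delta
#' method on the natural scale).
#'
#' @param fit An `msm6_fit`.
#' @param delta_method Natural-scale delta-method intervals.
#' @return Data frame with columns `transition`, `rate` (per year),
#'   `lcl`, `ucl` (NA when no variance matrix is available).
#' @export
transition_rate_table <- function(fit, delta_method = FALSE) {
  z <- stats::qnorm(1 - (1 - fit$ci_level) / 2)
  lam_names <- paste0("log_lambda0.", fit$info$lam_free)
  est <- fit$theta[lam_names]
  se <- if (!is.null(fit$vcov)) sqrt(pmax(diag(fit$vcov)[lam_names], 0)) else rep(NA_real_, length(est))
  rate <- exp(est)
  if (delta_method) {
    lcl <- rate - z * rate * se
    ucl <- rate + z * rate * se
  } else {
    lcl <- exp(est - z * se)
    ucl <- exp(est + z * se)
  }
  data.frame(transition = fit$info$lam_free, rate = unname(rate),
             lcl = unname(lcl), ucl = unname(ucl))
}

#' Rate ratios of the covariate effects
#'
#' One row per covariate group and covariate: `RR = exp(beta)` with
#' `exp(beta +/- z SE)` confidence limits, mirroring the layout of a
#' proportional-hazards effects table.
#'
#' @param fit A converged `msm6_fit` with covariates.
#' @return Data frame with columns `group`, `covariate`, `rr`, `lcl`,
#'   `ucl` (limits NA without a variance matrix).
#' @export
rate_ratio_table <- function(fit) {
  stopifnot(inherits(fit, "msm6_fit"))
  if (!length(fit$info$grp_free)) {
    stop("fit has no covariate effects", call. = FALSE)
  }
  z <- stats::qnorm(1 - (1 - fit$ci_level) / 2)
  rows <- expand.grid(covariate = c("age", "sex"), group = fit$info$grp_free,
                      stringsAsFactors = FALSE)[, 2:1]
  nm <- paste0("beta_", rows$covariate, ".", rows$group)
  est <- fit$theta[nm]
  se <- if (!is.null(fit$vcov)) sqrt(pmax(diag(fit$vcov)[nm], 0)) else rep(NA_real_, length(nm))
  data.frame(group = rows$group, covariate = rows$covariate,
             rr = unname(exp(est)), lcl = unname(exp(est - z * se)),
             ucl = unname(exp(est + z * se)))
}

#' Likelihood-ratio test between nested model fits
#'
#' Compares the maximized log-likelihoods of a full and a nested reduced
#' fit of the same data: statistic `2 (ll_full - ll_reduced)`, degrees
#' of freedom equal to the difference in free-parameter counts, p-value
#' from the upper chi-square tail. Used for the comparison between the
#' model with severity-specific CVD risk and the reduced model with a
#' common CVD incidence.
#'
#' @param full,reduced `msm6_fit` objects on the same data.
#' @param tol Tolerance for a negative statistic before a refit is
#'   demanded (default 0.01).
#' @return List with `statistic`, `df`, `p_value`.
#' @export
likelihood_ratio_test <- function(full, reduced, tol = 0.01) {
  stopifnot(inherits(full, "msm6_fit"), inherits(reduced, "msm6_fit"))
  df <- full$info$n_free - reduced$info$n_free
  if (df <= 0) stop("'reduced' is not nested in 'full'", call. = FALSE)
  if (full$n_intervals != reduced$n_intervals ||
      full$n_subjects != reduced$n_subjects) {
    stop("fits are not on the same data", call. = FALSE)
  }
  delta <- full$loglik - reduced$loglik
  if (delta < -tol) {
    stop(sprintf(
      "reduced model has higher log-likelihood (difference %.4g); refit the full model from better starting values",
      delta), call. = FALSE)
  }
  stat <- max(0, 2 * delta)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}
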