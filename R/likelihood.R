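#' Validate a long-format panel dataset
#'
#' Checks the panel schema and the structural rules of the observation
#' scheme: metabolic states (1--3) are panel-observed at screens; CVD
#' onset (4), CVD death (5) and other-cause death (6) are exactly-dated
#' registry events (`obs_kind = "exact_event"`); censoring closes a
#' record with unknown living state. Within a subject, times must be
#' strictly increasing, the first observation must be a panel screen in
#' a metabolic state, at most one CVD onset may occur, any death event
#' is final, and CVD death requires a preceding CVD onset.
#'
#' Observed regression out of MetS (a screen in state 1 or 2 after a
#' screen in state 3) is structurally impossible under the model's
#' natural-course topology. By default the retain-as-MetS carry-forward
#' rule is applied first (any screen after an observed MetS screen is
#' recoded to MetS, the number of recodes is reported); with
#' `carry_forward = FALSE` such sequences are rejected with the
#' offending row numbers.
#'
#' @param data Data frame with columns `subject_id`, `time` (years since
#'   entry), `state` (integer 1--6, `NA` allowed for censor rows),
#'   `obs_kind` (`"panel"`, `"exact_event"` or `"censor"`), `age` (years
#'   at observation) and `sex` (`"male"`/`"female"`).
#' @param carry_forward Apply the retain-as-MetS rule before validation
#'   (default `TRUE`).
#' @return The validated data frame, sorted by subject and time, of class
#'   `msm6_panel`, with attributes `n_subjects` and `n_carry_forward`.
#' @export
validate_panel <- function(data, carry_forward = TRUE) {
  required <- c("subject_id", "time", "state", "obs_kind", "age", "sex")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols)) {
    stop("panel data lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  data <- as.data.frame(data)[, union(required, names(data))]
  if (!nrow(data)) stop("panel data is empty", call. = FALSE)

  bad_kind <- !data$obs_kind %in% c("panel", "exact_event", "censor")
  if (any(bad_kind)) {
    stop("invalid obs_kind at row(s): ",
         paste(utils::head(which(bad_kind), 5L), collapse = ", "), call. = FALSE)
  }
  data$state <- as.integer(data$state)
  male <- sex_to_male(data$sex)  # validates sex coding

  ord <- order(data$subject_id, data$time)
  data <- data[ord, ]
  male <- male[ord]
  id <- match(data$subject_id, unique(data$subject_id))
  n <- nrow(data)
  first <- !duplicated(id)

  fail <- function(rows, msg) {
    stop(sprintf("%s at row(s): %s", msg,
                 paste(utils::head(rows, 5L), collapse = ", ")), call. = FALSE)
  }

  # carry-forward of MetS within subject, panel rows only
  n_cf <- 0L
  if (carry_forward) {
    is_panel <- data$obs_kind == "panel"
    seen3 <- stats::ave(is_panel & !is.na(data$state) & data$state == 3L, id,
                        FUN = cummax)
    recode <- is_panel & seen3 == 1 & !is.na(data$state) & data$state < 3L
    n_cf <- sum(recode)
    data$state[recode] <- 3L
  }

  pan <- data$obs_kind == "panel"
  if (any(pan & (is.na(data$state) | !data$state %in% 1:3))) {
    fail(which(pan & (is.na(data$state) | !data$state %in% 1:3)),
         "panel observations must have state 1, 2 or 3")
  }
  ev <- data$obs_kind == "exact_event"
  if (any(ev & (is.na(data$state) | !data$state %in% 4:6))) {
    fail(which(ev & (is.na(data$state) | !data$state %in% 4:6)),
         "exact events must have state 4, 5 or 6")
  }
  if (any(first & (!pan | !data$state %in% 1:3))) {
    fail(which(first & (!pan | !data$state %in% 1:3)),
         "first observation must be a panel screen in a metabolic state")
  }
  prev_same <- c(FALSE, id[-1L] == id[-n])
  dt_ok <- c(TRUE, data$time[-1L] > data$time[-n])
  if (any(prev_same & !dt_ok)) {
    fail(which(prev_same & !dt_ok), "times must be strictly increasing within subject")
  }
  # monotone MetS: regression is a panel row < 3 after an earlier MetS row
  lag_seen3 <- stats::ave(pan & data$state == 3L, id,
                          FUN = function(x) c(0, cummax(x)[-length(x)]))
  back <- pan & lag_seen3 == 1 & data$state < 3L
  if (any(back)) {
    fail(which(back),
         sprintf("%d panel observation(s) regress out of MetS (run with carry_forward = TRUE to apply the retain-as-MetS rule)",
                 sum(back)))
  }
  # event ordering within subject
  st <- ifelse(is.na(data$state), 0L, data$state)
  n4 <- tapply(st == 4L, id, sum)
  if (any(n4 > 1L)) fail(which(st == 4L), "more than one CVD onset for a subject")
  seen4 <- stats::ave(st == 4L, id, FUN = cummax)
  seen_death <- stats::ave(st %in% 5:6, id, FUN = cummax)
  after_death <- stats::ave(st %in% 5:6, id,
                            FUN = function(x) c(0, cummax(x)[-length(x)]))
  if (any(after_death == 1)) {
    fail(which(after_death == 1), "observations after a death event")
  }
  if (any(st == 5L & seen4 == 0)) {
    fail(which(st == 5L & seen4 == 0), "CVD death without a preceding CVD onset")
  }
  after4 <- stats::ave(st == 4L, id, FUN = function(x) c(0, cummax(x)[-length(x)]))
  if (any(after4 == 1 & pan)) {
    fail(which(after4 == 1 & pan), "panel screens after CVD onset are not modelled")
  }
  if (any(!is.finite(data$time) | data$time < 0)) {
    fail(which(!is.finite(data$time) | data$time < 0), "invalid observation time")
  }
  if (any(!is.finite(data$age))) fail(which(!is.finite(data$age)), "invalid age")

  structure(data, class = c("msm6_panel", "data.frame"),
            n_subjects = length(unique(id)), n_carry_forward = n_cf)
}

# ---- interval decomposition -------------------------------------------------

# Breaks validated panel data into the likelihood's independent
# interval contributions and aggregates identical ones. Intervals
# starting in a metabolic state are keyed by (from, kind, to, dt, age,
# male) with ages at integer years and dt at 1/365-year resolution;
# intervals starting in CVD are kept at exact covariate values because
# their contribution is a closed-form scalar. Interval kinds:
#   panel      next screen in state s
#   cvd_onset  exactly-dated entry into CVD
#   ocd        exactly-dated other-cause death
#   cvd_death  exactly-dated CVD death (from the CVD state)
#   censor     end of follow-up, alive
#' @keywords internal
interval_table <- function(data) {
  if (!inherits(data, "msm6_panel")) data <- validate_panel(data)
  n <- nrow(data)
  id <- match(data$subject_id, unique(data$subject_id))
  male <- sex_to_male(data$sex)
  i <- which(c(id[-1L] == id[-n], FALSE))   # interval start rows
  j <- i + 1L
  r <- data$state[i]
  kind <- ifelse(data$obs_kind[j] == "panel", "panel",
          ifelse(data$obs_kind[j] == "censor", "censor",
          ifelse(data$state[j] == 4L, "cvd_onset",
          ifelse(data$state[j] == 5L, "cvd_death", "ocd"))))
  s <- ifelse(kind == "panel", data$state[j], 0L)
  dt <- data$time[j] - data$time[i]
  age <- data$age[i]
  male <- male[i]

  met <- r %in% 1:3
  if (any(!met & kind == "panel")) {
    stop("panel observation following CVD onset", call. = FALSE)
  }
  if (any(met & kind == "cvd_death")) {
    stop("CVD death interval starting outside the CVD state", call. = FALSE)
  }

  agg <- function(df) {
    key <- do.call(paste, c(df[setdiff(names(df), "count")], sep = "\r"))
    u <- !duplicated(key)
    out <- df[u, , drop = FALSE]
    out$count <- as.vector(rowsum(rep(1L, nrow(df)), key)[match(key[u], sort(unique(key))), ])
    rownames(out) <- NULL
    out
  }
  mtab <- data.frame(r = r[met], kind = kind[met], s = s[met],
                     dt = round(dt[met] * 365) / 365,
                     agek = round(age[met]), male = male[met],
                     count = rep(1L, sum(met)))
  ctab <- data.frame(kind = kind[!met], dt = dt[!met], age = age[!met],
                     male = male[!met], count = rep(1L, sum(!met)))
  mtab <- if (nrow(mtab)) agg(mtab) else mtab
  ctab <- if (nrow(ctab)) agg(ctab) else ctab
  # covariate strata of the metabolic intervals, fixed across likelihood
  # evaluations
  gkey <- paste(mtab$agek, mtab$male)
  gtab <- mtab[!duplicated(gkey), c("agek", "male"), drop = FALSE]
  rownames(gtab) <- NULL
  list(met = mtab, cvd = ctab,
       g = match(gkey, paste(gtab$agek, gtab$male)), gtab = gtab,
       n_intervals = length(i),
       n_subjects = attr(data, "n_subjects"))
}

# ---- likelihood -------------------------------------------------------------

#' Log-likelihood contribution of one observation interval
#'
#' Reference implementation of the interval likelihood for a consecutive
#' pair of observations of one subject, using the full 6x6 transition
#' probability matrix. Covariates are held at their value at the start
#' of the interval (piecewise-constant age convention).
#'
#' The contribution depends on how the interval ends:
#' a panel screen in state `s` contributes `log P[r,s](dt)`; an
#' exactly-dated CVD onset contributes `log sum_m P[r,m](dt) l_m4` over
#' the metabolic states `m`; an exactly-dated death contributes the
#' analogous sum with the death intensity; censoring contributes the
#' probability of still being alive in a state consistent with the
#' registry (no unreported CVD onset or death). Structurally impossible
#' intervals return `-Inf` with attribute `impossible = TRUE` rather
#' than raising an error.
#'
#' @param prev,nxt Lists (or one-row data frames) with elements `time`,
#'   `state`, `obs_kind`, `age`, `sex`.
#' @param params An [intensity_params()] object.
#' @return Log-probability (scalar).
#' @export
interval_loglik <- function(prev, nxt, params) {
  prev <- as.list(prev); nxt <- as.list(nxt)
  r <- as.integer(prev$state)
  if (is.na(r) || r %in% 5:6) {
    stop("interval starting in an absorbing state", call. = FALSE)
  }
  dt <- nxt$time - prev$time
  if (!is.finite(dt) || dt <= 0) stop("interval of non-positive length", call. = FALSE)
  age <- prev$age
  sex <- prev$sex
  Q <- build_generator(params, age, sex)
  P <- transition_probability(Q, dt)
  male <- sex_to_male(sex)
  lam <- function(nm) intensity_for(params, nm, age, sex)

  imp <- function() structure(-Inf, impossible = TRUE)
  kind <- nxt$obs_kind
  if (kind == "panel") {
    s <- as.integer(nxt$state)
    if (!s %in% 1:3 || !r %in% 1:3) return(imp())
    p <- P[r, s]
    return(if (p > 0) log(p) else imp())
  }
  if (kind == "censor") {
    p <- if (r %in% 1:3) sum(P[r, 1:3]) else P[4, 4]
    return(if (p > 0) log(p) else imp())
  }
  d <- as.integer(nxt$state)
  if (d == 4L) {
    if (!r %in% 1:3) return(imp())
    p <- sum(P[r, 1:3] * c(lam("1-4"), lam("2-4"), lam("3-4")))
  } else if (d == 5L) {
    p <- if (r == 4L) P[4, 4] * lam("4-5") else 0
  } else if (d == 6L) {
    p <- if (r %in% 1:3) {
      sum(P[r, 1:3] * c(lam("1-6"), lam("2-6"), lam("3-6")))
    } else P[4, 4] * lam("4-6")
  } else {
    stop("invalid next state", call. = FALSE)
  }
  if (p > 0) log(p) else imp()
}

#' Cohort log-likelihood
#'
#' Sum of [interval_loglik()] over all consecutive observation pairs of
#' all subjects, computed with a fast vectorized path: the intervals are
#' aggregated by (state, outcome, length, integer age, sex), the 3x3
#' living-metabolic block of the generator is eigendecomposed once per
#' (age, sex) stratum, and all interval probabilities of the stratum are
#' evaluated from the spectral form in one pass. Intervals spent in the
#' CVD state are closed-form exponentials.
#'
#' @param data A validated panel (`msm6_panel` or raw data frame), or a
#'   prebuilt interval table from the internal decomposition.
#' @param params An [intensity_params()] object.
#' @return Scalar log-likelihood; `-Inf` (with attribute
#'   `n_impossible`) if any interval is structurally impossible.
#' @export
cohort_loglik <- function(data, params) {
  itab <- if (is.list(data) && !is.data.frame(data) && !is.null(data$met)) {
    data
  } else {
    interval_table(data)
  }
  if (itab$n_intervals == 0L && nrow(itab$met) == 0L && nrow(itab$cvd) == 0L) {
    if (is.null(itab$n_subjects) || itab$n_subjects == 0L) {
      stop("empty cohort", call. = FALSE)
    }
    return(0)
  }
  ll <- 0
  n_impossible <- 0L

  m <- itab$met
  if (nrow(m)) {
    gtab <- itab$gtab
    gi <- itab$g
    ng <- nrow(gtab)
    lamg <- stratum_intensities(params, gtab$agek, gtab$male)
    if (!all(is.finite(lamg))) {
      n_impossible <- n_impossible + sum(m$count)
      ll <- -Inf
    } else {
      # closed-form spectral decomposition of the 3x3 block, all strata
      # at once (real eigensystem; see block_spectral)
      sp <- block_spectral(lamg)
      D <- sp$D
      Varr <- sp$Varr
      Viarr <- sp$Viarr
      fallback <- !sp$ok
      lam4 <- lamg[, c("1-4", "2-4", "3-4"), drop = FALSE]
      lam6 <- lamg[, c("1-6", "2-6", "3-6"), drop = FALSE]
      wc <- matrix(0, ng, 3L)  # Vinv %*% CVD intensities
      wo <- matrix(0, ng, 3L)  # Vinv %*% OCD intensities
      ws <- matrix(0, ng, 3L)  # Vinv %*% 1 (survival among metabolic states)
      for (k in 1:3) {
        wc[, k] <- Viarr[, k, 1L] * lam4[, 1L] + Viarr[, k, 2L] * lam4[, 2L] +
          Viarr[, k, 3L] * lam4[, 3L]
        wo[, k] <- Viarr[, k, 1L] * lam6[, 1L] + Viarr[, k, 2L] * lam6[, 2L] +
          Viarr[, k, 3L] * lam6[, 3L]
        ws[, k] <- Viarr[, k, 1L] + Viarr[, k, 2L] + Viarr[, k, 3L]
      }
      rs <- which(!fallback[gi])
      if (length(rs)) {
        gr <- gi[rs]
        rr <- m$r[rs]
        kk <- m$kind[rs]
        ss <- m$s[rs]
        nr <- length(rs)
        A <- matrix(0, nr, 3L)
        Bm <- matrix(0, nr, 3L)
        E <- matrix(0, nr, 3L)
        for (k in 1:3) {
          A[, k] <- Varr[cbind(gr, rr, k)]
          E[, k] <- exp(D[cbind(gr, k)] * m$dt[rs])
        }
        pan <- kk == "panel"
        if (any(pan)) {
          for (k in 1:3) Bm[pan, k] <- Viarr[cbind(gr[pan], k, ss[pan])]
        }
        for (kset in list(list("cvd_onset", wc), list("ocd", wo),
                          list("censor", ws))) {
          ksel <- kk == kset[[1L]]
          if (any(ksel)) Bm[ksel, ] <- kset[[2L]][gr[ksel], , drop = FALSE]
        }
        p <- rowSums(A * Bm * E)
        cnt <- m$count[rs]
        bad <- p <= 0
        if (any(bad)) {
          n_impossible <- n_impossible + sum(cnt[bad])
          ll <- -Inf
        }
        if (is.finite(ll)) ll <- ll + sum(cnt[!bad] * log(p[!bad]))
      }
      # strata whose eigenvectors were too ill-conditioned: direct expm
      for (g in which(fallback)) {
        sel <- which(gi == g)
        B <- living_block_from(lamg[g, ])
        Pt <- block_expm(B, m$dt[sel], eig = NULL)
        p <- numeric(length(sel))
        for (i in seq_along(sel)) {
          Pi <- Pt[i, , ]
          p[i] <- switch(m$kind[sel[i]],
                         panel = Pi[m$r[sel[i]], m$s[sel[i]]],
                         cvd_onset = sum(Pi[m$r[sel[i]], ] * lamg[g, c("1-4", "2-4", "3-4")]),
                         ocd = sum(Pi[m$r[sel[i]], ] * lamg[g, c("1-6", "2-6", "3-6")]),
                         censor = sum(Pi[m$r[sel[i]], ]))
        }
        bad <- p <= 0
        if (any(bad)) {
          n_impossible <- n_impossible + sum(m$count[sel][bad])
          ll <- -Inf
        }
        if (is.finite(ll)) ll <- ll + sum(m$count[sel][!bad] * log(p[!bad]))
      }
    }
  }

  cv <- itab$cvd
  if (nrow(cv) && is.finite(ll)) {
    l45 <- intensity_for(params, "4-5", cv$age, cv$male)
    l46 <- intensity_for(params, "4-6", cv$age, cv$male)
    mu <- l45 + l46
    contrib <- -mu * cv$dt +
      ifelse(cv$kind == "cvd_death", log(l45),
      ifelse(cv$kind == "ocd", log(l46), 0))
    if (any(!is.finite(contrib))) {
      n_impossible <- n_impossible + sum(cv$count[!is.finite(contrib)])
      ll <- -Inf
    } else {
      ll <- ll + sum(cv$count * contrib)
    }
  }

  if (!is.finite(ll)) attr(ll, "n_impossible") <- n_impossible
  ll
}
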