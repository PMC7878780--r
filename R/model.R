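#' Covariate-specific transition intensity
#'
#' Evaluates the proportional-hazards intensity
#' `lambda0_rs * exp(beta_age_g * (age - ref_age) + beta_sex_g * male)`
#' for one allowed transition at given covariates.
#'
#' @param params An [intensity_params()] object.
#' @param transition Transition name such as `"2-3"`, or a length-2
#'   integer vector `c(from, to)`.
#' @param age Age in years.
#' @param sex `"male"` or `"female"` (vectors of the same length as
#'   `age` are accepted).
#' @return Intensity per year (vectorized over `age`/`sex`).
#' @examples
#' p <- default_intensity_params()
#' intensity_for(p, "2-3", age = 50, sex = "female") # baseline 0.0615
#' @export
intensity_for <- function(params, transition, age, sex) {
  stopifnot(inherits(params, "intensity_params"))
  if (is.numeric(transition) && length(transition) == 2L) {
    transition <- paste(transition, collapse = "-")
  }
  if (!transition %in% transition_names()) {
    stop(sprintf("transition %s is not in the model topology", transition),
         call. = FALSE)
  }
  g <- transition_group(transition, params$ocd_from_cvd_own)
  male <- sex_to_male(sex)
  rate <- params$lambda0[[transition]] *
    exp(params$beta_age[[g]] * (age - params$ref_age) + params$beta_sex[[g]] * male)
  if (any(!is.finite(rate))) {
    stop("non-finite intensity after covariate scaling", call. = FALSE)
  }
  rate
}

#' @keywords internal
sex_to_male <- function(sex) {
  if (is.numeric(sex)) return(as.numeric(sex))
  if (is.logical(sex)) return(as.numeric(sex))
  m <- match(tolower(as.character(sex)), c("female", "male"))
  if (anyNA(m)) stop("sex must be 'male' or 'female'", call. = FALSE)
  m - 1
}

#' Build the 6x6 generator matrix at given covariates
#'
#' Fills the allowed off-diagonal entries with the covariate-specific
#' intensities and sets each diagonal to minus its row sum; forbidden
#' entries are exactly zero and the two death states have all-zero rows.
#'
#' @inheritParams intensity_for
#' @return A 6x6 generator matrix (per year) with state labels as
#'   dimnames.
#' @examples
#' Q <- build_generator(default_intensity_params(), age = 50, sex = "female")
#' rowSums(Q) # all zero
#' @export
build_generator <- function(params, age, sex) {
  stopifnot(inherits(params, "intensity_params"), length(age) == 1L)
  male <- sex_to_male(sex)
  Q <- matrix(0, N_STATES, N_STATES, dimnames = list(STATE_LABELS, STATE_LABELS))
  tn <- transition_names()
  for (k in seq_len(nrow(TRANSITIONS))) {
    g <- transition_group(tn[k], params$ocd_from_cvd_own)
    Q[TRANSITIONS[k, 1L], TRANSITIONS[k, 2L]] <- params$lambda0[[tn[k]]] *
      exp(params$beta_age[[g]] * (age - params$ref_age) + params$beta_sex[[g]] * male)
  }
  if (any(!is.finite(Q))) {
    stop("non-finite intensity after covariate scaling", call. = FALSE)
  }
  diag(Q) <- -rowSums(Q)
  Q
}

#' Transition-probability matrix over an interval
#'
#' `P(t) = expm(Q t)`, computed by scaling-and-squaring (Ward's Pade
#' approximation via the Matrix package). Rows are renormalized only
#' within numerical tolerance: entries outside `[0, 1]` or row sums away
#' from 1 by more than `tol` raise an error rather than being silently
#' repaired.
#'
#' @param Q A 6x6 generator (from [build_generator()]), or any square
#'   generator matrix.
#' @param t Elapsed time in years (scalar, >= 0).
#' @param tol Numerical tolerance for the row-stochasticity repair
#'   (default `1e-8`).
#' @return The transition-probability matrix P(t).
#' @examples
#' Q <- build_generator(default_intensity_params(), 50, "female")
#' P <- transition_probability(Q, 1)
#' rowSums(P) # all 1
#' @export
transition_probability <- function(Q, t, tol = 1e-8) {
  stopifnot(is.matrix(Q), nrow(Q) == ncol(Q))
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t < 0) {
    stop("t must be a single non-negative number of years", call. = FALSE)
  }
  if (t == 0) {
    P0 <- diag(nrow(Q))
    dimnames(P0) <- dimnames(Q)
    return(P0)
  }
  P <- as.matrix(Matrix::expm(Q * t))
  dimnames(P) <- dimnames(Q)
  if (any(P < -tol) || any(P > 1 + tol)) {
    stop("transition probabilities outside [0, 1] beyond tolerance", call. = FALSE)
  }
  P[P < 0] <- 0
  P[P > 1] <- 1
  rs <- rowSums(P)
  if (any(abs(rs - 1) > tol)) {
    stop("transition-probability rows deviate from stochasticity beyond tolerance",
         call. = FALSE)
  }
  P / rs
}

# ---- fast machinery for the living-metabolic block --------------------------
#
# Because CVD and the two death states never return to the metabolic
# states, the transition probabilities among {FMD, MMD, MetS} equal the
# matrix exponential of the 3x3 sub-generator whose diagonal includes
# the exits to CVD and OCD. This block is what the panel likelihood
# needs, and its eigendecomposition lets P(t) be evaluated for many t
# at once without repeated expm calls.

# all 11 intensities for a vector of covariate strata (rows) at once
stratum_intensities <- function(params, age, male) {
  tn <- transition_names()
  out <- matrix(0, length(age), length(tn), dimnames = list(NULL, tn))
  for (nm in tn) {
    g <- transition_group(nm, params$ocd_from_cvd_own)
    out[, nm] <- params$lambda0[[nm]] *
      exp(params$beta_age[[g]] * (age - params$ref_age) + params$beta_sex[[g]] * male)
  }
  out
}

# 3x3 living-metabolic block from a named intensity vector
living_block_from <- function(l) {
  matrix(c(-(l[["1-2"]] + l[["1-4"]] + l[["1-6"]]), l[["1-2"]], 0,
           l[["2-1"]], -(l[["2-1"]] + l[["2-3"]] + l[["2-4"]] + l[["2-6"]]), l[["2-3"]],
           0, 0, -(l[["3-4"]] + l[["3-6"]])),
         nrow = 3L, byrow = TRUE)
}

living_block <- function(params, age, male) {
  l <- function(nm) {
    g <- transition_group(nm, params$ocd_from_cvd_own)
    params$lambda0[[nm]] *
      exp(params$beta_age[[g]] * (age - params$ref_age) + params$beta_sex[[g]] * male)
  }
  l12 <- l("1-2"); l21 <- l("2-1"); l23 <- l("2-3")
  l14 <- l("1-4"); l24 <- l("2-4"); l34 <- l("3-4")
  l16 <- l("1-6"); l26 <- l("2-6"); l36 <- l("3-6")
  B <- matrix(c(-(l12 + l14 + l16), l12, 0,
                l21, -(l21 + l23 + l24 + l26), l23,
                0, 0, -(l34 + l36)),
              nrow = 3L, byrow = TRUE)
  list(B = B, to_cvd = c(l14, l24, l34), to_ocd = c(l16, l26, l36))
}

# Closed-form spectral decomposition of the 3x3 living-metabolic block
# for all covariate strata at once. The MetS row is decoupled (no exit
# back to FMD/MMD), so one eigenvalue is its total exit rate and the
# other two are the real roots of the FMD-MMD 2x2 exchange block.
# Strata too close to an eigenvalue degeneracy are flagged not-ok and
# handled by the generic eigen/expm fallback.
block_spectral <- function(lamg) {
  a1 <- lamg[, "1-2"] + lamg[, "1-4"] + lamg[, "1-6"]
  a2 <- lamg[, "2-1"] + lamg[, "2-3"] + lamg[, "2-4"] + lamg[, "2-6"]
  a3 <- lamg[, "3-4"] + lamg[, "3-6"]
  l12 <- lamg[, "1-2"]; l21 <- lamg[, "2-1"]; l23 <- lamg[, "2-3"]
  s <- -(a1 + a2) / 2
  q <- sqrt(((a1 - a2) / 2)^2 + l12 * l21)
  mu1 <- s + q
  mu2 <- s - q
  e3 <- -a3
  scale <- 1 + a1 + a2 + a3
  det3 <- (a3 - a1) * (a3 - a2) - l12 * l21
  ok <- l12 > 1e-12 & q > 1e-7 * scale & abs(det3) > 1e-9 * scale^2 &
    abs(mu1 - e3) > 1e-7 * scale & abs(mu2 - e3) > 1e-7 * scale
  x <- l12 * l23 / det3
  y <- -(a3 - a1) * l23 / det3
  detA <- l12 * (mu2 - mu1)
  ng <- nrow(lamg)
  D <- cbind(mu1, mu2, e3)
  Varr <- array(0, c(ng, 3L, 3L))
  Varr[, 1L, 1L] <- l12;      Varr[, 1L, 2L] <- l12;      Varr[, 1L, 3L] <- x
  Varr[, 2L, 1L] <- mu1 + a1; Varr[, 2L, 2L] <- mu2 + a1; Varr[, 2L, 3L] <- y
  Varr[, 3L, 3L] <- 1
  Viarr <- array(0, c(ng, 3L, 3L))
  Viarr[, 1L, 1L] <- (mu2 + a1) / detA
  Viarr[, 1L, 2L] <- -l12 / detA
  Viarr[, 2L, 1L] <- -(mu1 + a1) / detA
  Viarr[, 2L, 2L] <- l12 / detA
  Viarr[, 1L, 3L] <- -(Viarr[, 1L, 1L] * x + Viarr[, 1L, 2L] * y)
  Viarr[, 2L, 3L] <- -(Viarr[, 2L, 1L] * x + Viarr[, 2L, 2L] * y)
  Viarr[, 3L, 3L] <- 1
  list(D = D, Varr = Varr, Viarr = Viarr, ok = ok)
}

# Eigendecomposition of the 3x3 block with a conditioning check; for
# this topology the eigenvalues are real, but the code stays
# complex-safe. Returns NULL when the eigenvectors are too
# ill-conditioned to use (caller falls back to direct expm).
block_eigen <- function(B) {
  e <- eigen(B)
  V <- e$vectors
  Vinv <- tryCatch(solve(V), error = function(cond) NULL)
  if (is.null(Vinv)) return(NULL)
  if (max(Mod(V %*% Vinv - diag(3))) > 1e-8) return(NULL)
  list(d = e$values, V = V, Vinv = Vinv)
}

# exp(B * t) for a vector of times, via the eigendecomposition when
# possible; rows/cols indexed 1..3 (FMD, MMD, MetS).
block_expm <- function(B, ts, eig = block_eigen(B)) {
  if (!is.null(eig)) {
    E <- exp(outer(ts, eig$d))           # n x 3
    out <- array(0, dim = c(length(ts), 3L, 3L))
    for (r in 1:3) for (s in 1:3) {
      w <- eig$V[r, ] * eig$Vinv[, s]
      out[, r, s] <- Re(E %*% w)
    }
    return(out)
  }
  out <- array(0, dim = c(length(ts), 3L, 3L))
  for (i in seq_along(ts)) {
    out[i, , ] <- as.matrix(Matrix::expm(B * ts[i]))
  }
  out
}
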