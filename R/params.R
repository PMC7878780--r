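#' Transition-intensity parameters with proportional-hazards covariates
#'
#' Container for the model's full parameter vector: one baseline
#' intensity per allowed transition (stored on the log scale, per year),
#' and one (age, sex) pair of log rate-ratios per covariate group. Each
#' of the seven specific transitions (FMD-MMD, MMD-FMD, MMD-MetS, the
#' three CVD incidences and CVD death) has its own covariate pair; the
#' other-cause-death intensities from the living metabolic states share
#' one pooled pair, which by default also covers OCD from CVD.
#'
#' Baseline intensities apply at the reference covariates (default:
#' female, age 50), which are carried with the object so that simulated
#' truth and fitted baselines are always comparable. The intensity for
#' transition r-s at covariates (age, sex) is
#' `lambda0_rs * exp(beta_age_g * (age - age_ref) + beta_sex_g * male)`.
#'
#' @param lambda0 Named numeric vector of baseline intensities per year
#'   on the natural scale, names from `rownames(msm6_topology())`
#'   ("1-2", "2-1", "2-3", "1-4", "2-4", "3-4", "4-5", "1-6", "2-6",
#'   "3-6", "4-6"). Missing transitions default to 0.
#' @param beta_age,beta_sex Named numeric vectors of log rate-ratios per
#'   covariate group ("1-2", "2-1", "2-3", "1-4", "2-4", "3-4", "4-5",
#'   "ocd", and "4-6" when `ocd_from_cvd_own`). Missing groups default
#'   to 0 (no effect).
#' @param ref_age Reference age in years (default 50).
#' @param ref_sex Reference sex; only `"female"` is supported as the
#'   reference level.
#' @param ocd_from_cvd_own If `TRUE`, OCD from CVD (4-6) gets its own
#'   covariate pair instead of sharing the pooled OCD pair.
#' @return An object of class `intensity_params`.
#' @examples
#' p <- intensity_params(lambda0 = c("1-2" = 0.45, "2-1" = 0.29))
#' intensity_for(p, "1-2", age = 50, sex = "female")
#' @export
intensity_params <- function(lambda0 = numeric(), beta_age = numeric(),
                             beta_sex = numeric(), ref_age = 50,
                             ref_sex = "female", ocd_from_cvd_own = FALSE) {
  tn <- transition_names()
  groups <- if (ocd_from_cvd_own) c(COVARIATE_GROUPS, "4-6") else COVARIATE_GROUPS

  fill <- function(x, names_all, what) {
    out <- stats::setNames(numeric(length(names_all)), names_all)
    if (length(x)) {
      bad <- setdiff(names(x), names_all)
      if (length(bad)) {
        stop(sprintf("unknown %s name(s): %s", what, paste(bad, collapse = ", ")),
             call. = FALSE)
      }
      out[names(x)] <- x
    }
    out
  }

  l0 <- fill(lambda0, tn, "transition")
  if (any(l0 < 0) || any(!is.finite(l0))) {
    stop("baseline intensities must be finite and non-negative", call. = FALSE)
  }
  ba <- fill(beta_age, groups, "covariate group")
  bs <- fill(beta_sex, groups, "covariate group")
  if (any(!is.finite(ba)) || any(!is.finite(bs))) {
    stop("log rate-ratios must be finite", call. = FALSE)
  }
  ref_sex <- match.arg(ref_sex, "female")
  stopifnot(is.numeric(ref_age), length(ref_age) == 1L, is.finite(ref_age))

  structure(list(lambda0 = l0, beta_age = ba, beta_sex = bs,
                 ref_age = ref_age, ref_sex = ref_sex,
                 ocd_from_cvd_own = ocd_from_cvd_own),
            class = "intensity_params")
}

#' @export
print.intensity_params <- function(x, digits = 4, ...) {
  cat("Six-state transition-intensity parameters\n")
  cat(sprintf("  reference covariates: %s, age %g\n", x$ref_sex, x$ref_age))
  tab <- data.frame(
    transition = names(x$lambda0),
    rate_pct_per_year = round(100 * x$lambda0, digits),
    age_RR = round(exp(x$beta_age[vapply(names(x$lambda0), transition_group,
                                         "", x$ocd_from_cvd_own)]), digits),
    sex_RR = round(exp(x$beta_sex[vapply(names(x$lambda0), transition_group,
                                         "", x$ocd_from_cvd_own)]), digits),
    row.names = NULL
  )
  print(tab, ...)
  invisible(x)
}

#' Default parameter set for an adult screening population
#'
#' A complete parameter set with plausible annual transition intensities
#' and age/sex rate ratios for an adult community-screening population:
#' fast exchange between no disorder and mild disorder (around 45%/yr
#' progression, 29%/yr regression), 6%/yr progression from mild disorder
#' to the syndrome, CVD incidence rising steeply with metabolic severity
#' (1.6%, 4.7%, 20%/yr), CVD case fatality of about 6 per 1,000
#' person-years, and rare other-cause mortality. It is the default truth
#' for the synthetic-cohort simulator and the parameter-recovery
#' harness.
#'
#' @param covariates If `FALSE`, all covariate log rate-ratios are set
#'   to zero (homogeneous-cohort variant).
#' @return An `intensity_params` object (reference: female, age 50).
#' @export
default_intensity_params <- function(covariates = TRUE) {
  lambda0 <- c(
    "1-2" = 0.4482, "2-1" = 0.2911, "2-3" = 0.0615,
    "1-4" = 0.0162, "2-4" = 0.0474, "3-4" = 0.2022,
    "4-5" = 0.0061,
    "1-6" = 0.0011, "2-6" = 0.0027, "3-6" = 0.0077, "4-6" = 0.0091
  )
  if (!covariates) {
    return(intensity_params(lambda0 = lambda0))
  }
  age_rr <- c("1-2" = 1.01, "2-1" = 0.97, "2-3" = 1.03, "1-4" = 1.06,
              "2-4" = 1.04, "3-4" = 1.01, "4-5" = 1.08, "ocd" = 1.10)
  sex_rr <- c("1-2" = 1.30, "2-1" = 0.67, "2-3" = 0.98, "1-4" = 0.50,
              "2-4" = 0.88, "3-4" = 0.86, "4-5" = 2.88, "ocd" = 3.63)
  intensity_params(lambda0 = lambda0, beta_age = log(age_rr),
                   beta_sex = log(sex_rr))
}

#' @keywords internal
params_groups <- function(params) {
  if (params$ocd_from_cvd_own) c(COVARIATE_GROUPS, "4-6") else COVARIATE_GROUPS
}

# ---- free-parameter packing for the optimizer -------------------------------

# The free vector is (log lambda0, beta_age, beta_sex) with the CVD
# incidences optionally tied to a single baseline (equal_cvd_risk) and
# covariate effects optionally dropped or tied.
free_param_info <- function(params, variant = c("full", "equal_cvd_risk"),
                            covariates = TRUE, tie_covariates = FALSE) {
  variant <- match.arg(variant)
  tn <- transition_names()
  groups <- params_groups(params)
  cvd <- c("1-4", "2-4", "3-4")
  lam_free <- if (variant == "equal_cvd_risk") {
    c(setdiff(tn, cvd), "cvd")   # one shared CVD baseline
  } else tn
  grp_free <- if (!covariates) character(0) else if (variant == "equal_cvd_risk" && tie_covariates) {
    c(setdiff(groups, cvd), "cvd")
  } else groups
  list(variant = variant, covariates = covariates, tie_covariates = tie_covariates,
       lam_free = lam_free, grp_free = grp_free,
       n_free = length(lam_free) + 2L * length(grp_free),
       names = c(paste0("log_lambda0.", lam_free),
                 if (length(grp_free)) paste0("beta_age.", grp_free),
                 if (length(grp_free)) paste0("beta_sex.", grp_free)))
}

pack_params <- function(params, info) {
  lam <- log(pmax(params$lambda0, 1e-12))
  getlam <- function(nm) if (nm == "cvd") mean(lam[c("1-4", "2-4", "3-4")]) else lam[[nm]]
  v <- vapply(info$lam_free, getlam, numeric(1))
  if (length(info$grp_free)) {
    getb <- function(b, nm) if (nm == "cvd") mean(b[c("1-4", "2-4", "3-4")]) else b[[nm]]
    v <- c(v, vapply(info$grp_free, function(g) getb(params$beta_age, g), numeric(1)),
           vapply(info$grp_free, function(g) getb(params$beta_sex, g), numeric(1)))
  }
  stats::setNames(v, info$names)
}

unpack_params <- function(theta, info, template) {
  tn <- transition_names()
  nl <- length(info$lam_free)
  lam <- theta[seq_len(nl)]
  names(lam) <- info$lam_free
  lambda0 <- stats::setNames(numeric(length(tn)), tn)
  for (nm in names(lam)) {
    if (nm == "cvd") {
      lambda0[c("1-4", "2-4", "3-4")] <- exp(lam[[nm]])
    } else lambda0[[nm]] <- exp(lam[[nm]])
  }
  ba <- template$beta_age * 0
  bs <- template$beta_sex * 0
  if (length(info$grp_free)) {
    ng <- length(info$grp_free)
    a <- theta[nl + seq_len(ng)]
    s <- theta[nl + ng + seq_len(ng)]
    names(a) <- names(s) <- info$grp_free
    for (g in info$grp_free) {
      if (g == "cvd") {
        ba[c("1-4", "2-4", "3-4")] <- a[[g]]
        bs[c("1-4", "2-4", "3-4")] <- s[[g]]
      } else {
        ba[[g]] <- a[[g]]
        bs[[g]] <- s[[g]]
      }
    }
  } else if (info$covariates) {
    ba <- template$beta_age
    bs <- template$beta_sex
  }
  intensity_params(lambda0 = lambda0, beta_age = ba, beta_sex = bs,
                   ref_age = template$ref_age, ref_sex = template$ref_sex,
                   ocd_from_cvd_own = template$ocd_from_cvd_own)
}

# ---- flat-file round trip ---------------------------------------------------

#' Read or write a parameter file
#'
#' Parameters are stored as flat YAML with keys `lambda0.<from>_<to>`,
#' `beta_age.<group>`, `beta_sex.<group>`, `reference.age` and
#' `reference.sex`; values round-trip bit-exactly through the full
#' double-precision representation.
#'
#' @param params An `intensity_params` object.
#' @param path File path.
#' @return `write_params` returns `path` invisibly; `read_params`
#'   returns an `intensity_params`.
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "intensity_params"))
  # doubles go to disk as full-precision decimal strings ("%.17g"), which
  # survive the YAML round trip bit-exactly
  enc <- function(v) stats::setNames(as.list(sprintf("%.17g", unname(v))),
                                     names(v))
  obj <- list(
    lambda0 = enc(stats::setNames(params$lambda0,
                                  gsub("-", "_", names(params$lambda0)))),
    beta_age = enc(stats::setNames(params$beta_age,
                                   gsub("-", "_", names(params$beta_age)))),
    beta_sex = enc(stats::setNames(params$beta_sex,
                                   gsub("-", "_", names(params$beta_sex)))),
    reference = list(age = params$ref_age, sex = params$ref_sex),
    ocd_from_cvd_own = params$ocd_from_cvd_own
  )
  yaml::write_yaml(obj, path, precision = 17)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  obj <- yaml::read_yaml(path)
  dec <- function(x) {
    if (is.null(x)) return(numeric())
    stats::setNames(vapply(x, as.numeric, numeric(1)), gsub("_", "-", names(x)))
  }
  intensity_params(
    lambda0 = dec(obj$lambda0),
    beta_age = dec(obj$beta_age),
    beta_sex = dec(obj$beta_sex),
    ref_age = as.numeric(obj$reference$age),
    ref_sex = obj$reference$sex,
    ocd_from_cvd_own = isTRUE(obj$ocd_from_cvd_own)
  )
}
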