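#' Harmonized metabolic-syndrome criteria thresholds
#'
#' Thresholds of the five harmonized criteria, with the waist cutoff
#' adjusted for Asian populations. All "at least" thresholds are
#' inclusive and the HDL "below" thresholds are exclusive, exactly as
#' written in the harmonized statement.
#'
#' @export
RMRC_THRESHOLDS <- list(
  waist_female  = 80,    # cm, >=
  waist_male    = 90,    # cm, >=
  triglycerides = 150,   # mg/dL, >=
  hdl_female    = 50,    # mg/dL, <
  hdl_male      = 40,    # mg/dL, <
  sbp           = 130,   # mmHg, >=
  dbp           = 85,    # mmHg, >=
  glucose       = 100    # mg/dL, >=
)

# Number of positive criteria at or above which a subject is staged MetS.
# The harmonized definition is operationally "three or more"; kept as a
# named constant so the cutoff is visible and auditable.
MET_S_MIN_CRITERIA <- 3L

criterion_names <- c("central_obesity", "hypertriglyceridemia", "low_hdl",
                     "high_bp", "hyperglycemia")

#' Evaluate the five metabolic-syndrome criteria for one screen
#'
#' Maps raw biomarkers and treatment history to the five-criteria vector:
#' central obesity (waist >= 80 cm women / 90 cm men), hypertriglyceridemia
#' (TG >= 150 mg/dL), low HDL (< 50 women / < 40 men), elevated blood
#' pressure (SBP >= 130 or DBP >= 85 mmHg) and hyperglycemia (fasting
#' glucose >= 100 mg/dL). Subjects under treatment for hypertension,
#' diabetes or hyperlipidemia are counted as positive on the elevated
#' blood pressure, hyperglycemia and hypertriglyceridemia criteria
#' respectively, regardless of the measured value.
#'
#' @param sex `"male"` or `"female"`.
#' @param waist Waist circumference in cm.
#' @param triglycerides Fasting triglycerides in mg/dL.
#' @param hdl HDL cholesterol in mg/dL.
#' @param sbp,dbp Systolic and diastolic blood pressure in mmHg.
#' @param glucose Fasting plasma glucose in mg/dL.
#' @param on_hypertension_treatment,on_diabetes_treatment,on_hyperlipidemia_treatment
#'   Logical treatment-history flags (default `FALSE`).
#' @param hyperlipidemia_sets_low_hdl If `TRUE`, hyperlipidemia treatment
#'   also sets the low-HDL criterion; by default it maps only to the
#'   hypertriglyceridemia criterion, treating "hyperlipidemia" as a
#'   single treated category.
#' @param permissive If `TRUE`, a missing biomarker without a covering
#'   treatment flag leaves that criterion `NA` (counted as negative in
#'   `n_positive`) instead of raising an error; the result is flagged
#'   `incomplete`.
#' @return A list of class `criteria_vector` with the five logical flags,
#'   `n_positive`, and `incomplete`.
#' @examples
#' evaluate_criteria("female", waist = 80, triglycerides = 149, hdl = 50,
#'                   sbp = 129, dbp = 84, glucose = 99)
#' @export
evaluate_criteria <- function(sex, waist, triglycerides, hdl, sbp, dbp, glucose,
                              on_hypertension_treatment = FALSE,
                              on_diabetes_treatment = FALSE,
                              on_hyperlipidemia_treatment = FALSE,
                              hyperlipidemia_sets_low_hdl = FALSE,
                              permissive = FALSE) {
  sex <- match.arg(sex, c("male", "female"))
  thr <- RMRC_THRESHOLDS
  male <- sex == "male"

  flag <- function(value, test, covered, name) {
    if (isTRUE(covered)) return(TRUE)
    if (is.null(value) || length(value) == 0L || is.na(value)) {
      if (permissive) return(NA)
      stop(sprintf("missing biomarker for criterion '%s' with no covering treatment flag",
                   name), call. = FALSE)
    }
    test(value)
  }

  co <- flag(waist, function(v) v >= if (male) thr$waist_male else thr$waist_female,
             FALSE, "central_obesity")
  tg <- flag(triglycerides, function(v) v >= thr$triglycerides,
             on_hyperlipidemia_treatment, "hypertriglyceridemia")
  lh <- flag(hdl, function(v) v < if (male) thr$hdl_male else thr$hdl_female,
             on_hyperlipidemia_treatment && hyperlipidemia_sets_low_hdl,
             "low_hdl")
  # blood pressure needs both readings unless treatment covers it
  bp <- if (isTRUE(on_hypertension_treatment)) {
    TRUE
  } else if (is.na(sbp) || is.na(dbp)) {
    if (!permissive) {
      stop("missing biomarker for criterion 'high_bp' with no covering treatment flag",
           call. = FALSE)
    }
    NA
  } else {
    sbp >= thr$sbp || dbp >= thr$dbp
  }
  gl <- flag(glucose, function(v) v >= thr$glucose,
             on_diabetes_treatment, "hyperglycemia")

  flags <- c(central_obesity = co, hypertriglyceridemia = tg, low_hdl = lh,
             high_bp = bp, hyperglycemia = gl)
  out <- as.list(flags)
  out$n_positive <- sum(flags, na.rm = TRUE)
  out$incomplete <- anyNA(flags)
  class(out) <- "criteria_vector"
  out
}

#' Stage a criteria vector on the refined metabolic classification
#'
#' Zero positive criteria is free of metabolic disorder (FMD, state 1),
#' one or two is mild metabolic disorder (MMD, state 2), three or more is
#' metabolic syndrome (MetS, state 3).
#'
#' @param criteria A `criteria_vector` from [evaluate_criteria()], or an
#'   integer count of positive criteria.
#' @return Integer state code (1, 2 or 3), with the state label as name.
#' @examples
#' classify_rmrc(0) # FMD
#' classify_rmrc(2) # MMD
#' classify_rmrc(3) # MetS
#' @export
classify_rmrc <- function(criteria) {
  n <- if (inherits(criteria, "criteria_vector")) criteria$n_positive else criteria
  stopifnot(is.numeric(n), length(n) >= 1L, all(n >= 0 & n <= 5))
  state <- ifelse(n == 0, 1L, ifelse(n < MET_S_MIN_CRITERIA, 2L, 3L))
  names(state) <- STATE_LABELS[state]
  state
}

#' Classify a table of screening records
#'
#' Vectorized front end for [evaluate_criteria()] + [classify_rmrc()]:
#' takes a data frame of screens (one row per subject-screen) and returns
#' it with the five criterion flags, the positive count and the staged
#' state appended. Expected columns: `sex`, `waist`, `triglycerides`,
#' `hdl`, `sbp`, `dbp`, `glucose`, and optionally the three treatment
#' flags. Column names can be remapped through `col_map`.
#'
#' @param screens Data frame of screening records.
#' @param col_map Named character vector mapping expected names to the
#'   names used in `screens`, e.g. `c(glucose = "fbs")`.
#' @param permissive Passed to [evaluate_criteria()]; incomplete rows are
#'   staged on observed criteria only and flagged.
#' @param hyperlipidemia_sets_low_hdl Passed to [evaluate_criteria()].
#' @return `screens` with columns `central_obesity`, `hypertriglyceridemia`,
#'   `low_hdl`, `high_bp`, `hyperglycemia`, `n_positive`, `incomplete`,
#'   `state` and `state_label` appended.
#' @export
classify_screens <- function(screens, col_map = NULL, permissive = FALSE,
                             hyperlipidemia_sets_low_hdl = FALSE) {
  stopifnot(is.data.frame(screens))
  get_col <- function(name, default = NULL) {
    src <- if (!is.null(col_map) && name %in% names(col_map)) col_map[[name]] else name
    if (src %in% names(screens)) screens[[src]] else default
  }
  n <- nrow(screens)
  sex <- get_col("sex")
  if (is.null(sex)) stop("column 'sex' is required", call. = FALSE)
  args <- list(
    waist = get_col("waist", rep(NA_real_, n)),
    triglycerides = get_col("triglycerides", rep(NA_real_, n)),
    hdl = get_col("hdl", rep(NA_real_, n)),
    sbp = get_col("sbp", rep(NA_real_, n)),
    dbp = get_col("dbp", rep(NA_real_, n)),
    glucose = get_col("glucose", rep(NA_real_, n)),
    on_hypertension_treatment = get_col("on_hypertension_treatment", rep(FALSE, n)),
    on_diabetes_treatment = get_col("on_diabetes_treatment", rep(FALSE, n)),
    on_hyperlipidemia_treatment = get_col("on_hyperlipidemia_treatment", rep(FALSE, n))
  )
  res <- vector("list", n)
  for (i in seq_len(n)) {
    cv <- tryCatch(
      evaluate_criteria(sex[i], args$waist[i], args$triglycerides[i],
                        args$hdl[i], args$sbp[i], args$dbp[i], args$glucose[i],
                        isTRUE(args$on_hypertension_treatment[i]),
                        isTRUE(args$on_diabetes_treatment[i]),
                        isTRUE(args$on_hyperlipidemia_treatment[i]),
                        hyperlipidemia_sets_low_hdl = hyperlipidemia_sets_low_hdl,
                        permissive = permissive),
      error = function(e) stop(sprintf("row %d: %s", i, conditionMessage(e)),
                               call. = FALSE)
    )
    res[[i]] <- cv
  }
  for (nm in criterion_names) {
    screens[[nm]] <- vapply(res, function(cv) {
      v <- cv[[nm]]; if (is.na(v)) NA else v
    }, logical(1))
  }
  screens$n_positive <- vapply(res, `[[`, integer(1), "n_positive")
  screens$incomplete <- vapply(res, `[[`, logical(1), "incomplete")
  screens$state <- unname(classify_rmrc(screens$n_positive))
  screens$state_label <- STATE_LABELS[screens$state]
  screens
}
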