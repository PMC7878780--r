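#' State space and transition topology of the six-state model
#'
#' The model distinguishes three living metabolic states -- free of
#' metabolic disorder (FMD, none of the five criteria), mild metabolic
#' disorder (MMD, 1--2 criteria) and metabolic syndrome (MetS, 3+
#' criteria) -- plus cardiovascular disease (CVD), death from CVD and
#' death from other causes (OCD). MetS can only be entered through MMD,
#' regression out of MetS is not allowed (the natural-course assumption:
#' observed regression from MetS reflects treatment, not natural
#' history), and CVD death can only occur from the CVD state. Both death
#' states are absorbing.
#'
#' @format Integer state codes: 1 = FMD, 2 = MMD, 3 = MetS, 4 = CVD,
#'   5 = CVD death, 6 = other-cause death.
#' @name states
NULL

#' @rdname states
#' @export
STATE_LABELS <- c("FMD", "MMD", "MetS", "CVD", "CVD_death", "OCD")

#' @rdname states
#' @export
N_STATES <- 6L

# the 11 allowed instantaneous transitions, in canonical order
TRANSITIONS <- matrix(c(
  1L, 2L,   # FMD  -> MMD   progression
  2L, 1L,   # MMD  -> FMD   regression
  2L, 3L,   # MMD  -> MetS  progression (only entry into MetS)
  1L, 4L,   # FMD  -> CVD
  2L, 4L,   # MMD  -> CVD
  3L, 4L,   # MetS -> CVD
  4L, 5L,   # CVD  -> CVD death
  1L, 6L,   # FMD  -> OCD
  2L, 6L,   # MMD  -> OCD
  3L, 6L,   # MetS -> OCD
  4L, 6L    # CVD  -> OCD
), ncol = 2L, byrow = TRUE, dimnames = list(NULL, c("from", "to")))

#' Allowed transitions of the six-state model
#'
#' Returns the 11 allowed ordered state pairs. Forbidden moves encode the
#' model's structural assumptions: no direct FMD to MetS jump, no
#' regression out of MetS, CVD death only from CVD, and no exit from the
#' two absorbing death states.
#'
#' @return A two-column integer matrix with columns `from` and `to`,
#'   one row per allowed transition, with rownames like `"1-2"`.
#' @examples
#' msm6_topology()
#' @export
msm6_topology <- function() {
  out <- TRANSITIONS
  rownames(out) <- transition_names()
  out
}

transition_names <- function() {
  paste(TRANSITIONS[, "from"], TRANSITIONS[, "to"], sep = "-")
}

#' @keywords internal
is_allowed_transition <- function(from, to) {
  any(TRANSITIONS[, "from"] == from & TRANSITIONS[, "to"] == to)
}

#' @keywords internal
transition_index <- function(from, to) {
  idx <- which(TRANSITIONS[, "from"] == from & TRANSITIONS[, "to"] == to)
  if (length(idx) != 1L) {
    stop(sprintf("transition %d->%d is not in the model topology", from, to),
         call. = FALSE)
  }
  idx
}

# Covariate groups: each of the seven specific transitions carries its own
# (age, sex) log rate-ratio pair; the other-cause-death transitions from
# the living metabolic states share one pooled pair, which by default also
# covers OCD from CVD (4-6).
COVARIATE_GROUPS <- c("1-2", "2-1", "2-3", "1-4", "2-4", "3-4", "4-5", "ocd")

#' @keywords internal
transition_group <- function(trans_name, ocd_from_cvd_own = FALSE) {
  if (trans_name %in% c("1-6", "2-6", "3-6")) return("ocd")
  if (trans_name == "4-6") return(if (ocd_from_cvd_own) "4-6" else "ocd")
  trans_name
}
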