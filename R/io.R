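#' Read or write long-format panel data
#'
#' The on-disk schema is one CSV row per observation with columns
#' `subject_id`, `time` (years since entry), `state` (1--6, empty for
#' censor rows), `obs_kind` (`panel` / `exact_event` / `censor`), `age`
#' (years) and `sex` (`male`/`female`). `read_panel` validates on load
#' and reports offending row numbers.
#'
#' @param path CSV file path.
#' @param carry_forward Passed to [validate_panel()].
#' @return `read_panel`: a validated `msm6_panel`; `write_panel`: the
#'   path, invisibly.
#' @export
read_panel <- function(path, carry_forward = TRUE) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_panel(raw, carry_forward = carry_forward)
}

#' @rdname read_panel
#' @param panel Panel data frame.
#' @export
write_panel <- function(panel, path) {
  cols <- c("subject_id", "time", "state", "obs_kind", "age", "sex")
  utils::write.csv(as.data.frame(panel)[, cols], path, row.names = FALSE,
                   na = "")
  invisible(path)
}
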