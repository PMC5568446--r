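#' Write / read a cohort dataset as flat CSV
#'
#' Columns: `subject`, `session`, `context_label`, `context_instance`,
#' `context_trial`, `choice`, `outcome_chosen`, `outcome_unchosen`
#' (empty under partial feedback), plus the scheduled probabilities
#' `p_a`, `p_b` so behavioural analyses are self-contained.
#'
#' @param data A stacked cohort data frame.
#' @param path File path.
#' @return `read_cohort` returns the data frame; `write_cohort` its
#'   input, invisibly.
#' @export
write_cohort <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE, na = "")
  invisible(data)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("outcome_unchosen" %in% names(d)) {
    d$outcome_unchosen <- as.numeric(d$outcome_unchosen)
  }
  d
}

#' Write / read a cohort fit table as CSV
#'
#' One row per subject and model with the resolved learning-rate slots,
#' `nll`, `lpp` and `bic` (the format produced by [fit_cohort()] and
#' consumed by [compare_models()]).
#'
#' @param fits A [fit_cohort()] data frame.
#' @param path File path.
#' @return `read_fits` returns the data frame; `write_fits` its input,
#'   invisibly.
#' @export
write_fits <- function(fits, path) {
  utils::write.csv(fits, path, row.names = FALSE)
  invisible(fits)
}

#' @rdname write_fits
#' @export
read_fits <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
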