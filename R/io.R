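#' Read analysis tables from CSV
#'
#' `read_subjects()` expects columns `id`, `v_index`, `delta` (blank when
#' missing), `m_flag`, covariate columns, and optionally `weight`,
#' `stratum`, `psu`.  `read_aux()` expects `id`, `visit_index`, `result`.
#' `read_calibration()` expects `id`, `xstar2`.  Empty fields are read as
#' missing.
#'
#' @param path Path to a CSV file.
#' @return A data.frame.
#' @export
read_subjects <- function(path) {
  df <- utils::read.csv(path, na.strings = c("", "NA"))
  need <- c("id", "v_index", "m_flag")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("subjects file lacks column(s): ", paste(miss, collapse = ", "))
  df
}

#' @rdname read_subjects
#' @export
read_aux <- function(path) {
  df <- utils::read.csv(path, na.strings = c("", "NA"))
  miss <- setdiff(c("id", "visit_index", "result"), names(df))
  if (length(miss))
    stop("auxiliary file lacks column(s): ", paste(miss, collapse = ", "))
  df
}

#' @rdname read_subjects
#' @export
read_calibration <- function(path) {
  df <- utils::read.csv(path, na.strings = c("", "NA"))
  miss <- setdiff(c("id", "xstar2"), names(df))
  if (length(miss))
    stop("calibration file lacks column(s): ", paste(miss, collapse = ", "))
  df
}

#' Write a coefficient table for a fit
#'
#' Writes estimate, standard error, 95% Wald interval and hazard ratio per
#' covariate as CSV.
#'
#' @param fit An `"aug_fit"` or `"cloglog_fit"` object.
#' @param path Output CSV path.
#' @return The table, invisibly.
#' @export
write_fit_csv <- function(fit, path) {
  z <- stats::qnorm(0.975)
  b <- fit$beta
  se <- fit$se_beta
  tab <- data.frame(term = names(b), estimate = unname(b),
                    se = unname(se),
                    lower = unname(b - z * se), upper = unname(b + z * se),
                    hr = exp(unname(b)))
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(tab)
}
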