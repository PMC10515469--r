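#' Discrete follow-up grid
#'
#' Defines the common visit boundaries \eqn{\tau_0 < \tau_1 < \dots < \tau_J}
#' that partition follow-up into the half-open intervals
#' \eqn{(\tau_{j-1}, \tau_j]} for \eqn{j = 1, \dots, J}, plus the residual
#' interval \eqn{(\tau_J, \infty)} indexed \eqn{J + 1}.  A visit at exactly
#' \eqn{\tau_l} observes the event if and only if \eqn{T \le \tau_l}.
#'
#' @param boundaries Numeric vector of strictly increasing visit times
#'   starting at 0 (baseline).  Length `J + 1`.
#' @return An object of class `"visit_grid"`: a list with elements
#'   `boundaries` and `J` (number of post-baseline visits).
#' @examples
#' g <- visit_grid(0:4)
#' g$J
#' @export
visit_grid <- function(boundaries) {
  boundaries <- as.numeric(boundaries)
  if (length(boundaries) < 2L)
    stop("'boundaries' must contain baseline and at least one visit time")
  if (boundaries[1L] != 0)
    stop("the first boundary (baseline) must be 0")
  if (any(diff(boundaries) <= 0))
    stop("'boundaries' must be strictly increasing")
  structure(list(boundaries = boundaries, J = length(boundaries) - 1L),
            class = "visit_grid")
}

#' @export
print.visit_grid <- function(x, ...) {
  cat("Visit grid: J =", x$J, "post-baseline visits at times",
      paste(x$boundaries[-1L], collapse = ", "), "\n")
  invisible(x)
}

#' Interval-difference transformation matrix
#'
#' Builds the \eqn{(J+1)\times(J+1)} upper-bidiagonal matrix \eqn{R} mapping
#' baseline survival probabilities \eqn{S = (S_1, \dots, S_{J+1})'} to
#' interval probabilities \eqn{\theta = R S}, i.e.
#' \eqn{\theta_j = S_j - S_{j+1}} (with \eqn{S_{J+2} \equiv 0}).
#'
#' @param J Positive integer, number of post-baseline visits.
#' @return A `(J+1) x (J+1)` numeric matrix.
#' @examples
#' r_matrix(2) %*% c(1, .6, .2)  # interval probabilities, sum to 1
#' @export
r_matrix <- function(J) {
  J <- as.integer(J)
  if (is.na(J) || J < 1L) stop("'J' must be a positive integer")
  R <- diag(J + 1L)
  R[cbind(seq_len(J), seq_len(J) + 1L)] <- -1
  R
}
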