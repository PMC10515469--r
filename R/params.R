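#' Baseline survival parameterization
#'
#' The baseline survival probabilities \eqn{1 = S_1 > S_2 > \dots > S_{J+1} > 0}
#' are optimized on an unconstrained scale through the cumulative log-hazard
#' coordinates \eqn{a_1, \dots, a_J}:
#' \deqn{S_{j+1} = \exp\{-\textstyle\sum_{k \le j} e^{a_k}\},}
#' so strict monotonicity holds by construction for any finite \eqn{a}.
#'
#' @param a Numeric vector of length `J` of unconstrained coordinates.
#' @return `ahaz_to_surv()`: the survival vector `S` of length `J + 1`
#'   (including the leading 1).  `surv_to_ahaz()`: the coordinate vector `a`.
#' @examples
#' a <- c(-1, 0, .5)
#' S <- ahaz_to_surv(a)
#' all.equal(surv_to_ahaz(S), a)
#' @export
ahaz_to_surv <- function(a) {
  c(1, exp(-cumsum(exp(a))))
}

#' @rdname ahaz_to_surv
#' @param s Numeric survival vector `S_1 = 1 > ... > S_{J+1} > 0`.
#' @export
surv_to_ahaz <- function(s) {
  if (s[1L] != 1) stop("'s' must start at S_1 = 1")
  if (any(diff(s) >= 0) || s[length(s)] <= 0)
    stop("'s' must be strictly decreasing and positive")
  log(diff(-log(s)))
}

## Pack/unpack the working parameter psi = (beta, a).
psi_pack <- function(beta, a) c(beta, a)
psi_unpack <- function(psi, p, J) {
  list(beta = psi[seq_len(p)], a = psi[p + seq_len(J)])
}

## Jacobian dS_{j}/da_k for j = 2..J+1 (row j-1), k = 1..J:
## dS_{j}/da_k = -S_{j} * exp(a_k) * 1{j - 1 >= k}.
surv_jacobian <- function(a) {
  S <- ahaz_to_surv(a)
  J <- length(a)
  lower <- outer(seq_len(J), seq_len(J), ">=")      # 1{j-1 >= k}
  jac <- -S[-1L] * lower * rep(exp(a), each = J)
  rbind(0, jac)                                      # S_1 = 1 is constant
}
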