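## Core likelihood machinery.
##
## Working parameters are psi = (beta, a), with a the unconstrained
## cumulative log-hazard coordinates of the baseline survival curve.  All
## heavy lifting is vectorized over subjects: with eta_i = exp(x_i'beta),
## S^eta the N x (J+1) matrix of S_j^{eta_i}, and theta_ij = S_j^{eta_i} -
## S_{j+1}^{eta_i}, each subject's likelihood contribution is
## L_i = sum_j B_ij C_ij theta_ij over the gold-standard-compatible
## intervals j (mask B), and l_i = log L_i.

lik_parts <- function(data, beta, a, need_grad = FALSE) {
  x <- data$x
  n <- nrow(x)
  J <- data$grid$J
  eta <- if (ncol(x)) exp(drop(x %*% beta)) else rep(1, n)
  S <- ahaz_to_surv(a)
  lS <- log(S)                                  # lS[1] = 0
  Seta <- exp(tcrossprod(eta, lS))              # N x (J+1), col j = S_j^eta
  theta <- Seta - cbind(Seta[, -1L, drop = FALSE], 0)
  BC <- data$C * data$mask
  Tbc <- BC * theta
  L <- rowSums(Tbc)
  out <- list(eta = eta, S = S, Seta = Seta, theta = theta, BC = BC,
              Tbc = Tbc, L = L, J = J, n = n)
  if (need_grad) {
    G <- Seta * rep(lS, each = n)               # S_j^eta * log S_j
    out$dLdeta <- rowSums(BC * (G - cbind(G[, -1L, drop = FALSE], 0)))
    ## tail sums T_ik = sum_{j > k} B C theta, k = 1..J
    tail_sel <- outer(seq_len(J + 1L), seq_len(J), ">")
    out$tail <- Tbc %*% tail_sel
  }
  out
}

ll_eval <- function(data, beta, a, weighted = FALSE, by_subject = FALSE) {
  parts <- lik_parts(data, beta, a)
  li <- log(parts$L)                            # -Inf where L == 0
  if (by_subject) return(li)
  if (any(!is.finite(li))) {
    bad <- data$id[!is.finite(li)]
    out <- -Inf
    attr(out, "zero_likelihood_ids") <- bad
    return(out)
  }
  if (weighted) sum(data$weight * li) else sum(li)
}

## Per-subject score matrix on the (beta, a) scale, N x (p + J).
## Unweighted contributions; callers apply weights.
score_matrix <- function(data, beta, a) {
  parts <- lik_parts(data, beta, a, need_grad = TRUE)
  n <- parts$n; J <- parts$J
  p <- ncol(data$x)
  invL <- 1 / parts$L
  sc_b <- if (p) {
    data$x * (parts$dLdeta * parts$eta * invL)
  } else {
    matrix(0, n, 0L)
  }
  ## d l_i / da_k = e^{a_k} eta_i (BC_{ik} Seta_{i,k+1} - T_ik) / L_i
  core <- parts$BC[, seq_len(J), drop = FALSE] *
    parts$Seta[, 1L + seq_len(J), drop = FALSE] - parts$tail
  sc_a <- core * (parts$eta * invL)
  sc_a <- sc_a * rep(exp(a), each = n)
  cbind(sc_b, sc_a)
}

score_eval <- function(data, beta, a, weighted = FALSE) {
  sm <- score_matrix(data, beta, a)
  w <- if (weighted) data$weight else rep(1, nrow(sm))
  out <- colSums(sm * w)
  names(out) <- c(colnames(data$x), paste0("a", seq_along(a)))
  out
}

#' Augmented log-likelihood
#'
#' Evaluates the (optionally survey-weighted) augmented log-likelihood at
#' regression coefficients `beta` and baseline survival `s`.  Each subject
#' contributes the log of the total probability of the intervals compatible
#' with their gold-standard observation, each interval weighted by the
#' probability of the observed auxiliary history given that interval:
#' subjects with an observed positive gold standard at visit \eqn{V_i} sum
#' over intervals \eqn{1..V_i}, observed negatives over
#' \eqn{V_i+1..J+1}, and subjects with a missing gold standard over all
#' intervals.
#'
#' @param data An [aug_data()] object.
#' @param beta Numeric vector of log hazard ratios (length `p`).
#' @param s Baseline survival vector `S_1 = 1 > ... > S_{J+1} > 0`.
#' @param weighted Use the sampling weights?
#' @param by_subject Return the vector of per-subject contributions
#'   (unweighted) instead of the total?
#' @return The total (weighted) log-likelihood, or the per-subject vector.
#'   A structurally impossible subject (zero-probability history, e.g.
#'   contradictory data under perfect tests) yields `-Inf`, with the
#'   offending subject ids attached as attribute `"zero_likelihood_ids"`.
#' @export
aug_loglik <- function(data, beta, s, weighted = FALSE, by_subject = FALSE) {
  stopifnot(inherits(data, "aug_data"))
  ll_eval(data, beta, surv_to_ahaz(s), weighted = weighted,
          by_subject = by_subject)
}

#' Score of the augmented log-likelihood
#'
#' Analytic gradient of [aug_loglik()] with respect to the working
#' parameters `(beta, a)`, where `a` are the unconstrained cumulative
#' log-hazard coordinates of `s` (see [ahaz_to_surv()]).
#'
#' @inheritParams aug_loglik
#' @param by_subject Return the `n x (p + J)` matrix of per-subject
#'   (unweighted) score contributions instead of the total?
#' @return Numeric vector of length `p + J`, or the per-subject matrix.
#' @export
aug_score <- function(data, beta, s, weighted = FALSE, by_subject = FALSE) {
  stopifnot(inherits(data, "aug_data"))
  a <- surv_to_ahaz(s)
  if (by_subject) return(score_matrix(data, beta, a))
  score_eval(data, beta, a, weighted = weighted)
}
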