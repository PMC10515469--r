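## Design-based (Binder linearization) variance for the weighted fit.

## Between-PSU with-replacement covariance of a total: rows of `scores` are
## per-subject weighted estimating-function contributions.
psu_total_cov <- function(scores, stratum, psu, lonely_psu = c("error", "center")) {
  lonely_psu <- match.arg(lonely_psu)
  key <- paste(stratum, psu, sep = "\r")
  z <- rowsum(scores, key, reorder = FALSE)
  z_str <- stratum[!duplicated(key)]
  k <- ncol(scores)
  B <- matrix(0, k, k)
  grand <- colMeans(z)
  for (h in unique(z_str)) {
    zh <- z[z_str == h, , drop = FALSE]
    nh <- nrow(zh)
    if (nh < 2L) {
      if (lonely_psu == "error")
        stop("stratum '", h, "' has a single PSU; supply certainty units, ",
             "collapse strata, or use lonely_psu = \"center\"")
      dev <- sweep(zh, 2L, grand)
      B <- B + crossprod(dev)
    } else {
      dev <- sweep(zh, 2L, colMeans(zh))
      B <- B + nh / (nh - 1) * crossprod(dev)
    }
  }
  B
}

#' Design-based sandwich variance for a weighted fit
#'
#' Computes the Taylor-linearization (Binder) variance
#' \eqn{A^{-1} B A^{-1}} for a survey-weighted augmented-likelihood fit,
#' where \eqn{A} is the numeric Jacobian of the weighted score total and
#' \eqn{B} is the with-replacement between-PSU covariance of the weighted
#' score total: within each stratum \eqn{h} with \eqn{n_h} sampled PSUs,
#' \eqn{B_h = \frac{n_h}{n_h-1} \sum_c (z_{hc} - \bar z_h)(z_{hc} - \bar z_h)'}
#' with \eqn{z_{hc}} the PSU sums of weighted per-subject scores, and
#' \eqn{B = \sum_h B_h}.  Stratum and PSU labels are taken from the data
#' used in the fit (defaults: a single stratum with each subject its own
#' PSU, which reduces to the iid robust sandwich).
#'
#' @param fit An [aug_fit()] object fitted with `weighted = TRUE` (an
#'   unweighted fit is treated as having unit weights).
#' @param lonely_psu How to handle strata with a single sampled PSU:
#'   `"error"` (default) or `"center"` (deviate the lone PSU total from the
#'   grand mean of all PSU totals).
#' @return A list of class `"aug_sandwich"` with `cov` (delta-method
#'   covariance of `(beta, S_2..S_{J+1})`), `cov_psi` (working scale),
#'   `se_beta`, and the `A` and `B` matrices.
#' @export
binder_sandwich <- function(fit, lonely_psu = c("error", "center")) {
  stopifnot(inherits(fit, "aug_fit"))
  data <- fit$data
  p <- fit$p
  J <- fit$grid$J
  psi <- psi_pack(fit$beta, fit$a)
  A <- num_hessian(function(q) {
    u <- psi_unpack(q, p, J)
    score_eval(data, u$beta, u$a, weighted = TRUE)
  }, psi)
  U <- score_matrix(data, fit$beta, fit$a) * data$weight
  B <- psu_total_cov(U, data$stratum, data$psu, lonely_psu)
  Ainv <- solve(A)
  cov_psi <- Ainv %*% B %*% t(Ainv)
  cov_psi <- (cov_psi + t(cov_psi)) / 2
  jac <- psi_jacobian(fit$a, p)
  cov <- jac %*% cov_psi %*% t(jac)
  nm <- c(colnames(data$x), paste0("S", 1L + seq_len(J)))
  dimnames(cov) <- list(nm, nm)
  structure(list(cov = cov, cov_psi = cov_psi,
                 se_beta = if (p) sqrt(diag(cov)[seq_len(p)]) else numeric(0),
                 A = A, B = B),
            class = "aug_sandwich")
}

#' Survey-weighted augmented-likelihood fit
#'
#' Convenience wrapper: maximizes the weighted log-likelihood and replaces
#' the model-based covariance with the design-based [binder_sandwich()]
#' variance.  The inverse-information covariance is kept in `$cov_model`.
#'
#' @inheritParams aug_fit
#' @inheritParams binder_sandwich
#' @return An `"aug_fit"` object whose `cov`, `cov_psi` and `se_beta` come
#'   from the design-based sandwich.
#' @export
aug_fit_svy <- function(data, init = NULL, control = list(),
                        lonely_psu = c("error", "center")) {
  fit <- aug_fit(data, weighted = TRUE, init = init, control = control)
  sw <- binder_sandwich(fit, lonely_psu = lonely_psu)
  fit$cov_model <- fit$cov
  fit$cov <- sw$cov
  fit$cov_psi <- sw$cov_psi
  fit$se_beta <- if (fit$p) stats::setNames(sw$se_beta, names(fit$beta)) else
    fit$se_beta
  fit$variance <- "binder"
  fit
}
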