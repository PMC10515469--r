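#' Standard no-auxiliary comparator (grouped-time cloglog)
#'
#' The benchmark estimator that ignores the auxiliary reports: among
#' subjects with an observed gold standard, regress the binary status
#' \eqn{\Delta_i} on the covariates with a complementary log-log link
#' (Prentice-Gloeckler grouped-time proportional hazards).  Under the
#' proportional hazards model,
#' \eqn{P(\Delta_i = 1 \mid x) = 1 - \exp\{-e^{\gamma_{V_i} + x'\beta}\}}
#' with \eqn{\gamma_v = \log\{-\log S(\tau_v)\}}, so with a common
#' assessment visit a single intercept suffices; with varying assessment
#' visits an intercept per distinct visit index is used.
#'
#' @param data An [aug_data()] object; subjects with a missing gold
#'   standard are dropped.
#' @param weighted Fit with the sampling weights?
#' @param design_variance With `weighted = TRUE`, compute the design-based
#'   between-PSU sandwich variance instead of the model-based one?
#' @param lonely_psu Passed to the PSU variance (see [binder_sandwich()]).
#' @return A list of class `"cloglog_fit"` with `beta`, `se_beta`, `cov`
#'   (covariance of `beta`), `gamma` (visit intercepts), `converged`, `n`.
#' @export
cloglog_fit <- function(data, weighted = FALSE, design_variance = weighted,
                        lonely_psu = c("error", "center")) {
  stopifnot(inherits(data, "aug_data"))
  keep <- data$m_flag == 0L
  if (!any(keep)) stop("no subjects with an observed gold standard")
  y <- data$delta[keep]
  x <- data$x[keep, , drop = FALSE]
  v <- data$v_index[keep]
  w <- data$weight[keep]
  p <- ncol(x)

  common_v <- length(unique(v)) == 1L
  mm <- if (common_v) cbind(`(Intercept)` = 1, x) else {
    vis <- stats::model.matrix(~ 0 + factor(v))
    colnames(vis) <- paste0("visit", sort(unique(v)))
    cbind(vis, x)
  }
  fam <- if (weighted) stats::quasibinomial("cloglog") else
    stats::binomial("cloglog")
  ## mustart independent of the sampling weights: glm.fit's default start
  ## reads prior weights as binomial denominators, which can send the
  ## cloglog IRLS off to divergence with large survey weights
  fit <- suppressWarnings(
    stats::glm.fit(mm, y, weights = w, family = fam,
                   mustart = (y + 0.5) / 2,
                   control = stats::glm.control(maxit = 100)))
  cf <- fit$coefficients
  bidx <- if (p) (length(cf) - p + 1L):length(cf) else integer(0)

  ## expected information X'WX with the IRLS weights w (dmu/deta)^2 / V(mu)
  mu <- pmin(pmax(fit$fitted.values, 1e-12), 1 - 1e-12)
  eta <- fit$linear.predictors
  dmu <- exp(eta - exp(eta))
  XtWX <- crossprod(mm * sqrt(w * dmu^2 / (mu * (1 - mu))))
  if (design_variance) {
    ## Binder sandwich: per-subject weighted score x between-PSU covariance
    U <- mm * (w * (y - mu) / (mu * (1 - mu)) * dmu)
    B <- psu_total_cov(U, data$stratum[keep], data$psu[keep], lonely_psu)
    Ainv <- solve(XtWX)
    cov_full <- Ainv %*% B %*% t(Ainv)
  } else {
    disp <- if (weighted) {
      sum((y - fit$fitted.values)^2 * fit$prior.weights /
            (fit$fitted.values * (1 - fit$fitted.values))) / fit$df.residual
    } else 1
    cov_full <- solve(XtWX) * disp
  }
  dimnames(cov_full) <- list(names(cf), names(cf))

  structure(list(
    beta = cf[bidx],
    gamma = cf[setdiff(seq_along(cf), bidx)],
    se_beta = sqrt(diag(cov_full))[bidx],
    cov = cov_full[bidx, bidx, drop = FALSE],
    cov_full = cov_full,
    converged = fit$converged, n = sum(keep), weighted = weighted
  ), class = "cloglog_fit")
}

#' @export
print.cloglog_fit <- function(x, ...) {
  cat("Grouped-time cloglog fit (no auxiliary data), n =", x$n, "\n")
  tab <- cbind(estimate = x$beta, se = x$se_beta, hr = exp(x$beta))
  print(round(tab, 4))
  if (!x$converged) cat("  WARNING: not converged\n")
  invisible(x)
}
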