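## Numeric Jacobian of a vector-valued function: central differences with
## step h_k = step * (1 + |psi_k|).  J[i, j] = d fn_i / d psi_j.
num_jacobian <- function(fn, psi, step = 1e-5) {
  k <- length(psi)
  cols <- vector("list", k)
  for (j in seq_len(k)) {
    h <- step * (1 + abs(psi[j]))
    up <- psi; up[j] <- up[j] + h
    dn <- psi; dn[j] <- dn[j] - h
    cols[[j]] <- (fn(up) - fn(dn)) / (2 * h)
  }
  do.call(cbind, cols)
}

## Numeric Hessian: central differences of the analytic score, symmetrized.
num_hessian <- function(fn_score, psi, step = 1e-5) {
  H <- num_jacobian(fn_score, psi, step)
  (H + t(H)) / 2
}

default_init <- function(data) {
  p <- ncol(data$x)
  J <- data$grid$J
  obs <- data$m_flag == 0L
  phat <- if (any(obs)) {
    stats::weighted.mean(data$delta[obs] == 1L, data$weight[obs])
  } else 0.2
  phat <- min(max(phat, 0.01), 0.99)
  vbar <- max(mean(data$v_index), 1)
  a0 <- rep(log(-log(1 - phat) / vbar), J)
  list(beta = rep(0, p), a = a0)
}

#' Fit the augmented-likelihood proportional hazards model
#'
#' Maximizes the augmented log-likelihood by quasi-Newton (BFGS) on the
#' unconstrained working parameters `(beta, a)`, where the baseline survival
#' curve is parameterized through cumulative log hazards so that
#' \eqn{1 = S_1 > \dots > S_{J+1} > 0} holds throughout.  The covariance is
#' the inverse of the observed information (numeric Hessian of the analytic
#' score) on the working scale, mapped to the `(beta, S)` scale by the delta
#' method.  With `weighted = TRUE` the weighted log-likelihood
#' \eqn{\sum_i w_i l_i} is maximized; note the inverse-information
#' covariance is then not design-consistent — use [binder_sandwich()] for
#' design-based standard errors.
#'
#' @param data An [aug_data()] object.
#' @param weighted Maximize the weighted log-likelihood?
#' @param init Optional list with elements `beta` and either `a` or `s`
#'   giving starting values; defaults to `beta = 0` and equal baseline
#'   hazard increments matched to the observed gold-standard positivity.
#' @param control List of control settings: `maxit` (default 500), `reltol`
#'   (default 1e-12), `grad_tol` — the convergence criterion on
#'   `max |score| / n_eff` (default 1e-6), `hess_step` (default 1e-5).
#' @return An object of class `"aug_fit"` with components `beta`, `s`, `a`,
#'   `loglik`, `cov` (delta-method covariance of `(beta, S_2..S_{J+1})`),
#'   `cov_psi` (working-scale covariance), `se_beta`, `converged`, `n_iter`,
#'   `score_norm`, and bookkeeping fields.
#' @examples
#' set.seed(1)
#' cfg <- scenario_config(n = 400, beta = log(1.5), lambda_b = 0.17)
#' sim <- sim_cohort(cfg)
#' d <- aug_data(sim$subjects, sim$aux, sim$grid, misclass(0.8, 0.9))
#' fit <- aug_fit(d)
#' coef(fit)
#' @export
aug_fit <- function(data, weighted = FALSE, init = NULL, control = list()) {
  stopifnot(inherits(data, "aug_data"))
  ctrl <- utils::modifyList(
    list(maxit = 500L, reltol = 1e-12, grad_tol = 1e-6, hess_step = 1e-5),
    control)
  p <- ncol(data$x)
  J <- data$grid$J
  if (is.null(init)) init <- default_init(data)
  if (!is.null(init$s) && is.null(init$a)) init$a <- surv_to_ahaz(init$s)
  psi0 <- psi_pack(init$beta, init$a)
  if (length(psi0) != p + J) stop("'init' has the wrong dimension")

  ll0 <- ll_eval(data, init$beta, init$a, weighted = weighted)
  if (!is.finite(ll0)) {
    bad <- attr(ll0, "zero_likelihood_ids")
    stop("zero likelihood at the starting values for subject(s) ",
         paste(utils::head(bad, 5L), collapse = ", "),
         if (length(bad) > 5L) ", ..." else "",
         ": the observed data are impossible under the supplied ",
         "sensitivity/specificity")
  }

  negll <- function(psi) {
    u <- psi_unpack(psi, p, J)
    -ll_eval(data, u$beta, u$a, weighted = weighted)
  }
  negsc <- function(psi) {
    u <- psi_unpack(psi, p, J)
    -score_eval(data, u$beta, u$a, weighted = weighted)
  }
  opt <- stats::optim(psi0, negll, negsc, method = "BFGS",
                      control = list(maxit = ctrl$maxit,
                                     reltol = ctrl$reltol))
  psi <- opt$par
  u <- psi_unpack(psi, p, J)
  sc <- -negsc(psi)
  score_norm <- sqrt(sum(sc^2))
  n_eff <- if (weighted) sum(data$weight) else length(data$id)
  converged <- opt$convergence == 0L && max(abs(sc)) / n_eff < ctrl$grad_tol

  H <- num_hessian(function(q) -negsc(q), psi, step = ctrl$hess_step)
  cov_psi <- tryCatch(solve(-H), error = function(e) NULL)
  if (is.null(cov_psi) || any(!is.finite(cov_psi))) {
    warning("observed information is singular; covariance not available")
    cov_psi <- NULL
  }
  S <- ahaz_to_surv(u$a)
  jac <- psi_jacobian(u$a, p)
  cov_bs <- if (!is.null(cov_psi)) jac %*% cov_psi %*% t(jac) else NULL
  nm <- c(colnames(data$x), paste0("S", 1L + seq_len(J)))
  if (!is.null(cov_bs)) dimnames(cov_bs) <- list(nm, nm)

  res <- structure(list(
    beta = stats::setNames(u$beta, colnames(data$x)),
    s = S, a = u$a, loglik = -opt$value,
    cov = cov_bs, cov_psi = cov_psi,
    se_beta = if (!is.null(cov_bs) && p) sqrt(diag(cov_bs)[seq_len(p)]) else
      rep(NA_real_, p),
    converged = converged, n_iter = opt$counts[["function"]],
    score_norm = score_norm, weighted = weighted,
    n = length(data$id), p = p, grid = data$grid, mis = data$mis,
    data = data, call = match.call()
  ), class = "aug_fit")
  if (!converged)
    warning("augmented-likelihood fit did not converge (score norm ",
            format(score_norm, digits = 3), ")")
  res
}

## Jacobian of (beta, S_2..S_{J+1}) with respect to (beta, a).
psi_jacobian <- function(a, p) {
  J <- length(a)
  dS <- surv_jacobian(a)[-1L, , drop = FALSE]   # (J) x (J), rows S_2..S_{J+1}
  rbind(cbind(diag(p), matrix(0, p, J)),
        cbind(matrix(0, J, p), dS))
}

#' @export
coef.aug_fit <- function(object, ...) {
  c(object$beta,
    stats::setNames(object$s[-1L], paste0("S", 1L + seq_along(object$a))))
}

#' @export
vcov.aug_fit <- function(object, ...) object$cov

#' @export
logLik.aug_fit <- function(object, ...) {
  structure(object$loglik, df = object$p + length(object$a),
            class = "logLik")
}

#' @export
print.aug_fit <- function(x, ...) {
  cat("Augmented-likelihood proportional hazards fit",
      if (x$weighted) "(survey weighted)" else "", "\n")
  cat(sprintf("  n = %d, J = %d, Se = %.3f, Sp = %.3f, logLik = %.3f\n",
              x$n, x$grid$J, x$mis$se, x$mis$sp, x$loglik))
  if (x$p) {
    tab <- summary(x)$coefficients
    print(round(tab, 4))
  }
  cat("  baseline survival:", paste(sprintf("%.3f", x$s), collapse = " "),
      "\n")
  if (!x$converged) cat("  WARNING: not converged\n")
  invisible(x)
}

#' Summarize an augmented-likelihood fit
#'
#' @param object An `"aug_fit"` object.
#' @param conf_level Confidence level for Wald intervals (default 0.95).
#' @param ... Unused.
#' @return A list with a coefficient table (estimate, SE, z, Wald CI and
#'   hazard ratio per covariate) and the baseline survival estimates.
#' @export
summary.aug_fit <- function(object, conf_level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  b <- object$beta; se <- object$se_beta
  tab <- cbind(estimate = b, se = se, z = b / se,
               lower = b - z * se, upper = b + z * se,
               hr = exp(b))
  structure(list(coefficients = tab, s = object$s,
                 conf_level = conf_level, converged = object$converged),
            class = "summary.aug_fit")
}

#' @export
print.summary.aug_fit <- function(x, ...) {
  print(round(x$coefficients, 4))
  invisible(x)
}
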