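#' Fit a linear regression-calibration model
#'
#' Weighted least squares of the reference measure \eqn{X^{**}} (classical
#' error) on the error-prone exposure \eqn{X^*} and error-free covariates
#' \eqn{Z}, giving the calibration equation
#' \eqn{\hat X = \delta^{(0)} + \delta^{(1)} X^* + \delta^{(2)'} Z} used to
#' replace the unobserved true exposure in the outcome model.
#'
#' @param x2 Numeric vector: the reference measure on the calibration
#'   subset.
#' @param xstar Numeric vector: the error-prone exposure.
#' @param z Matrix (or NULL) of error-free covariates.
#' @param weights Optional sampling weights (default 1).
#' @return Object of class `"calib_model"`: `coef` (named
#'   `(Intercept), xstar, z...`), `resid_var`, `n`.
#' @export
fit_calibration <- function(x2, xstar, z = NULL, weights = NULL) {
  n <- length(x2)
  if (length(xstar) != n) stop("'x2' and 'xstar' lengths differ")
  if (!is.null(z)) {
    z <- as.matrix(z)
    if (nrow(z) != n) stop("'z' has the wrong number of rows")
  }
  if (is.null(weights)) weights <- rep(1, n)
  mm <- cbind(`(Intercept)` = 1, xstar = xstar, z)
  k <- ncol(mm)
  if (n <= k) stop("calibration subset smaller than the number of regressors")
  qrm <- qr(mm * sqrt(weights))
  if (qrm$rank < k) {
    bad <- colnames(mm)[qrm$pivot[(qrm$rank + 1L):k]]
    stop("calibration design is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  cf <- qr.coef(qrm, x2 * sqrt(weights))
  r <- x2 - drop(mm %*% cf)
  resid_var <- sum(weights * r^2) / sum(weights) * n / (n - k)
  structure(list(coef = cf, resid_var = resid_var, n = n,
                 terms = colnames(mm)),
            class = "calib_model")
}

#' @export
print.calib_model <- function(x, ...) {
  cat("Regression-calibration model (n =", x$n, ")\n")
  print(round(x$coef, 4))
  cat("residual variance:", format(x$resid_var, digits = 4), "\n")
  invisible(x)
}

#' Predict calibrated exposure values
#'
#' Plug-in prediction \eqn{\hat X = \delta^{(0)} + \delta^{(1)} X^* +
#' \delta^{(2)'} Z} from a fitted calibration model.
#'
#' @param model A [fit_calibration()] object.
#' @param xstar Error-prone exposure values.
#' @param z Matrix (or NULL) of error-free covariates, in the same column
#'   order used when fitting.
#' @return Numeric vector of calibrated exposures.
#' @export
predict_xhat <- function(model, xstar, z = NULL) {
  stopifnot(inherits(model, "calib_model"))
  if (any(is.na(xstar))) stop("missing values in 'xstar'")
  mm <- cbind(1, xstar = xstar, z)
  if (ncol(mm) != length(model$coef))
    stop("covariate dimension does not match the calibration model")
  drop(mm %*% model$coef)
}

#' Estimate auxiliary sensitivity and specificity by cross-tabulation
#'
#' Estimates Se = P(self-report positive | reference positive) and
#' Sp = P(self-report negative | reference negative) as (weighted)
#' proportions from the 2x2 table of a self-report indicator against a
#' concurrent reference-standard indicator.
#'
#' @param selfreport Binary vector of self-reported statuses.
#' @param reference Binary vector of reference-standard statuses.
#' @param weights Optional sampling weights.
#' @return A [misclass()] object with attributes `n_pos` and `n_neg`
#'   (margin sizes).
#' @export
estimate_se_sp <- function(selfreport, reference, weights = NULL) {
  n <- length(selfreport)
  if (length(reference) != n) stop("input lengths differ")
  if (!all(selfreport %in% 0:1) || !all(reference %in% 0:1))
    stop("inputs must be binary")
  if (is.null(weights)) weights <- rep(1, n)
  pos <- reference == 1
  neg <- reference == 0
  if (!any(pos) || !any(neg))
    stop("a reference margin is empty; cannot estimate Se and Sp")
  se <- stats::weighted.mean(selfreport[pos], weights[pos])
  sp <- stats::weighted.mean(1 - selfreport[neg], weights[neg])
  out <- misclass(max(se, 1e-6), max(sp, 1e-6))
  attr(out, "n_pos") <- sum(pos)
  attr(out, "n_neg") <- sum(neg)
  out
}

## Margin membership and responses for the internal Se/Sp estimate.
##
## "cumulative": the self-report indicator is "ever reported
## positive by the gold-standard visit", cross-tabulated against the gold
## standard among all subjects with an observed gold standard.  This is how
## a status question ("have you been diagnosed?") is compared to a
## concurrent reference standard; under a per-visit error model it yields
## somewhat higher apparent sensitivity and lower apparent specificity than
## the per-visit values, which is what an internal estimate of this kind
## can deliver.
##
## "concurrent" (default): uses the single report at the gold-standard visit among
## subjects who still have one (reporting stops at the first positive).
## Because reports are conditionally independent given true status, these
## proportions estimate the per-visit Se and Sp without bias, at the cost
## of a much smaller margin.
sesp_crosstab_frame <- function(subjects, aux,
                                method = c("concurrent", "cumulative")) {
  method <- match.arg(method)
  obs <- subjects$m_flag == 0L
  w <- if (is.null(subjects$weight)) rep(1, nrow(subjects)) else
    subjects$weight
  if (method == "cumulative") {
    v_of <- subjects$v_index[match(aux$id, subjects$id)]
    pos <- aux[aux$result == 1L & aux$visit_index <= v_of, ]
    self <- as.integer(subjects$id %in% pos$id)
    return(data.frame(id = subjects$id[obs], self = self[obs],
                      ref = subjects$delta[obs], weight = w[obs]))
  }
  at_gs <- aux[aux$visit_index == subjects$v_index[match(aux$id, subjects$id)], ]
  idx <- match(subjects$id, at_gs$id)
  has <- obs & !is.na(idx)
  data.frame(id = subjects$id[has],
             self = at_gs$result[idx[has]],
             ref = subjects$delta[has],
             weight = w[has])
}

#' Regression-calibration analysis pipeline
#'
#' Full multi-stage analysis for an error-prone exposure: (1) optionally
#' estimate the auxiliary sensitivity/specificity internally by
#' cross-tabulating the report at the gold-standard visit against the gold
#' standard; (2) fit the (weighted) calibration model on the calibration
#' subset; (3) substitute the calibrated exposure in the outcome model and
#' fit either the augmented-likelihood estimator or the no-auxiliary
#' cloglog comparator; (4) compute the stacked estimating-equation sandwich
#' variance that propagates the uncertainty of all stages through the
#' survey design (see [stacked_sandwich()]).
#'
#' @param subjects Subject table as for [aug_data()], with the error-prone
#'   exposure in column `xstar_col` and error-free covariates in `z_cols`.
#' @param aux Auxiliary report table.
#' @param grid A [visit_grid()].
#' @param calib Calibration-subset table with columns `id` and `xstar2`.
#' @param xstar_col,z_cols Column names of the error-prone exposure and the
#'   error-free covariates.
#' @param mis A [misclass()] object of known Se/Sp, or `NULL` to estimate
#'   them internally (their uncertainty then enters the stacked variance).
#' @param sesp_method How the internal cross-tab is formed:
#'   `"concurrent"` (default) uses the single report made at the
#'   gold-standard visit, which estimates the per-visit error rates
#'   without bias; `"cumulative"` compares the
#'   ever-reported-positive-by-the-gold-visit indicator to the gold
#'   standard, which mirrors how a status question is validated against a
#'   concurrent reference standard but over-states per-visit sensitivity
#'   under the per-visit error model.
#' @param method `"aug"` (proposed) or `"cloglog"` (no-auxiliary
#'   comparator).
#' @param weighted Use sampling weights throughout?
#' @param variance Compute the stacked sandwich variance? (Skipping it is
#'   useful inside resampling loops that only need point estimates.)
#' @param lonely_psu Passed to the design-based variance.
#' @return A list of class `"rc_fit"`: the outcome `fit`, `calib_model`,
#'   `mis` (used Se/Sp), `stacked` (the [stacked_sandwich()] result),
#'   `se_beta` (stacked SEs for the outcome-model coefficients of
#'   interest), and bookkeeping.
#' @export
rc_fit <- function(subjects, aux, grid, calib, xstar_col = "xstar",
                   z_cols = NULL, mis = NULL,
                   method = c("aug", "cloglog"), weighted = TRUE,
                   sesp_method = c("concurrent", "cumulative"),
                   variance = TRUE,
                   lonely_psu = c("error", "center")) {
  method <- match.arg(method)
  sesp_method <- match.arg(sesp_method)
  subjects <- as.data.frame(subjects)
  w_all <- if (is.null(subjects$weight)) rep(1, nrow(subjects)) else
    subjects$weight

  estimate_mis <- is.null(mis)
  if (estimate_mis) {
    ct <- sesp_crosstab_frame(subjects, aux, sesp_method)
    mis <- estimate_se_sp(ct$self, ct$ref, ct$weight)
  }

  crow <- match(calib$id, subjects$id)
  if (any(is.na(crow))) stop("calibration rows reference unknown ids")
  zmat <- if (length(z_cols)) as.matrix(subjects[, z_cols, drop = FALSE]) else
    NULL
  cal <- fit_calibration(calib$xstar2, subjects[[xstar_col]][crow],
                         if (is.null(zmat)) NULL else
                           zmat[crow, , drop = FALSE],
                         weights = if (weighted) w_all[crow] else NULL)
  xhat <- predict_xhat(cal, subjects[[xstar_col]], zmat)

  subj2 <- subjects
  subj2$xhat <- xhat
  covars <- c("xhat", z_cols)
  if (method == "aug") {
    d <- aug_data(subj2, aux, grid, mis, covariates = covars)
    fit <- if (weighted) aug_fit_svy(d, lonely_psu = lonely_psu) else
      aug_fit(d)
  } else {
    d <- aug_data(subj2, NULL, grid, mis, covariates = covars)
    fit <- cloglog_fit(d, weighted = weighted, design_variance = weighted,
                       lonely_psu = lonely_psu)
  }

  stk <- if (!variance) NULL else
    stacked_sandwich(subjects = subj2, aux = aux, grid = grid,
                          calib = calib, xstar_col = xstar_col,
                          z_cols = z_cols, cal = cal, mis = mis,
                          include_sesp = estimate_mis && method == "aug",
                          sesp_method = sesp_method,
                          fit = fit, method = method, weighted = weighted,
                          lonely_psu = lonely_psu)

  structure(list(fit = fit, calib_model = cal, mis = mis, stacked = stk,
                 se_beta = if (is.null(stk)) fit$se_beta else stk$se_beta,
                 method = method,
                 weighted = weighted, covariates = covars),
            class = "rc_fit")
}

#' Stacked estimating-equation sandwich variance
#'
#' Treats the multi-stage estimator as one M-estimator in the stacked
#' parameter \eqn{\phi = (\delta, Se, Sp, \beta, a)} (components present as
#' applicable) with per-subject estimating functions: weighted least-squares
#' normal equations for the calibration stage, weighted binomial-proportion
#' equations on the reference-positive / reference-negative margins for Se
#' and Sp, and the outcome-model score.  The variance is
#' \eqn{A^{-1} B A^{-1}} with \eqn{A} the numeric Jacobian of the stacked
#' weighted estimating-equation total and \eqn{B} the design-based
#' between-PSU covariance of the stacked per-subject contributions.
#'
#' This is normally called through [rc_fit()]; the arguments mirror the
#' pieces assembled there.
#'
#' @param subjects Subject table including the `xhat` working column.
#' @param aux Auxiliary table.
#' @param grid A [visit_grid()].
#' @param calib Calibration subset (`id`, `xstar2`).
#' @param xstar_col,z_cols Covariate column names.
#' @param cal Fitted [fit_calibration()] model.
#' @param mis The Se/Sp used in the outcome model.
#' @param include_sesp Stack the Se/Sp estimating equations?
#' @param sesp_method Cross-tab construction for the Se/Sp stage (see
#'   [rc_fit()]).
#' @param fit The outcome-model fit (`"aug_fit"` or `"cloglog_fit"`).
#' @param method `"aug"` or `"cloglog"`.
#' @param weighted Use sampling weights?
#' @param lonely_psu Lone-PSU handling.
#' @return List with `cov` (outcome-coefficient block, delta scale for the
#'   augmented fit), `se_beta`, `cov_full` (full stacked covariance),
#'   `par_names`.
#' @export
stacked_sandwich <- function(subjects, aux, grid, calib, xstar_col, z_cols,
                             cal, mis, include_sesp, fit,
                             sesp_method = c("concurrent", "cumulative"),
                             method = c("aug", "cloglog"), weighted = TRUE,
                             lonely_psu = c("error", "center")) {
  method <- match.arg(method)
  sesp_method <- match.arg(sesp_method)
  n <- nrow(subjects)
  w <- if (weighted && !is.null(subjects$weight)) subjects$weight else
    rep(1, n)
  zmat <- if (length(z_cols)) as.matrix(subjects[, z_cols, drop = FALSE]) else
    NULL
  xstar <- subjects[[xstar_col]]
  mm_cal <- cbind(1, xstar, zmat)           # calibration design, all subjects
  k_cal <- ncol(mm_cal)
  in_cal <- subjects$id %in% calib$id
  x2 <- rep(NA_real_, n)
  x2[match(calib$id, subjects$id)] <- calib$xstar2

  ct <- if (include_sesp) sesp_crosstab_frame(subjects, aux, sesp_method) else
    NULL
  margin_pos <- margin_neg <- rep(FALSE, n)
  self_at_gs <- rep(NA_integer_, n)
  if (include_sesp) {
    row_ct <- match(ct$id, subjects$id)
    margin_pos[row_ct[ct$ref == 1]] <- TRUE
    margin_neg[row_ct[ct$ref == 0]] <- TRUE
    self_at_gs[row_ct] <- ct$self
  }

  ## outcome-model parameter block
  if (method == "aug") {
    psi_out <- psi_pack(fit$beta, fit$a)
    k_out <- length(psi_out)
  } else {
    psi_out <- c(fit$gamma, fit$beta)
    k_out <- length(psi_out)
  }
  phi_hat <- c(cal$coef,
               if (include_sesp) c(se = mis$se, sp = mis$sp),
               psi_out)
  idx_cal <- seq_len(k_cal)
  idx_sesp <- if (include_sesp) k_cal + 1:2 else integer(0)
  idx_out <- (k_cal + length(idx_sesp)) + seq_len(k_out)

  ## per-subject stacked estimating-function matrix at parameter phi
  ee_matrix <- function(phi) {
    delta <- phi[idx_cal]
    se_sp <- if (include_sesp) phi[idx_sesp] else c(mis$se, mis$sp)
    pout <- phi[idx_out]
    G <- matrix(0, n, length(phi))
    ## calibration stage
    r <- x2 - drop(mm_cal %*% delta)
    r[!in_cal] <- 0
    G[, idx_cal] <- mm_cal * (w * r)
    ## Se / Sp stages
    if (include_sesp) {
      G[margin_pos, idx_sesp[1L]] <-
        w[margin_pos] * (self_at_gs[margin_pos] - se_sp[1L])
      G[margin_neg, idx_sesp[2L]] <-
        w[margin_neg] * ((1 - self_at_gs[margin_neg]) - se_sp[2L])
    }
    ## outcome stage with exposure and error rates implied by phi
    xhat <- drop(mm_cal %*% delta)
    mis_phi <- structure(list(se = min(max(se_sp[1L], 1e-8), 1),
                              sp = min(max(se_sp[2L], 1e-8), 1)),
                         class = "misclass")
    subj2 <- subjects
    subj2$xhat <- xhat
    if (method == "aug") {
      d <- aug_data(subj2, aux, grid, mis_phi,
                    covariates = c("xhat", z_cols))
      u <- psi_unpack(pout, length(fit$beta), length(fit$a))
      G[, idx_out] <- score_matrix(d, u$beta, u$a) * w
    } else {
      keep <- subjects$m_flag == 0L
      mm_out <- cbind(1, xhat, zmat)[keep, , drop = FALSE]
      eta <- drop(mm_out %*% pout)
      mu <- pmin(pmax(-expm1(-exp(eta)), 1e-12), 1 - 1e-12)
      dmu <- exp(eta - exp(eta))
      y <- subjects$delta[keep]
      G[keep, idx_out] <- mm_out *
        (w[keep] * (y - mu) / (mu * (1 - mu)) * dmu)
    }
    G
  }

  total_ee <- function(phi) colSums(ee_matrix(phi))
  A <- num_jacobian(total_ee, phi_hat)   # block triangular, not symmetric
  G0 <- ee_matrix(phi_hat)
  stratum <- if (is.null(subjects$stratum)) rep(1L, n) else subjects$stratum
  psu <- if (is.null(subjects$psu)) subjects$id else subjects$psu
  B <- psu_total_cov(G0, stratum, psu, lonely_psu)
  Ainv <- solve(A)
  cov_full <- Ainv %*% B %*% t(Ainv)
  cov_full <- (cov_full + t(cov_full)) / 2

  if (method == "aug") {
    jac <- psi_jacobian(fit$a, length(fit$beta))
    cov_out <- jac %*% cov_full[idx_out, idx_out, drop = FALSE] %*% t(jac)
    se_beta <- sqrt(pmax(diag(cov_out)[seq_along(fit$beta)], 0))
    names(se_beta) <- names(fit$beta)
  } else {
    cov_out <- cov_full[idx_out, idx_out, drop = FALSE]
    nb <- length(fit$beta)
    bsel <- (k_out - nb + 1L):k_out
    se_beta <- sqrt(pmax(diag(cov_out)[bsel], 0))
    names(se_beta) <- names(fit$beta)
  }
  list(cov = cov_out, se_beta = se_beta, cov_full = cov_full,
       par_names = c(paste0("delta", seq_len(k_cal) - 1L),
                     if (include_sesp) c("se", "sp"),
                     paste0("psi", seq_len(k_out))))
}
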