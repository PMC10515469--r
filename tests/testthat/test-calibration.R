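test_that("calibration model recovers identity and hand-computed cases", {
  set.seed(22)
  x <- stats::rnorm(50)
  z <- stats::rnorm(50)
  fit <- fit_calibration(x, x, z)
  expect_equal(unname(fit$coef), c(0, 1, 0), tolerance = 1e-10)
  expect_equal(fit$resid_var, 0, tolerance = 1e-12)
  # duplicated rows at half weight reproduce the original fit
  y2 <- x + stats::rnorm(50, 0, 0.3)
  f1 <- fit_calibration(y2, x, z)
  f2 <- fit_calibration(rep(y2, 2), rep(x, 2), c(z, z),
                        weights = rep(0.5, 100))
  expect_equal(f1$coef, f2$coef, tolerance = 1e-10)
  # hand-computed prediction
  m <- list(coef = c(0.05, 0.5, 0.003), resid_var = 0, n = 10,
            terms = c("(Intercept)", "xstar", "z"))
  class(m) <- "calib_model"
  expect_equal(predict_xhat(m, 2, matrix(40)), 0.05 + 1 + 0.12)
  # rank deficiency is reported with the offending column
  expect_error(fit_calibration(y2, x, cbind(z, z)), "collinear")
})

test_that("calibration coefficients match the generating-moment oracle", {
  # regression of X on (X*, Z1, Z2) computed analytically from the
  # mixture moments of the cohort-mimic generator
  set.seed(23)
  cfg <- scenario_config("hchs", n = 25000)
  sim <- sim_hchs_cohort(cfg)
  s <- sim$subjects
  # validation-style fit: the true exposure as reference measure
  fit <- fit_calibration(s$x_true, s$xstar, cbind(s$age, s$bmi))
  mom <- auglik:::hchs_cell_moments()
  p <- mom$cells$p
  mu <- cbind(mom$cells$mx, mom$cells$mage, mom$cells$mbmi)
  mbar <- colSums(p * mu)
  Sigma_tot <- mom$Sigma + t(mu) %*% (p * mu) - tcrossprod(mbar)
  al <- cfg$error_model$alpha
  # moments of (X*, Z1, Z2) and their covariance with X
  a_lin <- c(al[2], al[3], al[4])       # X* = a0 + a_lin'(X,Z1,Z2) + e
  v_star <- drop(t(a_lin) %*% Sigma_tot %*% a_lin) + cfg$error_model$sigma_e2
  cov_star_z <- drop(Sigma_tot %*% a_lin)[2:3]
  cov_star_x <- drop(Sigma_tot %*% a_lin)[1]
  V <- rbind(c(v_star, cov_star_z),
             cbind(cov_star_z, Sigma_tot[2:3, 2:3]))
  cv <- c(cov_star_x, Sigma_tot[1, 2:3])
  delta_oracle <- solve(V, cv)
  expect_equal(unname(fit$coef[-1]), unname(delta_oracle), tolerance = 0.05)
})

test_that("sensitivity and specificity come from the 2x2 margins", {
  m <- estimate_se_sp(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_equal(m$se, 1)
  expect_equal(m$sp, 1)
  ref <- rep(c(1, 0), c(100, 100))
  self <- c(rep(1, 61), rep(0, 39), rep(0, 98), rep(1, 2))
  m <- estimate_se_sp(self, ref)
  expect_equal(m$se, 0.61)
  expect_equal(m$sp, 0.98)
  # degenerate self-reports
  m0 <- estimate_se_sp(rep(0, 200), ref)
  expect_equal(m0$se, 0, tolerance = 1e-5)
  expect_equal(m0$sp, 1)
  expect_error(estimate_se_sp(c(0, 1), c(1, 1)), "margin is empty")
})

test_that("stacking inert stages reproduces the plain design sandwich", {
  set.seed(24)
  cfg <- scenario_config(n = 500, lambda_b = 0.17, mr = 0.2)
  sim <- sim_cohort(cfg)
  s <- sim$subjects
  s$xstar <- s$x                       # error-free exposure
  calib <- data.frame(id = s$id[1:200], xstar2 = s$x[1:200])
  rc <- rc_fit(s, sim$aux, sim$grid, calib, xstar_col = "xstar",
               z_cols = NULL, mis = misclass(0.8, 0.9), method = "aug",
               weighted = TRUE)
  plain <- binder_sandwich(aug_fit(aug_data(transform(s, xhat = x),
                                            sim$aux, sim$grid,
                                            misclass(0.8, 0.9),
                                            covariates = "xhat"),
                                   weighted = TRUE))
  expect_equal(rc$stacked$cov[1, 1], plain$cov[1, 1], tolerance = 1e-6)
  # stacked covariance is symmetric PSD
  ev <- eigen(rc$stacked$cov_full, symmetric = TRUE,
              only.values = TRUE)$values
  expect_true(all(ev > -1e-8))
})

test_that("stacked standard errors agree with a pipeline bootstrap", {
  set.seed(25)
  n <- 500
  cfg <- scenario_config(n = n, lambda_b = 0.17, mr = 0.2)
  sim <- sim_cohort(cfg)
  s <- sim$subjects
  # error-prone exposure with known truth and a calibration subset
  s$xstar <- 0.1 + 0.6 * s$x + stats::rnorm(n, 0, 0.5)
  cal_id <- sort(sample(s$id, 200))
  calib <- data.frame(id = cal_id,
                      xstar2 = s$x[match(cal_id, s$id)] +
                        stats::rnorm(200, 0, 0.1))
  rc <- rc_fit(s, sim$aux, sim$grid, calib, xstar_col = "xstar",
               z_cols = NULL, mis = NULL, method = "aug", weighted = TRUE)
  aux_by_id <- split(sim$aux, factor(sim$aux$id, levels = s$id))
  nv <- vapply(aux_by_id, nrow, integer(1))
  B <- 500
  boot <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    take <- sample(n, replace = TRUE)
    sb <- s[take, ]; sb$id <- seq_len(n)
    auxb <- do.call(rbind, aux_by_id[take])
    auxb$id <- rep(seq_len(n), nv[take])
    in_cal <- s$id[take] %in% cal_id
    calb <- data.frame(id = seq_len(n)[in_cal],
                       xstar2 = calib$xstar2[match(s$id[take][in_cal],
                                                   cal_id)])
    fitb <- try(suppressWarnings(
      rc_fit(sb, auxb, sim$grid, calb, xstar_col = "xstar", z_cols = NULL,
             mis = NULL, method = "aug", weighted = TRUE,
             variance = FALSE)), silent = TRUE)
    if (!inherits(fitb, "try-error")) boot[b] <- fitb$fit$beta[[1]]
  }
  boot_se <- stats::sd(boot, na.rm = TRUE)
  expect_lt(abs(rc$se_beta[[1]] - boot_se) / boot_se, 0.15)
})
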