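test_that("generators are seed-deterministic", {
  for (kind in c("srs", "survey", "hchs")) {
    cfg <- scenario_config(kind, n = if (kind == "hchs") 1500 else 300,
                           lambda_b = 0.08, mr = 0.2)
    gen <- switch(kind, srs = sim_cohort, survey = sim_survey_cohort,
                  hchs = sim_hchs_cohort)
    set.seed(42); a <- gen(cfg)
    set.seed(42); b <- gen(cfg)
    expect_identical(a, b)
  }
})

test_that("auxiliary corruption follows the error and stopping rules", {
  set.seed(26)
  grid <- visit_grid(0:4)
  t_event <- stats::rexp(300, 0.4)
  # perfect tests: reports equal true status, truncation at seroconversion
  aux <- corrupt_aux(t_event, grid, se = 1, sp = 1)
  d_true <- outer(t_event, grid$boundaries[-1], ">=") * 0 +
    outer(t_event, grid$boundaries[-1], "<=")
  for (k in seq_len(nrow(aux))) {
    expect_equal(aux$result[k], d_true[aux$id[k], aux$visit_index[k]])
  }
  # no subject reports anything after a positive
  by_id <- split(aux, aux$id)
  for (ai in by_id) {
    pos <- which(ai$result == 1L)
    if (length(pos)) expect_equal(pos, nrow(ai))
  }
  # false positive frequency among never-events ~ 1 - Sp
  set.seed(27)
  far <- corrupt_aux(rep(1e6, 20000), grid, se = 1, sp = 0.9)
  first <- far[!duplicated(far$id) & far$visit_index == 1L, ]
  phat <- mean(first$result)
  expect_lt(abs(phat - 0.1), 3 * sqrt(0.1 * 0.9 / nrow(first)))
})

test_that("missingness mechanisms hit the marginal rate", {
  set.seed(28)
  grid <- visit_grid(0:8)
  never <- rep(1e6, 5000)  # no events, Sp = 1: no truncation
  for (mech in c("independent", "monotone")) {
    aux <- corrupt_aux(never, grid, se = 1, sp = 1, missing_rate = 0.2,
                       mechanism = mech)
    frac <- nrow(aux) / (5000 * 8)
    expect_lt(abs(frac - 0.8), 3 * sqrt(0.2 * 0.8 / (5000 * 8)) + 0.01)
    if (mech == "monotone") {
      # observed visits form a prefix of the schedule
      by_id <- split(aux$visit_index, aux$id)
      expect_true(all(vapply(by_id, function(v)
        identical(v, seq_along(v)), logical(1))))
    }
  }
})

test_that("gold standard missingness and event discretization are correct", {
  set.seed(29)
  grid <- visit_grid(0:4)
  t_event <- stats::rexp(50000, 0.3)
  gs <- apply_gold_standard(t_event, grid, gs_visit = 4L, mr = 0.4)
  expect_equal(gs$v_index, rep(4L, 50000))
  expect_lt(abs(mean(gs$m_flag) - 0.4), 3 * sqrt(0.4 * 0.6 / 50000))
  obs <- gs$m_flag == 0L
  expect_equal(gs$delta[obs], as.integer(t_event[obs] <= 4))
  expect_true(all(is.na(gs$delta[!obs])))
  # exponential scaling: doubling the rate halves the median event time
  m1 <- median(stats::rexp(2e5, 0.2))
  m2 <- median(stats::rexp(2e5, 0.4))
  expect_equal(m1 / m2, 2, tolerance = 0.05)
})

test_that("baseline rates give the documented censoring fractions", {
  set.seed(30)
  cfg <- scenario_config(n = 100000, lambda_b = 0.023)
  sim <- sim_cohort(cfg)
  expect_equal(mean(sim$truth$t_event > 4), 0.9, tolerance = 0.005)
  # independence of event times and covariate when beta = 0
  cfg0 <- scenario_config(n = 20000, beta = 0, lambda_b = 0.17)
  sim0 <- sim_cohort(cfg0)
  hi <- sim0$subjects$x > median(sim0$subjects$x)
  ks <- stats::ks.test(sim0$truth$t_event[hi], sim0$truth$t_event[!hi])
  expect_gt(ks$p.value, 1e-4)
})

test_that("multistage sampling yields valid weights and target size", {
  set.seed(31)
  cfg <- scenario_config("survey", n = 1000, lambda_b = 0.17)
  sizes <- totals <- numeric(6)
  for (b in seq_along(sizes)) {
    sim <- sim_survey_cohort(cfg)
    sizes[b] <- nrow(sim$subjects)
    totals[b] <- sum(sim$subjects$weight)
  }
  expect_lt(abs(mean(sizes) - 1000) / 1000, 0.2)
  # Horvitz-Thompson total of a constant estimates the superpopulation size
  des <- cfg$design
  expected_pop <- des$n_strata * des$n_bg * des$mean_hh * 1.9
  expect_lt(abs(mean(totals) - expected_pop) / expected_pop, 0.05)
  # equal-probability design gives constant weights
  cfg_eq <- scenario_config("survey", n = 600, lambda_b = 0.17)
  cfg_eq$design$hh_frac <- rep(0.25, 4)
  cfg_eq$design$person_frac <- c(0.5, 0.5)
  sim_eq <- sim_survey_cohort(cfg_eq)
  expect_equal(length(unique(sim_eq$subjects$weight)), 1L)
})

test_that("cohort-mimic generator matches its documented error model", {
  set.seed(32)
  cfg <- scenario_config("hchs", n = 12987)
  expect_equal(cfg$error_model$calib_n, 450L)
  sim <- sim_hchs_cohort(cfg)
  s <- sim$subjects
  expect_equal(nrow(sim$calib), 450L)
  # censoring fraction at the year-4 gold standard is calibrated to 0.90
  expect_equal(mean(sim$truth$t_event > 4), 0.9, tolerance = 0.02)
  expect_lt(abs(mean(s$m_flag) - 0.29), 0.02)
  # reconstruct the error term from the latent truth
  al <- cfg$error_model$alpha
  e <- s$xstar - (al[1] + al[2] * s$x_true + al[3] * s$age + al[4] * s$bmi)
  expect_equal(stats::var(e), 0.389, tolerance = 0.02)
  eps <- sim$calib$xstar2 - s$x_true[match(sim$calib$id, s$id)]
  # n = 450 draws: allow ~3 Monte-Carlo SEs of a variance estimate
  expect_equal(stats::var(eps), 0.019, tolerance = 0.2)
})

test_that("naive error-prone fits are attenuated relative to calibrated ones", {
  set.seed(33)
  cfg <- scenario_config("hchs", n = 6000)
  sim <- sim_hchs_cohort(cfg)
  s <- sim$subjects
  mis <- misclass(cfg$se, cfg$sp)
  d_naive <- aug_data(transform(s, xv = xstar), sim$aux, sim$grid, mis,
                      covariates = c("xv", "z1", "z2"))
  f_naive <- suppressWarnings(aug_fit(d_naive, weighted = TRUE))
  cal <- fit_calibration(sim$calib$xstar2,
                         s$xstar[match(sim$calib$id, s$id)],
                         cbind(s$z1, s$z2)[match(sim$calib$id, s$id), ])
  s$xhat <- predict_xhat(cal, s$xstar, cbind(s$z1, s$z2))
  d_cal <- aug_data(s, sim$aux, sim$grid, mis,
                    covariates = c("xhat", "z1", "z2"))
  f_cal <- suppressWarnings(aug_fit(d_cal, weighted = TRUE))
  expect_lt(abs(f_naive$beta[[1]]), abs(f_cal$beta[[1]]))
})
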