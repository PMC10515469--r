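test_that("subject contributions match hand-evaluated branch sums", {
  grid <- visit_grid(0:2)
  mis <- misclass(0.8, 0.9)
  s <- c(1, .6, .2)
  # validated negative at visit 1 with a positive report at visit 2:
  # log(Se * theta_2 + (1 - Sp) * theta_3) = log(.8 * .4 + .1 * .2)
  d <- aug_data(one_subject(x = 0, v = 1L, delta = 0L),
                data.frame(id = 1, visit_index = 2, result = 1), grid, mis)
  expect_equal(aug_loglik(d, 0, s), log(0.34))
  # missing gold standard, no reports: total probability is one
  d0 <- aug_data(one_subject(m = 1L), NULL, grid, mis)
  for (rep in 1:5) {
    expect_equal(aug_loglik(d0, stats::rnorm(1), random_surv(2)), 0)
  }
  # perfect tests reduce to the exact interval probability
  dp <- aug_data(one_subject(x = 0.5, v = 2L, delta = 1L),
                 data.frame(id = 1, visit_index = 1:2, result = c(0, 1)),
                 grid, misclass(1, 1))
  b <- 0.3
  sv <- c(1, .7, .3)
  eta <- exp(0.5 * b)
  expect_equal(aug_loglik(dp, b, sv), log(sv[2]^eta - sv[3]^eta))
})

test_that("interval probabilities are normalized and branches partition", {
  set.seed(4)
  grid <- visit_grid(0:4)
  mis <- misclass(0.8, 0.9)
  for (rep in 1:5) {
    beta <- stats::rnorm(1)
    s <- random_surv(4)
    x <- stats::rnorm(1)
    eta <- exp(x * beta)
    theta <- drop(r_matrix(4) %*% s^eta)
    expect_equal(sum(theta), 1, tolerance = 1e-12)
    # validated-positive + validated-negative likelihoods = missing-branch
    aux <- data.frame(id = 1, visit_index = c(1, 3), result = c(0, 0))
    v <- sample(1:4, 1)
    lp <- aug_loglik(aug_data(one_subject(x = x, v = v, delta = 1L), aux,
                              grid, mis), beta, s)
    ln <- aug_loglik(aug_data(one_subject(x = x, v = v, delta = 0L), aux,
                              grid, mis), beta, s)
    lm <- aug_loglik(aug_data(one_subject(x = x, v = v, m = 1L), aux,
                              grid, mis), beta, s)
    expect_equal(exp(lp) + exp(ln), exp(lm), tolerance = 1e-12)
  }
})

test_that("total likelihood matches an independent brute-force enumeration", {
  set.seed(5)
  for (rep in 1:4) {
    cohort <- tiny_cohort(n = 15L, J = 3L)
    d <- aug_data(cohort$subjects, cohort$aux, cohort$grid, cohort$mis)
    beta <- stats::rnorm(1, 0, 0.5)
    s <- random_surv(3)
    expect_equal(aug_loglik(d, beta, s),
                 brute_loglik(cohort$subjects, cohort$aux, cohort$grid,
                              0.8, 0.9, beta, s),
                 tolerance = 1e-10)
  }
})

test_that("weights scale the likelihood as replication would", {
  set.seed(6)
  cohort <- tiny_cohort(n = 8L)
  subj <- cohort$subjects
  subj$weight <- 2
  d1 <- aug_data(cohort$subjects, cohort$aux, cohort$grid, cohort$mis)
  d2 <- aug_data(subj, cohort$aux, cohort$grid, cohort$mis)
  beta <- 0.2; s <- random_surv(3)
  expect_equal(aug_loglik(d2, beta, s, weighted = TRUE),
               2 * aug_loglik(d1, beta, s))
  expect_equal(aug_loglik(d1, beta, s, weighted = TRUE),
               aug_loglik(d1, beta, s))
  # per-subject contributions sum to the total
  expect_equal(sum(aug_loglik(d1, beta, s, by_subject = TRUE)),
               aug_loglik(d1, beta, s))
})

test_that("analytic score matches central finite differences", {
  set.seed(7)
  for (rep in 1:3) {
    cohort <- tiny_cohort(n = 20L, J = 3L)
    d <- aug_data(cohort$subjects, cohort$aux, cohort$grid, cohort$mis)
    beta <- stats::rnorm(1, 0, 0.4)
    a <- stats::rnorm(3, -1, 0.5)
    s <- ahaz_to_surv(a)
    sc <- unname(aug_score(d, beta, s))
    psi <- c(beta, a)
    fd <- vapply(seq_along(psi), function(j) {
      h <- 1e-5 * (1 + abs(psi[j]))
      up <- psi; up[j] <- up[j] + h
      dn <- psi; dn[j] <- dn[j] - h
      (aug_loglik(d, up[1], ahaz_to_surv(up[-1])) -
         aug_loglik(d, dn[1], ahaz_to_surv(dn[-1]))) / (2 * h)
    }, numeric(1))
    expect_equal(sc, fd, tolerance = 1e-5)
  }
  # flat-likelihood subject: zero score
  d0 <- aug_data(one_subject(m = 1L), NULL, visit_grid(0:2), misclass(.8, .9))
  expect_equal(unname(aug_score(d0, 0.3, c(1, .6, .2))), rep(0, 3),
               tolerance = 1e-12)
})

test_that("structurally impossible histories yield -Inf with diagnostics", {
  grid <- visit_grid(0:2)
  # perfect tests, positive report at visit 1 but validated negative at 2
  d <- aug_data(one_subject(v = 2L, delta = 0L),
                data.frame(id = 1, visit_index = 1, result = 1),
                grid, misclass(1, 1))
  ll <- aug_loglik(d, 0, c(1, .6, .2))
  expect_identical(as.numeric(ll), -Inf)
  expect_equal(attr(ll, "zero_likelihood_ids"), 1L)
  expect_error(aug_fit(d), "impossible")
})
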