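#' Simulation scenario configuration
#'
#' Collects everything that defines one synthetic-cohort scenario: the
#' covariate law, true log hazard ratios, baseline exponential rate, visit
#' grid, auxiliary-outcome error rates and missingness, gold-standard visit
#' and missingness rate, and (for the survey and cohort-mimic scenarios) the
#' multistage sampling design and covariate error model.
#'
#' The defaults reproduce the simple-random-sample study conditions: a
#' single Gamma(0.2, 1) covariate, `beta = log(1.5)`, four annual auxiliary
#' visits, a gold standard at year 4, and auxiliary sensitivity 0.80 /
#' specificity 0.90.  Baseline rates `lambda_b` of 0.023, 0.08 and 0.17
#' give latent censoring fractions at year 4 of about 0.9, 0.7 and 0.5.
#'
#' @param kind `"srs"` (simple random sample), `"survey"` (stratified
#'   three-stage sample) or `"hchs"` (large multi-ethnic cohort mimic with
#'   covariate measurement error).
#' @param n Target sample size (exact for `"srs"`; approximate for the
#'   multistage designs, where it scales the superpopulation).
#' @param beta True log hazard ratio(s).
#' @param lambda_b Baseline exponential rate; event times are
#'   `Exponential(lambda_b * exp(x'beta))`.  For `"hchs"` this is solved
#'   numerically so the latent censoring fraction at the gold-standard
#'   visit equals `target_cr`.
#' @param covariate List describing the covariate law for `"srs"`:
#'   `list(dist = "gamma", shape, scale)` or `list(dist = "normal", mean,
#'   var)`.
#' @param grid A [visit_grid()]; defaults to annual visits `0:4` (`0:8` for
#'   `"hchs"`).
#' @param aux_visits Integer indices (into `1..J`) of the scheduled
#'   auxiliary visits; defaults to all.
#' @param se,sp True sensitivity and specificity used to corrupt the
#'   auxiliary reports.
#' @param mr Missingness rate of the gold-standard indicator.
#' @param aux_missing_rate Marginal per-visit missingness probability for
#'   auxiliary reports.
#' @param aux_missing_mechanism `"independent"` (each scheduled report is
#'   deleted independently) or `"monotone"` (loss to follow-up: reports
#'   stop for good at a geometric dropout visit whose rate is solved so
#'   the marginal per-visit missingness equals `aux_missing_rate`).  The
#'   cohort-mimic scenario defaults to `"monotone"`, as attrition is the
#'   dominant mechanism in annual telephone follow-up; the others to
#'   `"independent"`.
#' @param gs_visit Visit index of the gold-standard assessment.
#' @param design For `"survey"`/`"hchs"`: overrides for the multistage
#'   design (see Details in the package vignette); `NULL` uses defaults.
#' @param error_model For `"hchs"`: list with `alpha` (length 4:
#'   intercept, true exposure, age, BMI), `sigma_e2`, `sigma_eps2`,
#'   `calib_n`; `NULL` uses the documented defaults.
#' @param target_cr For `"hchs"`: latent censoring fraction at the
#'   gold-standard visit to which `lambda_b` is calibrated (default 0.90).
#' @return An object of class `"scenario_config"` (a validated list).
#' @export
scenario_config <- function(kind = c("srs", "survey", "hchs"),
                            n = 1000,
                            beta = log(1.5),
                            lambda_b = 0.023,
                            covariate = list(dist = "gamma", shape = 0.2,
                                             scale = 1),
                            grid = NULL,
                            aux_visits = NULL,
                            se = 0.8, sp = 0.9,
                            mr = 0,
                            aux_missing_rate = 0,
                            aux_missing_mechanism = NULL,
                            gs_visit = NULL,
                            design = NULL,
                            error_model = NULL,
                            target_cr = 0.9) {
  kind <- match.arg(kind)
  if (is.null(grid)) grid <- visit_grid(0:if (kind == "hchs") 8 else 4)
  stopifnot(inherits(grid, "visit_grid"))
  if (is.null(aux_visits)) aux_visits <- seq_len(grid$J)
  if (is.null(gs_visit)) gs_visit <- if (kind == "hchs") 4L else grid$J
  gs_visit <- as.integer(gs_visit)
  for (r in c(mr, aux_missing_rate))
    if (r < 0 || r > 1) stop("rates must lie in [0, 1]")
  if (lambda_b <= 0) stop("'lambda_b' must be positive")
  if (gs_visit < 1L || gs_visit > grid$J) stop("'gs_visit' out of range")
  if (any(aux_visits < 1L | aux_visits > grid$J))
    stop("'aux_visits' out of range")
  if (kind == "hchs") {
    mr <- if (missing(mr)) 0.29 else mr
    aux_missing_rate <- if (missing(aux_missing_rate)) 0.20 else
      aux_missing_rate
    if (is.null(aux_missing_mechanism)) aux_missing_mechanism <- "monotone" 
    if (missing(se)) se <- 0.61
    if (missing(sp)) sp <- 0.98
    if (missing(beta)) beta <- c(log(1.5), log(0.7), log(1.3))
    if (is.null(error_model))
      error_model <- list(alpha = c(0.05, 0.50, 0.003, 0.0009),
                          sigma_e2 = 0.389, sigma_eps2 = 0.019,
                          calib_n = max(10L, round(450 * n / 12987)))
  }
  if (kind %in% c("survey", "hchs") && is.null(design))
    design <- default_survey_design(kind, n)
  if (is.null(aux_missing_mechanism)) aux_missing_mechanism <- "independent"
  aux_missing_mechanism <- match.arg(aux_missing_mechanism,
                                     c("independent", "monotone"))
  structure(list(kind = kind, n = n, beta = beta, lambda_b = lambda_b,
                 covariate = covariate, grid = grid,
                 aux_visits = sort(unique(as.integer(aux_visits))),
                 se = se, sp = sp, mr = mr,
                 aux_missing_rate = aux_missing_rate,
                 aux_missing_mechanism = aux_missing_mechanism,
                 gs_visit = gs_visit,
                 design = design, error_model = error_model,
                 target_cr = target_cr),
            class = "scenario_config")
}

## Multistage design defaults.  The structure mirrors a four-stratum area
## sample with 376 block groups (94 per stratum), scaled down about 10x in
## persons per block group relative to the ~200,000-person frame it
## emulates.  Sampling is 40% of block groups per stratum, a
## stratum-specific household fraction, then a person fraction that
## differs by an age-subgroup indicator, so weights vary across strata and
## persons.  `mean_hh` (households per block group) scales the
## superpopulation so the expected sample size is ~n.
default_survey_design <- function(kind, n) {
  n_bg <- 94L
  bg_sampled <- 38L
  hh_frac <- c(0.20, 0.30, 0.25, 0.35)
  person_frac <- c(0.35, 0.65)
  subgroup_p <- 0.4
  ef3 <- (1 - subgroup_p) * person_frac[1] + subgroup_p * person_frac[2]
  persons_hh <- 1.9
  mean_hh <- n / (bg_sampled * persons_hh * ef3 * sum(hh_frac))
  list(n_strata = 4L, n_bg = n_bg, bg_sampled = bg_sampled,
       mean_hh = mean_hh,
       hh_frac = hh_frac, person_frac = person_frac,
       subgroup_p = subgroup_p,
       shapes = c(0.25, 0.15, 0.30, 0.10),
       scales = c(1.25, 0.75, 1.50, 0.50),
       bg_perturb = 0.15)
}

#' Corrupt true event times into error-prone auxiliary reports
#'
#' For each scheduled visit \eqn{\tau_l}, the true status is
#' \eqn{d = 1\{T \le \tau_l\}}; the report is positive with probability `se`
#' when `d = 1` and with probability `1 - sp` when `d = 0`.  Each scheduled
#' report is independently deleted with probability `missing_rate`, and the
#' observed series is truncated after the first observed positive (reports
#' stop once a subject self-reports the event).
#'
#' @param t_event Numeric vector of true event times.
#' @param grid A [visit_grid()].
#' @param aux_visits Scheduled visit indices.
#' @param se,sp Sensitivity and specificity.
#' @param missing_rate Marginal per-visit missingness probability.
#' @param mechanism `"independent"` per-visit deletion, or `"monotone"`
#'   geometric loss to follow-up calibrated to the same marginal rate.
#' @return Data frame with columns `id`, `visit_index`, `result`.
#' @export
corrupt_aux <- function(t_event, grid, aux_visits = seq_len(grid$J),
                        se = 0.8, sp = 0.9, missing_rate = 0,
                        mechanism = c("independent", "monotone")) {
  mechanism <- match.arg(mechanism)
  n <- length(t_event)
  K <- length(aux_visits)
  tau <- grid$boundaries[aux_visits + 1L]
  if (mechanism == "monotone" && missing_rate > 0) {
    ## continuation probability 1 - q such that the average over the K
    ## scheduled visits of P(visit k observed) = (1-q)^k equals
    ## 1 - missing_rate
    q <- stats::uniroot(function(q) {
      mean((1 - q)^seq_len(K)) - (1 - missing_rate)
    }, c(1e-9, 1 - 1e-9), tol = 1e-12)$root
    completed <- stats::rgeom(n, q)    # visits completed before dropout
  }
  keep_rows <- vector("list", K)
  prior_pos <- rep(FALSE, n)
  for (k in seq_len(K)) {
    d <- t_event <= tau[k]
    y <- stats::rbinom(n, 1L, ifelse(d, se, 1 - sp))
    obs <- if (mechanism == "monotone" && missing_rate > 0)
      completed >= k else stats::runif(n) >= missing_rate
    take <- obs & !prior_pos
    keep_rows[[k]] <- data.frame(id = which(take),
                                 visit_index = aux_visits[k],
                                 result = y[take])
    prior_pos <- prior_pos | (take & y == 1L)
  }
  out <- do.call(rbind, keep_rows)
  out <- out[order(out$id, out$visit_index), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Observe the gold standard with missingness
#'
#' The gold-standard status is \eqn{\Delta_i = 1\{T_i \le \tau_{V}\}} at the
#' assessment visit `gs_visit`; it is set missing (`m_flag = 1`, `delta =
#' NA`) with probability `mr`, via independent Uniform(0,1) draws.
#'
#' @inheritParams corrupt_aux
#' @param gs_visit Gold-standard visit index.
#' @param mr Missingness rate.
#' @return Data frame with columns `v_index`, `delta`, `m_flag`.
#' @export
apply_gold_standard <- function(t_event, grid, gs_visit, mr = 0) {
  n <- length(t_event)
  delta <- as.integer(t_event <= grid$boundaries[gs_visit + 1L])
  m <- as.integer(stats::runif(n) < mr)
  delta[m == 1L] <- NA_integer_
  data.frame(v_index = rep(gs_visit, n), delta = delta, m_flag = m)
}

draw_covariate <- function(n, spec) {
  switch(spec$dist,
         gamma = stats::rgamma(n, shape = spec$shape, scale = spec$scale),
         normal = stats::rnorm(n, mean = spec$mean, sd = sqrt(spec$var)),
         stop("unknown covariate distribution '", spec$dist, "'"))
}

#' Simulate a simple-random-sample cohort
#'
#' Draws covariates, continuous exponential event times with rate
#' `lambda_b * exp(x'beta)`, auxiliary reports (via [corrupt_aux()]) and the
#' gold-standard observation (via [apply_gold_standard()]).
#'
#' @param cfg A [scenario_config()] with `kind = "srs"`.
#' @return List with `subjects` (analysis table), `aux` (auxiliary report
#'   table), `truth` (true event times and intervals) and `grid`.
#' @export
sim_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"), cfg$kind == "srs")
  n <- cfg$n
  x <- draw_covariate(n, cfg$covariate)
  t_event <- stats::rexp(n, rate = cfg$lambda_b * exp(x * cfg$beta[1L]))
  gs <- apply_gold_standard(t_event, cfg$grid, cfg$gs_visit, cfg$mr)
  aux <- corrupt_aux(t_event, cfg$grid, cfg$aux_visits, cfg$se, cfg$sp,
                     cfg$aux_missing_rate, cfg$aux_missing_mechanism)
  subjects <- data.frame(id = seq_len(n), x = x, gs, weight = 1)
  truth <- data.frame(id = seq_len(n), t_event = t_event,
                      interval = event_interval(t_event, cfg$grid))
  list(subjects = subjects, aux = aux, truth = truth, grid = cfg$grid)
}

## True event interval index on the grid (J + 1 when beyond the last visit).
event_interval <- function(t_event, grid) {
  findInterval(t_event, grid$boundaries, left.open = TRUE) + 1L -
    (t_event <= 0)
}

## Build one multistage superpopulation and draw one sample from it.
## Returns person-level rows with exact inclusion probabilities.
sample_survey_frame <- function(des) {
  frames <- list()
  bg_id0 <- 0L
  for (s in seq_len(des$n_strata)) {
    sampled_bg <- sample.int(des$n_bg, des$bg_sampled)
    for (b in sampled_bg) {
      n_hh <- stats::rpois(1L, des$mean_hh)
      take_hh <- which(stats::runif(n_hh) < des$hh_frac[s])
      if (!length(take_hh)) next
      hh_size <- sample(1:3, length(take_hh), replace = TRUE,
                        prob = c(0.3, 0.5, 0.2))
      m <- sum(hh_size)
      sub <- stats::rbinom(m, 1L, des$subgroup_p)
      pf <- des$person_frac[sub + 1L]
      take_p <- stats::runif(m) < pf
      if (!any(take_p)) next
      pi_i <- (des$bg_sampled / des$n_bg) * des$hh_frac[s] * pf[take_p]
      frames[[length(frames) + 1L]] <- data.frame(
        stratum = s, psu = bg_id0 + b, subgroup = sub[take_p],
        weight = 1 / pi_i)
    }
    bg_id0 <- bg_id0 + des$n_bg
  }
  out <- do.call(rbind, frames)
  if (is.null(out) || nrow(out) < 50L)
    stop("multistage sample came out degenerate; check the design settings")
  rownames(out) <- NULL
  out
}

#' Simulate a stratified three-stage survey cohort
#'
#' Builds a superpopulation of four geographic strata divided into block
#' groups and households, draws a three-stage sample (block groups within
#' strata, households within block groups, persons within households) with
#' known inclusion probabilities, and attaches stratum- and block-group-
#' specific covariates: for stratum \eqn{s} and block group \eqn{g}, the
#' covariate is Gamma (or Normal) with parameters
#' \eqn{(shape_s + \omega_{gs}, scale_s + \rho_{gs})}, where the block-group
#' perturbations are Uniform(\eqn{\pm 0.15\,shape_s}) and
#' Uniform(\eqn{\pm 0.15\,scale_s}).  Event times, auxiliary reports and the
#' gold standard are then generated as in [sim_cohort()].
#'
#' @param cfg A [scenario_config()] with `kind = "survey"`.
#' @return As [sim_cohort()], with `weight`, `stratum` and `psu` columns on
#'   `subjects`.
#' @export
sim_survey_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"), cfg$kind == "survey")
  des <- cfg$design
  frame <- sample_survey_frame(des)
  n <- nrow(frame)
  ## block-group perturbations for the sampled PSUs
  upsu <- unique(frame[c("stratum", "psu")])
  upsu$omega <- stats::runif(nrow(upsu), -des$bg_perturb, des$bg_perturb) *
    des$shapes[upsu$stratum]
  upsu$rho <- stats::runif(nrow(upsu), -des$bg_perturb, des$bg_perturb) *
    des$scales[upsu$stratum]
  idx <- match(frame$psu, upsu$psu)
  par1 <- des$shapes[frame$stratum] + upsu$omega[idx]
  par2 <- des$scales[frame$stratum] + upsu$rho[idx]
  x <- if (identical(cfg$covariate$dist, "normal")) {
    stats::rnorm(n, mean = par1, sd = sqrt(pmax(par2, 1e-8)))
  } else {
    stats::rgamma(n, shape = pmax(par1, 1e-8), scale = pmax(par2, 1e-8))
  }
  t_event <- stats::rexp(n, rate = cfg$lambda_b * exp(x * cfg$beta[1L]))
  gs <- apply_gold_standard(t_event, cfg$grid, cfg$gs_visit, cfg$mr)
  aux <- corrupt_aux(t_event, cfg$grid, cfg$aux_visits, cfg$se, cfg$sp,
                     cfg$aux_missing_rate, cfg$aux_missing_mechanism)
  subjects <- data.frame(id = seq_len(n), x = x, gs,
                         weight = frame$weight, stratum = frame$stratum,
                         psu = frame$psu)
  truth <- data.frame(id = seq_len(n), t_event = t_event,
                      interval = event_interval(t_event, cfg$grid))
  list(subjects = subjects, aux = aux, truth = truth, grid = cfg$grid)
}

## Synthetic demographic cells and dietary covariate moments for the
## cohort-mimic generator.  These means/covariances are synthetic
## stand-ins chosen to be realistic for a log-scale dietary exposure (X),
## age in years (Z1) and BMI (Z2); they are not estimated from any cohort.
hchs_cell_moments <- function() {
  sexes <- 1:2; bgs <- 1:4
  cells <- expand.grid(sex = sexes, bg = bgs)
  cells$p <- c(0.48, 0.52)[cells$sex] * c(0.30, 0.25, 0.25, 0.20)[cells$bg]
  cells$mx <- 1.70 + 0.05 * (cells$sex == 1) +
    c(-0.08, 0, 0.04, 0.08)[cells$bg]
  cells$mage <- 44 + 2 * (cells$sex == 2) + c(-3, 1, 2, -1)[cells$bg]
  cells$mbmi <- 29.5 + 0.8 * (cells$sex == 2) +
    c(0.5, -0.3, 0.6, -0.5)[cells$bg]
  sds <- c(0.387, 14, 5.3)
  R <- matrix(c(1, -0.10, 0.15,
                -0.10, 1, 0.20,
                0.15, 0.20, 1), 3, 3)
  list(cells = cells, Sigma = diag(sds) %*% R %*% diag(sds),
       ref_age = c(44, 14), ref_bmi = c(29.5, 5.3))
}

#' Simulate a cohort mimicking a large multistage health study
#'
#' Generates a stratified three-stage sample (as [sim_survey_cohort()])
#' whose persons carry three covariates — a log-scale dietary exposure
#' \eqn{X}, age \eqn{Z_1} and BMI \eqn{Z_2} — drawn per (sex, background)
#' cell from multivariate normal distributions with synthetic moments.  The
#' hazard uses \eqn{\beta = (\log 1.5, \log 0.7, \log 1.3)} on
#' \eqn{(X, z_1, z_2)} with \eqn{z_1, z_2} standardized age and BMI, and the
#' baseline rate is solved so the latent censoring fraction at the
#' gold-standard visit (year 4 of 8 annual visits) equals `target_cr`
#' (default 0.90).  The observed exposure is error-prone:
#' \eqn{X^* = \alpha_0 + \alpha_1 X + \alpha_2 Z_1 + \alpha_3 Z_2 + e} with
#' \eqn{e \sim N(0, \sigma_e^2)}; a random calibration subset carries a
#' second measure with classical error, \eqn{X^{**} = X + \epsilon},
#' \eqn{\epsilon \sim N(0, \sigma_\epsilon^2)}.
#'
#' @param cfg A [scenario_config()] with `kind = "hchs"`.
#' @return List with `subjects` (including `xstar`, `z1`, `z2`, design
#'   columns and the latent true `x_true`), `aux`, `calib` (columns `id`,
#'   `xstar2`), `truth`, `grid`, and the solved `lambda_b`.
#' @export
sim_hchs_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"), cfg$kind == "hchs")
  frame <- sample_survey_frame(cfg$design)
  n <- nrow(frame)
  mom <- hchs_cell_moments()
  cell <- sample.int(nrow(mom$cells), n, replace = TRUE,
                     prob = mom$cells$p)
  mu <- cbind(mom$cells$mx[cell], mom$cells$mage[cell],
              mom$cells$mbmi[cell])
  Zn <- matrix(stats::rnorm(3L * n), n, 3L) %*% chol(mom$Sigma)
  X <- mu[, 1L] + Zn[, 1L]
  age <- mu[, 2L] + Zn[, 2L]
  bmi <- mu[, 3L] + Zn[, 3L]
  z1 <- (age - mom$ref_age[1L]) / mom$ref_age[2L]
  z2 <- (bmi - mom$ref_bmi[1L]) / mom$ref_bmi[2L]
  beta <- cfg$beta
  lp <- X * beta[1L] + z1 * beta[2L] + z2 * beta[3L]
  tau_v <- cfg$grid$boundaries[cfg$gs_visit + 1L]
  lam <- stats::uniroot(function(l) {
    mean(exp(-l * tau_v * exp(lp))) - cfg$target_cr
  }, c(1e-8, 10), tol = 1e-10)$root
  t_event <- stats::rexp(n, rate = lam * exp(lp))
  gs <- apply_gold_standard(t_event, cfg$grid, cfg$gs_visit, cfg$mr)
  aux <- corrupt_aux(t_event, cfg$grid, cfg$aux_visits, cfg$se, cfg$sp,
                     cfg$aux_missing_rate, cfg$aux_missing_mechanism)
  em <- cfg$error_model
  xstar <- em$alpha[1L] + em$alpha[2L] * X + em$alpha[3L] * age +
    em$alpha[4L] * bmi + stats::rnorm(n, 0, sqrt(em$sigma_e2))
  calib_id <- sort(sample.int(n, em$calib_n))
  calib <- data.frame(id = calib_id,
                      xstar2 = X[calib_id] +
                        stats::rnorm(em$calib_n, 0, sqrt(em$sigma_eps2)))
  subjects <- data.frame(id = seq_len(n), xstar = xstar, z1 = z1, z2 = z2,
                         x_true = X, age = age, bmi = bmi, gs,
                         weight = frame$weight, stratum = frame$stratum,
                         psu = frame$psu)
  truth <- data.frame(id = seq_len(n), t_event = t_event,
                      interval = event_interval(t_event, cfg$grid))
  list(subjects = subjects, aux = aux, calib = calib, truth = truth,
       grid = cfg$grid, lambda_b = lam)
}
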