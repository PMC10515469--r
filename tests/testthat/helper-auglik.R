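# Shared fixtures, built in code.

# One-subject table in the analysis layout.
one_subject <- function(x = 0, v = 1L, delta = 0L, m = 0L, weight = 1) {
  data.frame(id = 1L, x = x, v_index = v,
             delta = if (m == 1L) NA_integer_ else delta,
             m_flag = m, weight = weight)
}

# Small random cohort for likelihood-level tests (no simulator dependence):
# draws event times, builds aux reports and gold standard by hand.
tiny_cohort <- function(n = 12L, J = 3L, se = 0.8, sp = 0.9,
                        lambda = 0.3, beta = 0.4, mr = 0.25) {
  grid <- visit_grid(0:J)
  x <- stats::rnorm(n, 0, 1)
  t_event <- stats::rexp(n, lambda * exp(beta * x))
  v <- sample(1:J, n, replace = TRUE)
  m <- stats::rbinom(n, 1L, mr)
  delta <- ifelse(m == 1L, NA_integer_,
                  as.integer(t_event <= grid$boundaries[v + 1L]))
  rows <- list()
  for (i in seq_len(n)) {
    for (l in seq_len(J)) {
      d <- t_event[i] <= grid$boundaries[l + 1L]
      y <- stats::rbinom(1L, 1L, if (d) se else 1 - sp)
      rows[[length(rows) + 1L]] <- data.frame(id = i, visit_index = l,
                                              result = y)
      if (y == 1L) break
    }
  }
  list(subjects = data.frame(id = seq_len(n), x = x, v_index = v,
                             delta = delta, m_flag = m, weight = 1),
       aux = do.call(rbind, rows), grid = grid,
       mis = misclass(se, sp))
}

# Independent brute-force likelihood: per-subject loops straight from the
# probability model, sharing no code with the package internals.
brute_loglik <- function(subjects, aux, grid, se, sp, beta, s) {
  J <- grid$J
  theta_of <- function(x) {
    eta <- exp(x * beta)
    svec <- c(s^eta, 0)
    svec[1:(J + 1)] - svec[2:(J + 2)]
  }
  total <- 0
  for (i in seq_len(nrow(subjects))) {
    rowi <- subjects[i, ]
    ai <- aux[aux$id == rowi$id, , drop = FALSE]
    th <- theta_of(rowi$x)
    jset <- if (rowi$m_flag == 1L) 1:(J + 1) else if (rowi$delta == 1L)
      seq_len(rowi$v_index) else (rowi$v_index + 1L):(J + 1L)
    prob <- 0
    for (j in jset) {
      cij <- 1
      if (nrow(ai)) for (k in seq_len(nrow(ai))) {
        l <- ai$visit_index[k]; y <- ai$result[k]
        cij <- cij * if (l >= j) {
          if (y == 1L) se else 1 - se
        } else {
          if (y == 0L) sp else 1 - sp
        }
      }
      prob <- prob + cij * th[j]
    }
    total <- total + log(prob)
  }
  total
}

# Random valid baseline survival vector of length J + 1.
random_surv <- function(J) {
  ahaz_to_surv(stats::rnorm(J, -1, 0.7))
}
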