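#' Misclassification parameters of the auxiliary outcome
#'
#' Sensitivity `se` is the probability that an auxiliary report is positive
#' given the event has already occurred at the report time; specificity `sp`
#' is the probability of a negative report given the event has not yet
#' occurred.  Both are treated as known constants in the likelihood; they may
#' come from external data or be estimated internally (see
#' [estimate_se_sp()]).
#'
#' @param se,sp Sensitivity and specificity, each in (0, 1].
#' @return An object of class `"misclass"`.
#' @examples
#' misclass(0.8, 0.9)
#' @export
misclass <- function(se, sp) {
  if (!is.numeric(se) || !is.numeric(sp) || length(se) != 1L || length(sp) != 1L)
    stop("'se' and 'sp' must be scalars")
  if (se <= 0 || se > 1 || sp <= 0 || sp > 1)
    stop("'se' and 'sp' must lie in (0, 1]")
  if (se + sp <= 1)
    warning("se + sp <= 1: auxiliary outcome is uninformative or ",
            "anti-informative; check the error rates")
  structure(list(se = se, sp = sp), class = "misclass")
}

#' @export
print.misclass <- function(x, ...) {
  cat(sprintf("Auxiliary misclassification: Se = %.3f, Sp = %.3f\n",
              x$se, x$sp))
  invisible(x)
}

#' Auxiliary-history probability row
#'
#' For one subject, computes the vector \eqn{C_{i\cdot}} of length `J + 1`
#' whose \eqn{j}th entry is the probability of the observed auxiliary history
#' given the event time falls in interval \eqn{j}.  A report at visit
#' \eqn{l \ge j} is made with the event present, contributing
#' \eqn{Se^y (1-Se)^{1-y}}; a report at visit \eqn{l \le j - 1} is made with
#' the event absent, contributing \eqn{Sp^{1-y} (1-Sp)^y}.  Reports are
#' conditionally independent given the event interval, so entries are the
#' product over observed visits; a subject with no auxiliary data gets a row
#' of ones.
#'
#' @param visits Integer vector of observed auxiliary visit indices (in
#'   `1..J`, strictly increasing).
#' @param results Binary vector of the same length: the reported statuses.
#' @param J Number of post-baseline visits.
#' @param mis A [misclass()] object.
#' @return Numeric vector of length `J + 1`.
#' @examples
#' c_row(integer(0), integer(0), 3, misclass(0.8, 0.9))  # all ones
#' c_row(1L, 0L, 2, misclass(0.8, 0.9))                  # (0.2, 0.9, 0.9)
#' @export
c_row <- function(visits, results, J, mis) {
  visits <- as.integer(visits)
  results <- as.integer(results)
  if (length(visits) != length(results))
    stop("'visits' and 'results' must have equal length")
  if (length(visits) == 0L) return(rep(1, J + 1L))
  if (any(visits < 1L | visits > J))
    stop("auxiliary visit indices must lie in 1..J")
  if (is.unsorted(visits, strictly = TRUE))
    stop("auxiliary visit indices must be strictly increasing")
  if (!all(results %in% c(0L, 1L)))
    stop("auxiliary results must be binary")
  out <- rep(1, J + 1L)
  j <- seq_len(J + 1L)
  for (k in seq_along(visits)) {
    l <- visits[k]; y <- results[k]
    pos <- if (y == 1L) mis$se else 1 - mis$se
    neg <- if (y == 0L) mis$sp else 1 - mis$sp
    out <- out * ifelse(l >= j, pos, neg)
  }
  out
}

## Vectorized C-matrix over all subjects: aux has columns row (subject row
## index), visit_index, result.
build_c_matrix <- function(n, aux_row, aux_visit, aux_result, J, mis) {
  C <- matrix(1, n, J + 1L)
  if (length(aux_row) == 0L) return(C)
  for (l in sort(unique(aux_visit))) {
    sel <- aux_visit == l
    i <- aux_row[sel]
    y <- aux_result[sel]
    pos <- ifelse(y == 1L, mis$se, 1 - mis$se)
    neg <- ifelse(y == 0L, mis$sp, 1 - mis$sp)
    jpos <- seq_len(l)                    # event interval j <= l: status positive
    C[i, jpos] <- C[i, jpos, drop = FALSE] * pos
    if (l < J + 1L) {
      jneg <- (l + 1L):(J + 1L)           # event interval j > l: status negative
      C[i, jneg] <- C[i, jneg, drop = FALSE] * neg
    }
  }
  C
}

#' Assemble an analysis data set
#'
#' Validates and packs the subject table, auxiliary-visit table, follow-up
#' grid and misclassification parameters into the internal structure used by
#' the likelihood machinery.  The per-subject auxiliary-history probabilities
#' (the C matrix) are precomputed here because they do not depend on the
#' model parameters.
#'
#' @param subjects Data frame with one row per subject: columns `id`,
#'   `v_index` (gold-standard visit index in `1..J`), `delta` (gold-standard
#'   status, `NA` when missing), `m_flag` (1 if `delta` is missing), the
#'   covariate columns named in `covariates`, and optionally `weight`
#'   (default 1), `stratum` and `psu` (defaults: one stratum, each subject
#'   its own PSU).
#' @param aux Data frame of auxiliary reports with columns `id`,
#'   `visit_index`, `result`; may be `NULL` or empty.
#' @param grid A [visit_grid()].
#' @param mis A [misclass()] object.
#' @param covariates Character vector of covariate column names in
#'   `subjects`; defaults to all columns starting with `"x"` that are not
#'   design columns.
#' @return An object of class `"aug_data"`.
#' @export
aug_data <- function(subjects, aux, grid, mis, covariates = NULL) {
  stopifnot(inherits(grid, "visit_grid"), inherits(mis, "misclass"))
  subjects <- as.data.frame(subjects)
  n <- nrow(subjects)
  if (n == 0L) stop("'subjects' is empty")
  if (is.null(subjects$id)) subjects$id <- seq_len(n)
  if (anyDuplicated(subjects$id)) stop("duplicated subject ids")
  if (is.null(covariates)) {
    covariates <- grep("^x", names(subjects), value = TRUE)
    covariates <- setdiff(covariates, c("id"))
  }
  J <- grid$J

  v_index <- as.integer(subjects$v_index)
  if (any(is.na(v_index)) || any(v_index < 1L | v_index > J))
    stop("'v_index' must lie in 1..J")
  m_flag <- as.integer(subjects$m_flag)
  if (!all(m_flag %in% c(0L, 1L))) stop("'m_flag' must be binary")
  delta <- subjects$delta
  if (is.null(delta)) delta <- rep(NA_integer_, n)
  delta <- as.integer(delta)
  if (any(m_flag == 1L & !is.na(delta)))
    stop("'delta' must be missing exactly when m_flag = 1")
  if (any(m_flag == 0L & is.na(delta)))
    stop("'delta' must be observed when m_flag = 0")
  if (!all(delta[m_flag == 0L] %in% c(0L, 1L)))
    stop("'delta' must be binary")

  weight <- if (is.null(subjects$weight)) rep(1, n) else as.numeric(subjects$weight)
  if (any(!is.finite(weight)) || any(weight <= 0))
    stop("weights must be positive and finite")
  stratum <- if (is.null(subjects$stratum)) rep(1L, n) else subjects$stratum
  psu <- if (is.null(subjects$psu)) subjects$id else subjects$psu

  x <- as.matrix(subjects[, covariates, drop = FALSE])
  storage.mode(x) <- "double"
  if (any(!is.finite(x))) stop("covariates must be finite")

  if (is.null(aux) || nrow(as.data.frame(aux)) == 0L) {
    aux <- data.frame(id = integer(0), visit_index = integer(0),
                      result = integer(0))
  }
  aux <- as.data.frame(aux)
  row_of <- match(aux$id, subjects$id)
  if (any(is.na(row_of))) stop("auxiliary rows reference unknown subject ids")
  visit <- as.integer(aux$visit_index)
  result <- as.integer(aux$result)
  if (length(visit) && (any(visit < 1L) || any(visit > J)))
    stop("auxiliary visit indices must lie in 1..J")
  if (!all(result %in% c(0L, 1L))) stop("auxiliary results must be binary")
  ## per-subject structural checks: increasing visits, positives terminal
  if (length(visit)) {
    ord <- order(row_of, visit)
    row_of <- row_of[ord]; visit <- visit[ord]; result <- result[ord]
    same <- duplicated(row_of)
    if (any(same & c(FALSE, diff(visit) == 0L)))
      stop("duplicated auxiliary visit for a subject")
    ## a positive must be the last observed report for that subject
    not_last <- same[-1L] & result[-length(result)] == 1L
    if (any(not_last))
      stop("auxiliary reports continue after a positive result; ",
           "collection should stop at the first positive")
  }

  C <- build_c_matrix(n, row_of, visit, result, J, mis)

  ## Branch mask: intervals compatible with the gold-standard observation.
  mask <- matrix(TRUE, n, J + 1L)
  jj <- matrix(seq_len(J + 1L), n, J + 1L, byrow = TRUE)
  obs <- m_flag == 0L
  pos <- obs & delta == 1L
  neg <- obs & delta == 0L
  mask[pos, ] <- jj[pos, , drop = FALSE] <= v_index[pos]
  mask[neg, ] <- jj[neg, , drop = FALSE] > v_index[neg]

  structure(list(
    id = subjects$id, x = x, v_index = v_index, delta = delta,
    m_flag = m_flag, weight = weight, stratum = stratum, psu = psu,
    n_aux = tabulate(row_of, n), C = C, mask = mask, grid = grid, mis = mis,
    covariates = covariates
  ), class = "aug_data")
}

#' @export
print.aug_data <- function(x, ...) {
  cat(sprintf(
    "Augmented-likelihood data: %d subjects, %d covariate(s), J = %d\n",
    length(x$id), ncol(x$x), x$grid$J))
  cat(sprintf("  gold standard missing: %d (%.1f%%); auxiliary reports: %d\n",
              sum(x$m_flag), 100 * mean(x$m_flag), sum(x$n_aux)))
  invisible(x)
}
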