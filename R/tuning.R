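#' Cross-validation criterion on a random dichotomy
#'
#' Splits the sample at random into two halves and scores a penalty
#' configuration by one of two criteria:
#' \describe{
#'   \item{\code{"lscv"}}{two-fold least-squares cross-validation: each
#'     half-fit \eqn{\hat\beta_k} is scored against the held-out half by
#'     the unbiased L2-risk estimate
#'     \eqn{\hat\beta_k^\top\Psi\hat\beta_k - 2\,b_{-k}^\top\hat\beta_k}
#'     (where \eqn{b_{-k}} are the held-out empirical moments), and the
#'     two scores are summed.  Up to the constant \eqn{\|h\|^2} this
#'     estimates \eqn{\|h_{\hat\beta}\| ^2 - 2\langle h_{\hat\beta},
#'     h\rangle}, i.e. the L2 distance between the fitted and the true
#'     density — the loss the estimator itself minimizes.}
#'   \item{\code{"discrepancy"}}{the squared L2 distance between the two
#'     half-sample fits,
#'     \eqn{(\hat\beta_1-\hat\beta_2)^\top\Psi(\hat\beta_1-\hat\beta_2)}.
#'     Because the shrinkage bias common to both half-fits cancels in
#'     this difference, the criterion measures variance only and is
#'     minimized by arbitrarily strong penalization; it is provided for
#'     comparison and diagnostics.  A configuration under which both
#'     half-fits are identically zero is degenerate and scores
#'     \code{Inf}.}
#' }
#'
#' @param x numeric sample vector (length >= 4).
#' @param dict a \code{\link{dictionary}}.
#' @param spec a \code{\link{penalty_spec}}.
#' @param seed integer seed for the dichotomy.
#' @param n_splits number of random dichotomies to average over.
#' @param type \code{"lscv"} (default) or \code{"discrepancy"}.
#' @param ... passed to \code{\link{fit_coefficients}}.
#' @return scalar criterion value (lower is better; \code{"lscv"} may be
#'   negative).
#' @export
cv_criterion <- function(x, dict, spec, seed = 1L, n_splits = 1L,
                         type = c("lscv", "discrepancy"), ...) {
  type <- match.arg(type)
  n <- length(x)
  if (n < 4) stop("cross-validation needs at least 4 samples")
  H <- dict_eval(dict, x)
  gram <- gram_matrix(dict)
  L <- sup_norms(dict)
  set.seed(as.integer(seed))
  vals <- vapply(seq_len(n_splits), function(s) {
    half <- sample.int(n, floor(n / 2))
    .cv_one(H, gram, L, spec, half, type, ...)
  }, 0)
  mean(vals)
}

.cv_one <- function(H, gram, L, spec, half, type, ...) {
  n <- nrow(H)
  W <- ncol(H)
  idx2 <- setdiff(seq_len(n), half)
  if (length(half) == 0L || length(idx2) == 0L)
    stop("degenerate dichotomy: one half is empty")
  parts <- list(half, idx2)
  b <- lapply(parts, function(idx) colMeans(H[idx, , drop = FALSE]))
  f <- lapply(seq_along(parts), function(k) {
    wt <- compute_weights(spec, L, W, n = length(parts[[k]]))
    fit_coefficients(b[[k]], gram, wt$omega, spec$c, ...)
  })
  if (type == "discrepancy") {
    if (length(f[[1]]$support) == 0L && length(f[[2]]$support) == 0L)
      return(Inf)
    d <- f[[1]]$beta - f[[2]]$beta
    return(drop(d %*% gram %*% d))
  }
  # lscv: score each half-fit against the held-out moments
  sum(vapply(1:2, function(k) {
    beta <- f[[k]]$beta
    drop(beta %*% gram %*% beta) - 2 * sum(b[[3 - k]] * beta)
  }, 0))
}

#' Nested coordinate search for the tuning parameters
#'
#' Alternating one-dimensional minimization of the random-dichotomy
#' cross-validation criterion: holding \code{c} fixed, \code{lam1} is
#' chosen from \code{lam1_grid}; holding \code{lam1} fixed, \code{c} is
#' chosen from \code{c_grid}; rounds repeat until the criterion improves
#' by less than the precision \code{xi} or \code{max_rounds} is reached.
#' The same dichotomy (drawn once from \code{seed}) is used for every
#' evaluation, making the trace non-increasing by construction.  Grid
#' ties are broken toward the larger \code{lam1} (the sparser fit).
#'
#' @param x numeric sample vector.
#' @param dict a \code{\link{dictionary}}.
#' @param lam1_grid,c_grid sorted non-negative candidate values.
#' @param xi search precision on the criterion improvement
#'   (default 0.001).
#' @param spec template \code{\link{penalty_spec}} fixing \code{delta},
#'   \code{B}, \code{mode} and \code{weight_scale}.
#' @param n_splits dichotomies averaged per evaluation.
#' @param seed integer seed.
#' @param max_rounds cap on outer rounds.
#' @param type criterion type, see \code{\link{cv_criterion}}.
#' @param ... passed to \code{\link{fit_coefficients}}.
#' @return list with \code{lam1}, \code{c}, \code{criterion},
#'   \code{trace} (one row per outer round), \code{converged}.
#' @export
nested_search <- function(x, dict, lam1_grid, c_grid, xi = 1e-3,
                          spec = penalty_spec(), n_splits = 1L,
                          seed = 1L, max_rounds = 20L,
                          type = c("lscv", "discrepancy"), ...) {
  type <- match.arg(type)
  stopifnot(xi > 0, length(lam1_grid) >= 1, length(c_grid) >= 1,
            all(lam1_grid >= 0), all(c_grid >= 0),
            !is.unsorted(lam1_grid), !is.unsorted(c_grid))
  n <- length(x)
  H <- dict_eval(dict, x)
  gram <- gram_matrix(dict)
  L <- sup_norms(dict)
  set.seed(as.integer(seed))
  halves <- lapply(seq_len(n_splits), function(s)
    sample.int(n, floor(n / 2)))
  crit <- function(lam1, c) {
    sp <- penalty_spec(lam1 = lam1, c = c, delta = spec$delta, B = spec$B,
                       mode = spec$mode, weight_scale = spec$weight_scale)
    mean(vapply(halves, function(h)
      .cv_one(H, gram, L, sp, h, type, ...), 0))
  }
  lam1 <- lam1_grid[ceiling(length(lam1_grid) / 2)]
  cc <- c_grid[1]
  best <- crit(lam1, cc)
  trace <- data.frame(round = 0L, lam1 = lam1, c = cc, criterion = best)
  converged <- FALSE
  for (r in seq_len(max_rounds)) {
    vals1 <- vapply(lam1_grid, crit, 0, c = cc)
    m <- min(vals1)
    if (is.finite(m)) lam1 <- max(lam1_grid[vals1 == m])
    vals2 <- vapply(c_grid, crit, 0, lam1 = lam1)
    m2 <- min(vals2)
    if (is.finite(m2)) cc <- c_grid[which(vals2 == m2)[1]]
    new <- min(m2, m, best)
    trace <- rbind(trace,
                   data.frame(round = r, lam1 = lam1, c = cc,
                              criterion = new))
    if (best - new < xi) { best <- new; converged <- TRUE; break }
    best <- new
  }
  list(lam1 = lam1, c = cc, criterion = best, trace = trace,
       converged = converged)
}
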