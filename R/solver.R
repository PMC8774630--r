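#' Empirical dictionary moments
#'
#' Computes \eqn{b_j = (1/n)\sum_{i=1}^n h_j(X_i)}, the empirical inner
#' product between the sample and each dictionary component.  These are
#' the sufficient statistics of the empirical L2 criterion: for a density
#' \eqn{h_\beta} in the dictionary span,
#' \eqn{\|h_\beta - h\|^2 \propto -2 b^\top\beta + \beta^\top\Psi\beta}
#' up to a constant.
#'
#' @param dict a \code{\link{dictionary}}.
#' @param x numeric sample vector.
#' @return list with \code{b} (length-\code{W} vector) and \code{n}.
#' @export
empirical_moments <- function(dict, x) {
  H <- dict_eval(dict, x)
  list(b = colMeans(H), n = length(x))
}

#' Penalized objective value
#'
#' Evaluates the corrected sparse density estimation criterion
#' \deqn{Q(\beta) = -2 b^\top\beta + \beta^\top\Psi\beta
#'   + 2\sum_j \omega_j|\beta_j| + c\sum_j\beta_j^2 .}
#'
#' @param beta coefficient vector.
#' @param b empirical moment vector (see \code{\link{empirical_moments}}).
#' @param gram Gram matrix \eqn{\Psi}.
#' @param omega penalty weight vector.
#' @param c ridge tuning parameter.
#' @return scalar objective value.
#' @export
csde_objective <- function(beta, b, gram, omega, c = 0) {
  stopifnot(length(beta) == length(b))
  omega <- rep_len(omega, length(b))
  drop(-2 * sum(b * beta) + beta %*% gram %*% beta +
         2 * sum(omega * abs(beta)) + c * sum(beta^2))
}

#' Closed-form solution for an orthonormal dictionary
#'
#' When the dictionary is orthonormal (\eqn{\Psi = I}) the penalized
#' minimizer decouples into soft-thresholding of the simple mean estimator
#' \eqn{\tilde\beta_j = (1/n)\sum_i h_j(X_i)}:
#' \deqn{\hat\beta_j = (1 - \omega_j/|\tilde\beta_j|)_+
#'   \tilde\beta_j / (1 + c).}
#'
#' @param beta_tilde vector \eqn{\tilde\beta}.
#' @param omega weight vector (recycled).
#' @param c ridge tuning parameter.
#' @return thresholded coefficient vector.
#' @export
closed_form_orthonormal <- function(beta_tilde, omega, c = 0) {
  omega <- rep_len(omega, length(beta_tilde))
  out <- numeric(length(beta_tilde))
  nz <- beta_tilde != 0
  out[nz] <- pmax(0, 1 - omega[nz] / abs(beta_tilde[nz])) *
    beta_tilde[nz] / (1 + c)
  out
}

#' Fit penalized mixture coefficients by coordinate descent
#'
#' Minimizes the weighted Elastic-net penalized empirical L2 criterion by
#' cyclic coordinate descent, starting from \eqn{\beta = 0} (or a warm
#' start), sweeping coordinates in order until the largest coordinate
#' change falls below \code{tol}.  By default coefficients are constrained
#' non-negative, as appropriate for mixture weights.
#'
#' @param b empirical moment vector, or a list as returned by
#'   \code{\link{empirical_moments}}.
#' @param gram Gram matrix \eqn{\Psi} (symmetric PSD).
#' @param omega penalty weight vector (recycled to length \code{W}).
#' @param c ridge tuning parameter.
#' @param nonneg constrain \eqn{\beta \ge 0} (default \code{TRUE}).
#' @param tol convergence tolerance on the sup-norm coordinate change.
#' @param max_iter sweep cap; hitting it sets \code{converged = FALSE}
#'   with a warning.
#' @param beta0 optional warm start.
#' @param trace_objective record the objective after every sweep.
#' @return object of class \code{csde_fit}: \code{beta} (with entries
#'   below 1e-12 truncated to zero), \code{support}, \code{objective},
#'   \code{kkt} (per-coordinate residuals), \code{kkt_max_violation},
#'   \code{n_iter}, \code{converged}, and the penalty ingredients.
#' @export
fit_coefficients <- function(b, gram, omega, c = 0, nonneg = TRUE,
                             tol = 1e-6, max_iter = 10000L, beta0 = NULL,
                             trace_objective = FALSE) {
  if (is.list(b)) b <- b$b
  W <- length(b)
  stopifnot(nrow(gram) == W, ncol(gram) == W, tol > 0)
  omega <- rep_len(as.numeric(omega), W)
  if (is.null(beta0)) beta0 <- numeric(W)
  res <- cd_solve(as.numeric(b), gram, omega, c, nonneg, tol,
                  as.integer(max_iter), as.numeric(beta0),
                  trace_objective)
  if (!res$converged)
    warning(sprintf(
      "coordinate descent stopped at max_iter = %d (max delta %.3g)",
      max_iter, res$max_delta))
  beta <- res$beta
  beta[abs(beta) < 1e-12] <- 0
  kkt <- kkt_check(beta, b, gram, omega, c, nonneg)
  out <- list(beta = beta,
              support = which(beta != 0),
              objective = csde_objective(beta, b, gram, omega, c),
              kkt = kkt$residuals,
              kkt_max_violation = kkt$max_violation,
              n_iter = res$n_iter,
              converged = res$converged,
              objective_trace = res$objective_trace,
              omega = omega, c = c, nonneg = nonneg, b = b)
  class(out) <- "csde_fit"
  out
}

#' @export
print.csde_fit <- function(x, ...) {
  cat(sprintf(
    "csde fit: %d of %d coefficients active, objective %.6g\n",
    length(x$support), length(x$beta), x$objective))
  cat(sprintf("  sum(beta) = %.4f | KKT max violation %.3g | %s in %d sweeps\n",
              sum(x$beta), x$kkt_max_violation,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  invisible(x)
}

#' Fit the corrected sparse density estimator to a sample
#'
#' High-level interface: computes the empirical moments, the penalty
#' weights implied by \code{spec}, and runs \code{\link{fit_coefficients}}.
#'
#' @param x numeric sample vector.
#' @param dict a \code{\link{dictionary}}.
#' @param spec a \code{\link{penalty_spec}}.
#' @param ... further arguments passed to \code{\link{fit_coefficients}}
#'   (\code{tol}, \code{max_iter}, \code{nonneg}, ...).
#' @return a \code{csde_fit} (see \code{\link{fit_coefficients}}) with the
#'   resolved \code{spec} and weights attached.
#' @examples
#' d <- dictionary("gaussian", mean = c(0, 3), sd = 1)
#' x <- c(rnorm(50), rnorm(50, 3))
#' f <- csde_fit(x, d, penalty_spec(lam1 = 0.05, c = 0.01,
#'                                  weight_scale = "fixed_lam1"))
#' f$beta
#' @export
csde_fit <- function(x, dict, spec, ...) {
  m <- empirical_moments(dict, x)
  wt <- compute_weights(spec, sup_norms(dict), dict$W, m$n)
  fit <- fit_coefficients(m, gram_matrix(dict), wt$omega, spec$c, ...)
  fit$spec <- spec
  fit$weights <- wt
  fit
}

#' Verify the KKT stationarity conditions of a fit
#'
#' For the penalized criterion the first-order conditions at a minimizer
#' \eqn{\hat\beta} read, with
#' \eqn{g_k = b_k - (\Psi\hat\beta)_k - c\hat\beta_k}:
#' active coordinates satisfy
#' \eqn{g_k = \omega_k\,\mathrm{sign}(\hat\beta_k)}, inactive ones
#' \eqn{|g_k| \le \omega_k} (one-sided, \eqn{g_k \le \omega_k}, under the
#' non-negativity constraint).  The per-coordinate residual is the amount
#' by which the relevant condition fails; a converged fit should have a
#' residual no larger than a small multiple of the solver tolerance.
#'
#' @param beta coefficient vector (or a \code{csde_fit}).
#' @param b empirical moments.
#' @param gram Gram matrix.
#' @param omega weight vector.
#' @param c ridge tuning parameter.
#' @param nonneg whether the fit was non-negativity constrained.
#' @return list with \code{residuals} (length \code{W}) and
#'   \code{max_violation}.
#' @export
kkt_check <- function(beta, b, gram, omega, c = 0, nonneg = TRUE) {
  if (inherits(beta, "csde_fit")) {
    fit <- beta
    beta <- fit$beta
    if (missing(b)) b <- fit$b
    if (missing(omega)) omega <- fit$omega
    if (missing(c)) c <- fit$c
    if (missing(nonneg)) nonneg <- fit$nonneg
  }
  omega <- rep_len(omega, length(beta))
  g <- b - drop(gram %*% beta) - c * beta
  act <- beta != 0
  res <- numeric(length(beta))
  res[act] <- abs(g[act] - omega[act] * sign(beta[act]))
  if (nonneg) {
    res[!act] <- pmax(0, g[!act] - omega[!act])
  } else {
    res[!act] <- pmax(0, abs(g[!act]) - omega[!act])
  }
  list(residuals = res, max_violation = if (length(res)) max(res) else 0)
}

#' Coherence and eigenvalue diagnostics of a Gram matrix
#'
#' Computes the identifiability diagnostics used by the theory: the
#' pairwise coherence \eqn{\rho_W(i,j) =
#' \langle h_i,h_j\rangle / (\|h_i\|\|h_j\|)}, its maximum over the given
#' support (\code{rho_max}), the cumulative local coherence
#' \eqn{\rho^*= \sum_{i \in I}\sum_{j>i} |\rho_W(i,j)|} (\code{rho_star}),
#' and the smallest eigenvalue of \eqn{\Psi_W} (\code{lambda_min}).
#'
#' @param gram Gram matrix.
#' @param support integer index set \eqn{I} (e.g. an estimated support);
#'   may be empty, in which case the coherence fields are \code{NA}.
#' @return list with \code{rho_max}, \code{rho_star}, \code{lambda_min}.
#' @export
coherence_diagnostics <- function(gram, support = integer(0)) {
  W <- nrow(gram)
  lam_min <- min(eigen(gram, symmetric = TRUE, only.values = TRUE)$values)
  if (length(support) == 0L)
    return(list(rho_max = NA_real_, rho_star = NA_real_,
                lambda_min = lam_min))
  nrm <- sqrt(diag(gram))
  rho <- gram / tcrossprod(nrm)
  rho_max <- max(vapply(support, function(i) max(abs(rho[i, -i])), 0))
  rho_star <- sum(vapply(support, function(i)
    if (i < W) sum(abs(rho[i, (i + 1L):W])) else 0, 0))
  list(rho_max = rho_max, rho_star = rho_star, lambda_min = lam_min)
}
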