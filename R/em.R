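#' EM estimation of mixture weights with fixed components
#'
#' Maximum-likelihood estimation of the mixing proportions of a finite
#' mixture whose component densities are known and fixed (the classical
#' comparison method for dictionary-based weight estimation).  The E-step
#' computes responsibilities
#' \eqn{w_{ij} = p_j h_j(x_i) / \sum_s p_s h_s(x_i)}; the M-step sets
#' \eqn{p_j \leftarrow \sum_i w_{ij} / n}.  Iteration stops when the
#' largest weight change falls below the cessation level \code{xi}.
#'
#' @param x numeric sample vector.
#' @param dict a \code{\link{dictionary}} of fixed components.
#' @param xi cessation level on \eqn{\max_j|\Delta p_j|} (default 1e-4).
#' @param max_iter iteration cap.
#' @param init initial weights on the simplex; default equal weights
#'   \eqn{1/W}.
#' @return list with \code{beta} (simplex weight vector), \code{loglik}
#'   (observed-data log-likelihood trace, one entry per iteration),
#'   \code{n_iter}, \code{converged}.
#' @examples
#' d <- dictionary("gaussian", mean = c(0, 5), sd = 1)
#' em_fit(c(rnorm(30), rnorm(10, 5)), d)$beta
#' @export
em_fit <- function(x, dict, xi = 1e-4, max_iter = 5000L, init = NULL) {
  stopifnot(length(x) >= 1, xi > 0)
  W <- dict$W
  if (is.null(init)) init <- rep(1 / W, W)
  stopifnot(length(init) == W, all(init >= 0),
            abs(sum(init) - 1) < 1e-8)
  H <- dict_eval(dict, x)          # n x W
  n <- length(x)
  p <- init
  loglik <- numeric(0)
  converged <- FALSE
  it <- 0L
  repeat {
    it <- it + 1L
    mix <- drop(H %*% p)
    bad <- mix <= 0
    if (any(bad)) {
      warning(sprintf(
        "%d sample(s) have zero density under every component; using uniform responsibilities",
        sum(bad)))
    }
    loglik <- c(loglik, sum(log(mix[!bad])))
    resp <- sweep(H, 2L, p, "*")
    resp[!bad, ] <- resp[!bad, , drop = FALSE] / mix[!bad]
    resp[bad, ] <- 1 / W
    p_new <- colSums(resp) / n
    delta <- max(abs(p_new - p))
    p <- p_new
    if (delta < xi) { converged <- TRUE; break }
    if (it >= max_iter) break
  }
  if (!converged)
    warning(sprintf("EM stopped at max_iter = %d", max_iter))
  list(beta = p, loglik = loglik, n_iter = it, converged = converged)
}
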