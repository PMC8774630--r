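#' l1 coefficient error
#'
#' \eqn{\sum_j |\hat\beta_j - \beta^*_j|}.  For a simplex-valued truth and
#' the zero estimate this equals 1.
#'
#' @param beta_hat,beta_star coefficient vectors of equal length.
#' @return non-negative scalar.
#' @export
l1_error <- function(beta_hat, beta_star) {
  if (length(beta_hat) != length(beta_star))
    stop("coefficient vectors must have equal length")
  sum(abs(beta_hat - beta_star))
}

#' Evaluation grid for density distances
#'
#' @param lower,upper grid end points (continuous case).
#' @param n_points number of grid points (>= 1001).
#' @param tail_mass per-component tail mass at which the integer range is
#'   truncated (discrete case).
#' @return object of class \code{csde_grid}.
#' @export
grid_spec <- function(lower = NULL, upper = NULL, n_points = 20001L,
                      tail_mass = 1e-10) {
  if (!is.null(lower) && !is.null(upper) && lower >= upper)
    stop("grid lower bound must be below upper bound")
  stopifnot(n_points >= 1001L, tail_mass <= 1e-10)
  structure(list(lower = lower, upper = upper,
                 n_points = as.integer(n_points), tail_mass = tail_mass),
            class = "csde_grid")
}

.default_grid <- function(dict, grid = NULL) {
  if (is.null(grid)) grid <- grid_spec()
  if (dict$discrete) {
    kmax <- max(vapply(dict$rate, function(l)
      stats::qpois(grid$tail_mass, l, lower.tail = FALSE), 0)) + 1L
    return(list(x = 0:kmax, w = rep(1, kmax + 1L), discrete = TRUE))
  }
  lo <- grid$lower
  hi <- grid$upper
  if (dict$family == "gaussian") {
    lo_def <- min(dict$mean) - 8 * max(dict$sd)
    hi_def <- max(dict$mean) + 8 * max(dict$sd)
    if (is.null(lo) || is.null(hi)) {
      lo <- lo_def
      hi <- hi_def
    } else {
      # every component must leave < 1e-8 mass outside the grid
      miss <- stats::pnorm(lo, dict$mean, dict$sd) +
        stats::pnorm(hi, dict$mean, dict$sd, lower.tail = FALSE)
      if (max(miss) > 1e-8) {
        warning("grid does not cover the dictionary mass; widening")
        lo <- min(lo, lo_def)
        hi <- max(hi, hi_def)
      }
    }
  } else if (is.null(lo) || is.null(hi)) {
    lo <- dict$support[1]
    hi <- dict$support[2]
  }
  x <- seq(lo, hi, length.out = grid$n_points)
  h <- x[2] - x[1]
  w <- rep(h, grid$n_points)
  w[c(1L, grid$n_points)] <- h / 2   # composite trapezoid
  list(x = x, w = w, discrete = FALSE)
}

#' Total-variation error between two dictionary mixtures
#'
#' Computes \eqn{\mathrm{TV}(h_{\beta^*}, h_{\hat\beta}) =
#' \int |h_{\beta^*}(x) - h_{\hat\beta}(x)|\,dx} (a sum over the integers
#' for discrete dictionaries).  Note the convention carries no factor 1/2,
#' so the distance between two densities ranges in [0, 2].  The continuous
#' integral uses a composite trapezoid rule on a wide grid (default: the
#' component mean range extended by 8 standard deviations, 20001 points).
#'
#' @param dict a \code{\link{dictionary}} (the clean components).
#' @param beta_hat,beta_star coefficient vectors of length \code{W}.
#' @param grid optional \code{\link{grid_spec}}.
#' @return non-negative scalar.
#' @export
tv_error <- function(dict, beta_hat, beta_star, grid = NULL) {
  stopifnot(length(beta_hat) == dict$W, length(beta_star) == dict$W)
  g <- .default_grid(dict, grid)
  H <- dict_eval(dict, g$x)
  sum(g$w * abs(drop(H %*% (beta_hat - beta_star))))
}

#' Support recovery metrics
#'
#' Compares the estimated support \eqn{\hat I = \{j: \hat\beta_j >
#' 10^{-12}\}} with the true support \eqn{I^*}.  Precision is
#' \eqn{|\hat I \cap I^*| / |\hat I|} (1 when both sets are empty, 0 when
#' only \eqn{\hat I} is empty); recall analogously.
#'
#' @param beta_hat,beta_star coefficient vectors of equal length.
#' @return list with \code{exact_recovery}, \code{precision},
#'   \code{recall}.
#' @export
support_metrics <- function(beta_hat, beta_star) {
  if (length(beta_hat) != length(beta_star))
    stop("coefficient vectors must have equal length")
  I_hat <- which(abs(beta_hat) > 1e-12)
  I_star <- which(abs(beta_star) > 1e-12)
  inter <- length(intersect(I_hat, I_star))
  prec <- if (length(I_hat) == 0L) as.numeric(length(I_star) == 0L)
          else inter / length(I_hat)
  rec <- if (length(I_star) == 0L) as.numeric(length(I_hat) == 0L)
         else inter / length(I_star)
  list(exact_recovery = setequal(I_hat, I_star),
       precision = prec, recall = rec)
}
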