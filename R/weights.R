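#' Concentration rate v(delta)
#'
#' The rate \eqn{v(\delta) = \sqrt{\log(W/\delta)/n}} appearing in the
#' McDiarmid-type deviation bound for the empirical moments
#' \eqn{(1/n)\sum_i h_k(X_i)}.  It is the scale at which the data-dependent
#' penalty weights are set so that the KKT conditions at the true
#' coefficient vector hold with probability at least \eqn{1-\delta}.
#'
#' @param delta confidence level in (0, 1).
#' @param W dictionary size.
#' @param n sample size.
#' @return \eqn{\sqrt{\log(W/\delta)/n}}, a positive real.
#' @export
v_of <- function(delta, W, n) {
  stopifnot(n >= 1, W >= 1, delta > 0, delta < 1)
  if (W / delta <= 1) stop("W/delta must exceed 1")
  sqrt(log(W / delta) / n)
}

#' Penalty specification
#'
#' Bundles the tuning parameters of the weighted Elastic-net penalty
#' \eqn{2\sum_j \omega_j|\beta_j| + c\sum_j \beta_j^2}.
#'
#' The theoretical weights are
#' \eqn{\omega_k = 2\sqrt{2}\,L_k\,v(\delta/2) + cB}, where
#' \eqn{L_k = \|h_k\|_\infty}, \eqn{B} bounds \eqn{\max_j|\beta^*_j|}
#' (\eqn{B = 1} for mixture weights) and the shift \eqn{cB} compensates the
#' ridge term in the stationarity conditions.  Three conventions relate a
#' printed scalar \code{lam1} to these weights (\code{weight_scale}):
#' \describe{
#'   \item{\code{"delta"}}{theory-faithful: \code{lam1} is ignored and
#'     \eqn{v(\delta/2)} is used as is.}
#'   \item{\code{"fixed_lam1"}}{\code{lam1} replaces \eqn{v(\delta/2)}:
#'     \eqn{\omega_k = 2\sqrt2 L_k \lambda_1 + cB}.}
#'   \item{\code{"scaled_delta"}}{\code{lam1} multiplies the whole
#'     theoretical weight:
#'     \eqn{\omega_k = \lambda_1(2\sqrt2 L_k v(\delta/2) + cB)}.}
#' }
#' \code{mode} selects the estimator family: \code{"csde"} as above,
#' \code{"spades"} the un-shifted weighted-l1 weights
#' \eqn{4 L_k v(\delta/2)} (with the same \code{lam1} conventions and no
#' \eqn{cB} shift), and \code{"uniform"} the flat weights
#' \eqn{\omega_k = \lambda_1} of plain Lasso / Elastic-net.
#'
#' @param lam1 non-negative l1 scale.
#' @param c non-negative ridge tuning parameter (the measurement-error
#'   correction; 0 means no correction).
#' @param delta confidence level in (0,1); default 0.1.
#' @param B coefficient bound, default 1 (mixture weights sum to one).
#' @param mode \code{"csde"}, \code{"spades"} or \code{"uniform"}.
#' @param weight_scale \code{"scaled_delta"}, \code{"fixed_lam1"} or
#'   \code{"delta"}.
#' @return an object of class \code{penalty_spec}.
#' @export
penalty_spec <- function(lam1 = 0, c = 0, delta = 0.1, B = 1,
                         mode = c("csde", "spades", "uniform"),
                         weight_scale = c("scaled_delta", "fixed_lam1",
                                          "delta")) {
  mode <- match.arg(mode)
  weight_scale <- match.arg(weight_scale)
  stopifnot(lam1 >= 0, c >= 0, delta > 0, delta < 1, B > 0)
  structure(list(lam1 = lam1, c = c, delta = delta, B = B, mode = mode,
                 weight_scale = weight_scale),
            class = "penalty_spec")
}

#' Compute data-dependent penalty weights
#'
#' Evaluates the weight vector \eqn{\omega} for a given penalty
#' specification and component sup-norms, together with the shifted
#' weights \eqn{\tilde\omega = \omega - cB} that enter the concentration
#' bound (for \code{spades} and \code{uniform} modes there is no shift and
#' \eqn{\tilde\omega = \omega}).
#'
#' @param spec a \code{\link{penalty_spec}}.
#' @param L vector of sup-norms \eqn{L_k} (strictly positive).
#' @param W dictionary size (defaults to \code{length(L)}).
#' @param n sample size (needed whenever \eqn{v(\delta/2)} enters).
#' @return list with components \code{omega}, \code{omega_tilde} and the
#'   shift \code{shift = omega - omega_tilde}.
#' @examples
#' sp <- penalty_spec(lam1 = 0.074, mode = "uniform")
#' compute_weights(sp, L = rep(0.4, 3), n = 100)$omega
#' @export
compute_weights <- function(spec, L, W = length(L), n = NULL) {
  stopifnot(inherits(spec, "penalty_spec"))
  L <- as.numeric(L)
  if (length(L) != W) L <- rep_len(L, W)
  if (any(L <= 0)) stop("sup-norms must be strictly positive")
  need_v <- spec$mode != "uniform" && spec$weight_scale != "fixed_lam1"
  if (need_v && is.null(n))
    stop("sample size n is required for delta-based weight scales")
  v2 <- if (need_v) v_of(spec$delta / 2, W, n) else NA_real_
  shift <- 0
  omega <- switch(spec$mode,
    uniform = rep(spec$lam1, W),
    spades = switch(spec$weight_scale,
      delta = 4 * L * v2,
      fixed_lam1 = 4 * L * spec$lam1,
      scaled_delta = spec$lam1 * 4 * L * v2),
    csde = {
      cB <- spec$c * spec$B
      switch(spec$weight_scale,
        delta = { shift <- cB; 2 * sqrt(2) * L * v2 + cB },
        fixed_lam1 = { shift <- cB; 2 * sqrt(2) * L * spec$lam1 + cB },
        scaled_delta = {
          shift <- spec$lam1 * cB
          spec$lam1 * (2 * sqrt(2) * L * v2 + cB)
        })
    })
  list(omega = omega, omega_tilde = omega - shift, shift = shift)
}
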