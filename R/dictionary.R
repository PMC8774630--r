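#' Construct a dictionary of base densities
#'
#' A dictionary is an ordered family \eqn{\{h_j\}_{j=1}^W} of known
#' probability densities (or probability mass functions) whose non-negative
#' linear combination models an unknown density
#' \eqn{h_{\beta}(z) = \sum_j \beta_j h_j(z)}.  Supported families are
#' Gaussian location-scale components, Poisson components, and arbitrary
#' user-supplied (\code{custom}) densities.
#'
#' On construction the component sup-norms \eqn{L_j = \|h_j\|_\infty} and
#' the Gram matrix \eqn{\Psi_W} of pairwise L2 inner products
#' \eqn{\langle h_i, h_j\rangle} are computed and stored: Gaussian entries
#' by closed form, Poisson entries by a truncated series, custom entries by
#' adaptive quadrature.
#'
#' @param family one of \code{"gaussian"}, \code{"poisson"},
#'   \code{"custom"}.
#' @param mean numeric vector of component means \eqn{a_j}
#'   (Gaussian family).
#' @param sd numeric vector of component standard deviations
#'   \eqn{\sigma_j > 0} (Gaussian family); recycled against \code{mean}.
#' @param rate numeric vector of Poisson rates \eqn{\lambda_j > 0}.
#' @param densities list of vectorized density functions (custom family).
#' @param support for the custom family, a length-2 numeric vector on
#'   which the densities live (used for quadrature and sup-norm search).
#' @param scale internal multiplier per component (used by
#'   \code{\link{normalize_dictionary}}); defaults to 1.
#' @return an object of class \code{csde_dictionary} with fields
#'   \code{family}, \code{W}, the component parameters, \code{L}
#'   (sup-norms), \code{gram} (\eqn{\Psi_W}) and \code{discrete} flag.
#' @examples
#' d <- dictionary("gaussian", mean = 0.5 * (1:10), sd = 1)
#' d$W
#' d$L[1]                      # 1 / sqrt(2*pi)
#' @export
dictionary <- function(family = c("gaussian", "poisson", "custom"),
                       mean = NULL, sd = NULL, rate = NULL,
                       densities = NULL, support = NULL, scale = NULL) {
  family <- match.arg(family)
  d <- switch(family,
    gaussian = {
      if (is.null(mean)) stop("gaussian dictionary requires 'mean'")
      if (is.null(sd)) stop("gaussian dictionary requires 'sd'")
      W <- length(mean)
      sd <- rep_len(as.numeric(sd), W)
      if (any(!is.finite(mean)) || any(!is.finite(sd)) || any(sd <= 0))
        stop("gaussian parameters must be finite with sd > 0")
      list(family = family, W = W, mean = as.numeric(mean), sd = sd,
           discrete = FALSE)
    },
    poisson = {
      if (is.null(rate)) stop("poisson dictionary requires 'rate'")
      rate <- as.numeric(rate)
      if (any(!is.finite(rate)) || any(rate <= 0))
        stop("poisson rates must be finite and > 0")
      list(family = family, W = length(rate), rate = rate, discrete = TRUE)
    },
    custom = {
      if (!is.list(densities) || !all(vapply(densities, is.function, TRUE)))
        stop("custom dictionary requires a list of density functions")
      if (is.null(support) || length(support) != 2L || diff(support) <= 0)
        stop("custom dictionary requires support = c(lower, upper)")
      list(family = family, W = length(densities), densities = densities,
           support = as.numeric(support), discrete = FALSE)
    })
  d$scale <- if (is.null(scale)) rep(1, d$W) else rep_len(scale, d$W)
  if (any(d$scale <= 0)) stop("component scale multipliers must be > 0")
  class(d) <- "csde_dictionary"
  d$L <- vapply(seq_len(d$W), function(j) .sup_norm_one(d, j), 0)
  d$gram <- .gram_compute(d)
  d
}

#' @export
print.csde_dictionary <- function(x, ...) {
  cat(sprintf("csde dictionary: %d %s component%s (%s support)\n", x$W,
              x$family, if (x$W == 1L) "" else "s",
              if (x$discrete) "integer" else "real"))
  invisible(x)
}

#' Evaluate all dictionary components
#'
#' @param dict a \code{csde_dictionary}.
#' @param x numeric vector of evaluation points; must be non-negative
#'   integers for a discrete family.
#' @return a \code{length(x)} by \code{W} matrix with entry
#'   \eqn{(i,j) = h_j(x_i)}.
#' @export
dict_eval <- function(dict, x) {
  stopifnot(inherits(dict, "csde_dictionary"))
  x <- as.numeric(x)
  if (any(!is.finite(x))) stop("evaluation points must be finite")
  if (dict$discrete && any(x != floor(x) | x < 0))
    stop("discrete dictionary evaluated at non-integer or negative points")
  H <- switch(dict$family,
    gaussian = vapply(seq_len(dict$W), function(j)
      stats::dnorm(x, dict$mean[j], dict$sd[j]), numeric(length(x))),
    poisson = vapply(seq_len(dict$W), function(j)
      stats::dpois(x, dict$rate[j]), numeric(length(x))),
    custom = vapply(seq_len(dict$W), function(j)
      dict$densities[[j]](x), numeric(length(x))))
  H <- matrix(H, nrow = length(x), ncol = dict$W)
  sweep(H, 2L, dict$scale, "*")
}

.sup_norm_one <- function(dict, j) {
  s <- dict$scale[j]
  v <- switch(dict$family,
    gaussian = 1 / (dict$sd[j] * sqrt(2 * pi)),
    poisson = {
      lam <- dict$rate[j]
      # pmf mode at floor(lambda); brute force over a safe range is cheap
      kmax <- max(2, ceiling(lam + 10 * sqrt(lam) + 10))
      max(stats::dpois(0:kmax, lam))
    },
    custom = {
      g <- seq(dict$support[1], dict$support[2], length.out = 20001L)
      max(dict$densities[[j]](g))
    })
  s * v
}

#' Component sup-norms
#'
#' Returns \eqn{L_j = \|h_j\|_\infty} for every component: the closed form
#' \eqn{1/(\sigma_j\sqrt{2\pi})} for Gaussian components and the exact pmf
#' maximum for Poisson components.  These bound the summands of the
#' empirical moments and drive the concentration-based penalty weights.
#'
#' @param dict a \code{csde_dictionary}.
#' @return numeric vector of length \code{W}, all strictly positive.
#' @export
sup_norms <- function(dict) {
  stopifnot(inherits(dict, "csde_dictionary"))
  dict$L
}

#' Gram matrix of the dictionary
#'
#' The matrix \eqn{\Psi_W} with entries
#' \eqn{\langle h_i,h_j\rangle = \int h_i(x)h_j(x)\,dx} (a sum over the
#' integers for discrete families).  Gaussian entries use the closed form
#' \deqn{\langle\phi(\cdot|a_i,\sigma_i), \phi(\cdot|a_j,\sigma_j)\rangle
#'   = \frac{\exp\{-(a_i-a_j)^2 / (2(\sigma_i^2+\sigma_j^2))\}}
#'          {\sqrt{2\pi(\sigma_i^2+\sigma_j^2)}},}
#' Poisson entries a truncated product series (truncation where both tail
#' masses are below 1e-12), custom entries adaptive quadrature.
#'
#' @param dict a \code{csde_dictionary}.
#' @return symmetric \code{W} by \code{W} matrix with positive diagonal.
#' @export
gram_matrix <- function(dict) {
  stopifnot(inherits(dict, "csde_dictionary"))
  dict$gram
}

.gram_compute <- function(dict) {
  W <- dict$W
  G <- switch(dict$family,
    gaussian = {
      v <- outer(dict$sd^2, dict$sd^2, "+")
      dm <- outer(dict$mean, dict$mean, "-")
      exp(-dm^2 / (2 * v)) / sqrt(2 * pi * v)
    },
    poisson = {
      # shared truncation point: both tails below 1e-12 beyond kmax
      kmax <- max(vapply(dict$rate, function(l)
        stats::qpois(1e-12, l, lower.tail = FALSE), 0)) + 1L
      P <- vapply(dict$rate, function(l) stats::dpois(0:kmax, l),
                  numeric(kmax + 1L))
      crossprod(P)
    },
    custom = {
      G <- matrix(0, W, W)
      for (i in seq_len(W)) for (j in i:W) {
        f <- dict$densities[[i]]; g <- dict$densities[[j]]
        q <- stats::integrate(function(x) f(x) * g(x),
                              dict$support[1], dict$support[2],
                              rel.tol = 1e-10, abs.tol = 1e-12,
                              subdivisions = 500L)
        if (q$message != "OK")
          stop(sprintf("quadrature failed for gram entry (%d,%d): %s",
                       i, j, q$message))
        G[i, j] <- G[j, i] <- q$value
      }
      G
    })
  G <- G * tcrossprod(dict$scale)
  (G + t(G)) / 2
}

#' Normalize a dictionary to unit L2 norm
#'
#' Divides each component by its L2 norm \eqn{\|h_j\| = \sqrt{\Psi_{jj}}}
#' so the resulting Gram matrix has unit diagonal.  This mirrors the
#' standardization of covariates in penalized regression; note the rescaled
#' components are no longer probability densities.
#'
#' @param dict a \code{csde_dictionary}.
#' @return a \code{csde_dictionary} whose Gram diagonal is 1.
#' @export
normalize_dictionary <- function(dict) {
  stopifnot(inherits(dict, "csde_dictionary"))
  nrm <- sqrt(diag(dict$gram))
  if (any(nrm <= 0)) stop("zero-norm component cannot be normalized")
  sc <- dict$scale / nrm
  switch(dict$family,
    gaussian = dictionary("gaussian", mean = dict$mean, sd = dict$sd,
                          scale = sc),
    poisson = dictionary("poisson", rate = dict$rate, scale = sc),
    custom = dictionary("custom", densities = dict$densities,
                        support = dict$support, scale = sc))
}
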