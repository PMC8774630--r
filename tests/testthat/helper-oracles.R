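# Shared oracles and fixture builders for the test suite.

# General-purpose non-negative quadratic-program oracle for the penalized
# criterion: with beta >= 0 the l1 term is linear, so the objective is a
# smooth strictly convex quadratic and box-constrained L-BFGS-B solves it
# to high precision.  Independent of the coordinate-descent path.
qp_oracle <- function(b, gram, omega, c = 0) {
  W <- length(b)
  omega <- rep_len(omega, W)
  fn <- function(beta)
    drop(-2 * sum(b * beta) + beta %*% gram %*% beta +
           2 * sum(omega * beta) + c * sum(beta^2))
  gr <- function(beta)
    drop(-2 * b + 2 * gram %*% beta + 2 * omega + 2 * c * beta)
  o <- stats::optim(rep(0, W), fn, gr, method = "L-BFGS-B", lower = 0,
                    control = list(maxit = 2000L, factr = 1e1,
                                   pgtol = 1e-12))
  o$par
}

# Random strictly convex test problem with a non-trivial active set.
random_problem <- function(W, seed) {
  set.seed(seed)
  A <- matrix(rnorm(W * W), W, W)
  gram <- crossprod(A) / W + diag(0.05, W)
  list(b = runif(W, -0.2, 0.8),
       gram = gram,
       omega = runif(W, 0.01, 0.3),
       c = sample(c(0, runif(1, 0, 0.5)), 1))
}

# Numerical-quadrature inner product of two gaussian densities; the
# independent check for the closed-form Gram entries.
gauss_inner_quad <- function(m1, s1, m2, s2) {
  stats::integrate(function(x) dnorm(x, m1, s1) * dnorm(x, m2, s2),
                   -Inf, Inf, rel.tol = 1e-12)$value
}

# Total-variation distance between the mixtures of two (possibly
# different) gaussian dictionaries, by brute-force quadrature.
tv_between_dicts <- function(d1, beta1, d2, beta2, lo, hi) {
  f <- function(x)
    abs(drop(dict_eval(d1, x) %*% beta1) - drop(dict_eval(d2, x) %*% beta2))
  stats::integrate(f, lo, hi, rel.tol = 1e-10, subdivisions = 1000L)$value
}
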