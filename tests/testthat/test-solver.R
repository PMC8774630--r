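test_that("objective evaluates its four terms", {
  expect_equal(csde_objective(0, b = 0.5, gram = matrix(1), omega = 0.1,
                              c = 0.3), 0)
  # W = 1 hand case: -2*0.5*0.4 + 0.16 + 2*0.1*0.4 = -0.16
  expect_equal(csde_objective(0.4, b = 0.5, gram = matrix(1), omega = 0.1,
                              c = 0), -0.16, tolerance = 1e-12)
  # adding a ridge term increases the objective by c * sum(beta^2)
  beta <- c(0.3, 0.1)
  G <- matrix(c(1, 0.2, 0.2, 1), 2)
  expect_equal(csde_objective(beta, c(0.4, 0.2), G, 0.05, c = 0.2) -
                 csde_objective(beta, c(0.4, 0.2), G, 0.05, c = 0),
               0.2 * sum(beta^2), tolerance = 1e-12)
})

test_that("orthonormal closed form soft-thresholds and shrinks", {
  expect_equal(closed_form_orthonormal(0.5, 0.1, 0), 0.4)
  expect_equal(closed_form_orthonormal(0.5, 0.1, 0.25), 0.32)
  expect_equal(closed_form_orthonormal(0.05, 0.1, 0), 0)
  expect_equal(closed_form_orthonormal(0.05, 0.1, 3), 0)
  expect_equal(closed_form_orthonormal(-0.5, 0.1, 0), -0.4)
  expect_equal(closed_form_orthonormal(0, 0.1, 0.5), 0)
})

test_that("coordinate descent matches the closed form on orthonormal grams", {
  set.seed(11)
  for (rep in 1:5) {
    W <- sample(3:12, 1)
    b <- runif(W, -0.3, 0.8)
    omega <- runif(W, 0, 0.3)
    c <- runif(1, 0, 0.5)
    f <- fit_coefficients(b, diag(W), omega, c, nonneg = FALSE,
                          tol = 1e-12)
    expect_equal(f$beta, closed_form_orthonormal(b, omega, c),
                 tolerance = 1e-10)
    fn <- fit_coefficients(pmax(b, 0), diag(W), omega, c, nonneg = TRUE,
                           tol = 1e-12)
    expect_equal(fn$beta, closed_form_orthonormal(pmax(b, 0), omega, c),
                 tolerance = 1e-10)
  }
})

test_that("sub-threshold problems give the zero fit in one sweep", {
  f <- fit_coefficients(c(0.05, 0.1), diag(2), omega = c(0.1, 0.2))
  expect_equal(f$beta, c(0, 0))
  expect_equal(f$n_iter, 1L)
  expect_equal(f$kkt_max_violation, 0)
  expect_length(f$support, 0)
})

test_that("decoupled two-coordinate problem solves by hand", {
  f <- fit_coefficients(c(0.5, 0.05), diag(2), omega = c(0.1, 0.1),
                        c = 0.1, tol = 1e-12)
  expect_equal(f$beta, c(0.4 / 1.1, 0), tolerance = 1e-10)
  expect_equal(f$support, 1L)
})

test_that("fits agree with a non-negative QP oracle on random problems", {
  for (seed in 1:50) {
    p <- random_problem(sample(2:20, 1), seed)
    f <- fit_coefficients(p$b, p$gram, p$omega, p$c, tol = 1e-10,
                          max_iter = 50000L)
    ref <- qp_oracle(p$b, p$gram, p$omega, p$c)
    expect_lt(max(abs(f$beta - ref)), 1e-6)
    expect_lt(f$kkt_max_violation, 1e-6)
  }
  # plain non-negative Lasso special case: c = 0, uniform weights
  p <- random_problem(15, 99)
  f <- fit_coefficients(p$b, p$gram, rep(0.05, 15), 0, tol = 1e-10,
                        max_iter = 50000L)
  expect_lt(max(abs(f$beta - qp_oracle(p$b, p$gram, rep(0.05, 15), 0))),
            1e-6)
})

test_that("the objective is non-increasing across sweeps", {
  for (seed in c(3, 17)) {
    p <- random_problem(12, seed)
    f <- fit_coefficients(p$b, p$gram, p$omega, p$c,
                          trace_objective = TRUE)
    expect_true(all(diff(f$objective_trace) <= 1e-12))
  }
})

test_that("consistent rescaling of the problem leaves the fit invariant", {
  p <- random_problem(8, 5)
  f1 <- fit_coefficients(p$b, p$gram, p$omega, p$c, tol = 1e-10)
  t <- 3.7
  f2 <- fit_coefficients(t * p$b, t * p$gram, t * p$omega, t * p$c,
                         tol = 1e-10)
  expect_equal(f2$beta, f1$beta, tolerance = 1e-8)
})

test_that("KKT residuals flag perturbed solutions", {
  p <- random_problem(10, 21)
  f <- fit_coefficients(p$b, p$gram, p$omega, p$c, tol = 1e-8)
  expect_lt(f$kkt_max_violation, 1e-6)
  k <- f$support[1]
  beta_p <- f$beta
  beta_p[k] <- beta_p[k] + 0.01
  viol <- kkt_check(beta_p, p$b, p$gram, p$omega, p$c)$max_violation
  expect_gte(viol, 0.01 * (p$gram[k, k] + p$c) - 1e-6)
})

test_that("hitting max_iter warns and reports non-convergence", {
  p <- random_problem(10, 33)
  expect_warning(f <- fit_coefficients(p$b, p$gram, p$omega, p$c,
                                       tol = 1e-12, max_iter = 2L),
                 "max_iter")
  expect_false(f$converged)
})

test_that("coherence diagnostics match hand calculations", {
  di <- coherence_diagnostics(diag(3), support = 1:2)
  expect_equal(di$rho_max, 0)
  expect_equal(di$rho_star, 0)
  expect_equal(di$lambda_min, 1)
  G <- matrix(c(1, 0.5, 0.5, 1), 2)
  d2 <- coherence_diagnostics(G, support = 1L)
  expect_equal(d2$rho_max, 0.5)
  expect_equal(d2$rho_star, 0.5)
  expect_equal(d2$lambda_min, 0.5, tolerance = 1e-12)
  empty <- coherence_diagnostics(G, integer(0))
  expect_true(is.na(empty$rho_max))
  expect_equal(empty$lambda_min, 0.5, tolerance = 1e-12)
})

test_that("csde_fit wires moments, weights and solver together", {
  set.seed(8)
  d <- dictionary("gaussian", mean = c(0, 4), sd = 1)
  x <- c(rnorm(80), rnorm(20, 4))
  f <- csde_fit(x, d, penalty_spec(lam1 = 0.02, c = 0.01,
                                   weight_scale = "fixed_lam1"))
  expect_s3_class(f, "csde_fit")
  expect_true(all(f$beta >= 0))
  expect_setequal(f$support, 1:2)
  expect_gt(f$beta[1], f$beta[2])
  m <- empirical_moments(d, x)
  expect_equal(m$b, colMeans(dict_eval(d, x)))
  expect_true(all(m$b <= sup_norms(d)))
})
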