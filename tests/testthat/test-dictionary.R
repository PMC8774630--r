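test_that("construction validates parameters", {
  expect_error(dictionary("gaussian", mean = 0, sd = -1), "sd > 0")
  expect_error(dictionary("poisson", rate = c(1, 0)), "> 0")
  expect_error(dictionary("gaussian", mean = 1), "requires 'sd'")
  expect_error(dictionary("custom", densities = list(dnorm)), "support")
})

test_that("every component integrates (or sums) to one", {
  d <- dictionary("gaussian", mean = c(-1, 0, 2), sd = c(0.5, 1, 2))
  for (j in 1:3) {
    mass <- integrate(function(x) dict_eval(d, x)[, j], -Inf, Inf,
                      rel.tol = 1e-10)$value
    expect_equal(mass, 1, tolerance = 1e-8)
  }
  dp <- dictionary("poisson", rate = c(0.3, 2.5, 9))
  expect_equal(colSums(dict_eval(dp, 0:200)), rep(1, 3), tolerance = 1e-8)
})

test_that("evaluation matches the component laws and support rules", {
  d1 <- dictionary("gaussian", mean = 0, sd = 1)
  expect_equal(dict_eval(d1, 0)[1, 1], 1 / sqrt(2 * pi), tolerance = 1e-6)
  # location-shift invariance: component 9 of the mean grid 0.5*j at its
  # own mean gives the standard normal mode
  d2 <- dictionary("gaussian", mean = 0.5 * (1:10), sd = 1)
  expect_equal(dict_eval(d2, 4.5)[1, 9], 1 / sqrt(2 * pi),
               tolerance = 1e-6)
  dp <- dictionary("poisson", rate = 1)
  expect_equal(dict_eval(dp, 0)[1, 1], exp(-1), tolerance = 1e-10)
  expect_error(dict_eval(dp, 1.5), "non-integer")
  expect_error(dict_eval(dp, -1), "non-integer|negative")
  H <- dict_eval(d2, c(-1, 0, 3))
  expect_equal(dim(H), c(3L, 10L))
  expect_true(all(H >= 0))
})

test_that("sup-norms are exact and bound the evaluations everywhere", {
  expect_equal(sup_norms(dictionary("gaussian", mean = 3, sd = 1)),
               1 / sqrt(2 * pi), tolerance = 1e-10)
  expect_equal(sup_norms(dictionary("gaussian", mean = 0, sd = 0.4)),
               1 / (0.4 * sqrt(2 * pi)), tolerance = 1e-10)
  # brute-force pmf maxima, including the integer-rate tie case
  expect_equal(sup_norms(dictionary("poisson", rate = 2.5)),
               max(dpois(0:200, 2.5)), tolerance = 1e-12)
  expect_equal(sup_norms(dictionary("poisson", rate = 3)),
               max(dpois(0:200, 3)), tolerance = 1e-12)
  d <- dictionary("gaussian", mean = c(-2, 0, 1, 5), sd = c(0.3, 1, 2, 5))
  H <- dict_eval(d, seq(-20, 30, length.out = 10000L))
  expect_true(all(t(H) <= sup_norms(d) + 1e-12))
})

test_that("gaussian Gram closed form agrees with quadrature", {
  expect_equal(gram_matrix(dictionary("gaussian", mean = 0, sd = 1))[1, 1],
               1 / (2 * sqrt(pi)), tolerance = 1e-10)
  set.seed(42)
  d <- dictionary("gaussian", mean = runif(5, -3, 3), sd = runif(5, 0.3, 2))
  G <- gram_matrix(d)
  for (i in 1:5) for (j in i:5)
    expect_equal(G[i, j],
                 gauss_inner_quad(d$mean[i], d$sd[i], d$mean[j], d$sd[j]),
                 tolerance = 1e-8)
  # vanishing overlap
  far <- dictionary("gaussian", mean = c(0, 1000), sd = 1)
  expect_lt(gram_matrix(far)[1, 2], 1e-300)
})

test_that("poisson Gram matches the brute-force series", {
  d <- dictionary("poisson", rate = c(1, 4))
  G <- gram_matrix(d)
  expect_equal(G[1, 1], sum(exp(-2) / factorial(0:100)^2),
               tolerance = 1e-10)
  expect_equal(G[1, 2], sum(dpois(0:200, 1) * dpois(0:200, 4)),
               tolerance = 1e-12)
})

test_that("Gram matrices are symmetric PSD with positive diagonal", {
  set.seed(7)
  for (d in list(
    dictionary("gaussian", mean = rnorm(8), sd = runif(8, 0.2, 2)),
    dictionary("poisson", rate = sort(runif(8, 0.2, 10))))) {
    G <- gram_matrix(d)
    expect_identical(G, t(G))
    expect_true(all(diag(G) > 0))
    expect_true(all(G >= 0))
    expect_gte(min(eigen(G, symmetric = TRUE, only.values = TRUE)$values),
               -1e-10)
  }
})

test_that("custom-family quadrature Gram agrees with the gaussian closed form", {
  d <- dictionary("custom",
                  densities = list(function(x) dnorm(x, 0, 1),
                                   function(x) dnorm(x, 1, 0.7)),
                  support = c(-10, 10))
  ref <- dictionary("gaussian", mean = c(0, 1), sd = c(1, 0.7))
  expect_equal(gram_matrix(d), gram_matrix(ref), tolerance = 1e-8)
})

test_that("normalization yields unit diagonal and is idempotent", {
  d <- dictionary("gaussian", mean = c(0, 1, 4), sd = c(1, 0.5, 2))
  nd <- normalize_dictionary(d)
  expect_equal(diag(gram_matrix(nd)), rep(1, 3), tolerance = 1e-10)
  nd2 <- normalize_dictionary(nd)
  expect_equal(nd2$scale, nd$scale, tolerance = 1e-12)
  # the rescaled sigma = 1 component has unit L2 norm by quadrature
  f <- function(x) (nd$scale[1] * dnorm(x))^2
  expect_equal(integrate(f, -Inf, Inf, rel.tol = 1e-10)$value, 1,
               tolerance = 1e-8)
})
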