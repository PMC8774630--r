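#' True coefficient pattern of the high-dimensional experiments
#'
#' The sparse simplex vector with eight active mixture weights used by
#' both the contaminated Gaussian and the Poisson experiments:
#' value 0.2 at position 9; 0.1 at positions 20, 26, 37, 48 and 76;
#' 0.15 at positions 54 and 65; zeros elsewhere.
#'
#' @param W dictionary size (>= 76).
#' @return numeric vector of length \code{W} summing to 1.
#' @export
beta_star_pattern <- function(W) {
  if (W < 76) stop("the coefficient pattern needs W >= 76")
  beta <- numeric(W)
  beta[c(9, 20, 26, 37, 48, 54, 65, 76)] <-
    c(0.2, 0.1, 0.1, 0.1, 0.1, 0.15, 0.15, 0.1)
  beta
}

.sigma_pattern <- function(W) {
  s <- c(rep(1, 20), rep(0.8, 6), rep(0.6, 11), rep(0.4, 11),
         rep(0.6, 6), rep(0.8, 11))
  if (W < length(s)) stop("the sd pattern needs W >= 65")
  c(s, rep(1.2, W - length(s)))
}

#' Contaminated Gaussian mixture scenario
#'
#' The clean density is a Gaussian mixture
#' \eqn{h_{\beta^*}(x)=\sum_j \beta^*_j\,\phi(x\,|\,a j, \sigma_j)} with
#' means \eqn{a j}, the block standard-deviation pattern
#' (1 x20, 0.8 x6, 0.6 x11, 0.4 x11, 0.6 x6, 0.8 x11, 1.2 padding) and
#' the sparse simplex \code{\link{beta_star_pattern}}.  The observed data
#' are drawn with every component standard deviation inflated by the
#' factor \code{inflation} — additive measurement error realized as
#' component-wise variance inflation.  Fitting uses the clean dictionary.
#'
#' @param W dictionary size (>= 76).
#' @param a mean spacing (default 0.5).
#' @param n sample size per replicate (default 100).
#' @param inflation standard-deviation inflation factor of the observed
#'   mixture (default 1.1; 1 means no contamination).
#' @return object of class \code{csde_scenario} with fields \code{dict}
#'   (clean), \code{dict_obs} (contaminated), \code{beta_star}, \code{n}
#'   and a \code{sample(n)} draw function (component index from
#'   \eqn{\beta^*}, then one draw from that observed component).
#' @export
gaussian_scenario <- function(W, a = 0.5, n = 100L, inflation = 1.1) {
  beta <- beta_star_pattern(W)
  sds <- .sigma_pattern(W)
  means <- a * seq_len(W)
  dict <- dictionary("gaussian", mean = means, sd = sds)
  dict_obs <- dictionary("gaussian", mean = means, sd = inflation * sds)
  structure(list(
    name = sprintf("gaussian_w%d", W),
    family = "gaussian", dict = dict, dict_obs = dict_obs,
    beta_star = beta, n = as.integer(n),
    contamination = list(type = "gaussian_sd_inflation",
                         factor = inflation),
    sample = function(m = n) {
      j <- sample.int(W, m, replace = TRUE, prob = beta)
      stats::rnorm(m, means[j], inflation * sds[j])
    }), class = "csde_scenario")
}

#' Overdispersed Poisson mixture scenario
#'
#' The clean p.m.f. is a Poisson mixture
#' \eqn{h_{\beta^*}(x)=\sum_j \beta^*_j\,p(x\,|\,\lambda_j = a j)} with
#' the sparse simplex \code{\link{beta_star_pattern}}.  Measurement error
#' turns each Poisson component into a negative binomial with the same
#' mean \eqn{\lambda_j} and dispersion \code{r} (variance
#' \eqn{\lambda_j + \lambda_j^2/r}); observations are drawn from the
#' negative binomial mixture while fitting uses the Poisson dictionary.
#'
#' @param W dictionary size (>= 76).
#' @param a rate spacing (default 0.1).
#' @param n sample size per replicate (default 100).
#' @param r negative-binomial dispersion (default 6); \code{r = Inf}
#'   recovers the uncontaminated Poisson mixture.
#' @return a \code{csde_scenario} (see \code{\link{gaussian_scenario}}).
#' @export
poisson_scenario <- function(W, a = 0.1, n = 100L, r = 6) {
  beta <- beta_star_pattern(W)
  rates <- a * seq_len(W)
  dict <- dictionary("poisson", rate = rates)
  structure(list(
    name = sprintf("poisson_w%d", W),
    family = "poisson", dict = dict, dict_obs = dict,
    beta_star = beta, n = as.integer(n),
    contamination = list(type = "poisson_to_negbin", r = r),
    sample = function(m = n) {
      j <- sample.int(W, m, replace = TRUE, prob = beta)
      if (is.infinite(r)) stats::rpois(m, rates[j])
      else stats::rnbinom(m, size = r, mu = rates[j])
    }), class = "csde_scenario")
}

#' Low-dimensional Gaussian mixture scenarios
#'
#' Two small uncontaminated Gaussian mixtures used to compare the
#' penalized estimator with the EM algorithm at n = 50:
#' \enumerate{
#'   \item W = 6, \eqn{\beta = (0.3,0,0,0.3,0,0.4)},
#'     \eqn{\mu = (0,10,20,30,40,50)}, \eqn{\sigma = (1,...,6)};
#'   \item W = 7, \eqn{\beta = (0.1,0,0,0.8,0,0,0.1)},
#'     \eqn{\mu = (0,...,6)},
#'     \eqn{\sigma = (0.3,0.2,0.2,0.1,0.2,0.2,0.3)}.
#' }
#'
#' @param n sample size per replicate (default 50).
#' @return list of two \code{csde_scenario} objects.
#' @export
lowdim_scenarios <- function(n = 50L) {
  mk <- function(name, beta, mu, sigma) {
    dict <- dictionary("gaussian", mean = mu, sd = sigma)
    force(beta)
    structure(list(
      name = name, family = "gaussian", dict = dict, dict_obs = dict,
      beta_star = beta, n = as.integer(n),
      contamination = list(type = "none"),
      sample = function(m = n) {
        j <- sample.int(length(beta), m, replace = TRUE, prob = beta)
        stats::rnorm(m, mu[j], sigma[j])
      }), class = "csde_scenario")
  }
  list(
    mk("lowdim_1", c(0.3, 0, 0, 0.3, 0, 0.4),
       c(0, 10, 20, 30, 40, 50), 1:6),
    mk("lowdim_2", c(0.1, 0, 0, 0.8, 0, 0, 0.1),
       0:6, c(0.3, 0.2, 0.2, 0.1, 0.2, 0.2, 0.3)))
}

#' @export
print.csde_scenario <- function(x, ...) {
  cat(sprintf("scenario %s: W = %d, n = %d, |support| = %d, %s\n",
              x$name, x$dict$W, x$n, sum(x$beta_star != 0),
              x$contamination$type))
  invisible(x)
}

.fit_estimator <- function(est, x, scen, settings, H, gram, L, seed) {
  n <- length(x)
  W <- ncol(H)
  b <- colMeans(H)
  s <- settings
  fit_b <- function(spec) {
    wt <- compute_weights(spec, L, W, n)
    # ill-conditioned grams (large W, strong overlap) converge slowly
    fit_coefficients(b, gram, wt$omega, spec$c, max_iter = 50000L)$beta
  }
  switch(est,
    oracle = scen$beta_star,
    em = em_fit(x, scen$dict, xi = if (is.null(s$xi)) 1e-4 else s$xi)$beta,
    lasso = fit_b(penalty_spec(lam1 = s$lam1, c = 0, mode = "uniform")),
    elastic_net = {
      sp <- penalty_spec(lam1 = s$lam1, c = s$c, mode = "uniform")
      # uniform weights, ridge in the objective only
      fit_b(sp)
    },
    spades = fit_b(penalty_spec(lam1 = s$lam1, c = 0, mode = "spades",
                                delta = .or(s$delta, 0.1),
                                weight_scale = .or(s$weight_scale,
                                                   "scaled_delta"))),
    csde = {
      ws <- .or(s$weight_scale, "scaled_delta")
      if (isTRUE(s$tune)) {
        ts <- nested_search(x, scen$dict, lam1_grid = s$lam1_grid,
                            c_grid = s$c_grid, xi = .or(s$xi, 1e-3),
                            spec = penalty_spec(delta = .or(s$delta, 0.1),
                                                B = .or(s$B, 1),
                                                mode = "csde",
                                                weight_scale = ws),
                            seed = seed)
        fit_b(penalty_spec(lam1 = ts$lam1, c = ts$c,
                           delta = .or(s$delta, 0.1), B = .or(s$B, 1),
                           mode = "csde", weight_scale = ws))
      } else {
        fit_b(penalty_spec(lam1 = s$lam1, c = s$c,
                           delta = .or(s$delta, 0.1), B = .or(s$B, 1),
                           mode = "csde", weight_scale = ws))
      }
    },
    stop(sprintf("unknown estimator '%s'", est)))
}

.or <- function(a, b) if (is.null(a)) b else a

#' Run a replicated simulation experiment
#'
#' For each replicate \code{i} the seed \code{base_seed + i - 1} is set,
#' \code{n} observations are drawn from the scenario's observed law, each
#' requested estimator is fitted, and the l1 coefficient error, the
#' total-variation error (against the clean mixture) and the support
#' precision/recall are recorded.  Replicates in which an estimator fails
#' are recorded as missing, excluded from the summary, and counted.
#'
#' @param scenario a \code{csde_scenario}.
#' @param estimators character vector drawn from \code{"lasso"},
#'   \code{"elastic_net"}, \code{"spades"}, \code{"csde"}, \code{"em"},
#'   \code{"oracle"}.
#' @param settings named list (one entry per estimator) of tuning
#'   settings: \code{lam1}, \code{c}, \code{delta}, \code{B},
#'   \code{weight_scale}; for tuned CSDE \code{tune = TRUE} with
#'   \code{lam1_grid}, \code{c_grid}, \code{xi}; for EM \code{xi}.
#' @param N number of replicates.
#' @param base_seed integer; replicate \code{i} uses
#'   \code{base_seed + i - 1}.
#' @param grid optional \code{\link{grid_spec}} for the TV error.
#' @return object of class \code{error_summary}: \code{summary} data
#'   frame (per estimator: mean/sd of l1 and TV error, mean
#'   precision/recall, failure count) and \code{per_replicate} data
#'   frame with one row per (replicate, estimator).
#' @export
run_experiment <- function(scenario, estimators, settings = list(),
                           N = 100L, base_seed = 1L, grid = NULL) {
  stopifnot(inherits(scenario, "csde_scenario"))
  gram <- gram_matrix(scenario$dict)
  L <- sup_norms(scenario$dict)
  # grid and clean-density evaluations shared across replicates
  g <- .default_grid(scenario$dict, grid)
  Hg <- dict_eval(scenario$dict, g$x)
  rows <- vector("list", N * length(estimators))
  k <- 0L
  for (i in seq_len(N)) {
    seed_i <- as.integer(base_seed + i - 1L)
    set.seed(seed_i)
    x <- scenario$sample(scenario$n)
    H <- dict_eval(scenario$dict, x)
    for (est in estimators) {
      k <- k + 1L
      res <- tryCatch({
        beta <- .fit_estimator(est, x, scenario, settings[[est]],
                               H, gram, L, seed_i)
        sm <- support_metrics(beta, scenario$beta_star)
        data.frame(replicate = i, seed = seed_i, estimator = est,
                   l1 = l1_error(beta, scenario$beta_star),
                   tv = sum(g$w * abs(drop(
                     Hg %*% (beta - scenario$beta_star)))),
                   n_active = sum(beta != 0),
                   precision = sm$precision, recall = sm$recall,
                   exact_recovery = sm$exact_recovery,
                   failed = FALSE)
      }, error = function(e) {
        warning(sprintf("replicate %d, estimator %s failed: %s",
                        i, est, conditionMessage(e)))
        data.frame(replicate = i, seed = seed_i, estimator = est,
                   l1 = NA_real_, tv = NA_real_, n_active = NA_integer_,
                   precision = NA_real_, recall = NA_real_,
                   exact_recovery = NA, failed = TRUE)
      })
      rows[[k]] <- res
    }
  }
  per_rep <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(per_rep, per_rep$estimator),
    function(d) {
      ok <- d[!d$failed, , drop = FALSE]
      data.frame(estimator = d$estimator[1], n_rep = nrow(ok),
                 n_failed = sum(d$failed),
                 l1_mean = mean(ok$l1), l1_sd = stats::sd(ok$l1),
                 tv_mean = mean(ok$tv), tv_sd = stats::sd(ok$tv),
                 precision = mean(ok$precision),
                 recall = mean(ok$recall),
                 exact_recovery_rate = mean(ok$exact_recovery))
    }))
  summ <- summ[match(unique(per_rep$estimator), summ$estimator), ]
  rownames(summ) <- NULL
  structure(list(scenario = scenario$name, summary = summ,
                 per_replicate = per_rep, base_seed = base_seed, N = N),
            class = "error_summary")
}

#' @export
print.error_summary <- function(x, ...) {
  cat(sprintf("experiment %s: N = %d replicates (base seed %d)\n",
              x$scenario, x$N, x$base_seed))
  print(x$summary, digits = 4)
  invisible(x)
}
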