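# csde — corrected sparse density estimation for contaminated samples

`csde` estimates an unknown univariate density as a **sparse non-negative
combination of known dictionary densities** when the observations carry
additive measurement error: you see `X = Z + ε` but want the density `h` of
`Z`.  Mixture-type densities of this kind arise throughout biostatistics and
epidemiological modelling (latent subpopulations, multi-modal exposure and
environmental distributions, overdispersed counts), and the estimator here
is designed for the high-dimensional regime where the dictionary size `W`
can exceed the sample size `n`.

Writing `h_β(z) = Σ_j β_j h_j(z)` over a dictionary `{h_j}` with Gram matrix
`Ψ_ij = ⟨h_i, h_j⟩` and empirical moments `b_j = (1/n) Σ_i h_j(X_i)`, the
**corrected sparse density estimator (CSDE)** solves

```
β̂ = argmin_{β ≥ 0}  −2 bᵀβ + βᵀΨβ + 2 Σ_j ω_j |β_j| + c Σ_j β_j²
```

a weighted Elastic-net penalized empirical L2 criterion.  The weights
`ω_k = 2√2 L_k v(δ/2) + cB` (with `L_k = ‖h_k‖_∞` and
`v(δ) = √(log(W/δ)/n)`) come from a McDiarmid concentration bound that makes
the first-order (KKT) conditions hold with high probability; the ridge
parameter `c` is the correction for measurement error.  Special cases give
the classical baselines: flat weights with `c = 0` is the non-negative
Lasso, sup-norm-proportional weights with `c = 0` is the SPADES-style
weighted-l1 estimator.  An EM algorithm for mixture weights with fixed
components, cross-validation by random dichotomy, KKT diagnostics,
coherence/eigenvalue diagnostics and a full simulation harness round out
the package.

## Worked example

Fit the contaminated multi-modal Gaussian mixture scenario at `W = 81`:

```r
library(csde)
set.seed(42)
sc   <- gaussian_scenario(81)          # clean dict + 1.1-sd-inflated sampling
x    <- sc$sample(100)                 # n = 100 contaminated observations
spec <- penalty_spec(lam1 = 0.065, c = 0.027)
fit  <- csde_fit(x, sc$dict, spec)
fit
#> csde fit: 11 of 81 coefficients active, objective -0.0148927
#>   sum(beta) = 0.4410 | KKT max violation 1.86e-07 | converged in 30 sweeps

l1_error(fit$beta, sc$beta_star)                 # 0.908
tv_error(sc$dict, fit$beta, sc$beta_star)        # 0.576
```

Eleven of 81 coefficients are active, clustered around the eight true
mixture locations; the KKT residual certifies the solver converged to the
penalized optimum.  The total mass `Σ β̂ = 0.44` is well below 1 — the
penalty deliberately shrinks, which is why the coefficient l1 error (0.91)
and the TV error (0.58, without the conventional 1/2 factor, so ranging
in [0, 2]) are the natural performance summaries.  Diagnostics for
identifiability:

```r
coherence_diagnostics(gram_matrix(sc$dict), fit$support)
#> rho_max 0.958  rho_star 25.52  lambda_min 1.01e-16
```

— this dictionary is heavily coherent and rank-deficient, exactly the
regime in which the concentration-based weights and the ridge correction
earn their keep.  `run_experiment()` replicates whole simulation studies
(Gaussian, overdispersed Poisson, low-dimensional EM comparisons) with
per-replicate seeds, and `nested_search()` tunes `(λ1, c)` by two-fold
least-squares cross-validation on a random dichotomy.  A thin command-line
front end lives at `inst/cli/csde.R`
(`Rscript csde.R fit|tune|em|simulate|diagnostics ...`).

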