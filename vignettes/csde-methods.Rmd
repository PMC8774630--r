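---
title: "Corrected sparse density estimation: models, tuning and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Corrected sparse density estimation: models, tuning and simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csde)
```

## The model

We observe an i.i.d. univariate sample $X_1,\dots,X_n$ that is a
contaminated version of draws $Z_i$ from an unknown density $h$: the
measurement mechanism adds zero-mean error, $X_i = Z_i + \varepsilon_i$.
The target $h$ is modelled as a sparse non-negative combination of a
*dictionary* of known densities $\{h_j\}_{j=1}^W$,
$$h_{\beta^*}(z) = \sum_{j=1}^W \beta^*_j\, h_j(z), \qquad
  \sum_j \beta^*_j = 1,\ \beta^*_j \ge 0,$$
with possibly $W \gg n$.  Because
$\|h_\beta - h\|^2 \propto -2\,\mathrm{E}\,h_\beta(X) + \|h_\beta\|^2$,
an empirical L2 criterion needs only the moments
$b_j = \tfrac1n \sum_i h_j(X_i)$ and the Gram matrix
$\Psi_{ij} = \langle h_i, h_j\rangle$.  The corrected sparse density
estimator (CSDE) minimizes
$$Q(\beta) \;=\; -2\,b^\top\beta + \beta^\top\Psi\beta
  + 2\sum_j \omega_j |\beta_j| + c \sum_j \beta_j^2,
  \qquad \beta \ge 0,$$
a weighted Elastic-net penalized criterion.  The weighted $\ell_1$ term
induces sparsity with component-specific thresholds; the ridge term with
tuning parameter $c$ is the *measurement-error correction* — it grows with
the error variability and stabilizes the fit against the bias the
contamination induces in $b$.  Setting $c = 0$ and flat weights recovers
the plain (non-negative) Lasso; $c = 0$ with sup-norm-proportional
weights is the SPADES-style weighted-$\ell_1$ estimator.

All of this is univariate by design: every experiment the package
reproduces, and the dictionaries it ships, live on the real line or the
non-negative integers.

## Penalty weights

Concentration of the empirical moments drives the weights.  McDiarmid's
bounded-difference inequality gives, for each component with sup-norm
$L_k = \|h_k\|_\infty$, the deviation rate
$v(\delta) = \sqrt{\log(W/\delta)/n}$, and the theoretical weight
$$\omega_k \;=\; 2\sqrt2\, L_k\, v(\delta/2) + cB,$$
where $B$ bounds the largest coefficient ($B = 1$ by default, since
mixture weights live on the simplex) and the shift $cB$ offsets the ridge
contribution to the stationarity conditions.  We use the analytic
sup-norm everywhere, for discrete families too (brute-force maximization
of the pmf is exact and cheap), rather than any sample-based
approximation of $L_k$.  Note the concentration argument itself only
bounds $\max_i |h_k(X_i)|$ by $2L_k$; using the analytic $L_k$ is the
deterministic, data-free convention.

A reproduction detail deserves honesty.  Published tables for this family
of methods print a single scalar $\lambda_1$ per method and dictionary
size.  Three ways of relating that scalar to the weights are implemented
(`weight_scale` in `penalty_spec()`):

* `"delta"` — the theoretical weight as is, ignoring $\lambda_1$;
* `"fixed_lam1"` — $\lambda_1$ *replaces* $v(\delta/2)$;
* `"scaled_delta"` — $\lambda_1$ *multiplies* the whole theoretical
  weight, $\omega_k = \lambda_1\,(2\sqrt2 L_k v(\delta/2) + cB)$.

At $n = 100$ the first two produce weights larger than every empirical
moment for the tabulated $(\lambda_1, c)$ values, i.e. the identically
zero fit, in both the Gaussian and the Poisson experiment.  Only the
multiplicative reading yields non-degenerate fits, and it reproduces the
Gaussian-experiment TV error essentially exactly.  `"scaled_delta"` is
therefore the package default and the convention used in all
reproduction runs; the other two remain available and tested.  $\delta$
defaults to 0.1 and is recorded with every run.

## Solver

Cyclic coordinate descent from the zero start, sweeping $j = 1..W$ in
fixed order (bit-reproducible runs), with the closed-coordinate update
$$\beta_j \leftarrow
  \frac{\big(b_j - \sum_{k\ne j}\Psi_{jk}\beta_k - \omega_j\big)_+}
       {\Psi_{jj} + c}$$
in non-negative mode, or the corresponding soft-thresholding update in
signed mode.  The inner loop is compiled (C++) and maintains $\Psi\beta$
incrementally.  Convergence is declared when the largest coordinate
change in a sweep falls below `tol` (default $10^{-6}$; the printed
"precision $\xi$" levels of the reproduced experiments govern the tuning
search and the EM stopping rule, not this inner loop).  The support is
read off after truncating entries below $10^{-12}$ — the criterion keeps
exact zeros, so this cutoff only guards against representation noise.
Every fit carries its KKT residuals: for active coordinates
$|g_k - \omega_k \operatorname{sign}\hat\beta_k|$ with
$g_k = b_k - (\Psi\hat\beta)_k - c\hat\beta_k$, for inactive ones the
excess of $g_k$ over $\omega_k$ (one-sided under non-negativity, which is
our reading of the stationarity conditions for the constrained problem;
the signed two-sided check is used in signed mode).  Non-negativity is
the default because the mixture weights are non-negative; the orthonormal
special case has the explicit soft-thresholding solution
$\hat\beta_j = (1-\omega_j/|\tilde\beta_j|)_+ \tilde\beta_j/(1+c)$, which
the test suite uses as an equivalence oracle, alongside a
general-purpose constrained quadratic-programming oracle.

## Tuning by random dichotomy

The sample is split at random into two halves.  The package scores a
candidate $(\lambda_1, c)$ by two-fold least-squares cross-validation:
each half-fit $\hat\beta_k$ is evaluated against the held-out half
through $\hat\beta_k^\top\Psi\hat\beta_k - 2\,b_{-k}^\top\hat\beta_k$,
an unbiased estimate (up to the constant $\|h\|^2$) of the L2 risk of
the fitted density.  The more literal alternative — the squared L2
distance between the two half-sample fits — is implemented as
`type = "discrepancy"` but is *not* used for tuning: the shrinkage bias
common to both half-fits cancels in their difference, so that criterion
measures variance only and is driven to zero by arbitrarily strong
penalization.  We measured exactly this failure (tuned low-dimensional
fits collapsing toward zero mass) before switching the default to the
risk-based score.

The search itself is the nested coordinate descent over
$(\lambda_1, c)$: alternate one-dimensional grid minimizations until the
criterion improves by less than the precision $\xi$ (interpreted as a
bound on the criterion improvement, and logged); ties prefer the larger
$\lambda_1$, i.e. the sparser fit.  The same dichotomy is reused for
every evaluation inside one search, which makes the trace non-increasing
by construction and the search deterministic given the seed.  For the
low-dimensional reproduction runs the grids are
$\lambda_1 \in 10^{\{-3,\dots,-0.5\}}$ (11 log-spaced points) and
$c \in \{0\} \cup 10^{\{-3,\dots,-0.5\}}$ (6 points): wide enough to span
weak-to-strong penalization for those scenarios without entering the
all-zero regime.

## EM baseline

For fixed, known components the mixing proportions are also estimable by
maximum likelihood via EM: responsibilities
$w_{ij} = p_j h_j(x_i) / \sum_s p_s h_s(x_i)$, then
$p_j \leftarrow \sum_i w_{ij}/n$ (the double-sum denominator equals $n$
because responsibilities sum to one per observation).  Equal weights
initialize; iteration stops when $\max_j |\Delta p_j|$ falls below the
cessation level $\xi$ (default $10^{-4}$).  The observed-data
log-likelihood is logged each iteration and asserted non-decreasing.
Samples with zero density under every component (possible only through
numerical underflow) get uniform responsibilities, with a warning.

## Error metrics

The $\ell_1$ coefficient error is $\sum_j|\hat\beta_j - \beta^*_j|$; the
total-variation error is $\int |h_{\beta^*} - h_{\hat\beta}|$ —
deliberately *without* the conventional 1/2, so two densities can be up
to distance 2 apart.  Coefficients are *not* renormalized to the simplex
before evaluation: the raw penalized estimator is what the errors
describe, and with strong penalties its total mass can be well below one
(which is why $\ell_1$ errors cluster near 1 and TV errors can be
large).  Continuous TV integrals use a composite trapezoid rule on the
component mean range extended by eight standard deviations, 20\,001
points by default (doubling the resolution moves results by less than
$10^{-6}$); grids that fail to cover $1-10^{-8}$ of every component's
mass are widened with a warning.  Discrete TV errors sum over the
integers out to where all component tail masses are below $10^{-10}$.
Gram entries come from the Gaussian closed form, a truncated product
series (both tails below $10^{-12}$) for Poisson, and adaptive quadrature
for custom families.

## Synthetic data: what is emulated, and what is not

`gaussian_scenario(W)` draws from the contaminated multi-modal Gaussian
mixture used in the high-dimensional experiments: means $0.5j$, a block
pattern of standard deviations (twenty 1's, six 0.8's, eleven 0.6's,
eleven 0.4's, six 0.6's, eleven 0.8's, then 1.2's), and a sparse simplex
$\beta^*$ with eight active weights (0.2 at position 9; 0.1 at 20, 26,
37, 48, 76; 0.15 at 54, 65).  Two printed inconsistencies are resolved
once: the zero-padding of $\beta^*$ is taken so the last active index is
76 in both the Gaussian and the Poisson experiment, and the sd blocks
(which count to 65) are padded with 1.2 up to length $W$ exactly.
Measurement error enters as a component-wise standard-deviation inflation
by the factor 1.1 — equivalent to adding independent Gaussian noise per
component — and sampling draws the component index from $\beta^*$ and
then one observation from the inflated component (exact, no rejection).
`poisson_scenario(W)` uses Poisson rates $0.1j$ and observes negative
binomials with the same means and dispersion $r = 6$ (variance
$\lambda + \lambda^2/r$), the discrete analogue of added noise.
`lowdim_scenarios()` are the two small uncontaminated mixtures
($W = 6, 7$, $n = 50$) used for the EM comparison.

Replicate $i$ of an experiment uses seed `base_seed + i - 1`, recorded in
the per-replicate table, so any replicate can be re-run in isolation.

These generators emulate the *published study conditions*, not real
contaminated data: error laws are exactly the stated parametric forms,
components are exactly the dictionary entries (no misspecification), and
samples are i.i.d.  Passing reproduction tests therefore demonstrates
correctness of the estimator and harness under those conditions, not
robustness to dictionary misspecification, dependence, or non-parametric
error laws.

## Reproduction scale and observed behaviour

All reproduction runs use the published scale — $n = 100$, $W = 321$,
$N = 100$ replicates for the two high-dimensional experiments; $n = 50$,
$N = 100$ for the low-dimensional ones — and finish in seconds thanks to
the compiled solver and closed-form Gram matrices.  Two honest
discrepancies with the published tables persist and are deliberately left
visible.  First, the printed TV errors of the discrete experiment
(about 0.002 for every estimator) are far below what any estimator can
achieve from $n = 100$ samples — estimating a pmf to three decimals
everywhere needs orders of magnitude more data — and our runs give TV
errors around 0.6–0.7 there.  Second, the tuned low-dimensional CSDE
reaches a mean $\ell_1$ error of about 0.13–0.14, which a sweep over
*fixed* $\lambda_1$ values shows is the floor attainable under our
generator for any tuning whatsoever; the published 0.109 sits below that
floor, a generator-level offset also visible (at ~8%) in the EM
baseline.  The package reports what it computes.

## Known limitations

Univariate dictionaries only; no dictionary learning or component
estimation (EM estimates weights with components fixed); the
non-asymptotic oracle-inequality constants are not computed — the
coherence and minimal-eigenvalue quantities are exposed as empirical
diagnostics (`coherence_diagnostics()`) only.  The cross-validation
criterion assumes the two half-samples are exchangeable; heavy
serial dependence in real data would break the random dichotomy.
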