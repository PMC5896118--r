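---
title: "Methods: sparse negative-binomial DBNs by variational inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sparse negative-binomial DBNs by variational inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nbdbn)
```

## The model

RNA-Seq time series give non-negative integer counts whose variance grows
faster than their mean. nbdbn models a panel of M genes over L ordered time
points (R replicates) as a first-order dynamic Bayesian network with
negative-binomial observations: for each gene i,

$$ y_t \sim \mathrm{NB2}\!\big(s_t \exp(X_{t-1}\beta),\ \omega\big), $$

where NB2 means mean $\mu$ and variance $\mu + \mu^2/\omega$, $s_t$ is a
per-sample size factor absorbed into the linear predictor as a fixed
offset $\log s_t$, and the rows of $X$ hold the remaining genes' values at
the preceding time point of the same replicate (transitions never cross
replicates). Edges of the network are directed parent-at-$t{-}1$ →
child-at-$t$; self-loops are excluded by default, so each regression has
$W = M - 1$ slope candidates plus an intercept.

Sparsity comes from the horseshoe prior on the slopes:
$\beta_w \sim N(0, \zeta_w^2)$, $\zeta_w \sim C^+(0, \tau)$,
$\tau \sim C^+(0, \sigma)$, $p(\sigma^2) \propto 1/\sigma^2$. For
inference every half-Cauchy is expanded into its inverse-gamma scale
mixture ($\zeta^2_w \mid a_w \sim \mathrm{IG}(\tfrac12, 1/a_w)$,
$a_w \mid \tau^2 \sim \mathrm{IG}(\tfrac12, 1/\tau^2)$, and so on down the
chain), which `horseshoe_marginal_check()` verifies against the
half-Cauchy CDF by simulation. The intercept gets a flat-ish normal prior
and the dispersion a weakly informative gamma prior (defaults below).

## Variational inference

The likelihood is augmented as a Poisson–Gamma mixture,
$y_t \mid \lambda_t \sim \mathrm{Pois}(\lambda_t)$,
$\lambda_t \sim \Gamma(\omega, \omega e^{-\eta_t})$ with
$\eta_t = X_t\beta + \log s_t$, so that all factors except $q(\beta)$ and
$q(\omega)$ have conjugate closed-form mean-field updates
(`poisson_gamma_mixture_check()` verifies the identity by Monte Carlo).
The mean-field family is

* $q(\lambda_t)$: Gamma, updated to shape $y_t + E[\omega]$ and rate
  $1 + E[\omega]\,E[e^{-\eta_t}]$, with
  $E[e^{-\eta_t}] = \exp(-X_t\mu - \log s_t + \tfrac12 X_t \Sigma X_t^\top)$
  from the log-normal mean of the Gaussian $q(\beta)$;
* $q(\beta) = N(\mu, \Sigma)$, updated by one non-conjugate variational
  message passing (NCVMP) step per sweep:
  $\Sigma = [\bar\omega X^\top \mathrm{diag}(E[\lambda] \cdot w) X + M]^{-1}$
  and $\mu \leftarrow \mu + \Sigma[\bar\omega X^\top(E[\lambda]\cdot w - 1) - M\mu]$,
  where $w$ is the expected inverse link above,
  $M = \mathrm{diag}(E[1/\zeta_w^2], 1/v_c)$ is the prior precision, and
  $\bar\omega = E_q[\omega]$ (the alternative of integrating the update
  over $q(\omega)$ is not implemented);
* $q(\omega)$: a discrete distribution on a log-spaced grid, with weights
  proportional to the pointwise exponentiated expected log joint — i.e.
  numerical quadrature for the one intractable one-dimensional factor;
* inverse-gamma factors for $\zeta^2_w$, $a_w$, $\tau^2$, $b$, $\sigma^2$
  with fixed shapes $(1, 1, \tfrac{1+W}{2}, 1, \tfrac12)$ and scales built
  from reciprocal expectations of their neighbours. The scale of
  $q(\zeta^2_w)$ is $\tfrac12 E[\beta_w^2] + E[1/a_w]$; the reciprocal
  expectation is what the inverse-gamma message supplies (the factor
  $q(a_w)$ has shape 1, so its direct mean does not even exist).

Sweeps run $\lambda \to \beta \to \omega \to$ horseshoe (the order is a
package choice; mean-field coordinate ascent permits any) until the
relative ELBO change is below `tol` or `max_iter` is hit; non-convergence
is a warning and a flag, never an error. NCVMP does not guarantee a
monotone ELBO, so the $\beta$ step is damped: if the ELBO drops beyond a
tolerance the step is halved (a convex combination of old and new
$\mu, \Sigma$) up to eight times — standard NCVMP stabilization. The fit is
fully deterministic given data and configuration.

With the dispersion or the local scales held fixed (`fixed_omega`,
`fixed_zeta2`) the ELBO is an exact lower bound on the reduced model's log
evidence, which the test suite checks against dense-grid integration on
small problems. In the full model the discrete quadrature factor makes the
ELBO a monitoring quantity rather than a strict bound on the continuous
evidence.

## Tunable parameters

| parameter | default | meaning / rationale |
|---|---|---|
| `tol` | 1e-6 | relative ELBO change declaring convergence |
| `max_iter` | 500 | sweep cap; typical fits converge in tens of sweeps |
| `omega_grid_size`, `omega_range` | 200, [1e-2, 1e3] | dispersion quadrature grid, uniform in log ω; spans far beyond dispersions seen in bulk RNA-Seq |
| `omega_prior_shape/rate` | 0.01, 0.01 | weakly informative Gamma prior on ω (mean 1, variance 100) |
| `intercept_var` | 100 | N(0, 10²) intercept prior — diffuse on the log-count scale |
| `clip` | 50 | exponent bound inside `exp()`; clip events are counted and reported |
| `damping_max`, `damping_tol` | 8, 1e-8 | step-halving guard for the NCVMP update |
| `cutoff` | 0.95 | edge selection threshold on the sign-probability score |

The gamma prior's hyperparameters and the intercept variance are package
choices (the hierarchy only fixes the distributional families); both are
exposed in `vb_config()` rather than hard-coded.

## The predictor transform

The model regresses log-mean counts on predictor values through
$\exp(X\beta)$, and regulatory coefficients of magnitude ~0.3 are only
meaningful if predictors live on a bounded scale — raw counts in the
hundreds would explode the link. The default transform is therefore
$\log(1 + \mathrm{count}/s)$ per predictor, centred and scaled to unit
variance (`"log-std"`); `"log"` and `"raw"` are available for users who
want the untransformed behaviour. Constant predictor columns are zeroed
and flagged rather than dropped, keeping the edge table complete. The
transform used is recorded in the network object and the CLI run log,
because coefficient magnitudes are only comparable within a transform.
This is the single largest modelling choice in the package and the default
was fixed before any benchmarking of alternatives.

## Edge scores and selection

An edge is scored by $1 - 2\Phi(-|\mu_w|/\mathrm{sd}_w)$, the posterior
probability that the coefficient shares the sign of its mean minus the
opposite tail. Algebraically, score $> c$ holds exactly when zero lies
outside the central $c$ credible interval, so "posterior probability
> 0.95" and "zero outside the 95% CI" select identical edge sets — the
suite asserts this on every fitted model it produces. The same score is
the continuous ranking statistic for the ROC/PR curves (any strictly
monotone transform of $|\mu|/\mathrm{sd}$ would give identical curve
metrics). Betweenness centrality of the selected-edge digraph uses unit
edge weights and the $(n-1)(n-2)$ normalization.

## The synthetic benchmark

`sample_structure()` is a surrogate for curated regulatory-network
subsampling: children are drawn uniformly, parents by preferential
attachment on out-degree, giving a few hub regulators, mean in-degree 1.5
by default, and edge density well under 10% of ordered pairs at benchmark
sizes. Users with a real reference network can subsample a module of it
instead. `sample_parameters()` draws nonzero coefficients from the equally
weighted $N(0.3, 0.1^2)/N(-0.3, 0.1^2)$ mixture — the component spread is
read as a standard deviation, the common convention in this literature —
and per-gene baseline (mean, dispersion) pairs with replacement from an
empirical table. The packaged table is synthetic (log-normal means around
100 counts, dispersions log-uniform in [0.05, 5]), emulating the marginal
behaviour of bulk RNA-Seq panels so that no external download is needed;
`synthetic_mean_dispersion()` regenerates it. Initial states are i.i.d.
baseline NB2 draws; size factors default to 1, with a log-normal option
(sd 0.2) to exercise depth normalization.

`simulate_counts()` then iterates the DBN forward with the same log-scale
predictor convention used in fitting (centred at the parent's baseline
rather than an empirical mean, since the latter is unknown while
simulating). The generator emulates the count marginals, the
autoregressive dependence structure, and replicate structure of real
designs; it does not emulate measurement batch effects, gene-length or
GC biases, unmodelled feedback within a time step, or the
non-stationarity of strongly driven differentiation courses — so passing
benchmarks demonstrate correct recovery *under the model class*, not
performance guarantees on arbitrary real data.

Structure, parameter and count draws take separate seeds, so each stage is
independently reproducible.

## Evaluation metrics

Evaluation is directed: each ordered pair (i → j), i ≠ j, is one instance,
so a reversed edge costs both a false negative and a false positive.
AUC-PR uses continuous (Davis–Goadrich) interpolation with ties collapsed
to single thresholds; it is the headline metric because true edges are
rare. The partial AUC-ROC restricts to specificity ≥ 0.95 (a sensitivity
focus is available by a flag, via the class-swap reflection of the ROC)
and applies the McClish correction so 0.5 is chance and 1 is perfect. MCC
is computed from the selected-edge calls, returning 0 with a warning on a
degenerate confusion marginal. All three implementations are pinned by
brute-force oracles (threshold enumeration, trapezoid integration with
boundary interpolation, fine-grid Riemann sums) on small instances, and
the partial AUC is additionally cross-checked against pROC.

## Numerical choices and degenerate inputs

Exponents in the expected inverse link are clipped at ±50 before
exponentiation and the events counted. Quadrature weights are normalized
by log-sum-exp, and total underflow raises an error suggesting a wider
grid. A singular coefficient-update precision raises an error naming
collinearity as the likely cause. Initialization is $\mu = 0$ with the
intercept at $\log(\overline{y/s})$, $\Sigma = 0.1 I$, $q(\omega)$ at the
prior on the grid, and unit inverse-gamma scales. Size-factor estimation
delegates to the standard median-of-ratios implementation and refuses
(with advice to use total-count mode) when no gene is nonzero in every
sample. Times are ordered as they appear in the metadata, never
lexicographically.

## Problem sizes in the tests and acceptance script

The suite exercises the exact benchmark settings — 20 time points, 3
replicates, the ±0.3 coefficient mixture on 25-node networks (5 repeated
data sets, one structure) — plus strong-signal (±0.8) 10-node recovery
over 5 seeds, shuffled-time nulls, and a ridge-on-log-counts baseline
through the same evaluator. These sizes keep a full run in the minutes
range on one core while leaving the per-gene regressions (N = 57 rows,
W = 24 predictors) at their realistic shape; 50-node networks run with the
same code path and complete in minutes.

## Known limitations

* One dispersion per gene, NB2 only; no NB1, zero-inflation, or
  gene-specific dispersion trends.
* Inter-slice edges only: no instantaneous (within-time-point)
  interactions and no structure search beyond per-gene shrinkage.
* Mean-field posteriors underestimate joint uncertainty; credible
  intervals are per-coefficient and approximate.
* The full-model ELBO mixes a discrete quadrature factor into a
  continuous bound and is used for convergence monitoring only.
* Coefficients are defined on the transformed predictor scale; comparing
  magnitudes across transforms is meaningless.
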