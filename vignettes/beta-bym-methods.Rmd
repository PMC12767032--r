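---
title: "Beta-BYM disease mapping: model, sampler and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Beta-BYM disease mapping: model, sampler and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`betabym` estimates small-area prevalence from one bounded observation per
area. Each area's observed proportion $Y_i \in (0,1)$ is modelled as
conditionally beta distributed in the mean-precision parameterization,

$$Y_i \mid \mu_i, \phi \sim \mathrm{Beta}(\mu_i \phi,\ (1-\mu_i)\phi),
\qquad \mathbb{E}(Y_i) = \mu_i,\quad
\mathrm{Var}(Y_i) = \frac{\mu_i(1-\mu_i)}{1+\phi},$$

with a logit link on the mean and a Besag-York-Mollié (BYM) decomposition
of area effects:

$$\operatorname{logit}(\mu_i) = \beta_0 + x_i'\beta + w_i + v_i .$$

Here $x_i$ are area-level covariates kept in percent units (so a
coefficient is a log-odds change per percentage point), $v_i \sim
N(0, \sigma_v^2)$ is unstructured heterogeneity, and $w$ carries spatial
dependence through the intrinsic conditional autoregressive (ICAR) prior

$$w_i \mid w_{-i} \sim N\!\big(\bar w_{\delta_i},\ \sigma_w^2 / n_{\delta_i}\big),$$

where $\delta_i$ is the set of contiguous neighbours and $n_{\delta_i}$
its size. Jointly this is the degenerate Gaussian with precision
$Q/\sigma_w^2$, $Q = D - A$ (degree matrix minus adjacency), which has
rank $n - c$ for $c$ connected components. Because the ICAR kernel is
invariant to adding a constant per component, we impose the usual
per-component sum-to-zero constraint on $w$ so that $\beta_0$ is
identified. Isolated areas (degree zero) have $w_i$ pinned at 0 and enter
only through $v_i$.

The precision $\phi$ is a single scalar. A heteroscedastic per-area
$\phi_i$ is a conceivable extension (the likelihood interface would accept
a vector); with one observation per area it is not identifiable without a
model for $\phi_i$, so constant precision is the minimal reading and the
only one implemented.

### Priors

Defaults emulate the flat defaults common in disease-mapping software and
are all overridable through `prior_spec()`:

| parameter | prior | default |
|---|---|---|
| $\beta_j$ | $N(0, sd)$ | sd = 31.62 (precision 0.001) |
| $\beta_0$ | flat | (improper; proper normal available) |
| $1/\sigma_w^2,\ 1/\sigma_v^2$ | Gamma(shape, rate) | (1, 5e-5) |
| $\phi$ | Gamma(shape, rate) | (1, 0.01) |

## Inference

Sampling is adaptive Metropolis-within-Gibbs, written in C++ for the inner
loops:

* scalar random-walk updates for $\beta_0$ and each $\beta_j$, with
  covariates centred internally (the chain works with
  $\beta_0^c = \beta_0 + \bar x'\beta$, which removes the strong
  intercept-slope coupling; draws are mapped back);
* single-site random-walk updates for each $w_i$ and $v_i$ on
  *alternating* sweeps — a deliberate mitigation of the well-known BYM
  random-walk stickiness between the two effect vectors;
* after every $w$ sweep the field is re-centred to the per-component
  sum-to-zero constraint, with the mean absorbed into the intercept. For a
  connected graph this leaves the linear predictor untouched and is exact
  under the flat intercept prior; under a proper intercept prior the
  neglected prior-density change per sweep is of order
  $|\bar w| \cdot |\beta_0| / sd^2 \approx 10^{-6}$ and is ignored;
* exact conjugate Gibbs draws for $\sigma_w^2$ and $\sigma_v^2$ (Gamma
  posteriors on the precisions given the fields);
* a joint rescaling move $(w, \sigma_w^2) \to (c\,w, c^2 \sigma_w^2)$
  (and similarly for $v$) whose ICAR/Gaussian kernels cancel exactly; this
  lets the field scale jump between regimes that the single-site updates
  traverse slowly, and was the difference between R-hat $\approx 1.6$ and
  R-hat $< 1.05$ at the default budget on 64-area problems;
* for connected graphs, a joint "shift" move $\beta_j \mathrel{+}= d$,
  $w \mathrel{-}= d\,x^c_j$ along the flat likelihood direction created by
  the confounding between a spatially smooth covariate and the ICAR field;
* a scalar random walk on $\log\phi$.

Proposal scales adapt by Robbins-Monro toward 0.44 acceptance during
burn-in only (`adapt_until <= n_burnin`), so the retained chain is
Markovian. All randomness flows through R's RNG: a run is bit-reproducible
from `mcmc_config(seed = )`.

Defaults are 4 chains of 20,000 iterations, 10,000 burn-in, thinning 5 —
about 3 seconds for 64 areas and one covariate on one core. Chains start
overdispersed: intercept at $\operatorname{logit}(\bar y)$ plus jitter,
coefficients jittered near 0, $w = v = 0$, variances log-uniform on
$[0.005, 0.5]$, and $\phi$ around its method-of-moments estimate. (Drawing
initial variances from the Gamma(1, 5e-5) precision prior itself would
start chains at absurd scales ~1e-5; the log-uniform range is
overdispersed around the scientifically plausible region instead.)

Convergence is monitored by split-$\widehat R$ and rank-normalized
effective sample size per scalar; a fit is flagged converged when every
monitored $\widehat R < 1.05$.

### What is and is not well identified

With a single proportion per area the data separate the *total*
area-level variability from the likelihood noise, but only weakly separate
$v$ from the beta sampling variation: $\sigma_v^2$ and $\phi$ trade off
against each other, and in simulation the $\sigma_v^2$ posterior
concentrates below truth while $\phi$ compensates. Predictions $\mu_i$,
coefficients and exceedance probabilities — the quantities reported — are
insensitive to this trade-off; interval coverage for $\sigma_v^2$ and
$\phi$ individually is poor and should not be over-interpreted. The same
simulation experiments show calibrated coverage and negligible bias for
the covariate coefficient (the inferential target).

## Reported quantities

* **Predictions** — posterior mean, SD and central 95% credible interval
  of each $\mu_i$, rendered in percent.
* **Exceedance probabilities** — $\Pr(\mu_i > t \mid y)$ as the fraction
  of retained draws above $t$; defaults $t \in \{0.70, 0.75\}$, the
  conventional high-burden screening thresholds, user-configurable.
* **Covariate significance** — a coefficient is flagged when its central
  95% credible interval excludes zero.
* **Overall prevalence** — the *unweighted* mean/min/max across areas, for
  both observed and predicted columns (no population weighting).
* **Cross-validation** — leave-one-out at area level: each refit drops
  area $i$'s likelihood term; its prevalence is predicted as
  $\operatorname{logit}^{-1}(\beta_0 + x_i'\beta + \bar w_{\delta_i})$
  using the ICAR conditional mean of its neighbours' sampled fields (0 for
  isolated areas) and the prior mean 0 for $v_i$. Predictive power is the
  Pearson correlation between observed and held-out predictions. This
  area-level LOOCV with spatial conditional-mean prediction is a
  reconstruction of "cross-validation" as commonly practised for areal
  models, not a replication of any specific published procedure. A fast
  mode subsamples folds.
* **Prediction SD** — the posterior SD of $\mu_i$ (not the
  back-transformed SD of the linear predictor, which is the other
  plausible reading).

## The synthetic-data generator

`generate_dataset()` runs the model generatively on a contiguity graph:
spatially smooth covariates are independent ICAR fields rescaled to a
stated percent mean and scale; $w$ is drawn by spectral decomposition of
$Q$ (independent normals with variance $\sigma_w^2/\lambda_j$ on the
non-null eigenvectors, which enforces the constraint by construction);
outcomes are beta draws. Draws within $10^{-6}$ of the boundary are
redrawn rather than clamped, preserving the open-interval support without
distorting the likelihood; configurations that saturate the mean for more
than 10% of areas are refused.

The default configuration is the package's reference study condition: an
8×8 rook lattice (n = 64, comparable to a 67-county state), one smooth
"sedentary" covariate (mean 25%, scale 5), true coefficient 0.023 per
percentage point, intercept set so prevalence centres near 68%,
$\sigma_w^2 = 0.05$, $\sigma_v^2 = 0.01$, $\phi = 200$. These values place
the simulations in the regime of a state-wide adult-obesity county
analysis: prevalence around 60–80%, a coefficient of a few hundredths per
percent, and spatial variance dominating unstructured variance.

What the generator deliberately does *not* emulate: survey sampling error
and weighting within areas (the observed proportion is treated as the
area's outcome, as in the data the model is designed for), covariate
measurement error, and irregular county geometry (unit squares stand in
for polygons). Passing tests on synthetic data therefore demonstrate
correctness of the inferential machinery under the model's own
assumptions, not robustness to their violation.

## Spatial structure

Queen contiguity (any shared boundary point) is the default polygon rule,
the common choice for US county maps; rook (shared segment of positive
length) is available. The computation is done directly on the supplied
coordinates with exact segment-intersection tests — contiguity is
projection-invariant for valid polygons, so no reprojection is attempted.
Geometry input is GeoJSON; repair is limited to closing rings and
dropping duplicate consecutive vertices. Where geometry is unavailable or
untrusted, a plain tab-separated edge list is a first-class input.

Numerical choices worth noting: the ICAR log density uses the
pairwise-difference kernel with rank $n - c$, each undirected edge counted
once; eigenvalues below $10^{-8}$ (relative) are treated as the null
space; the constraint is enforced to $10^{-8}$ and verified on every
retained draw in the tests.

## Validation strategy

The package is validated along two independent routes rather than against
its own code: dense grid integration of the exact posterior on a reduced
4-area model (v collapsed, $\phi$ and $\sigma_w^2$ fixed; 41×41×17³ grid
over a mode±6sd box located by BFGS) must agree with MCMC means and 95%
interval endpoints within 3 Monte-Carlo standard errors plus half a grid
step; and simulation-based calibration on the default fixture (25
replicates) must give 85–100% interval coverage and |mean bias| < 0.01 for
the covariate coefficient. Closed-form checks (beta survivor function for
exceedance, $\sigma_w^2 Q^+$ for the field sampler's covariance) and a
finite-difference score identity complete the surface. Problem sizes in
the test suite (n = 9 to 100, up to 25 replicates, 64 cross-validation
folds) were chosen so the full suite runs in minutes on one core while
keeping every check at its stated statistical tolerance.

## Maps

Static choropleths render to PNG (ggplot2) or to SVG through a direct
writer whose output is byte-deterministic given identical inputs — useful
for regression-testing figures. The interactive map is a single
self-contained HTML file (inline SVG and vanilla JavaScript, no network
access): hovering an area shows its name, observed and predicted
prevalence, the 95% interval bounds and each significant risk factor, all
to one decimal place. Class breaks are quantile-based with 5 classes by
default (explicit cut points supported) on a light-to-red palette, red
marking the highest burden; colour class is monotone in the mapped value
by construction.

## Known limitations

* One observation per area means $\sigma_v^2$ and $\phi$ are only jointly
  identified (see above).
* The intercept's flat prior relies on the likelihood for propriety; with
  zero covariates and an empty graph the model should be given a proper
  `beta0_sd`.
* LOOCV refits the model once per fold; for very large n use the fold
  subsampling argument.
* Shapefile input is not parsed; convert to GeoJSON or supply an edge
  list.
* Multi-component maps re-centre $w$ per component with a single global
  intercept absorption; for heavily fragmented graphs consider supplying
  per-component intercept covariates.
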