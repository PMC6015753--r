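---
title: "Bayesian tracer mixing models with tracermix: model, priors, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian tracer mixing models with tracermix}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

A mixing model estimates the proportional contributions $p_k$ of $K$
sources to a mixture from $J$ tracers (stable isotope ratios, fatty-acid
profiles, ...) measured on both. The core mass-balance assumption is that
the expected mixture value of tracer $j$ is the proportion-weighted
combination of the (discrimination-corrected) source means,
$\mathbb{E}[Y_{ij}] = \sum_k p_{ik}\,(\mu^s_{jk} + \lambda_{jk})$,
where $\lambda_{jk}$ is the trophic discrimination shift. With
concentration dependence the weights become
$q_{ikj} = p_{ik} c_{jk} / \sum_k p_{ik} c_{jk}$, so proportions reflect
elemental mass balance.

`tracermix` implements the three mixture error structures used across
this model family:

* **residual only**: $Y_{ij} \sim N(\cdot,\ \sigma_j^2)$ — variance
  unrelated to source spread; appropriate when each mixture datum
  integrates many source samples (composite/pooled sampling);
* **process only**: variance $\sum_k p_{ik}^2(\omega_{jk}^2 +
  \tau_{jk}^2)$ — each consumer takes one IID sample from each source, so
  source (and discrimination, $\tau$) variability propagates. Estimable
  only with a single mixture observation, and therefore auto-selected
  exactly then;
* **process × multiplicative**: the process variance scaled per tracer
  by $\xi_j$. $\xi_j < 1$ means consumers integrate over many prey items
  ("feeding at the mean" as $\xi_j \to 0$); $\xi_j \gg 1$ flags
  unmodelled structure (missing sources, unmodelled grouping, routing).
  This is the default and the recommended structure for consumer-diet
  data. We do not provide a separate additive residual+process
  structure: the multiplicative form subsumes it for our purposes.

Covariates act on the isometric log-ratio (ILR) scale. Per-individual
proportions are
$p_i = \mathrm{ilr}^{-1}(\beta_0 + \sum_m \beta_m x_{im} + \sum_r
\beta_{r,\ell(i)})$, with fixed categorical effects dummy-coded
(baseline = first level seen in the data), continuous covariates
centered and scaled to unit SD internally (sampler geometry; predictions
are reported on the raw covariate scale), and random-effect offsets
$\beta_{r,\ell} \sim N(0, \gamma_r^2)$ shared across ILR coordinates of
one factor. Comparing $\gamma_r^2$ across factors ranks their
importance to diet variability.

**ILR basis.** The basis is the fixed sequential binary partition in
source-input order: coordinate $t$ balances source $t$ against sources
$t+1..K$. Posterior proportions are invariant to this choice; ILR-space
coefficients are not, so coefficient tables must be read against this
basis. The inverse transform is $p = \mathrm{softmax}(Vz)$ with $V$ the
orthonormal basis matrix.

## Source-data treatments

* **raw**: per-sample source data; true means and variances are model
  parameters (fully Bayesian), and with `use_covariance = TRUE` full
  per-source tracer covariance matrices are estimated (multivariate
  normal source model).
* **summary**: mean/SD/$n$ per source; the model updates true means and
  variances through sufficient-statistic likelihoods: $\bar{x}_{kj} \sim
  N(\mu_{kj}, \omega_{kj}^2/n_k)$ and $(n_k-1)s^2_{kj}/\omega^2_{kj}
  \sim \chi^2_{n_k-1}$. (The chi-square form was a design choice; the
  literature leaves the exact sufficient-statistic density unstated.)
  Tracers are independent under this treatment — covariance cannot be
  recovered from summaries.
* **fixed**: means/SDs pinned at the inputs; reproduces the behaviour of
  the older fixed-source models and is approached by `summary` with
  $n \approx 10^4$ or more (a property the tests verify).

## Priors

* Source proportions: Dirichlet($\alpha$) on the *intercept*
  composition, default $\alpha = (1, \ldots, 1)$ — uniform on the
  simplex ("generalist"), but with non-uniform marginals that
  concentrate near 0 as $K$ grows; `prior_marginal_summary()` makes
  this visible, and we recommend plotting any prior before use.
  Informative priors built from auxiliary counts (stomach contents,
  prey surveys) can be rescaled to a chosen total weight while keeping
  the prior mean (`informative_prior_from_counts()`); rescaling to
  total weight $K$ matches the generalist prior's weight. How far to
  downweight such data for tissue-turnover mismatch is a judgment call;
  we expose `total_weight` and recommend sensitivity analysis rather
  than a default rule. Zero counts are an error, not a silent
  pseudo-count: priors are scientific claims.
* ILR coefficients: $N(0, 1000)$ (variance), diffuse on the transformed
  scale.
* Random-effect variances: $\gamma^2 \sim U(0, 20)$.
* Residual SDs: $\sigma_j \sim U(0, u_j)$ with $u_j$ defaulting to
  10× the observed data range (weakly informative on the SD scale).
* Multiplicative error: $\xi_j$ half-Cauchy with scale 1 — heavy-tailed
  on the positive line so both the $\xi \ll 1$ and $\xi \gg 1$ regimes
  are reachable; the family and scale are exposed in
  `variance_prior_spec()` because this choice is a package convention,
  not a published formula.
* Source means: $N(0, 1000^2)$; source precisions: Gamma(0.001, 0.001);
  covariance Cholesky factors: near-flat log-diagonals and $N(0, 100^2)$
  off-diagonals.

Because sampling happens in ILR space, the Dirichlet prior on the
intercept composition enters through the change of variables
$|\partial p/\partial z| = \sqrt{K}\prod_k p_k$; a dedicated test draws
from the prior with the likelihood disabled and checks the marginals
against the analytic Beta marginals by Kolmogorov–Smirnov.

## Sampling and diagnostics

The sampler is adaptive Metropolis-within-Gibbs over unconstrained
parameters (ILR coordinates, log-SDs, log-$\xi$), written in C++.
Componentwise random-walk steps adapt toward 44% acceptance during
burn-in only, so post-burn-in draws come from a fixed kernel. Because
the ILR intercept coordinates are often strongly correlated a
posteriori, each sweep adds one covariance-adaptive joint proposal over
the global composition block (intercept + fixed coefficients), with the
proposal covariance learned during burn-in (Haario-style) and frozen
afterwards. Partial-update caching makes error- and source-parameter
updates $O(N)$; random-effect offsets touch only their own rows.

Defaults are 3 chains × 100,000 iterations, 50,000 burn-in, thin 50 —
package defaults chosen to mirror common practice for this model family,
not a published prescription. Diagnostics are split-$\hat{R}$
(threshold 1.05, stricter than the common 1.1 — cheap insurance at desk
scale) and Geweke z-scores with batch-means standard errors; constant
parameters are reported as degenerate rather than dividing by zero.
Initialization is overdispersed: uniform-diet ILR coordinates plus
chain-specific jitter, variances at data-scale heuristics. Fits are
bit-reproducible given the seed.

`grid_posterior()` provides an exhaustive brute-force posterior for
K = 2, fixed-source, intercept-only models with $J \le 2$: given $p$,
the likelihood factorizes over tracers, so per-tracer nuisance
parameters ($\sigma_j$ or $\xi_j$) are marginalized by dense 1-D
quadrature on a log grid. It shares no code with the sampler and is the
oracle in the acceptance tests (total-variation distance < 0.02).

## Model comparison

The pointwise log-likelihood retained per draw contains one entry per
*consumer* (the joint density over tracers): the exchangeable unit is
the consumer, and models being compared differ only in mixture
structure, so source-data terms are excluded from the LOO matrix — a
documented choice the literature leaves implicit. `waic()` and
`psis_loo()` implement WAIC and Pareto-smoothed importance-sampling
LOO (tail = min(0.2 S, 3√S) ratios, Zhang–Stephens generalized-Pareto
fit, $k > 0.7$ flagged). `compare_models()` builds the relative-support
table: LOOic, SEs, differences vs the best model with paired pointwise
SEs, Akaike weights $w_m \propto e^{-\Delta_m/2}$, and per-tracer
posterior medians of $\xi_j$ (medians, since the choice between mean
and median is unstated in the sources we follow).

## Post-hoc analysis

* `combine_sources()` sums proportions draw-wise over groups, which
  preserves the correlation structure; it returns the aggregated prior
  alongside because combining $G$ sources under the generalist prior
  implicitly gives the combined group $G$ times the prior weight —
  users should inspect that prior before interpreting combined
  posteriors.
* `specialization_index()` is the normalized distance from the
  generalist barycenter, $\epsilon = \sqrt{\tfrac{K}{K-1}\sum_k (p_k -
  1/K)^2}$: 0 for a perfect generalist, 1 at any vertex. The external
  source that coined the index is cited rather than reproduced in the
  literature we follow; this form satisfies every property those
  analyses use and is flagged as an interpretation.
* `predict_proportions()` evaluates fitted proportion curves over a
  covariate grid (medians and credible bands); extrapolation beyond the
  observed range errors unless explicitly overridden.
* `calc_area()` reports the convex-hull area of discrimination-corrected
  source means in two-tracer space and the fraction of mixture points
  inside (boundary counts as inside; exact orientation predicates for
  determinism). Whether the original surface-area metric normalizes by
  source variance is ambiguous; we return the raw area and the inside
  fraction and leave normalization to the analyst.

## The synthetic-data generator

`simulation_scenario()` states a complete generative world — true diet
(global or covariate-linked), source populations, discrimination,
concentrations, error regime — and `simulate_sources()` /
`simulate_mixture()` draw from exactly the distributions the likelihood
assumes. `alligator_like_fixture()` emulates the structure of the
classic estuarine-consumer case study: 181 consumers, 2 sources
(freshwater/marine), 2 tracers (d13C/d15N), a strong ontogenetic Length
effect anchored at $p_{marine} = 0.09$ at 37.7 cm and $0.96$ at
315.5 cm (the published fitted-curve endpoints, used here as the stated
world), a null Sex effect, Length-binned size classes, individual
random offsets ($\gamma = 0.5$, a moderate value chosen once), realistic
estuarine isotope values, and $\xi = (5.3, 1.0)$ — the elevated carbon
value emulating unmodelled structure on that tracer.

What a green test on this fixture establishes: the full pipeline
(IO → fit → prediction → comparison) recovers the qualitative case-study
behaviours — monotone $p_{marine}$ vs Length, U-shaped specialization,
Length preferred by LOO, $\xi$ shrinking as covariates absorb
variability. What it does not establish: agreement with the published
numeric estimates, which require the published data file (not shipped;
real data never are in this package). Real data also bring features the
generator does not emulate: non-normal source distributions, tracer
covariance driven by shared physiology, measurement error correlated
with covariates, and missing sources.

## Numerical and design notes

* ILR boundary: compositions with any $p_k \le 0$ have no ILR image and
  error out; `inverse_ilr` subtracts the max coordinate before
  exponentiating, so extreme coordinates approach vertices without
  overflow.
* Process-only data at $N > 1$: acceptance testing simulates under the
  process-only story but fits the multiplicative model (truth nested at
  $\xi = 1$), since the process-only likelihood is defined only for a
  single mixture row.
* Concentration columns are proportions in (0, 1]; percentages must be
  divided by 100 before input.
* Test-suite MCMC runs are shortened relative to package defaults
  (typically 5–40k iterations vs 100k) purely for budget; replicate
  counts of the stated designs (50 coverage replicates, 50 ordering
  replicates, 10-seed LOO properties) are unchanged.
* Delimiter detection accepts comma and tab only, and factor levels
  order by first appearance — reproducibility over convenience.
* Known limitations: discrimination factors are inputs, never estimated
  (they are confounded with the proportions); systems with many more
  sources than tracers remain underdetermined and prior-sensitive (the
  Dirichlet prior grows more informative on marginals as $K$ grows —
  be cautious beyond ~7 sources); the polygon diagnostic is defined for
  exactly two tracers.

## A worked example

```{r, eval = FALSE}
library(tracermix)
fx <- alligator_like_fixture(seed = 4)
spec <- model_spec(error_spec("process_x_multiplicative"),
                   effect_design(fixed_continuous = "Length"))
f <- fit(spec, fx$mix, fx$src, fx$disc,
         mcmc_settings(n_chains = 3, n_iter = 12000, n_burn = 6000,
                       thin = 6, seed = 2))
convergence_diagnostics(f)
predict_proportions(f, list(Length = c(37.7, 116.9, 315.5)))
```
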