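# tracermix

Bayesian tracer mixing models for estimating proportional source
contributions to mixtures — most commonly, the composition of a
consumer's diet from stable isotope (or fatty-acid) data on the consumer
and its candidate prey. The package is aimed at trophic ecologists and
anyone partitioning a mixture with chemical tracers (pollutant sourcing,
sediment fingerprinting, nutrient transfer).

## The model

For consumer $i$ and tracer $j$, with sources $k = 1..K$:

$$Y_{ij} \sim N\Big(\sum_k p_{ik}\,(\mu^s_{jk} + \lambda_{jk}),\;\; v_{ij}\Big)$$

where $\lambda_{jk}$ are discrimination (trophic enrichment) factors and
the variance $v_{ij}$ follows one of three error structures:

| structure | $v_{ij}$ | use case |
|---|---|---|
| residual only | $\sigma_j^2$ | pooled/composite sampling |
| process only | $\sum_k p_{ik}^2(\omega^2_{jk} + \tau^2_{jk})$ | single mixture datum (auto-selected) |
| process × multiplicative | process variance $\times\ \xi_j$ | consumer-diet data (default) |

Proportions live on the simplex; covariates act through the isometric
log-ratio transform,
$p_i = \mathrm{ilr}^{-1}(\beta_0 + \beta_1 x_i + \beta_{\mathrm{group}(i)})$,
with fixed categorical, fixed continuous, and random (hierarchical)
effects. Priors: Dirichlet($\alpha$) on the intercept composition
(default generalist $\alpha = \mathbf{1}$, or rescaled count-based
informative priors), $N(0, 1000)$ ILR coefficients, $U(0, 20)$
random-effect variances, half-Cauchy $\xi_j$. Source data enter raw
(fully Bayesian, optional tracer covariance), as summary statistics, or
fixed. Posteriors are sampled by a built-in adaptive
Metropolis-within-Gibbs sampler (C++ core, seed-reproducible), and
models are compared with WAIC and PSIS-LOO plus Akaike weights.
Post-hoc tools: a-posteriori source combining (with the aggregated-prior
warning), the specialization index
$\epsilon = \sqrt{\tfrac{K}{K-1}\sum_k(p_k - 1/K)^2}$, fitted
proportion-vs-covariate curves, and the two-tracer mixing-polygon
diagnostic.

See `vignettes/tracer-mixing-models.Rmd` for the full model account and
design decisions.

## Worked example

Everything below is generated in code — no data files needed. The
synthetic fixture emulates a classic estuarine case study: 181
consumers, two sources (freshwater/marine), two tracers (d13C/d15N), an
ontogenetic diet shift with total length, and individual variation.

```r
library(tracermix)
fx <- alligator_like_fixture(seed = 4)

spec <- model_spec(error_spec("process_x_multiplicative"),
                   effect_design(fixed_continuous = "Length"))
f <- fit(spec, fx$mix, fx$src, fx$disc,
         mcmc_settings(n_chains = 3, n_iter = 12000, n_burn = 6000,
                       thin = 6, seed = 2))

f0 <- fit(model_spec(error_spec("process_x_multiplicative")),
          fx$mix, fx$src, fx$disc,
          mcmc_settings(n_chains = 3, n_iter = 12000, n_burn = 6000,
                        thin = 6, seed = 2))
compare_models(list(intercept = f0, Length = f))
#>       model    LOOic SE_LOOic   dLOOic SE_dLOOic       weight   xi_d13C  xi_d15N
#> 1    Length 1460.718 25.56928   0.0000        NA 1.000000e+00  6.023305 1.421130
#> 2 intercept 1708.017 29.50252 247.2997  25.37645 1.993227e-54 12.636049 3.536446

predict_proportions(f, list(Length = c(37.7, 116.9, 315.5)))$quantiles[, "marine", 2]
#> 0.09932828 0.34769549 0.96492022
```

Reading the output: the Length model is decisively preferred by LOO
(lower LOOic, all the Akaike weight), and the multiplicative error
terms shrink when Length absorbs diet variability (xi_d13C 12.6 → 6.0) —
the diagnostic signature of a covariate that explains real structure.
The fitted marine proportion rises monotonically from ~0.10 for the
smallest animal to ~0.96 for the largest, recovering the truth the
fixture was generated from (0.09 → 0.96).

## Command line

```sh
inst/cli/tracermix simulate --seed 2 --out data/
inst/cli/tracermix fit --config run.yaml
inst/cli/tracermix summarize --archive out/
inst/cli/tracermix compare --archives out_a,out_b
```

A run config (YAML or JSON) names the data files, tracers, covariates,
model options, and MCMC settings; `run()` writes a draws archive with a
manifest from which every output is regenerable.

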