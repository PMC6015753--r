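test_that("mixture_mean handles vertices, discrimination, and concentration", {
  mu <- matrix(c(-20, -10), 2, 1)
  expect_equal(mixture_mean(c(1, 0), mu), -20)
  lam <- matrix(1, 2, 1)
  expect_equal(mixture_mean(c(0.5, 0.5), mu, lam), -14)
  # equal concentrations cancel
  conc <- matrix(0.3, 2, 1)
  expect_equal(mixture_mean(c(0.7, 0.3), mu, NULL, conc),
               mixture_mean(c(0.7, 0.3), mu))
  # unequal concentrations reweight: p=(.5,.5), c=(.2,.8) -> q=(.2,.8)
  conc2 <- matrix(c(0.2, 0.8), 2, 1)
  expect_equal(mixture_mean(c(0.5, 0.5), mu, NULL, conc2),
               0.2 * -20 + 0.8 * -10)
})

test_that("mixture_scale implements the three error structures", {
  sds <- matrix(sqrt(c(4, 8)), 2, 1)
  # hand evaluation: 0.25*4 + 0.25*8 = 3; x xi=2 -> 6
  expect_equal(mixture_scale(c(0.5, 0.5), sds, error = "process_only"), 3)
  expect_equal(mixture_scale(c(0.5, 0.5), sds, error = "process_x_multiplicative",
                             xi = 2), 6)
  # xi = 1 collapses to the process-only variance
  expect_equal(mixture_scale(c(0.3, 0.7), sds, error = "process_x_multiplicative",
                             xi = 1),
               mixture_scale(c(0.3, 0.7), sds, error = "process_only"))
  # vertex with no discrimination SD: source variance times xi
  expect_equal(mixture_scale(c(1, 0), sds, error = "process_x_multiplicative",
                             xi = 3), 12)
  # residual error ignores source variances entirely
  expect_equal(mixture_scale(c(0.5, 0.5), sds, error = "residual_only",
                             sigma = 1.5), 2.25)
  expect_equal(mixture_scale(c(0.9, 0.1), sds * 10, error = "residual_only",
                             sigma = 1.5), 2.25)
  # discrimination SD adds inside the proportion-squared weighting
  tau <- matrix(c(1, 2), 2, 1)
  expect_equal(mixture_scale(c(0.5, 0.5), sds, tau, error = "process_only"),
               0.25 * (4 + 1) + 0.25 * (8 + 4))
})

test_that("covariance mode with diagonal source covariances equals independent mode", {
  set.seed(20)
  sds <- matrix(runif(6, 0.5, 2), 3, 2)
  tau <- matrix(runif(6, 0, 0.5), 3, 2)
  p <- c(0.2, 0.5, 0.3)
  covs <- lapply(1:3, function(k) diag(sds[k, ]^2, 2))
  v_ind <- mixture_scale(p, sds, tau, error = "process_x_multiplicative",
                         xi = c(2, 0.5))
  v_cov <- mixture_scale(p, sds, tau, error = "process_x_multiplicative",
                         xi = c(2, 0.5), source_covs = covs)
  expect_equal(diag(v_cov), v_ind, tolerance = 1e-12)
  expect_equal(v_cov[1, 2], 0)
})

test_that("individual proportions: intercept-only, null effects, monotone continuous", {
  set.seed(21)
  mix <- mixture_data(matrix(rnorm(40), 20, 2),
                      fixed_factors = list(Sex = rep(c("F", "M"), 10)),
                      continuous_covariates = list(Len = sort(runif(20, 1, 10))))
  b0 <- c(0.4, -0.2)
  # no effects: all rows identical to inverse_ilr(beta0)
  P0 <- individual_proportions(list(ilr_intercept = b0), effect_design(), mix)
  expect_equal(P0, matrix(rep(inverse_ilr(b0), each = 20), 20, 3))
  # binary effect with zero coefficient: groups identical
  Pn <- individual_proportions(
    list(ilr_intercept = b0, fixed_coefficients = list(SexM = c(0, 0))),
    effect_design(fixed_categorical = "Sex"), mix)
  expect_equal(Pn, P0)
  # continuous effect: ILR coordinates monotone along the covariate
  Pl <- individual_proportions(
    list(ilr_intercept = b0, fixed_coefficients = list(Len = c(0.8, 0.3))),
    effect_design(fixed_continuous = "Len"), mix)
  Z <- ilr_transform(Pl)
  expect_true(all(diff(Z[, 1]) > 0))
  expect_true(all(diff(Z[, 2]) > 0))
  expect_equal(rowSums(Pl), rep(1, 20))
})

test_that("pointwise log-likelihood matches direct normal evaluation and invariants", {
  src <- source_data("fixed", matrix(c(-20, -10), 2, 1), matrix(c(1, 2), 2, 1),
                     c(10L, 10L), tracer_names = "x")
  disc <- zero_discrimination(src)
  p <- c(0.5, 0.5)
  st <- list(ilr_intercept = ilr_transform(p), xi = 1.3)
  mval <- mixture_mean(p, src$means)
  v <- mixture_scale(p, src$sds, error = "process_x_multiplicative", xi = 1.3)
  # single consumer sitting exactly at the mixture mean
  mix1 <- mixture_data(matrix(mval, 1, 1), tracer_names = "x")
  spec1 <- model_spec(error_spec("process_x_multiplicative"))
  st1 <- list(ilr_intercept = ilr_transform(p))
  ll1 <- suppressMessages(
    log_likelihood_pointwise(st1, spec1, mix1, src, disc))  # auto process_only
  v1 <- mixture_scale(p, src$sds, error = "process_only")
  expect_equal(ll1$mixture, unname(-0.5 * log(2 * pi * v1)))
  # doubling xi at a vertex changes the density by the closed-form scale change
  pv <- c(1 - 1e-12, 1e-12)
  stv <- function(xi) list(ilr_intercept = ilr_transform(pv), xi = xi)
  mixv <- mixture_data(matrix(-19, 2, 1), tracer_names = "x")
  spec <- model_spec(error_spec("process_x_multiplicative"))
  ll_a <- log_likelihood_pointwise(stv(2), spec, mixv, src, disc)$mixture[1]
  ll_b <- log_likelihood_pointwise(stv(4), spec, mixv, src, disc)$mixture[1]
  var_a <- 2 * 1^2                       # p ~ vertex: source 1 variance x xi
  expect_equal(ll_b - ll_a,
               dnorm(-19, -20, sqrt(2 * var_a), log = TRUE) -
                 dnorm(-19, -20, sqrt(var_a), log = TRUE), tolerance = 1e-6)
  # residual-only likelihood is invariant to source variances
  mixN <- mixture_data(matrix(rnorm(5, -15), 5, 1), tracer_names = "x")
  str <- list(ilr_intercept = ilr_transform(p), residual_sd = 2)
  spec_r <- model_spec(error_spec("residual_only"))
  ll_r1 <- log_likelihood_pointwise(str, spec_r, mixN, src, disc)
  src_inflated <- source_data("fixed", src$means, src$sds * 7, src$sample_sizes,
                              tracer_names = "x")
  ll_r2 <- log_likelihood_pointwise(str, spec_r, mixN, src_inflated, disc)
  expect_equal(ll_r1$mixture, ll_r2$mixture)
})

test_that("fixed treatment matches summary treatment at pinned source state", {
  b <- oracle_bundle(seed = 31, N = 8L)
  src_sum <- source_data("summary", b$src$means, b$src$sds, c(1000000L, 1000000L),
                         source_names = b$src$source_names,
                         tracer_names = b$src$tracer_names)
  disc <- zero_discrimination(b$src)
  st <- list(ilr_intercept = c(0.3), xi = c(1.2, 0.9),
             source_means = b$src$means, source_sds = b$src$sds)
  spec <- model_spec(error_spec("process_x_multiplicative"))
  ll_fix <- log_likelihood_pointwise(st, spec, b$mix, b$src, disc)
  ll_sum <- log_likelihood_pointwise(st, spec, b$mix, src_sum, disc)
  expect_lt(max(abs(ll_fix$mixture - ll_sum$mixture)), 1e-3)
})

test_that("model validation enforces the error-structure and flag invariants", {
  b <- oracle_bundle(seed = 32, N = 5L)
  disc <- zero_discrimination(b$src)
  expect_error(
    tracermix:::validate_model(model_spec(error_spec("process_only")),
                               b$mix, b$src, disc),
    "single")
  expect_error(
    tracermix:::validate_model(model_spec(use_covariance = TRUE),
                               b$mix, b$src, disc),
    "raw source treatment")
  expect_error(
    tracermix:::validate_model(model_spec(use_concentration = TRUE),
                               b$mix, b$src, disc),
    "concentrations")
  expect_error(
    tracermix:::validate_model(
      model_spec(effects = effect_design(fixed_continuous = "nope")),
      b$mix, b$src, disc),
    "unknown covariate")
})

test_that("C++ and R likelihood implementations agree across configurations", {
  configs <- list(
    list(kind = "process_x_multiplicative", treat = "summary", conc = FALSE),
    list(kind = "residual_only", treat = "summary", conc = FALSE),
    list(kind = "process_x_multiplicative", treat = "raw", conc = FALSE),
    list(kind = "process_x_multiplicative", treat = "fixed", conc = TRUE)
  )
  set.seed(909)
  for (cf in configs) {
    scen <- simulation_scenario(
      K = 3L, J = 2L, N = 12L, p = c(0.4, 0.4, 0.2),
      source_means = rbind(c(-24, 4), c(-16, 11), c(-10, 17)),
      source_sds = matrix(1, 3, 2), source_n = c(15L, 15L, 15L),
      concentrations = if (cf$conc) matrix(runif(6, 0.1, 0.9), 3, 2) else NULL,
      error_kind = cf$kind,
      sigma = if (cf$kind == "residual_only") c(1, 1.2) else NULL,
      xi = if (cf$kind == "process_x_multiplicative") c(1.5, 0.7) else NULL,
      seed = 77)
    src <- simulate_sources(scen, if (cf$treat == "raw") "raw" else "summary")
    if (cf$treat == "fixed") src <- as_fixed_sources(src)
    mix <- simulate_mixture(scen)
    spec <- model_spec(error_spec(cf$kind), use_concentration = cf$conc)
    f <- fit(spec, mix, src, NULL,
             mcmc_settings(n_chains = 1L, n_iter = 60L, n_burn = 30L, thin = 3L,
                           seed = 4L))
    for (s in c(1L, nrow(f$draws))) {
      st <- tracermix:::draw_state(f, s)
      ll <- log_likelihood_pointwise(st, spec, mix, src, f$disc)
      expect_equal(ll$mixture, unname(f$loglik[s, ]), tolerance = 1e-10,
                   info = paste(cf$kind, cf$treat))
    }
  }
})

test_that("covariance-mode sampler agrees with the R multivariate likelihood", {
  scen <- simulation_scenario(
    K = 2L, J = 2L, N = 10L, p = c(0.6, 0.4),
    source_means = rbind(c(-24, 4), c(-14, 12)),
    source_sds = rbind(c(1.2, 1), c(1, 0.8)),
    source_cor = matrix(c(1, 0.6, 0.6, 1), 2, 2),
    source_n = c(20L, 20L),
    error_kind = "process_x_multiplicative", xi = c(1, 1), seed = 55)
  src <- simulate_sources(scen, "raw")
  mix <- simulate_mixture(scen)
  spec <- model_spec(error_spec("process_x_multiplicative"), use_covariance = TRUE)
  f <- fit(spec, mix, src, NULL,
           mcmc_settings(n_chains = 1L, n_iter = 100L, n_burn = 50L, thin = 5L,
                         seed = 8L))
  st <- tracermix:::draw_state(f, nrow(f$draws))
  ll <- log_likelihood_pointwise(st, spec, mix, src, f$disc)
  expect_equal(ll$mixture, unname(f$loglik[nrow(f$draws), ]), tolerance = 1e-10)
})
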