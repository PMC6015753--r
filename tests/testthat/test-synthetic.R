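test_that("scenario + seed fixes every draw bit-identically", {
  scen <- recovery_scenario("process_x_multiplicative", seed = 200)
  expect_identical(simulate_sources(scen, "raw")$raw_samples,
                   simulate_sources(scen, "raw")$raw_samples)
  m1 <- simulate_mixture(scen); m2 <- simulate_mixture(scen)
  expect_identical(m1$values, m2$values)
  expect_identical(attr(m1, "truth"), attr(m2, "truth"))
  scen2 <- recovery_scenario("process_x_multiplicative", seed = 201)
  expect_false(identical(simulate_mixture(scen2)$values, m1$values))
})

test_that("simulated sources respect their population parameters", {
  scen <- simulation_scenario(
    K = 2L, J = 2L, N = 5L, p = c(0.5, 0.5),
    source_means = rbind(c(-20, 5), c(-10, 12)),
    source_sds = rbind(c(1e-12, 1e-12), c(2, 1)),
    source_cor = matrix(c(1, 0.7, 0.7, 1), 2, 2),
    source_n = c(4L, 4000L), error_kind = "process_only", seed = 210)
  src <- simulate_sources(scen, "raw")
  # (near-)zero SD: all samples at the mean
  expect_lt(max(abs(sweep(src$raw_samples[[1]], 2, c(-20, 5)))), 1e-9)
  # LLN: large-n sample means within 3*omega/sqrt(n) of truth
  expect_lt(abs(src$means[2, 1] - (-10)), 3 * 2 / sqrt(4000))
  expect_lt(abs(src$means[2, 2] - 12), 3 * 1 / sqrt(4000))
  # correlated tracers recover the target correlation
  expect_equal(cor(src$raw_samples[[2]])[1, 2], 0.7, tolerance = 0.05)
  # summary mode reports exact sample statistics of the same draws
  src_s <- simulate_sources(scen, "summary")
  expect_identical(src_s$means, src$means)
  expect_identical(src_s$sds, src$sds)
})

test_that("mixture generator limits: feeding at the mean, vertex diets, monotone covariate response", {
  base <- list(K = 2L, J = 1L, N = 40L,
               source_means = matrix(c(-20, -10), 2, 1),
               source_sds = matrix(1, 2, 1), source_n = c(10L, 10L))
  # xi -> 0: consumers collapse onto the weighted source mean
  scen0 <- do.call(simulation_scenario,
                   c(base, list(p = c(0.3, 0.7), xi = 1e-8, seed = 220)))
  m0 <- simulate_mixture(scen0)
  expect_lt(max(abs(m0$values - (0.3 * -20 + 0.7 * -10))), 1e-2)
  # vertex diet: consumers distributed as source 1 (shifted by discrimination)
  base2 <- base; base2$N <- 4000L
  scen1 <- do.call(simulation_scenario,
                   c(base2, list(p = c(1 - 1e-12, 1e-12),
                                 disc_means = matrix(2, 2, 1),
                                 error_kind = "process_only", seed = 221)))
  m1 <- simulate_mixture(scen1)
  expect_equal(mean(m1$values), -18, tolerance = 0.1)
  expect_equal(sd(m1$values), 1, tolerance = 0.05)
  # a covariate-linked diet makes consumer tracer means monotone in the covariate
  scen2 <- simulation_scenario(
    K = 2L, J = 1L, N = 400L, p = c(0.5, 0.5),
    source_means = matrix(c(-20, -10), 2, 1), source_sds = matrix(0.5, 2, 1),
    source_n = c(10L, 10L), error_kind = "process_x_multiplicative",
    xi = 0.05, continuous = list(L = list(range = c(0, 10), beta = -1.2)),
    seed = 222)
  m2 <- simulate_mixture(scen2)
  o <- order(m2$continuous_covariates$L)
  smoothed <- stats::filter(m2$values[o, 1], rep(1 / 50, 50))
  expect_gt(cor(m2$continuous_covariates$L, m2$values[, 1]), 0.9)
  expect_true(all(diff(na.omit(as.numeric(smoothed))) > -0.5))
})

test_that("generative and likelihood stories agree (entropy check per error kind)", {
  for (kind in c("residual_only", "process_x_multiplicative")) {
    scen <- recovery_scenario(kind, seed = 230, N = 2000L,
                              xi = c(0.7, 2), sigma = c(0.9, 1.4))
    src <- as_fixed_sources(simulate_sources(scen, "summary"))
    mix <- simulate_mixture(scen)
    # evaluate the true parameters under the model likelihood, but with the
    # *population* source parameters the generator actually used
    src_pop <- source_data("fixed", scen$source_means, scen$source_sds,
                           scen$source_n,
                           source_names = src$source_names,
                           tracer_names = src$tracer_names)
    st <- list(ilr_intercept = scen$ilr_intercept,
               residual_sd = scen$sigma, xi = scen$xi)
    ll <- log_likelihood_pointwise(st, model_spec(error_spec(kind)), mix,
                                   src_pop, zero_discrimination(src_pop))
    # E[-log f] per observation = 0.5*sum_j log(2*pi*e*v_j)
    p <- scen$p
    v <- sapply(1:2, function(j) {
      if (kind == "residual_only") scen$sigma[j]^2
      else sum(p^2 * scen$source_sds[, j]^2) * scen$xi[j]
    })
    entropy <- -0.5 * sum(log(2 * pi * exp(1) * v))
    expect_equal(mean(ll$mixture), entropy, tolerance = 0.05,
                 info = kind)
  }
})

test_that("alligator-like fixture has the case-study structure", {
  fx <- alligator_like_fixture(seed = 5)
  expect_equal(nrow(fx$mix$values), 181L)
  expect_equal(ncol(fx$mix$values), 2L)
  expect_equal(fx$src$source_names, c("freshwater", "marine"))
  expect_equal(fx$mix$tracer_names, c("d13C", "d15N"))
  expect_equal(range(fx$mix$continuous_covariates$Length), c(37.7, 315.5))
  expect_equal(nlevels(fx$mix$fixed_factors$Sex), 2L)
  expect_equal(nlevels(fx$mix$fixed_factors$`Size class`), 4L)
  expect_equal(nlevels(fx$mix$random_factors$Individual), 181L)
  # truth recorded for recovery tests
  expect_equal(dim(fx$truth$p_individual), c(181L, 2L))
  expect_identical(alligator_like_fixture(seed = 5)$mix$values, fx$mix$values)
})

test_that("LOO prefers the Length model under a strong true Length effect (9/10 seeds)", {
  st <- mcmc_settings(n_chains = 2L, n_iter = 5000L, n_burn = 2500L, thin = 5L,
                      seed = 13L)
  wins <- 0L
  for (s in 1:10) {
    fx <- alligator_like_fixture(seed = 300L + s, n_consumers = 90L)
    f0 <- fit(model_spec(error_spec("process_x_multiplicative")),
              fx$mix, fx$src, fx$disc, st)
    fL <- fit(model_spec(error_spec("process_x_multiplicative"),
                         effect_design(fixed_continuous = "Length")),
              fx$mix, fx$src, fx$disc, st)
    wins <- wins + (psis_loo(fL$loglik)$looic < psis_loo(f0$loglik)$looic)
  }
  expect_gte(wins, 9L)
})

test_that("LOO never credits a null Sex effect by more than 2 (10 seeds)", {
  st <- mcmc_settings(n_chains = 2L, n_iter = 5000L, n_burn = 2500L, thin = 5L,
                      seed = 14L)
  ok <- TRUE
  for (s in 1:10) {
    fx <- alligator_like_fixture(seed = 400L + s, n_consumers = 90L)
    fL <- fit(model_spec(error_spec("process_x_multiplicative"),
                         effect_design(fixed_continuous = "Length")),
              fx$mix, fx$src, fx$disc, st)
    fLS <- fit(model_spec(error_spec("process_x_multiplicative"),
                          effect_design(fixed_continuous = "Length",
                                        fixed_categorical = "Sex")),
               fx$mix, fx$src, fx$disc, st)
    gain <- psis_loo(fL$loglik)$looic - psis_loo(fLS$loglik)$looic
    ok <- ok && (gain <= 2)
  }
  expect_true(ok)
})
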