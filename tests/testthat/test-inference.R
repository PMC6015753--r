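test_that("mcmc settings validate and fits are bit-reproducible under a seed", {
  expect_error(mcmc_settings(n_iter = 100, n_burn = 100), "exceed")
  expect_error(mcmc_settings(n_iter = 100, n_burn = 50, thin = 60), "thin")
  b <- oracle_bundle(seed = 1, N = 6L)
  spec <- model_spec(error_spec("process_x_multiplicative"))
  st <- mcmc_settings(n_chains = 2L, n_iter = 400L, n_burn = 200L, thin = 2L,
                      seed = 99L)
  f1 <- fit(spec, b$mix, b$src, NULL, st)
  f2 <- fit(spec, b$mix, b$src, NULL, st)
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$loglik, f2$loglik)
  f3 <- fit(spec, b$mix, b$src, NULL,
            mcmc_settings(n_chains = 2L, n_iter = 400L, n_burn = 200L, thin = 2L,
                          seed = 100L))
  expect_false(identical(f1$draws, f3$draws))
})

test_that("a single consumer auto-selects the process-only error structure", {
  b <- oracle_bundle(seed = 2, N = 1L)
  expect_message(
    f <- fit(model_spec(error_spec("process_x_multiplicative")), b$mix, b$src,
             NULL, mcmc_settings(n_chains = 2L, n_iter = 400L, n_burn = 200L,
                                 thin = 2L, seed = 3L)),
    "process-only")
  expect_equal(f$spec$error$kind, "process_only")
  expect_false(any(grepl("log_xi", colnames(f$draws))))
})

test_that("convergence diagnostics: null case, split detector, degenerate guard", {
  set.seed(50)
  null_chains <- lapply(1:3, function(i) {
    matrix(rnorm(4000), 2000, 2, dimnames = list(NULL, c("a", "b")))
  })
  d <- convergence_diagnostics(null_chains)
  expect_true(all(abs(d$rhat - 1) < 0.01))
  expect_true(attr(d, "pass"))
  # chains centered at different values are flagged hard
  shifted <- list(matrix(rnorm(1000), ncol = 1), matrix(rnorm(1000, 5), ncol = 1))
  d2 <- convergence_diagnostics(shifted)
  expect_gt(d2$rhat[1], 2)
  expect_false(attr(d2, "pass"))
  # constant draws are reported degenerate, not NaN
  const <- list(matrix(1, 100, 1), matrix(1, 100, 1))
  d3 <- convergence_diagnostics(const)
  expect_true(d3$degenerate[1])
  expect_false(d3$flagged[1])
  expect_warning(convergence_diagnostics(matrix(rnorm(100), ncol = 1)),
                 "single chain")
})

test_that("posterior_summary gives closed-form quantiles on known draws", {
  set.seed(51)
  u <- matrix(runif(200000), ncol = 1, dimnames = list(NULL, "u"))
  s <- posterior_summary(u)
  expect_equal(s$q0.025, 0.025, tolerance = 0.005)
  expect_equal(s$q0.975, 0.975, tolerance = 0.005)
  expect_equal(s$mean, s$q0.500, tolerance = 0.005)
})

test_that("prior recovery: with the likelihood disabled, p marginals match the Dirichlet prior", {
  scen <- recovery_scenario("process_x_multiplicative", seed = 61, N = 20L)
  src <- simulate_sources(scen, "summary")
  mix <- simulate_mixture(scen)
  alpha <- c(1, 1, 1)
  f <- fit(model_spec(error_spec("process_x_multiplicative"),
                      prior = dirichlet_prior(alpha)),
           mix, as_fixed_sources(src), NULL,
           mcmc_settings(n_chains = 3L, n_iter = 130000L, n_burn = 10000L,
                         thin = 7L, seed = 6L),
           likelihood_off = TRUE)
  P <- p_global_draws(f)
  expect_gt(nrow(P), 50000)
  # marginal of p_1 under Dirichlet(1,1,1) is Beta(1, 2)
  ks <- suppressWarnings(stats::ks.test(P[, 1], "pbeta", 1, 2))
  expect_gt(ks$p.value, 0.01)
  expect_equal(unname(colMeans(P)), rep(1 / 3, 3), tolerance = 0.02)
})

test_that("grid posterior: flat likelihood returns the Beta prior; vertex data recover the vertex", {
  # identical sources + residual error -> likelihood carries no information
  # about p, so the posterior equals the Beta(1, 1) prior
  set.seed(70)
  src_same <- source_data("fixed", matrix(c(-15, -15), 2, 1),
                          matrix(c(1, 1), 2, 1), c(10L, 10L), tracer_names = "x")
  mix <- mixture_data(matrix(rnorm(8, -15), 8, 1), tracer_names = "x")
  g <- grid_posterior(model_spec(error_spec("residual_only")), mix, src_same)
  mass <- as.numeric(tapply(g$density, rep(1:10, each = length(g$p1) / 10), sum))
  expect_equal(mass, rep(0.1, 10), tolerance = 1e-8)
  # strongly separated sources, mixture at source 1's mean
  src_sep <- source_data("fixed", matrix(c(-25, -5), 2, 1),
                         matrix(c(0.5, 0.5), 2, 1), c(10L, 10L),
                         tracer_names = "x")
  mix1 <- mixture_data(matrix(rep(-25, 6), 6, 1), tracer_names = "x")
  g1 <- grid_posterior(model_spec(error_spec("process_x_multiplicative")),
                       mix1, src_sep)
  expect_gt(sum(g1$density[g1$p1 > 0.9]), 0.95)
  expect_error(grid_posterior(model_spec(), mix1,
                              source_data("fixed", matrix(-15, 3, 1) + 0:2,
                                          matrix(1, 3, 1), rep(5L, 3),
                                          tracer_names = "x")),
               "K = 2")
})

test_that("MCMC matches the grid oracle for residual-only error too", {
  b <- oracle_bundle(seed = 71, error_kind = "residual_only", N = 12L, J = 1L)
  spec <- model_spec(error_spec("residual_only"))
  g <- grid_posterior(spec, b$mix, b$src)
  f <- fit(spec, b$mix, b$src, NULL,
           mcmc_settings(n_chains = 3L, n_iter = 30000L, n_burn = 6000L,
                         thin = 2L, seed = 5L))
  expect_lt(tv_distance(p_global_draws(f)[, 1], g), 0.02)
})

test_that("intercept-only posterior mean lands within 3 posterior SDs of truth", {
  scen <- recovery_scenario("process_x_multiplicative", seed = 81, N = 150L)
  src <- simulate_sources(scen, "summary")
  mix <- simulate_mixture(scen)
  f <- fit(model_spec(error_spec("process_x_multiplicative")), mix, src, NULL,
           test_settings(seed = 7L))
  P <- p_global_draws(f)
  for (k in 1:3) {
    expect_lt(abs(mean(P[, k]) - scen$p[k]), 3 * sd(P[, k]))
  }
})

test_that("variance partitioning orders two random-effect SDs correctly", {
  # gamma_A >> gamma_B must be recovered in at least 45/50 replicates
  correct <- 0L
  for (r in 1:50) {
    scen <- simulation_scenario(
      K = 3L, J = 2L, N = 90L, p = c(0.4, 0.35, 0.25),
      source_means = rbind(c(-24, 4), c(-16, 11), c(-10, 17)),
      source_sds = matrix(1, 3, 2), source_n = c(25L, 25L, 25L),
      error_kind = "process_x_multiplicative", xi = c(1, 1),
      random_factors = list(A = list(L = 10L, gamma = 1.6),
                            B = list(L = 6L, gamma = 0.25)),
      seed = 500L + r)
    src <- as_fixed_sources(simulate_sources(scen, "summary"))
    mix <- simulate_mixture(scen)
    f <- fit(model_spec(error_spec("process_x_multiplicative"),
                        effect_design(random = c("A", "B"))),
             mix, src, NULL,
             mcmc_settings(n_chains = 2L, n_iter = 6000L, n_burn = 3000L,
                           thin = 6L, seed = r))
    gA <- median(exp(f$draws[, "log_gamma_A"]))
    gB <- median(exp(f$draws[, "log_gamma_B"]))
    correct <- correct + (gA > gB)
  }
  expect_gte(correct, 45L)
})
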