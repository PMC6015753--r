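# Shared fixture builders: everything is generated in code, no data files.

# Well-separated 3-source, 2-tracer scenario used by recovery tests.
recovery_scenario <- function(error_kind, seed, N = 200L, xi = c(1, 1),
                              sigma = c(0.8, 0.8), p = c(0.5, 0.3, 0.2)) {
  simulation_scenario(
    K = 3L, J = 2L, N = N, p = p,
    source_means = rbind(c(-24, 4), c(-16, 11), c(-10, 17)),
    source_sds = matrix(1, 3, 2), source_n = c(25L, 25L, 25L),
    error_kind = error_kind,
    sigma = if (error_kind == "residual_only") sigma else NULL,
    xi = if (error_kind == "process_x_multiplicative") xi else NULL,
    seed = seed
  )
}

# Tiny two-source fixed-source bundle for oracle comparisons.
oracle_bundle <- function(seed, error_kind = "process_x_multiplicative",
                          N = 10L, J = 2L, xi = c(1.5, 0.8), sigma = c(1, 1.2)) {
  scen <- simulation_scenario(
    K = 2L, J = J, N = N, p = c(0.6, 0.4),
    source_means = matrix(c(-24, -14, 5, 12), 2, 2)[, seq_len(J), drop = FALSE],
    source_sds = matrix(c(1.2, 1, 1, 0.8), 2, 2)[, seq_len(J), drop = FALSE],
    source_n = c(10000L, 10000L),
    error_kind = error_kind,
    sigma = if (error_kind == "residual_only") sigma[seq_len(J)] else NULL,
    xi = if (error_kind == "process_x_multiplicative") xi[seq_len(J)] else NULL,
    seed = seed
  )
  list(scen = scen,
       src = as_fixed_sources(simulate_sources(scen, "summary")),
       mix = simulate_mixture(scen))
}

# Short-but-adequate MCMC settings for tests (documented scaling of the
# package defaults to fit the suite budget; see the methods vignette).
test_settings <- function(seed, n_iter = 8000L, n_burn = 4000L, thin = 4L,
                          n_chains = 3L) {
  mcmc_settings(n_chains = n_chains, n_iter = n_iter, n_burn = n_burn,
                thin = thin, seed = seed)
}

# Random simplex points (for ILR property tests).
random_simplex <- function(n, K) {
  x <- matrix(stats::rexp(n * K), n, K)
  x / rowSums(x)
}
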