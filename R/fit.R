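#' MCMC run settings
#'
#' Defaults mirror a "normal" production run length for this model
#' family: 3 chains of 100,000 iterations, 50,000 burn-in, thinned by 50
#' (1,000 saved draws per chain). Step sizes adapt toward a 0.44
#' acceptance rate during burn-in only and are frozen afterwards, so the
#' saved draws come from a valid (non-adaptive) Markov chain.
#'
#' @param n_chains number of chains (>= 3 recommended; >= 2 needed for
#'   split-Rhat).
#' @param n_iter iterations per chain.
#' @param n_burn burn-in iterations per chain (`< n_iter`).
#' @param thin keep every `thin`-th post-burn-in iteration.
#' @param seed integer seed fixing the full draw sequence.
#' @param adapt_batch step-size adaptation window (iterations).
#' @return an object of class `mcmc_settings`.
#' @export
mcmc_settings <- function(n_chains = 3L, n_iter = 100000L, n_burn = 50000L,
                          thin = 50L, seed = 1L, adapt_batch = 50L) {
  n_chains <- as.integer(n_chains); n_iter <- as.integer(n_iter)
  n_burn <- as.integer(n_burn); thin <- as.integer(thin)
  if (n_chains < 1L) stop("need at least one chain", call. = FALSE)
  if (n_iter <= n_burn) stop("n_iter must exceed n_burn", call. = FALSE)
  if (thin < 1L || (n_iter - n_burn) < thin) {
    stop("thin must be positive and leave at least one saved draw", call. = FALSE)
  }
  structure(list(n_chains = n_chains, n_iter = n_iter, n_burn = n_burn,
                 thin = thin, seed = as.integer(seed),
                 adapt_batch = as.integer(adapt_batch)),
            class = "mcmc_settings")
}

error_kind_code <- c(residual_only = 0L, process_only = 1L,
                     process_x_multiplicative = 2L)
treat_code <- c(fixed = 0L, summary = 1L, raw = 2L)

# Assemble everything the C++ sampler needs, plus the parameter layout.
build_model_internals <- function(spec, mix, src, disc) {
  spec <- validate_model(spec, mix, src, disc)
  des <- build_design(spec$effects, mix)
  K <- length(src$source_names); J <- ncol(mix$values); N <- nrow(mix$values)
  Km1 <- K - 1L
  treat <- treat_code[[src$treatment]]
  if (src$treatment == "raw" && spec$use_covariance) treat <- 3L
  raw <- matrix(0, 0L, J); raw_id <- integer()
  if (src$treatment == "raw") {
    raw <- do.call(rbind, src$raw_samples)
    raw_id <- rep(seq_len(K), vapply(src$raw_samples, nrow, integer(1)))
  }
  R <- length(des$ran)
  ran_index <- if (R) {
    do.call(cbind, lapply(des$ran, `[[`, "index"))
  } else matrix(0L, N, 0L)
  model <- list(
    Y = mix$values, V = ilr_basis(K), lambda = disc$means, tau2 = disc$sds^2,
    conc = if (is.null(src$concentrations)) matrix(1, K, J) else src$concentrations,
    use_conc = spec$use_concentration,
    error_kind = error_kind_code[[spec$error$kind]],
    src_treat = treat,
    src_mean = unname(src$means), src_sd = unname(src$sds),
    src_n = src$sample_sizes,
    raw = unname(raw), raw_id = raw_id,
    Xfix = unname(des$X), ran_index = unname(ran_index),
    ran_L = if (R) vapply(des$ran, function(r) length(r$levels), integer(1)) else integer(),
    alpha = spec$prior$alpha,
    coef_sd = spec$variance_priors$ilr_coefficient_sd,
    gamma_upper = spec$variance_priors$random_effect_sd_upper,
    sigma_upper = spec$variance_priors$residual_sd_upper,
    xi_scale = spec$variance_priors$xi_scale,
    mu_prior_sd = 1000
  )
  # parameter names, in the exact order of the C++ layout
  nm <- paste0("beta0[", seq_len(Km1), "]")
  for (cn in colnames(des$X)) nm <- c(nm, paste0("b_", cn, "[", seq_len(Km1), "]"))
  for (r in seq_len(R)) {
    fac <- des$ran[[r]]
    for (l in fac$levels) nm <- c(nm, paste0("re_", fac$name, "[", l, ",", seq_len(Km1), "]"))
    nm <- c(nm, paste0("log_gamma_", fac$name))
  }
  tr <- mix$tracer_names
  if (spec$error$kind == "residual_only") nm <- c(nm, paste0("log_sigma[", tr, "]"))
  if (spec$error$kind == "process_x_multiplicative") nm <- c(nm, paste0("log_xi[", tr, "]"))
  if (treat %in% c(1L, 2L)) {
    grid <- expand.grid(j = seq_len(J), k = seq_len(K))[, c("k", "j")]
    nm <- c(nm, paste0("mu_s[", src$source_names[grid$k], ",", tr[grid$j], "]"),
            paste0("log_omega_s[", src$source_names[grid$k], ",", tr[grid$j], "]"))
  } else if (treat == 3L) {
    grid <- expand.grid(j = seq_len(J), k = seq_len(K))[, c("k", "j")]
    nm <- c(nm, paste0("mu_s[", src$source_names[grid$k], ",", tr[grid$j], "]"))
    for (k in seq_len(K)) {
      nm <- c(nm, paste0("chol_", src$source_names[k], "_d[", seq_len(J), "]"))
      if (J > 1L) nm <- c(nm, paste0("chol_", src$source_names[k], "_o[",
                                     seq_len(J * (J - 1L) / 2L), "]"))
    }
  }
  list(spec = spec, design = des, model = model, param_names = nm,
       K = K, J = J, N = N, treat = treat)
}

# Overdispersed chain-specific initial values (uses the current RNG stream).
init_theta <- function(internals, jitter = 1) {
  m <- internals$model
  K <- internals$K; J <- internals$J; Km1 <- K - 1L
  th <- stats::rnorm(Km1, 0, 0.3 * jitter)
  th <- c(th, stats::rnorm(ncol(m$Xfix) * Km1, 0, 0.2 * jitter))
  for (L in m$ran_L) {
    th <- c(th, stats::rnorm(L * Km1, 0, 0.1 * jitter),
            log(0.5) + stats::rnorm(1, 0, 0.2 * jitter))
  }
  if (m$error_kind == 0L) {
    s0 <- pmin(apply(m$Y, 2L, stats::sd) + 1e-6, m$sigma_upper / 4)
    th <- c(th, log(s0) + stats::rnorm(J, 0, 0.2 * jitter))
  } else if (m$error_kind == 2L) {
    th <- c(th, stats::rnorm(J, 0, 0.3 * jitter))
  }
  if (internals$treat %in% c(1L, 2L)) {
    th <- c(th, as.numeric(t(m$src_mean)) + stats::rnorm(K * J, 0, 0.05 * jitter),
            log(as.numeric(t(m$src_sd))) + stats::rnorm(K * J, 0, 0.05 * jitter))
  } else if (internals$treat == 3L) {
    th <- c(th, as.numeric(t(m$src_mean)) + stats::rnorm(K * J, 0, 0.05 * jitter))
    for (k in seq_len(K)) {
      samp <- m$raw[m$raw_id == k, , drop = FALSE]
      cv <- stats::cov(samp)
      ch <- tryCatch(t(chol(cv)), error = function(e) diag(sqrt(diag(cv)), J))
      th <- c(th, log(diag(ch)) + stats::rnorm(J, 0, 0.05 * jitter))
      if (J > 1L) th <- c(th, ch[lower.tri(ch)] + stats::rnorm(J * (J - 1L) / 2L,
                                                               0, 0.05 * jitter))
    }
  }
  th
}

data_fingerprint <- function(mix) {
  v <- mix$values
  paste0(nrow(v), "x", ncol(v), ":",
         format(sum(v * rep_len(c(1, pi, exp(1), sqrt(2)), length(v))),
                digits = 17))
}

#' Fit the mixing model by MCMC
#'
#' Samples the joint posterior with an adaptive Metropolis-within-Gibbs
#' sampler (componentwise random-walk proposals on unconstrained
#' parameters; adaptation restricted to burn-in). The per-consumer
#' mixture log-likelihood is retained for every saved draw, which is
#' what [waic()] and [psis_loo()] consume.
#'
#' Draws are bit-reproducible given `settings$seed`. With a single
#' mixture row the process-only error structure is selected
#' automatically.
#'
#' @param spec a [model_spec()].
#' @param mix a [mixture_data()].
#' @param src a [source_data()].
#' @param disc a [discrimination_data()], or `NULL` for zero discrimination.
#' @param settings an [mcmc_settings()].
#' @param likelihood_off sample from the prior only (no data terms);
#'   used for prior-predictive checks.
#' @return an object of class `mixing_fit` with elements `draws`
#'   (saved draws x parameters, all chains stacked), `chain` (chain id
#'   per row), `loglik` (saved draws x N pointwise mixture
#'   log-likelihood), `param_names`, `accept`, plus the validated spec,
#'   data, and settings.
#' @export
fit <- function(spec, mix, src, disc = NULL, settings = mcmc_settings(),
                likelihood_off = FALSE) {
  stopifnot(inherits(settings, "mcmc_settings"))
  if (is.null(disc)) disc <- zero_discrimination(src)
  internals <- build_model_internals(spec, mix, src, disc)
  old <- .Random.seed_guard(settings$seed)
  on.exit(old(), add = TRUE)
  chains <- vector("list", settings$n_chains)
  lls <- vector("list", settings$n_chains)
  accepts <- vector("list", settings$n_chains)
  for (ch in seq_len(settings$n_chains)) {
    th0 <- init_theta(internals, jitter = 1)
    res <- run_chain_cpp(internals$model, th0, settings$n_iter, settings$n_burn,
                         settings$thin, settings$adapt_batch, likelihood_off)
    colnames(res$draws) <- internals$param_names
    chains[[ch]] <- res$draws
    lls[[ch]] <- res$loglik
    accepts[[ch]] <- res$accept
  }
  draws <- do.call(rbind, chains)
  structure(list(
    draws = draws,
    chain = rep(seq_len(settings$n_chains), each = nrow(chains[[1L]])),
    loglik = do.call(rbind, lls),
    param_names = internals$param_names,
    accept = Reduce(`+`, accepts) / settings$n_chains,
    spec = internals$spec, mix = mix, src = src, disc = disc,
    design = internals$design, settings = settings,
    data_hash = data_fingerprint(mix)
  ), class = "mixing_fit")
}

#' @export
print.mixing_fit <- function(x, ...) {
  cat(sprintf("mixing_fit: %d sources, %d tracers, %d consumers; %s error\n",
              length(x$src$source_names), ncol(x$mix$values), nrow(x$mix$values),
              x$spec$error$kind))
  cat(sprintf("  %d chains x %d saved draws, %d parameters\n",
              x$settings$n_chains, sum(x$chain == 1L), ncol(x$draws)))
  print(posterior_summary(x))
  invisible(x)
}

#' Posterior draws of the intercept (population-level) diet proportions
#' @param fit_obj a `mixing_fit`.
#' @return draws x K matrix of simplex rows, columns named by source.
#' @export
p_global_draws <- function(fit_obj) {
  stopifnot(inherits(fit_obj, "mixing_fit"))
  Km1 <- length(fit_obj$src$source_names) - 1L
  Z <- fit_obj$draws[, paste0("beta0[", seq_len(Km1), "]"), drop = FALSE]
  P <- inverse_ilr(Z)
  colnames(P) <- fit_obj$src$source_names
  P
}

#' Posterior draws of per-individual diet proportions
#' @param fit_obj a `mixing_fit`.
#' @param rows which consumer rows to include (default all).
#' @return array draws x length(rows) x K.
#' @export
p_individual_draws <- function(fit_obj, rows = seq_len(nrow(fit_obj$mix$values))) {
  stopifnot(inherits(fit_obj, "mixing_fit"))
  S <- nrow(fit_obj$draws)
  K <- length(fit_obj$src$source_names)
  des <- fit_obj$design
  out <- array(NA_real_, c(S, length(rows), K),
               dimnames = list(NULL, fit_obj$mix$ids[rows], fit_obj$src$source_names))
  for (s in seq_len(S)) {
    st <- draw_state(fit_obj, s)
    Z <- ilr_predictor(st, des, nrow(fit_obj$mix$values))
    out[s, , ] <- inverse_ilr(Z[rows, , drop = FALSE])
  }
  out
}

# Rebuild a parameter-state list from saved draw s.
draw_state <- function(fit_obj, s) {
  d <- fit_obj$draws[s, ]
  nm <- fit_obj$param_names
  Km1 <- length(fit_obj$src$source_names) - 1L
  K <- Km1 + 1L; J <- ncol(fit_obj$mix$values)
  st <- list(ilr_intercept = unname(d[paste0("beta0[", seq_len(Km1), "]")]))
  des <- fit_obj$design
  st$fixed_coefficients <- lapply(colnames(des$X), function(cn) {
    unname(d[paste0("b_", cn, "[", seq_len(Km1), "]")])
  })
  names(st$fixed_coefficients) <- colnames(des$X)
  st$random_offsets <- lapply(des$ran, function(fac) {
    mat <- matrix(NA_real_, length(fac$levels), Km1)
    for (li in seq_along(fac$levels)) {
      mat[li, ] <- d[paste0("re_", fac$name, "[", fac$levels[li], ",", seq_len(Km1), "]")]
    }
    mat
  })
  st$random_sds <- vapply(des$ran, function(fac) {
    exp(unname(d[paste0("log_gamma_", fac$name)]))
  }, numeric(1))
  tr <- fit_obj$mix$tracer_names
  if (fit_obj$spec$error$kind == "residual_only") {
    st$residual_sd <- exp(unname(d[paste0("log_sigma[", tr, "]")]))
  }
  if (fit_obj$spec$error$kind == "process_x_multiplicative") {
    st$xi <- exp(unname(d[paste0("log_xi[", tr, "]")]))
  }
  src <- fit_obj$src
  if (src$treatment == "fixed") {
    st$source_means <- src$means
    st$source_sds <- src$sds
  } else {
    st$source_means <- matrix(NA_real_, K, J, dimnames = dimnames(src$means))
    for (k in seq_len(K)) for (j in seq_len(J)) {
      st$source_means[k, j] <- d[paste0("mu_s[", src$source_names[k], ",", tr[j], "]")]
    }
    if (fit_obj$spec$use_covariance) {
      st$source_covs <- lapply(seq_len(K), function(k) {
        L <- diag(exp(unname(d[paste0("chol_", src$source_names[k], "_d[",
                                      seq_len(J), "]")])), J)
        if (J > 1L) {
          L[lower.tri(L)] <- unname(d[paste0("chol_", src$source_names[k], "_o[",
                                             seq_len(J * (J - 1L) / 2L), "]")])
        }
        tcrossprod(L)
      })
      st$source_sds <- t(vapply(st$source_covs, function(S) sqrt(diag(S)), numeric(J)))
    } else {
      st$source_sds <- matrix(NA_real_, K, J, dimnames = dimnames(src$sds))
      for (k in seq_len(K)) for (j in seq_len(J)) {
        st$source_sds[k, j] <- exp(d[paste0("log_omega_s[", src$source_names[k],
                                            ",", tr[j], "]")])
      }
    }
  }
  st
}

#' Posterior summary table
#'
#' Means, medians and equal-tailed credible intervals for the derived
#' quantities users report: global diet proportions, the specialization
#' index of the global diet, error parameters (sigma or xi), and
#' random-effect SDs.
#'
#' @param x a `mixing_fit`, or a numeric matrix of draws (one column per
#'   quantity).
#' @param probs interval probabilities (default 95% equal-tailed plus
#'   the median).
#' @return a data.frame with one row per quantity.
#' @export
posterior_summary <- function(x, probs = c(0.025, 0.5, 0.975)) {
  if (inherits(x, "mixing_fit")) {
    P <- p_global_draws(x)
    mats <- list(P)
    eps <- apply(P, 1L, specialization_index)
    mats <- c(mats, list(matrix(eps, ncol = 1L, dimnames = list(NULL, "epsilon"))))
    tr <- x$mix$tracer_names
    if (x$spec$error$kind == "residual_only") {
      s <- exp(x$draws[, paste0("log_sigma[", tr, "]"), drop = FALSE])
      colnames(s) <- paste0("sigma[", tr, "]")
      mats <- c(mats, list(s))
    }
    if (x$spec$error$kind == "process_x_multiplicative") {
      s <- exp(x$draws[, paste0("log_xi[", tr, "]"), drop = FALSE])
      colnames(s) <- paste0("xi[", tr, "]")
      mats <- c(mats, list(s))
    }
    for (fac in names(x$design$ran)) {
      g <- exp(x$draws[, paste0("log_gamma_", fac), drop = FALSE])
      colnames(g) <- paste0("gamma_", fac)
      mats <- c(mats, list(g))
    }
    x <- do.call(cbind, mats)
  }
  x <- as.matrix(x)
  if (!nrow(x)) stop("no draws to summarize", call. = FALSE)
  qs <- t(apply(x, 2L, stats::quantile, probs = probs, names = FALSE))
  colnames(qs) <- paste0("q", format(probs, trim = TRUE))
  data.frame(quantity = colnames(x), mean = colMeans(x),
             sd = apply(x, 2L, stats::sd), qs,
             row.names = NULL, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Convergence diagnostics: split-Rhat and Geweke z
#'
#' Split-Rhat halves every chain (so within-chain drift registers as
#' between-"chain" variance) and compares between to within variance;
#' values above 1.05 are flagged. The Geweke statistic compares the mean
#' of the first 10% to the last 50% of each chain with batch-means
#' standard errors. Degenerate (constant) parameters are reported as
#' such rather than dividing by zero.
#'
#' @param fit_obj a `mixing_fit`, or a list of chain matrices with equal
#'   columns.
#' @param rhat_threshold flag threshold (default 1.05).
#' @return data.frame with columns `parameter`, `rhat`, `geweke_z`,
#'   `degenerate`, `flagged`, and attribute `pass` (logical).
#' @export
convergence_diagnostics <- function(fit_obj, rhat_threshold = 1.05) {
  if (inherits(fit_obj, "mixing_fit")) {
    chains <- lapply(unique(fit_obj$chain), function(ch) {
      fit_obj$draws[fit_obj$chain == ch, , drop = FALSE]
    })
  } else if (is.list(fit_obj)) {
    chains <- lapply(fit_obj, as.matrix)
  } else {
    chains <- list(as.matrix(fit_obj))
  }
  single <- length(chains) == 1L
  if (single) {
    warning("single chain: split-Rhat unavailable, reporting Geweke only")
  }
  pn <- colnames(chains[[1L]])
  if (is.null(pn)) pn <- paste0("par", seq_len(ncol(chains[[1L]])))
  out <- data.frame(parameter = pn, rhat = NA_real_, geweke_z = NA_real_,
                    degenerate = FALSE, stringsAsFactors = FALSE)
  for (p in seq_along(pn)) {
    cols <- lapply(chains, function(m) m[, p])
    if (all(vapply(cols, function(v) stats::var(v) == 0, logical(1)))) {
      out$degenerate[p] <- TRUE
      next
    }
    if (!single) {
      halves <- unlist(lapply(cols, function(v) {
        h <- length(v) %/% 2L
        list(v[seq_len(h)], v[(h + 1L):(2L * h)])
      }), recursive = FALSE)
      n <- length(halves[[1L]])
      means <- vapply(halves, mean, numeric(1))
      vars <- vapply(halves, stats::var, numeric(1))
      W <- mean(vars); B <- n * stats::var(means)
      out$rhat[p] <- if (W > 0) sqrt(((n - 1) / n * W + B / n) / W) else Inf
    }
    v <- cols[[1L]]
    n <- length(v)
    a <- v[seq_len(max(2L, floor(0.1 * n)))]
    b <- v[(floor(0.5 * n) + 1L):n]
    se2 <- function(u) {
      nb <- max(2L, floor(sqrt(length(u))))
      bm <- colMeans(matrix(u[seq_len(nb * (length(u) %/% nb))], nrow = length(u) %/% nb))
      stats::var(bm) / nb
    }
    den <- se2(a) + se2(b)
    out$geweke_z[p] <- if (den > 0) (mean(a) - mean(b)) / sqrt(den) else 0
  }
  out$flagged <- !out$degenerate & !is.na(out$rhat) & out$rhat > rhat_threshold
  attr(out, "pass") <- !any(out$flagged)
  out
}

#' Exhaustive grid posterior for tiny two-source models
#'
#' Brute-force reference posterior over the first source proportion for
#' K = 2 models with fixed sources, no covariates, and J <= 2 tracers.
#' Nuisance error parameters (per-tracer sigma or xi) are marginalized
#' over a dense 1-D quadrature grid per tracer; given p the likelihood
#' factorizes across tracers, so the marginalization is exact up to
#' quadrature error. Serves as the independent oracle the MCMC sampler
#' is tested against; it deliberately shares no code with the sampler.
#'
#' @param spec a [model_spec()] (no effects).
#' @param mix a [mixture_data()].
#' @param src a fixed-treatment [source_data()] with K = 2.
#' @param disc a [discrimination_data()] or `NULL`.
#' @param grid_resolution number of interior p grid points (>= 200).
#' @param nuisance_resolution quadrature points per nuisance parameter.
#' @return list with `p1` (grid midpoints), `density` (probabilities
#'   summing to 1), class `grid_posterior`.
#' @export
grid_posterior <- function(spec, mix, src, disc = NULL, grid_resolution = 400L,
                           nuisance_resolution = 201L) {
  if (is.null(disc)) disc <- zero_discrimination(src)
  spec <- validate_model(spec, mix, src, disc)
  K <- length(src$source_names)
  if (K != 2L) stop("grid_posterior supports exactly K = 2 sources", call. = FALSE)
  J <- ncol(mix$values)
  if (J > 2L) stop("grid_posterior supports J <= 2 tracers", call. = FALSE)
  if (src$treatment != "fixed") stop("grid_posterior requires fixed sources", call. = FALSE)
  if (length(spec$effects$fixed_categorical) || length(spec$effects$fixed_continuous) ||
      length(spec$effects$random)) {
    stop("grid_posterior supports intercept-only models", call. = FALSE)
  }
  if (grid_resolution < 200L) stop("grid_resolution must be >= 200", call. = FALSE)
  G <- as.integer(grid_resolution)
  p1 <- (seq_len(G) - 0.5) / G
  alpha <- spec$prior$alpha
  logpost <- stats::dbeta(p1, alpha[1L], alpha[2L], log = TRUE)
  Y <- mix$values
  mu <- src$means + disc$means
  om2 <- src$sds^2
  tau2 <- disc$sds^2
  kind <- spec$error$kind
  for (j in seq_len(J)) {
    mean_j <- p1 * mu[1L, j] + (1 - p1) * mu[2L, j]
    pv_j <- p1^2 * (om2[1L, j] + tau2[1L, j]) + (1 - p1)^2 * (om2[2L, j] + tau2[2L, j])
    if (kind == "process_only") {
      ll <- rowSums(vapply(Y[, j], function(y) {
        stats::dnorm(y, mean_j, sqrt(pv_j), log = TRUE)
      }, numeric(G)))
      logpost <- logpost + ll
    } else if (kind == "residual_only") {
      sd_y <- stats::sd(Y[, j]); if (!is.finite(sd_y) || sd_y == 0) sd_y <- 1
      up <- spec$variance_priors$residual_sd_upper
      lsig <- seq(log(sd_y) - 6, min(log(up), log(sd_y) + 6),
                  length.out = nuisance_resolution)
      # sigma ~ U(0, up): weight propto sigma on the log grid (Jacobian)
      lw <- lsig
      grid_ll <- vapply(lsig, function(ls) {
        colSums(vapply(seq_len(G), function(g) {
          stats::dnorm(Y[, j], mean_j[g], exp(ls), log = TRUE)
        }, numeric(nrow(Y))))
      }, numeric(G))
      logpost <- logpost + apply(sweep(grid_ll, 2L, lw, `+`), 1L, logsumexp)
    } else {
      lxi <- seq(-9, 9, length.out = nuisance_resolution)
      xs <- spec$variance_priors$xi_scale
      lw <- lxi - log1p((exp(lxi) / xs)^2)       # half-Cauchy + Jacobian
      grid_ll <- vapply(lxi, function(lx) {
        v <- pv_j * exp(lx)
        colSums(vapply(seq_len(G), function(g) {
          stats::dnorm(Y[, j], mean_j[g], sqrt(v[g]), log = TRUE)
        }, numeric(nrow(Y))))
      }, numeric(G))
      logpost <- logpost + apply(sweep(grid_ll, 2L, lw, `+`), 1L, logsumexp)
    }
  }
  w <- exp(logpost - max(logpost))
  structure(list(p1 = p1, density = w / sum(w)), class = "grid_posterior")
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Total variation distance between MCMC draws and a grid posterior
#'
#' Bins draws of p1 into equal-width bins and compares the binned mass
#' with the grid posterior aggregated to the same bins.
#'
#' @param draws numeric vector of p1 draws in (0, 1).
#' @param grid a `grid_posterior`.
#' @param n_bins number of bins.
#' @return total variation distance in `[0, 1]`.
#' @export
tv_distance <- function(draws, grid, n_bins = 10L) {
  stopifnot(inherits(grid, "grid_posterior"))
  breaks <- seq(0, 1, length.out = n_bins + 1L)
  h_mcmc <- tabulate(findInterval(draws, breaks, rightmost.closed = TRUE),
                     nbins = n_bins) / length(draws)
  h_grid <- tapply(grid$density,
                   findInterval(grid$p1, breaks, rightmost.closed = TRUE), sum)
  h_g <- numeric(n_bins)
  h_g[as.integer(names(h_grid))] <- h_grid
  0.5 * sum(abs(h_mcmc - h_g))
}
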