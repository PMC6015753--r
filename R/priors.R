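#' Dirichlet prior on source proportions
#'
#' Constructor and validator for the Dirichlet prior placed on the vector
#' of proportional source contributions.
#'
#' @param alpha numeric vector of positive hyperparameters, length K >= 2.
#' @param source_names optional character vector of K source labels.
#' @return an object of class `dirichlet_prior`.
#' @export
dirichlet_prior <- function(alpha, source_names = NULL) {
  alpha <- as.numeric(alpha)
  K <- length(alpha)
  if (K < 2L) stop("a Dirichlet prior needs at least 2 sources", call. = FALSE)
  if (any(!is.finite(alpha)) || any(alpha <= 0)) {
    stop("all Dirichlet hyperparameters must be positive and finite", call. = FALSE)
  }
  if (is.null(source_names)) source_names <- paste0("source", seq_len(K))
  if (length(source_names) != K) {
    stop("source_names must have one label per hyperparameter", call. = FALSE)
  }
  structure(list(alpha = alpha, source_names = as.character(source_names)),
            class = "dirichlet_prior")
}

#' @export
print.dirichlet_prior <- function(x, ...) {
  cat("Dirichlet prior on", length(x$alpha), "sources\n")
  cat(paste0("  alpha(", x$source_names, ") = ", format(x$alpha)), sep = "\n")
  invisible(x)
}

#' Default ("uninformative"/generalist) prior
#'
#' All hyperparameters set to 1: uniform over the simplex (every
#' combination of proportions equally likely a priori), with mean diet
#' `(1/K, ..., 1/K)`. Note the marginals of each individual proportion
#' are Beta(1, K-1), i.e. not uniform for K > 2.
#'
#' @param K number of sources, `K >= 2`.
#' @param source_names optional labels.
#' @return a [dirichlet_prior()].
#' @export
default_prior <- function(K, source_names = NULL) {
  K <- as.integer(K)
  if (is.na(K) || K < 2L) stop("the generalist prior needs K >= 2 sources", call. = FALSE)
  dirichlet_prior(rep(1, K), source_names)
}

#' Informative prior from auxiliary counts
#'
#' Builds a Dirichlet prior from count data such as stomach or fecal
#' contents. With `total_weight = NULL` the counts are used directly as
#' hyperparameters (prior "sample size" equal to the number of items
#' counted — usually very informative). Otherwise the counts are rescaled
#' to sum to `total_weight` while keeping the prior mean fixed at
#' `counts / sum(counts)`; `total_weight = K` gives the same total weight
#' as the generalist prior.
#'
#' @param counts non-negative numeric vector, at least two entries > 0.
#' @param total_weight positive scalar, or `NULL` to use raw counts.
#'   Defaults to the number of sources.
#' @param source_names optional labels.
#' @return a [dirichlet_prior()].
#' @export
informative_prior_from_counts <- function(counts, total_weight = length(counts),
                                          source_names = NULL) {
  counts <- as.numeric(counts)
  if (length(counts) < 2L) stop("need counts for at least 2 sources", call. = FALSE)
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("counts must be non-negative and finite", call. = FALSE)
  }
  if (sum(counts > 0) < 2L) {
    stop("at least two sources must have a positive count", call. = FALSE)
  }
  if (any(counts == 0)) {
    stop(paste("zero counts give alpha_k = 0, which is not a valid Dirichlet;",
               "add a pseudo-count (e.g. 1) to sources you believe are",
               "possible but unobserved"), call. = FALSE)
  }
  if (is.null(total_weight)) {
    alpha <- counts
  } else {
    total_weight <- as.numeric(total_weight)
    if (length(total_weight) != 1L || !is.finite(total_weight) || total_weight <= 0) {
      stop("total_weight must be a positive scalar (or NULL for raw counts)",
           call. = FALSE)
    }
    alpha <- total_weight * counts / sum(counts)
  }
  dirichlet_prior(alpha, source_names)
}

#' Aggregate a Dirichlet prior over a source grouping
#'
#' Uses the aggregation property of the Dirichlet: summing components of
#' a Dirichlet vector yields a Dirichlet with summed hyperparameters.
#' This is the prior implied for combined-source proportions, emitted as
#' a warning payload by [combine_sources()]: aggregating G sources under
#' the generalist prior gives the combined group G times the prior
#' weight of an unaggregated source.
#'
#' @param prior a [dirichlet_prior()].
#' @param grouping named character vector or list mapping every source
#'   name to a group name (see [source_grouping()]); alternatively a
#'   `source_grouping` object.
#' @return a [dirichlet_prior()] over the groups.
#' @export
aggregate_prior <- function(prior, grouping) {
  stopifnot(inherits(prior, "dirichlet_prior"))
  g <- as_source_grouping(grouping, prior$source_names)
  alpha_g <- vapply(g$groups, function(members) {
    sum(prior$alpha[match(members, prior$source_names)])
  }, numeric(1))
  dirichlet_prior(alpha_g, names(g$groups))
}

#' Draw from a Dirichlet distribution
#'
#' Standard gamma construction: `X_k ~ Gamma(alpha_k, 1)` normalized by
#' the row sum.
#'
#' @param n number of draws.
#' @param alpha hyperparameter vector.
#' @return `n x K` matrix of simplex rows.
#' @export
rdirichlet <- function(n, alpha) {
  K <- length(alpha)
  x <- matrix(stats::rgamma(n * K, shape = rep(alpha, each = n), rate = 1),
              nrow = n, ncol = K)
  x / rowSums(x)
}

#' Monte-Carlo summary of Dirichlet prior marginals
#'
#' Summarizes the marginal distribution of each source proportion under
#' a Dirichlet prior. Useful for judging prior informativeness: the
#' generalist prior is uniform on the simplex but its marginals pile up
#' on small values as K grows.
#'
#' @param prior a [dirichlet_prior()].
#' @param n_draws number of Monte-Carlo draws, `>= 1000`.
#' @param seed integer seed; draws are deterministic given the seed.
#' @param probs quantile levels for the summary.
#' @return data.frame with one row per source: analytic mean, MC mean,
#'   MC standard error, and the requested quantiles.
#' @export
prior_marginal_summary <- function(prior, n_draws = 10000L, seed = 1L,
                                   probs = c(0.025, 0.25, 0.5, 0.75, 0.975)) {
  stopifnot(inherits(prior, "dirichlet_prior"))
  n_draws <- as.integer(n_draws)
  if (n_draws < 1000L) stop("use at least 1000 draws for a stable summary", call. = FALSE)
  old <- .Random.seed_guard(seed)
  on.exit(old(), add = TRUE)
  draws <- rdirichlet(n_draws, prior$alpha)
  qs <- t(apply(draws, 2L, stats::quantile, probs = probs, names = FALSE))
  colnames(qs) <- paste0("q", format(probs, trim = TRUE))
  out <- data.frame(
    source = prior$source_names,
    mean_analytic = prior$alpha / sum(prior$alpha),
    mean_mc = colMeans(draws),
    mc_se = apply(draws, 2L, stats::sd) / sqrt(n_draws),
    stringsAsFactors = FALSE
  )
  cbind(out, as.data.frame(qs))
}

#' Priors for non-compositional parameters
#'
#' Weakly informative defaults for every parameter that is not a source
#' proportion, mirroring common practice for variance parameters in
#' hierarchical linear models:
#' * residual tracer SDs: Uniform(0, `residual_sd_upper`);
#' * multiplicative error \eqn{\xi_j}: heavy-tailed half-Cauchy with
#'   scale `xi_scale` (admits both \eqn{\xi \ll 1} and \eqn{\xi \gg 1});
#' * ILR-space fixed-effect coefficients: Normal(0, `ilr_coefficient_sd`^2),
#'   default variance 1000;
#' * random-effect SDs \eqn{\gamma}: variance Uniform(0,
#'   `random_effect_sd_upper`^2), default variance upper bound 20.
#'
#' @param residual_sd_upper upper bound for residual SD priors. The
#'   model-building code replaces `NA` with 10x the mixture data range
#'   per tracer.
#' @param xi_family only `"half_cauchy"` is implemented.
#' @param xi_scale scale of the half-Cauchy prior on each xi.
#' @param random_effect_sd_upper upper bound on random-effect SDs
#'   (default `sqrt(20)` so the variance is U(0, 20)).
#' @param ilr_coefficient_sd prior SD of ILR-space coefficients
#'   (default `sqrt(1000)`).
#' @return an object of class `variance_prior_spec`.
#' @export
variance_prior_spec <- function(residual_sd_upper = NA_real_,
                                xi_family = "half_cauchy",
                                xi_scale = 1,
                                random_effect_sd_upper = sqrt(20),
                                ilr_coefficient_sd = sqrt(1000)) {
  xi_family <- match.arg(xi_family, "half_cauchy")
  chk <- function(x, nm, na_ok = FALSE) {
    if (na_ok && is.na(x)) return(invisible())
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
      stop(sprintf("%s must be a positive finite scalar", nm), call. = FALSE)
    }
  }
  chk(residual_sd_upper, "residual_sd_upper", na_ok = TRUE)
  chk(xi_scale, "xi_scale")
  chk(random_effect_sd_upper, "random_effect_sd_upper")
  chk(ilr_coefficient_sd, "ilr_coefficient_sd")
  structure(list(residual_sd_upper = residual_sd_upper,
                 xi_family = xi_family, xi_scale = xi_scale,
                 random_effect_sd_upper = random_effect_sd_upper,
                 ilr_coefficient_sd = ilr_coefficient_sd),
            class = "variance_prior_spec")
}

# Run code under a temporary seed, restoring the caller's RNG state.
.Random.seed_guard <- function(seed) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  saved <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  function() {
    if (has_seed) assign(".Random.seed", saved, envir = globalenv())
    invisible()
  }
}
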