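#' Mixture error structure
#'
#' The three likelihood variance formulations for mixture tracer data:
#' * `"residual_only"`: \eqn{Y_{ij} ~ N(\sum_k p_k \mu_{jk}, \sigma_j^2)} —
#'   a per-tracer residual variance unrelated to source variability
#'   (appropriate for integrated/composite sampling designs);
#' * `"process_only"`: variance \eqn{\sum_k p_k^2 \omega_{jk}^2} — each
#'   consumer takes one IID sample from each source, so source
#'   variability propagates. Only permitted when there is a single
#'   mixture row (no residual variance is estimable from one point);
#' * `"process_x_multiplicative"`: process variance scaled per tracer by
#'   \eqn{\xi_j}; \eqn{\xi_j < 1} implies integration over many prey
#'   items, \eqn{\xi_j \gg 1} flags unmodelled structure. The
#'   recommended default for consumer diet data.
#'
#' @param kind one of the three structures above.
#' @return an object of class `error_spec`.
#' @export
error_spec <- function(kind = c("process_x_multiplicative", "residual_only",
                                "process_only")) {
  kind <- match.arg(kind)
  structure(list(kind = kind), class = "error_spec")
}

#' Covariate effect design on the ILR scale
#'
#' Declares which mixture covariates drive per-individual diet
#' proportions. The linear predictor for consumer i is
#' \deqn{z_i = \beta_0 + \sum \beta X_i + \sum \beta_{level(i)}}
#' in ILR space, back-transformed to proportions via [inverse_ilr()].
#' Continuous covariates are centered and scaled to unit SD internally
#' (sampler geometry); predictions are back-transformed so users work on
#' the raw covariate scale.
#'
#' @param fixed_categorical character vector of fixed-factor names.
#' @param fixed_continuous character vector of continuous covariate names.
#' @param random character vector of random-factor names (declare nested
#'   factors in order, outer first).
#' @return an object of class `effect_design`.
#' @export
effect_design <- function(fixed_categorical = character(),
                          fixed_continuous = character(),
                          random = character()) {
  all_names <- c(fixed_categorical, fixed_continuous, random)
  if (anyDuplicated(all_names)) {
    stop("each covariate may appear in at most one effect role", call. = FALSE)
  }
  structure(list(fixed_categorical = as.character(fixed_categorical),
                 fixed_continuous = as.character(fixed_continuous),
                 random = as.character(random),
                 include_intercept = TRUE),
            class = "effect_design")
}

#' Full model specification
#'
#' Assembles the error structure, effect design, Dirichlet prior and
#' variance priors that, together with the data, fully determine the
#' joint posterior density.
#'
#' @param error an [error_spec()].
#' @param effects an [effect_design()].
#' @param prior a [dirichlet_prior()] on the intercept composition, or
#'   `NULL` for the generalist prior (resolved against K at validation).
#' @param variance_priors a [variance_prior_spec()].
#' @param use_covariance estimate full per-source tracer covariance
#'   matrices (raw source treatment with a process-type error only).
#' @param use_concentration apply concentration-dependent (mass-balance)
#'   weighting; requires concentrations in the source data.
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(error = error_spec(), effects = effect_design(),
                       prior = NULL, variance_priors = variance_prior_spec(),
                       use_covariance = FALSE, use_concentration = FALSE) {
  stopifnot(inherits(error, "error_spec"), inherits(effects, "effect_design"),
            inherits(variance_priors, "variance_prior_spec"))
  if (!is.null(prior)) stopifnot(inherits(prior, "dirichlet_prior"))
  structure(list(error = error, effects = effects, prior = prior,
                 variance_priors = variance_priors,
                 use_covariance = isTRUE(use_covariance),
                 use_concentration = isTRUE(use_concentration)),
            class = "model_spec")
}

# Validate a model_spec against a data bundle; returns the spec with the
# prior resolved, the residual-SD upper bound filled from the data range,
# and the error kind auto-selected for single-consumer data.
validate_model <- function(spec, mix, src, disc) {
  stopifnot(inherits(spec, "model_spec"), inherits(mix, "mixture_data"),
            inherits(src, "source_data"), inherits(disc, "discrimination_data"))
  K <- length(src$source_names)
  N <- nrow(mix$values)
  if (!identical(mix$tracer_names, src$tracer_names)) {
    stop("mixture and source tracer names must match (same order)", call. = FALSE)
  }
  if (!all(dim(disc$means) == dim(src$means))) {
    stop("discrimination shape must match the K x J source shape", call. = FALSE)
  }
  if (is.null(spec$prior)) {
    spec$prior <- default_prior(K, src$source_names)
  } else if (length(spec$prior$alpha) != K) {
    stop("Dirichlet prior length must equal the number of sources", call. = FALSE)
  }
  if (N == 1L && spec$error$kind != "process_only") {
    message("single mixture row: selecting the process-only error structure")
    spec$error <- error_spec("process_only")
  }
  if (N > 1L && spec$error$kind == "process_only") {
    stop(paste("the process-only error structure is permitted only for a single",
               "mixture row; use process_x_multiplicative (or residual_only)"),
         call. = FALSE)
  }
  if (spec$use_covariance) {
    if (src$treatment != "raw") {
      stop("use_covariance requires the raw source treatment", call. = FALSE)
    }
    if (spec$error$kind == "residual_only") {
      stop("use_covariance requires a process-type error structure", call. = FALSE)
    }
  }
  if (spec$use_concentration && is.null(src$concentrations)) {
    stop("use_concentration requires concentrations in the source data", call. = FALSE)
  }
  eff <- spec$effects
  known <- c(names(mix$fixed_factors), names(mix$random_factors),
             names(mix$continuous_covariates))
  missing <- setdiff(c(eff$fixed_categorical, eff$fixed_continuous, eff$random), known)
  if (length(missing)) {
    stop(sprintf("effects reference unknown covariate(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  for (nm in eff$random) {
    f <- c(mix$fixed_factors, mix$random_factors)[[nm]]
    if (nlevels(f) == 2L) {
      stop(sprintf("factor '%s' has only two levels; use it as a fixed effect", nm),
           call. = FALSE)
    }
  }
  if (is.na(spec$variance_priors$residual_sd_upper)) {
    rng <- apply(mix$values, 2L, function(y) diff(range(y)))
    spec$variance_priors$residual_sd_upper <- max(10 * max(rng), 10)
  }
  spec
}

# Fixed-effect design matrix: standardized continuous columns plus
# treatment-coded dummies (first-appearance baseline). Random factors are
# returned as level-index vectors.
build_design <- function(effects, mix) {
  N <- nrow(mix$values)
  cols <- list(); centers <- numeric(); scales <- numeric()
  for (nm in effects$fixed_continuous) {
    x <- mix$continuous_covariates[[nm]]
    if (is.null(x)) stop(sprintf("continuous covariate '%s' not found", nm), call. = FALSE)
    ctr <- mean(x); scl <- stats::sd(x)
    if (!is.finite(scl) || scl == 0) scl <- 1
    cols[[nm]] <- (x - ctr) / scl
    centers[nm] <- ctr; scales[nm] <- scl
  }
  for (nm in effects$fixed_categorical) {
    f <- mix$fixed_factors[[nm]]
    if (is.null(f)) f <- mix$random_factors[[nm]]
    if (is.null(f)) stop(sprintf("factor '%s' not found", nm), call. = FALSE)
    for (lv in levels(f)[-1L]) {
      cols[[paste0(nm, lv)]] <- as.numeric(f == lv)
    }
  }
  X <- if (length(cols)) do.call(cbind, cols) else matrix(0, N, 0L)
  colnames(X) <- names(cols)
  ran <- lapply(effects$random, function(nm) {
    f <- c(mix$random_factors, mix$fixed_factors)[[nm]]
    if (is.null(f)) stop(sprintf("random factor '%s' not found", nm), call. = FALSE)
    list(name = nm, levels = levels(f), index = as.integer(f))
  })
  names(ran) <- effects$random
  list(X = X, centers = centers, scales = scales, ran = ran)
}

#' Per-individual diet proportions from a parameter state
#'
#' Applies the ILR-space linear predictor
#' `beta0 + fixed terms + random offsets` row by row and back-transforms
#' to the simplex. With no effects every row equals
#' `inverse_ilr(beta0)` — the model collapses to a single global diet.
#'
#' @param state a list with elements `ilr_intercept` (length K-1),
#'   `fixed_coefficients` (named list of K-1 vectors, one per design
#'   column — continuous coefficients on the standardized scale), and
#'   `random_offsets` (named list of L x (K-1) matrices).
#' @param effects an [effect_design()].
#' @param mix a [mixture_data()].
#' @return N x K matrix of proportions; rows sum to 1.
#' @export
individual_proportions <- function(state, effects, mix) {
  des <- build_design(effects, mix)
  Z <- ilr_predictor(state, des, nrow(mix$values))
  P <- inverse_ilr(Z)
  colnames(P) <- NULL
  P
}

# N x (K-1) matrix of linear predictors.
ilr_predictor <- function(state, des, N) {
  beta0 <- state$ilr_intercept
  Km1 <- length(beta0)
  Z <- matrix(rep(beta0, each = N), N, Km1)
  if (ncol(des$X)) {
    B <- do.call(rbind, lapply(colnames(des$X), function(cn) {
      b <- state$fixed_coefficients[[cn]]
      if (is.null(b)) stop(sprintf("state lacks coefficients for '%s'", cn), call. = FALSE)
      b
    }))
    Z <- Z + des$X %*% B
  }
  for (nm in names(des$ran)) {
    off <- state$random_offsets[[nm]]
    if (is.null(off)) stop(sprintf("state lacks random offsets for '%s'", nm), call. = FALSE)
    Z <- Z + off[des$ran[[nm]]$index, , drop = FALSE]
  }
  Z
}

#' Expected mixture tracer values for one consumer
#'
#' Without concentration dependence:
#' \eqn{\mu_j = \sum_k p_k (\mu_{jk} + \lambda_{jk})}. With it, source
#' contributions are mass-balance weighted:
#' \eqn{\sum_k p_k c_{jk} (\mu_{jk}+\lambda_{jk}) / \sum_k p_k c_{jk}}.
#'
#' @param p_row length-K proportion vector.
#' @param source_means K x J matrix of source tracer means.
#' @param discrimination_means K x J matrix of discrimination means
#'   (default zero).
#' @param concentrations optional K x J concentration matrix.
#' @return length-J vector of expected tracer values.
#' @export
mixture_mean <- function(p_row, source_means, discrimination_means = NULL,
                         concentrations = NULL) {
  source_means <- as.matrix(source_means)
  mu <- source_means + if (is.null(discrimination_means)) 0 else as.matrix(discrimination_means)
  if (is.null(concentrations)) {
    as.numeric(crossprod(mu, p_row))
  } else {
    q <- sweep(p_row * as.matrix(concentrations), 2L,
               colSums(p_row * as.matrix(concentrations)), "/")
    colSums(q * mu)
  }
}

#' Mixture variance (or covariance) for one consumer
#'
#' Implements the three error structures. For the process forms,
#' discrimination uncertainty adds to the source variance
#' (\eqn{\omega^2 + \tau^2}) inside the proportion-squared weighting,
#' and concentration weights replace raw proportions when supplied.
#' With `source_covs`, the weighted combination is over full source
#' covariance matrices and a J x J covariance is returned (diagonal
#' source covariances reproduce the independent-tracer result exactly).
#'
#' @param p_row length-K proportion vector.
#' @param source_sds K x J matrix of source tracer SDs.
#' @param discrimination_sds K x J matrix of discrimination SDs (default 0).
#' @param error an [error_spec()] (or its kind string).
#' @param sigma length-J residual SDs (residual_only).
#' @param xi length-J multiplicative terms (process_x_multiplicative).
#' @param concentrations optional K x J concentration matrix.
#' @param source_covs optional list of K per-source J x J covariance
#'   matrices (overrides `source_sds`).
#' @return length-J variance vector, or a J x J covariance matrix when
#'   `source_covs` is given.
#' @export
mixture_scale <- function(p_row, source_sds, discrimination_sds = NULL,
                          error = error_spec(), sigma = NULL, xi = NULL,
                          concentrations = NULL, source_covs = NULL) {
  kind <- if (inherits(error, "error_spec")) error$kind else as.character(error)
  source_sds <- as.matrix(source_sds)
  K <- nrow(source_sds); J <- ncol(source_sds)
  tau2 <- if (is.null(discrimination_sds)) matrix(0, K, J) else as.matrix(discrimination_sds)^2
  if (kind == "residual_only") {
    if (is.null(sigma) || length(sigma) != J) {
      stop("residual_only needs a length-J sigma", call. = FALSE)
    }
    return(as.numeric(sigma)^2)
  }
  q <- if (is.null(concentrations)) {
    matrix(p_row, K, J)
  } else {
    sweep(p_row * as.matrix(concentrations), 2L,
          colSums(p_row * as.matrix(concentrations)), "/")
  }
  xi_mult <- if (kind == "process_x_multiplicative") {
    if (is.null(xi) || length(xi) != J) {
      stop("process_x_multiplicative needs a length-J xi", call. = FALSE)
    }
    as.numeric(xi)
  } else rep(1, J)
  if (!is.null(source_covs)) {
    Omega <- matrix(0, J, J)
    for (k in seq_len(K)) {
      Sk <- as.matrix(source_covs[[k]]) + diag(tau2[k, ], J)
      Omega <- Omega + tcrossprod(q[k, ]) * Sk
    }
    s <- sqrt(xi_mult)
    return(Omega * tcrossprod(s))
  }
  v <- colSums(q^2 * (source_sds^2 + tau2))
  v * xi_mult
}

#' Pointwise log-likelihood of a parameter state
#'
#' Reference (pure-R) evaluation of the model likelihood: one joint
#' normal (or multivariate normal) log-density per consumer, plus the
#' source-data terms implied by the treatment:
#' * `raw`: per-sample normal (or MVN with `use_covariance`) given the
#'   current source means/SDs;
#' * `summary`: sufficient-statistic densities — sample mean
#'   \eqn{\bar{x} ~ N(\mu, \omega^2/n)} and sample variance via
#'   \eqn{(n-1)s^2/\omega^2 ~ \chi^2_{n-1}};
#' * `fixed`: no source contribution (means/SDs pinned at the inputs).
#'
#' This function is independent of the C++ sampler and doubles as its
#' test oracle.
#'
#' @param state parameter state list; see [individual_proportions()] plus
#'   `residual_sd`, `xi`, `source_means`, `source_sds` (or `source_covs`)
#'   as required by the spec.
#' @param spec a [model_spec()].
#' @param mix a [mixture_data()].
#' @param src a [source_data()].
#' @param disc a [discrimination_data()].
#' @return list with `mixture` (length-N vector of per-consumer joint
#'   log-densities), `source` (scalar), and `total`.
#' @export
log_likelihood_pointwise <- function(state, spec, mix, src, disc) {
  spec <- validate_model(spec, mix, src, disc)
  N <- nrow(mix$values); J <- ncol(mix$values)
  P <- individual_proportions(state, spec$effects, mix)
  mu_s <- if (src$treatment == "fixed") src$means else state$source_means
  sd_s <- if (src$treatment == "fixed") src$sds else state$source_sds
  covs <- if (spec$use_covariance) state$source_covs else NULL
  conc <- if (spec$use_concentration) src$concentrations else NULL
  ll_mix <- numeric(N)
  for (i in seq_len(N)) {
    m <- mixture_mean(P[i, ], mu_s, disc$means, conc)
    if (!is.null(covs)) {
      Om <- mixture_scale(P[i, ], sd_s, disc$sds, spec$error, xi = state$xi,
                          concentrations = conc, source_covs = covs)
      ll_mix[i] <- dmvnorm_log(mix$values[i, ], m, Om)
    } else {
      v <- mixture_scale(P[i, ], sd_s, disc$sds, spec$error,
                         sigma = state$residual_sd, xi = state$xi,
                         concentrations = conc)
      ll_mix[i] <- sum(stats::dnorm(mix$values[i, ], m, sqrt(v), log = TRUE))
    }
    if (!is.finite(ll_mix[i])) {
      stop(sprintf("non-finite mixture log-likelihood at row %d", i), call. = FALSE)
    }
  }
  ll_src <- 0
  if (src$treatment == "summary") {
    K <- nrow(src$means)
    for (k in seq_len(K)) for (j in seq_len(J)) {
      n <- src$sample_sizes[k]
      om <- sd_s[k, j]
      ll_src <- ll_src +
        stats::dnorm(src$means[k, j], mu_s[k, j], om / sqrt(n), log = TRUE)
      if (n > 1L) {
        stat <- (n - 1) * src$sds[k, j]^2 / om^2
        ll_src <- ll_src + stats::dchisq(stat, df = n - 1, log = TRUE) +
          log((n - 1) / om^2)
      }
    }
  } else if (src$treatment == "raw") {
    for (k in seq_along(src$raw_samples)) {
      Xs <- src$raw_samples[[k]]
      if (!is.null(covs)) {
        for (r in seq_len(nrow(Xs))) {
          ll_src <- ll_src + dmvnorm_log(Xs[r, ], mu_s[k, ], as.matrix(covs[[k]]))
        }
      } else {
        for (j in seq_len(J)) {
          ll_src <- ll_src +
            sum(stats::dnorm(Xs[, j], mu_s[k, j], sd_s[k, j], log = TRUE))
        }
      }
    }
  }
  list(mixture = ll_mix, source = ll_src, total = sum(ll_mix) + ll_src)
}

# Small-J multivariate normal log-density (no external dependency).
dmvnorm_log <- function(x, mu, Sigma) {
  ch <- chol(Sigma)
  z <- backsolve(ch, x - mu, transpose = TRUE)
  -0.5 * length(x) * log(2 * pi) - sum(log(diag(ch))) - 0.5 * sum(z^2)
}
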