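#' Widely applicable information criterion (WAIC)
#'
#' \eqn{elpd_{waic} = \sum_i [\log \frac{1}{S}\sum_s e^{ll_{si}} -
#' Var_s(ll_{si})]}, \eqn{WAIC = -2\, elpd}. The standard error follows
#' from the across-observation variance of the pointwise contributions.
#'
#' @param pointwise_loglik draws x observations matrix of pointwise
#'   log-likelihoods (finite), e.g. `fit$loglik`.
#' @return list with `waic`, `se`, `p_waic`, `elpd`, and `pointwise`
#'   (per-observation elpd contributions).
#' @export
waic <- function(pointwise_loglik) {
  ll <- as.matrix(pointwise_loglik)
  if (nrow(ll) < 2L) stop("need at least 2 draws", call. = FALSE)
  if (any(!is.finite(ll))) stop("pointwise log-likelihoods must be finite", call. = FALSE)
  lpd <- apply(ll, 2L, logsumexp) - log(nrow(ll))
  p_i <- apply(ll, 2L, stats::var)
  pw <- lpd - p_i
  elpd <- sum(pw)
  list(waic = -2 * elpd, se = 2 * sqrt(ncol(ll) * stats::var(pw)),
       p_waic = sum(p_i), elpd = elpd, pointwise = pw)
}

# Generalized-Pareto fit to exceedances (Zhang & Stephens 2009 profile
# posterior-mean method). x must be positive exceedances over the cutoff.
gpd_fit <- function(x) {
  x <- sort(x)
  n <- length(x)
  if (n < 5L || x[n] <= 0 || stats::sd(x) == 0) {
    return(list(k = NA_real_, sigma = NA_real_))
  }
  m <- 30L + floor(sqrt(n))
  jj <- seq_len(m)
  xstar <- x[max(1L, floor(n / 4 + 0.5))]
  theta <- 1 / x[n] + (1 - sqrt(m / (jj - 0.5))) / (3 * xstar)
  kfun <- function(b) -mean(log1p(-b * x))
  lth <- vapply(theta, function(b) {
    k <- kfun(b)
    n * (log(b / k) + k - 1)
  }, numeric(1))
  w <- exp(lth - logsumexp(lth))
  b_hat <- sum(w * theta)
  k_hat <- kfun(b_hat)
  list(k = k_hat, sigma = k_hat / b_hat)
}

# Pareto-smooth one vector of log importance ratios; returns smoothed
# log weights and the shape diagnostic k.
psis_smooth <- function(lw, tail_len) {
  S <- length(lw)
  lw <- lw - max(lw)
  if (tail_len < 5L) return(list(lw = lw, k = NA_real_))
  ord <- order(lw)
  tail_idx <- ord[(S - tail_len + 1L):S]
  cut <- exp(lw[ord[S - tail_len]])
  exceed <- exp(lw[tail_idx]) - cut
  fit <- gpd_fit(exceed)
  if (!is.finite(fit$k)) return(list(lw = lw, k = fit$k))
  q <- (seq_len(tail_len) - 0.5) / tail_len
  smoothed <- if (abs(fit$k) < 1e-12) {
    cut - fit$sigma * log1p(-q)
  } else {
    cut + fit$sigma / fit$k * ((1 - q)^(-fit$k) - 1)
  }
  smoothed <- pmin(smoothed, exp(0))            # truncate at the raw max
  lw[tail_idx[order(exp(lw[tail_idx]))]] <- log(smoothed)
  list(lw = lw, k = fit$k)
}

#' Pareto-smoothed importance-sampling leave-one-out cross-validation
#'
#' Approximates exact leave-one-out by importance sampling with
#' generalized-Pareto smoothing of the largest `min(0.2 S, 3 sqrt(S))`
#' importance ratios per observation. Observations with tail shape
#' `k > 0.7` are flagged as unreliable.
#'
#' @param pointwise_loglik draws x observations matrix.
#' @return list with `looic`, `se`, `elpd`, `pareto_k` (per
#'   observation), `flagged` (indices with k > 0.7), and `pointwise`.
#' @export
psis_loo <- function(pointwise_loglik) {
  ll <- as.matrix(pointwise_loglik)
  if (nrow(ll) < 2L) stop("need at least 2 draws", call. = FALSE)
  if (any(!is.finite(ll))) stop("pointwise log-likelihoods must be finite", call. = FALSE)
  S <- nrow(ll); N <- ncol(ll)
  tail_len <- floor(min(0.2 * S, 3 * sqrt(S)))
  pw <- numeric(N); k <- numeric(N)
  for (i in seq_len(N)) {
    sm <- psis_smooth(-ll[, i], tail_len)
    pw[i] <- logsumexp(sm$lw + ll[, i]) - logsumexp(sm$lw)
    k[i] <- sm$k
  }
  elpd <- sum(pw)
  list(looic = -2 * elpd, se = 2 * sqrt(N * stats::var(pw)), elpd = elpd,
       pareto_k = k, flagged = which(is.finite(k) & k > 0.7), pointwise = pw)
}

#' Relative-support table for a set of fitted models
#'
#' Computes PSIS-LOO for every fit, differences against the best
#' (lowest LOOic) model, standard errors of the differences from the
#' paired pointwise contributions, and Akaike weights
#' \eqn{w_m = e^{-\Delta_m/2} / \sum e^{-\Delta/2}} — the estimated
#' probability each model predicts best on new data. Per-tracer
#' posterior medians of the multiplicative error \eqn{\xi_j} are
#' appended when present. All fits must be to identical mixture data
#' (enforced via a data fingerprint).
#'
#' @param fits named list of `mixing_fit` objects.
#' @return data.frame of class `comparison_table`, rows sorted by
#'   LOOic: `model`, `LOOic`, `SE_LOOic`, `dLOOic`, `SE_dLOOic`,
#'   `weight`, and `xi_<tracer>` columns where applicable.
#' @export
compare_models <- function(fits) {
  if (length(fits) < 2L) stop("compare at least 2 fitted models", call. = FALSE)
  stopifnot(all(vapply(fits, inherits, logical(1), "mixing_fit")))
  if (is.null(names(fits))) names(fits) <- paste0("model", seq_along(fits))
  hashes <- vapply(fits, `[[`, character(1), "data_hash")
  if (length(unique(hashes)) != 1L) {
    stop("models were not fitted to identical mixture data; refusing to compare",
         call. = FALSE)
  }
  loos <- lapply(fits, function(f) psis_loo(f$loglik))
  looic <- vapply(loos, `[[`, numeric(1), "looic")
  se <- vapply(loos, `[[`, numeric(1), "se")
  best <- which.min(looic)
  d <- looic - looic[best]
  se_d <- vapply(seq_along(fits), function(m) {
    if (m == best) return(NA_real_)
    diff <- loos[[m]]$pointwise - loos[[best]]$pointwise
    2 * sqrt(length(diff) * stats::var(diff))
  }, numeric(1))
  w <- exp(-0.5 * d); w <- w / sum(w)
  out <- data.frame(model = names(fits), LOOic = looic, SE_LOOic = se,
                    dLOOic = d, SE_dLOOic = se_d, weight = w,
                    row.names = NULL, stringsAsFactors = FALSE)
  tracers <- fits[[1L]]$mix$tracer_names
  for (j in seq_along(tracers)) {
    out[[paste0("xi_", tracers[j])]] <- vapply(fits, function(f) {
      cn <- paste0("log_xi[", tracers[j], "]")
      if (cn %in% colnames(f$draws)) stats::median(exp(f$draws[, cn])) else NA_real_
    }, numeric(1))
  }
  out <- out[order(out$LOOic), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("comparison_table", "data.frame")
  out
}
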