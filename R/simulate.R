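#' Simulation scenario
#'
#' Declares the complete generative story for a synthetic tracer data
#' set: the true diet (global, or a rule linking diet to covariates via
#' ILR coefficients), the source populations, discrimination,
#' concentrations, and the mixture error regime. The generator draws
#' data with exactly the statistical structure each error structure and
#' effect design assumes, so every model stage is testable offline.
#'
#' @param K,J,N numbers of sources, tracers, consumers.
#' @param p true global diet proportions (length K); ignored when
#'   covariate rules are given (the intercept is then `ilr_intercept`).
#' @param ilr_intercept true ILR intercept (default `ilr_transform(p)`).
#' @param source_means,source_sds K x J matrices of true source tracer
#'   means and SDs.
#' @param source_cor optional J x J tracer correlation matrix shared by
#'   all sources (raw-sample generation and mixture process noise).
#' @param source_n per-source sample sizes for [simulate_sources()].
#' @param disc_means,disc_sds K x J discrimination means/SDs (default 0).
#' @param concentrations optional K x J concentration matrix in (0, 1].
#' @param error_kind one of the [error_spec()] kinds.
#' @param sigma true residual SDs (length J; residual_only).
#' @param xi true multiplicative terms (length J; process_x_multiplicative).
#' @param continuous named list of continuous-covariate rules:
#'   `list(range = c(lo, hi), beta = <K-1 vector>)` (beta on the
#'   standardized scale of the generated covariate).
#' @param fixed_factors named list of fixed-factor rules:
#'   `list(levels = <labels>, beta = <(L-1) x (K-1) matrix>)` (treatment
#'   coding, first level baseline).
#' @param random_factors named list of random-factor rules:
#'   `list(L = <levels>, gamma = <SD of ILR offsets>)`.
#' @param seed integer seed; fixes every draw of the scenario.
#' @return an object of class `simulation_scenario`.
#' @export
simulation_scenario <- function(K, J, N, p = rep(1 / K, K), ilr_intercept = NULL,
                                source_means, source_sds, source_cor = NULL,
                                source_n = rep(25L, K),
                                disc_means = NULL, disc_sds = NULL,
                                concentrations = NULL,
                                error_kind = "process_x_multiplicative",
                                sigma = NULL, xi = NULL,
                                continuous = list(), fixed_factors = list(),
                                random_factors = list(), seed = 1L) {
  K <- as.integer(K); J <- as.integer(J); N <- as.integer(N)
  stopifnot(K >= 2L, J >= 1L, N >= 1L)
  source_means <- matrix(as.numeric(source_means), K, J)
  source_sds <- matrix(as.numeric(source_sds), K, J)
  stopifnot(all(source_sds > 0))
  if (is.null(ilr_intercept)) {
    stopifnot(length(p) == K, all(p > 0))
    p <- p / sum(p)
    ilr_intercept <- ilr_transform(p)
  }
  error_kind <- match.arg(error_kind,
                          c("process_x_multiplicative", "residual_only", "process_only"))
  if (error_kind == "residual_only") {
    stopifnot(length(sigma) == J, all(sigma > 0))
  }
  if (error_kind == "process_x_multiplicative") {
    if (is.null(xi)) xi <- rep(1, J)
    stopifnot(length(xi) == J, all(xi > 0))
  }
  if (is.null(disc_means)) disc_means <- matrix(0, K, J)
  if (is.null(disc_sds)) disc_sds <- matrix(0, K, J)
  if (!is.null(source_cor)) {
    source_cor <- matrix(as.numeric(source_cor), J, J)
    stopifnot(isSymmetric(source_cor), all(diag(source_cor) == 1))
  }
  structure(list(K = K, J = J, N = N, p = p, ilr_intercept = ilr_intercept,
                 source_means = matrix(disc_check(source_means), K, J),
                 source_sds = source_sds, source_cor = source_cor,
                 source_n = as.integer(source_n),
                 disc_means = matrix(as.numeric(disc_means), K, J),
                 disc_sds = matrix(as.numeric(disc_sds), K, J),
                 concentrations = concentrations,
                 error_kind = error_kind, sigma = sigma, xi = xi,
                 continuous = continuous, fixed_factors = fixed_factors,
                 random_factors = random_factors, seed = as.integer(seed)),
            class = "simulation_scenario")
}

disc_check <- function(x) { stopifnot(all(is.finite(x))); as.numeric(x) }

# Correlated normal rows: n x J draws with given SD vector and correlation.
rmvn_rows <- function(n, mean, sds, cor = NULL) {
  J <- length(mean)
  Z <- matrix(stats::rnorm(n * J), n, J)
  if (!is.null(cor)) Z <- Z %*% chol(cor)
  sweep(Z, 2L, sds, `*`) + matrix(mean, n, J, byrow = TRUE)
}

#' Simulate source data under a scenario
#'
#' Raw per-source samples are drawn from (multivariate) normal source
#' populations; `mode = "summary"` reports the exact sample statistics
#' of those draws. Deterministic given the scenario seed.
#'
#' @param scenario a [simulation_scenario()].
#' @param mode `"raw"` or `"summary"`.
#' @return a [source_data()].
#' @export
simulate_sources <- function(scenario, mode = c("summary", "raw")) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  mode <- match.arg(mode)
  old <- .Random.seed_guard(scenario$seed + 1L)
  on.exit(old(), add = TRUE)
  raw <- lapply(seq_len(scenario$K), function(k) {
    rmvn_rows(scenario$source_n[k], scenario$source_means[k, ],
              scenario$source_sds[k, ], scenario$source_cor)
  })
  names(raw) <- paste0("source", seq_len(scenario$K))
  means <- per_source_stat(raw, colMeans, scenario$J)
  sds <- per_source_stat(raw, function(m) apply(m, 2L, stats::sd), scenario$J)
  if (mode == "raw") {
    source_data("raw", means, sds, scenario$source_n, raw_samples = raw,
                concentrations = scenario$concentrations)
  } else {
    source_data("summary", means, sds, scenario$source_n,
                source_names = names(raw),
                concentrations = scenario$concentrations)
  }
}

#' Simulate mixture (consumer) data under a scenario
#'
#' Generates covariates, per-individual diet proportions through the
#' ILR linear predictor, and tracer values under the scenario's error
#' regime using the *true* source parameters:
#' * residual: \eqn{Y_{ij} ~ N(\sum_k p_{ik}(\mu_{jk}+\lambda_{jk}), \sigma_j^2)};
#' * process regimes: variance \eqn{\sum_k q_{ikj}^2(\omega_{jk}^2+\tau_{jk}^2)}
#'   scaled by \eqn{\xi_j} (with concentration weights \eqn{q} when present,
#'   correlated across tracers if `source_cor` is set).
#'
#' The true per-individual proportions and all latent effects are stored
#' in `attr(, "truth")` for recovery tests.
#'
#' @param scenario a [simulation_scenario()].
#' @return a [mixture_data()] with a `truth` attribute.
#' @export
simulate_mixture <- function(scenario) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  old <- .Random.seed_guard(scenario$seed + 2L)
  on.exit(old(), add = TRUE)
  K <- scenario$K; J <- scenario$J; N <- scenario$N; Km1 <- K - 1L
  Z <- matrix(rep(scenario$ilr_intercept, each = N), N, Km1)
  cont <- list(); fixed <- list(); random <- list()
  truth <- list(ilr_intercept = scenario$ilr_intercept,
                coefficients = list(), offsets = list(), gamma = list())
  for (nm in names(scenario$continuous)) {
    rule <- scenario$continuous[[nm]]
    x <- stats::runif(N, rule$range[1L], rule$range[2L])
    if (!is.null(rule$values)) x <- rule$values
    xs <- (x - mean(x)) / stats::sd(x)
    Z <- Z + outer(xs, as.numeric(rule$beta))
    cont[[nm]] <- x
    truth$coefficients[[nm]] <- as.numeric(rule$beta)
  }
  for (nm in names(scenario$fixed_factors)) {
    rule <- scenario$fixed_factors[[nm]]
    L <- length(rule$levels)
    lev <- rule$levels[sample.int(L, N, replace = TRUE)]
    lev[seq_len(L)] <- rule$levels          # every level observed
    beta <- matrix(as.numeric(rule$beta), L - 1L, Km1)
    idx <- match(lev, rule$levels)
    add <- rbind(rep(0, Km1), beta)[idx, , drop = FALSE]
    Z <- Z + add
    fixed[[nm]] <- lev
    truth$coefficients[[nm]] <- beta
  }
  for (nm in names(scenario$random_factors)) {
    rule <- scenario$random_factors[[nm]]
    L <- as.integer(rule$L)
    lev_labels <- paste0(nm, seq_len(L))
    idx <- rep_len(seq_len(L), N)[sample.int(N)]
    off <- matrix(stats::rnorm(L * Km1, 0, rule$gamma), L, Km1)
    Z <- Z + off[idx, , drop = FALSE]
    random[[nm]] <- lev_labels[idx]
    truth$offsets[[nm]] <- off
    truth$gamma[[nm]] <- rule$gamma
  }
  P <- inverse_ilr(Z)
  mu_eff <- scenario$source_means + scenario$disc_means
  var_s <- scenario$source_sds^2 + scenario$disc_sds^2
  Y <- matrix(NA_real_, N, J)
  for (i in seq_len(N)) {
    q <- if (is.null(scenario$concentrations)) {
      matrix(P[i, ], K, J)
    } else {
      sweep(P[i, ] * scenario$concentrations, 2L,
            colSums(P[i, ] * scenario$concentrations), `/`)
    }
    m <- colSums(q * mu_eff)
    if (scenario$error_kind == "residual_only") {
      Y[i, ] <- stats::rnorm(J, m, scenario$sigma)
    } else {
      xi <- if (scenario$error_kind == "process_x_multiplicative") scenario$xi else rep(1, J)
      if (is.null(scenario$source_cor)) {
        v <- colSums(q^2 * var_s) * xi
        Y[i, ] <- stats::rnorm(J, m, sqrt(v))
      } else {
        Om <- matrix(0, J, J)
        for (k in seq_len(K)) {
          Sk <- outer(scenario$source_sds[k, ], scenario$source_sds[k, ]) *
            scenario$source_cor + diag(scenario$disc_sds[k, ]^2, J)
          Om <- Om + tcrossprod(q[k, ]) * Sk
        }
        Om <- Om * outer(sqrt(xi), sqrt(xi))
        Y[i, ] <- m + as.numeric(crossprod(chol(Om), stats::rnorm(J)))
      }
    }
  }
  truth$p <- scenario$p
  truth$p_individual <- P
  mix <- mixture_data(Y, tracer_names = paste0("tracer", seq_len(J)),
                      fixed_factors = fixed, random_factors = random,
                      continuous_covariates = cont)
  attr(mix, "truth") <- truth
  mix
}

#' Alligator-style synthetic case-study bundle
#'
#' Generates a synthetic data set with the structure of the classic
#' estuarine-consumer case study: 181 consumers, two sources
#' (freshwater, marine), two tracers (d13C, d15N), a strong ontogenetic
#' shift (total Length, cm) from a freshwater diet in small animals to a
#' marine diet in large ones, a null Sex effect, a Size-class factor
#' binned from Length, and individual-level random diet variation. The
#' mixture error regime is process-by-multiplicative with an elevated
#' carbon xi, emulating unmodelled structure on that tracer.
#'
#' This is a synthetic stand-in, not the published data set: quantities
#' estimated from it test structure and recovery, not the published
#' numbers.
#'
#' @param seed integer seed.
#' @param n_consumers number of consumers (default 181).
#' @return list with `mix`, `src` (summary treatment), `disc`,
#'   `scenario`, and `truth` (the latent state used for generation).
#' @export
alligator_like_fixture <- function(seed = 1L, n_consumers = 181L) {
  len_range <- c(37.7, 315.5)
  # anchor the true diet rule at p_marine = 0.09 (smallest) and 0.96 (largest)
  z_lo <- ilr_transform(c(0.91, 0.09))
  z_hi <- ilr_transform(c(0.04, 0.96))
  old <- .Random.seed_guard(seed + 11L)
  lengths <- len_range[1L] + diff(len_range) * stats::rbeta(n_consumers, 1.3, 2.2)
  old()
  lengths[1L] <- len_range[1L]; lengths[2L] <- len_range[2L]; lengths[3L] <- 116.9
  slope_raw <- (z_hi - z_lo) / diff(len_range)
  beta_len <- slope_raw * stats::sd(lengths)
  intercept <- z_lo + slope_raw * (mean(lengths) - len_range[1L])
  scen <- simulation_scenario(
    K = 2L, J = 2L, N = n_consumers,
    ilr_intercept = intercept,
    source_means = rbind(c(-27.0, 7.0),   # freshwater: d13C, d15N
                         c(-17.5, 12.0)), # marine
    source_sds = rbind(c(1.6, 1.1), c(1.1, 1.0)),
    source_n = c(25L, 25L),
    disc_means = rbind(c(0.4, 2.3), c(0.4, 2.3)),
    disc_sds = rbind(c(0.5, 0.6), c(0.5, 0.6)),
    error_kind = "process_x_multiplicative",
    xi = c(5.3, 1.0),
    continuous = list(Length = list(range = len_range, values = lengths,
                                    beta = beta_len)),
    fixed_factors = list(Sex = list(levels = c("female", "male"),
                                    beta = matrix(0, 1L, 1L))),
    random_factors = list(Individual = list(L = n_consumers, gamma = 0.5)),
    seed = seed
  )
  src <- simulate_sources(scen, mode = "summary")
  src$source_names <- c("freshwater", "marine")
  rownames(src$means) <- rownames(src$sds) <- src$source_names
  mix <- simulate_mixture(scen)
  mix$tracer_names <- c("d13C", "d15N")
  colnames(mix$values) <- mix$tracer_names
  src$tracer_names <- c("d13C", "d15N")
  colnames(src$means) <- colnames(src$sds) <- src$tracer_names
  # size classes binned from length, as in the original study design
  size_class <- cut(mix$continuous_covariates$Length,
                    breaks = c(0, 60, 120, 183, Inf),
                    labels = c("small juvenile", "large juvenile",
                               "subadult", "adult"))
  mix$fixed_factors$`Size class` <-
    factor(as.character(size_class), levels = unique(as.character(size_class)))
  disc <- discrimination_data(scen$disc_means, scen$disc_sds,
                              source_names = src$source_names,
                              tracer_names = src$tracer_names)
  list(mix = mix, src = src, disc = disc, scenario = scen,
       truth = attr(mix, "truth"))
}
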