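#' Source grouping for a-posteriori aggregation
#'
#' Maps every original source onto a group. Surjective and exhaustive:
#' each source is assigned exactly once and every group has at least one
#' member.
#'
#' @param map named character vector: `names(map)` are source names,
#'   values are group names.
#' @return an object of class `source_grouping` with `map` and `groups`
#'   (named list of member vectors, in first-appearance group order).
#' @export
source_grouping <- function(map) {
  map <- unlist(map)
  if (is.null(names(map)) || any(!nzchar(names(map)))) {
    stop("grouping must be a named vector: source name -> group name", call. = FALSE)
  }
  if (anyDuplicated(names(map))) {
    stop("every source must be assigned exactly once", call. = FALSE)
  }
  groups <- split(names(map), factor(map, levels = unique(map)))
  structure(list(map = map, groups = groups), class = "source_grouping")
}

as_source_grouping <- function(grouping, source_names) {
  g <- if (inherits(grouping, "source_grouping")) grouping else source_grouping(grouping)
  unknown <- setdiff(names(g$map), source_names)
  if (length(unknown)) {
    stop(sprintf("grouping names unknown source(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  missing <- setdiff(source_names, names(g$map))
  if (length(missing)) {
    stop(sprintf("grouping must cover every source; missing: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  g
}

#' Combine sources a posteriori
#'
#' For every posterior draw, the combined-group proportion is the sum of
#' its member proportions, so the grouped posterior accounts for the
#' correlation between the original proportions. The aggregated prior is
#' returned alongside as a warning payload: under the generalist prior,
#' merging G sources gives the combined group G times the prior weight
#' of an unmerged source, pulling its posterior upward.
#'
#' @param x a `mixing_fit`, or a draws x K matrix with source-name
#'   columns.
#' @param grouping a [source_grouping()] or a named source -> group map.
#' @param prior optional [dirichlet_prior()] (taken from the fit when
#'   `x` is a `mixing_fit`).
#' @return object of class `combined_sources`: `draws` (draws x G),
#'   `grouping`, `aggregated_prior`, `original_prior`.
#' @export
combine_sources <- function(x, grouping, prior = NULL) {
  if (inherits(x, "mixing_fit")) {
    if (is.null(prior)) prior <- x$spec$prior
    x <- p_global_draws(x)
  }
  x <- as.matrix(x)
  if (is.null(colnames(x))) stop("draws matrix needs source-name columns", call. = FALSE)
  g <- as_source_grouping(grouping, colnames(x))
  grouped <- vapply(g$groups, function(members) {
    rowSums(x[, members, drop = FALSE])
  }, numeric(nrow(x)))
  grouped <- matrix(grouped, nrow = nrow(x),
                    dimnames = list(NULL, names(g$groups)))
  agg <- if (!is.null(prior)) aggregate_prior(prior, g) else NULL
  structure(list(draws = grouped, grouping = g, aggregated_prior = agg,
                 original_prior = prior),
            class = "combined_sources")
}

#' @export
print.combined_sources <- function(x, ...) {
  cat("combined_sources:", ncol(x$draws), "groups from",
      length(x$grouping$map), "sources\n")
  print(posterior_summary(x$draws))
  if (!is.null(x$aggregated_prior)) {
    cat("note: the combined-source posterior reflects the aggregated prior\n")
    print(x$aggregated_prior)
  }
  invisible(x)
}

#' Specialization index
#'
#' Normalized Euclidean distance of a diet composition from the
#' perfect-generalist barycenter:
#' \deqn{\epsilon = \sqrt{\frac{K}{K-1} \sum_k (p_k - 1/K)^2}}
#' 0 at the generalist diet `(1/K, ..., 1/K)`, 1 at any vertex (complete
#' specialist). This is an interpretation of the specialization index
#' used in the trophic-ecology literature (the normalized
#' distance-from-barycenter form); it is invariant to source
#' permutation. Applied draw-wise to global, per-covariate-value, or
#' per-individual proportions.
#'
#' @param p simplex vector, or matrix with simplex rows.
#' @return scalar in `[0, 1]`, or a vector (one value per row).
#' @export
specialization_index <- function(p) {
  if (is.matrix(p)) return(apply(p, 1L, specialization_index))
  K <- length(p)
  sqrt((K / (K - 1)) * sum((p - 1 / K)^2))
}

#' Posterior predictions of diet proportions over a covariate grid
#'
#' Evaluates the fitted ILR-space linear predictor at user-supplied
#' covariate values and back-transforms each posterior draw, giving the
#' fitted-proportion curves (medians and credible bands) over the range
#' of a continuous covariate, or at chosen factor levels.
#'
#' Covariates omitted from `newdata` are held at their reference values:
#' continuous covariates at their observed mean (the centered design
#' makes this the identity) and factors at their baseline level. Random
#' effects are excluded (population-level prediction). Values outside
#' the observed covariate range error unless `allow_extrapolation`.
#'
#' @param fit_obj a `mixing_fit`.
#' @param newdata named list of covariate values; vectors are crossed
#'   into a grid with `expand.grid` when more than one is supplied.
#' @param probs quantiles to report per grid point and source.
#' @param allow_extrapolation permit values outside the observed range.
#' @return object of class `proportion_prediction`: `grid` (data.frame),
#'   `quantiles` (grid x source x prob array), `epsilon_quantiles`
#'   (grid x prob), and `draws` (draws x grid x source array).
#' @export
predict_proportions <- function(fit_obj, newdata, probs = c(0.05, 0.5, 0.95),
                                allow_extrapolation = FALSE) {
  stopifnot(inherits(fit_obj, "mixing_fit"))
  if (!length(newdata)) stop("newdata must name at least one covariate", call. = FALSE)
  grid <- expand.grid(newdata, stringsAsFactors = FALSE)
  des <- fit_obj$design
  eff <- fit_obj$spec$effects
  S <- nrow(fit_obj$draws)
  K <- length(fit_obj$src$source_names)
  Km1 <- K - 1L
  nm <- names(newdata)
  unknown <- setdiff(nm, c(eff$fixed_continuous, eff$fixed_categorical))
  if (length(unknown)) {
    stop(sprintf("not fixed effects in this model: %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  # design row for each grid point, mirroring build_design()
  X <- matrix(0, nrow(grid), ncol(des$X), dimnames = list(NULL, colnames(des$X)))
  for (v in nm) {
    if (v %in% eff$fixed_continuous) {
      raw <- fit_obj$mix$continuous_covariates[[v]]
      vals <- as.numeric(grid[[v]])
      if (!allow_extrapolation &&
          (any(vals < min(raw)) || any(vals > max(raw)))) {
        stop(sprintf("'%s' values outside the observed range [%g, %g]; set allow_extrapolation = TRUE to override",
                     v, min(raw), max(raw)), call. = FALSE)
      }
      X[, v] <- (vals - des$centers[v]) / des$scales[v]
    } else {
      f <- c(fit_obj$mix$fixed_factors, fit_obj$mix$random_factors)[[v]]
      lv <- as.character(grid[[v]])
      bad <- setdiff(lv, levels(f))
      if (length(bad)) {
        stop(sprintf("unseen level(s) of '%s': %s", v, paste(bad, collapse = ", ")),
             call. = FALSE)
      }
      for (l in levels(f)[-1L]) X[, paste0(v, l)] <- as.numeric(lv == l)
    }
  }
  beta0 <- fit_obj$draws[, paste0("beta0[", seq_len(Km1), "]"), drop = FALSE]
  B <- array(0, c(S, ncol(des$X), Km1))
  for (fi in seq_len(ncol(des$X))) {
    B[, fi, ] <- fit_obj$draws[, paste0("b_", colnames(des$X)[fi], "[",
                                        seq_len(Km1), "]"), drop = FALSE]
  }
  G <- nrow(grid)
  draws <- array(NA_real_, c(S, G, K),
                 dimnames = list(NULL, NULL, fit_obj$src$source_names))
  for (g in seq_len(G)) {
    Z <- beta0
    for (fi in seq_len(ncol(des$X))) {
      if (X[g, fi] != 0) Z <- Z + X[g, fi] * B[, fi, , drop = FALSE][, 1L, ]
    }
    draws[, g, ] <- inverse_ilr(Z)
  }
  qs <- apply(draws, c(2L, 3L), stats::quantile, probs = probs, names = FALSE)
  qs <- aperm(qs, c(2L, 3L, 1L))
  dimnames(qs) <- list(NULL, fit_obj$src$source_names, paste0("q", format(probs, trim = TRUE)))
  eps <- apply(draws, c(1L, 2L), function(p) specialization_index(p))
  eps_q <- t(apply(eps, 2L, stats::quantile, probs = probs, names = FALSE))
  colnames(eps_q) <- paste0("q", format(probs, trim = TRUE))
  structure(list(grid = grid, quantiles = qs, epsilon_quantiles = eps_q,
                 draws = draws),
            class = "proportion_prediction")
}

#' Mixing-polygon area diagnostic
#'
#' Convex-hull (shoelace) area of the discrimination-corrected source
#' means in two-tracer space, plus the fraction of mixture points inside
#' the hull (boundary counts as inside, using exact orientation
#' predicates). Mixture points outside the polygon violate the basic
#' mixing assumptions; a small polygon relative to source variability
#' warns that the prior will be influential.
#'
#' @param src a [source_data()].
#' @param disc a [discrimination_data()] or `NULL`.
#' @param mix a [mixture_data()] (J = 2 required).
#' @return list with `area`, `inside_fraction`, `hull` (vertex matrix),
#'   and `degenerate` flag.
#' @export
calc_area <- function(src, disc = NULL, mix) {
  stopifnot(inherits(src, "source_data"), inherits(mix, "mixture_data"))
  if (is.null(disc)) disc <- zero_discrimination(src)
  if (ncol(mix$values) != 2L || ncol(src$means) != 2L) {
    stop("the polygon diagnostic is defined for exactly 2 tracers", call. = FALSE)
  }
  pts <- src$means + disc$means
  K <- nrow(pts)
  if (K < 3L) {
    warning("fewer than 3 sources: degenerate polygon with area 0")
    return(list(area = 0, inside_fraction = NA_real_, hull = pts, degenerate = TRUE))
  }
  h <- grDevices::chull(pts)            # clockwise vertex order
  hull <- pts[h, , drop = FALSE]
  n <- nrow(hull)
  # shoelace
  x <- hull[, 1L]; y <- hull[, 2L]
  area2 <- sum(x * c(y[-1L], y[1L]) - c(x[-1L], x[1L]) * y)
  area <- abs(area2) / 2
  if (n < 3L || area == 0) {
    warning("collinear sources: degenerate polygon with area 0")
    return(list(area = 0, inside_fraction = NA_real_, hull = hull, degenerate = TRUE))
  }
  if (area2 > 0) { hull <- hull[n:1L, , drop = FALSE]; x <- hull[, 1L]; y <- hull[, 2L] }
  inside <- vapply(seq_len(nrow(mix$values)), function(i) {
    px <- mix$values[i, 1L]; py <- mix$values[i, 2L]
    # clockwise hull: inside iff every edge cross-product <= 0
    all(vapply(seq_len(n), function(e) {
      e2 <- if (e == n) 1L else e + 1L
      (x[e2] - x[e]) * (py - y[e]) - (y[e2] - y[e]) * (px - x[e]) <= 0
    }, logical(1)))
  }, logical(1))
  list(area = area, inside_fraction = mean(inside), hull = hull, degenerate = FALSE)
}
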