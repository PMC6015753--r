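#' Mixture (consumer) tracer data
#'
#' Container for the N x J matrix of mixture tracer values plus any
#' covariates attached to the mixture rows. In diet studies the rows are
#' consumers and the columns are tracers (e.g. d13C, d15N in permil).
#'
#' Factors keep their levels in order of first appearance so design
#' matrices are reproducible regardless of locale. A factor with exactly
#' two levels may only be used as a fixed effect: random-effect SDs are
#' not estimable from two groups.
#'
#' @param values numeric N x J matrix, no missing values.
#' @param tracer_names character vector of J tracer labels.
#' @param fixed_factors named list of factor/character vectors (length N)
#'   used as fixed categorical effects.
#' @param random_factors named list of factor/character vectors (length N)
#'   used as random effects; each needs >= 3 levels.
#' @param continuous_covariates named list of numeric vectors (length N).
#' @param ids optional character vector of N row labels.
#' @return an object of class `mixture_data`.
#' @export
mixture_data <- function(values, tracer_names = colnames(values),
                         fixed_factors = list(), random_factors = list(),
                         continuous_covariates = list(), ids = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  N <- nrow(values); J <- ncol(values)
  if (N < 1L || J < 1L) stop("mixture data needs N >= 1 rows and J >= 1 tracers", call. = FALSE)
  if (anyNA(values) || any(!is.finite(values))) {
    stop("mixture tracer values must be complete and finite", call. = FALSE)
  }
  if (is.null(tracer_names)) tracer_names <- paste0("tracer", seq_len(J))
  if (length(tracer_names) != J) stop("tracer_names must have one label per column", call. = FALSE)
  colnames(values) <- tracer_names

  mk_factor <- function(x, nm, role) {
    if (length(x) != N) stop(sprintf("factor '%s' must have %d values", nm, N), call. = FALSE)
    f <- factor(as.character(x), levels = unique(as.character(x)))
    if (nlevels(f) < 2L) {
      stop(sprintf("factor '%s' needs >= 2 levels to be used as an effect", nm), call. = FALSE)
    }
    if (role == "random" && nlevels(f) == 2L) {
      stop(sprintf(paste("factor '%s' has only 2 levels and must be used as a",
                         "fixed effect: a random-effect SD cannot be estimated",
                         "from two groups"), nm), call. = FALSE)
    }
    f
  }
  check_named <- function(lst, what) {
    if (length(lst) && (is.null(names(lst)) || any(!nzchar(names(lst))))) {
      stop(sprintf("%s must be a named list", what), call. = FALSE)
    }
  }
  check_named(fixed_factors, "fixed_factors")
  check_named(random_factors, "random_factors")
  check_named(continuous_covariates, "continuous_covariates")
  if (any(names(fixed_factors) %in% names(random_factors))) {
    stop("a factor may appear in at most one of fixed/random roles", call. = FALSE)
  }
  fixed_factors <- mapply(mk_factor, fixed_factors, names(fixed_factors),
                          MoreArgs = list(role = "fixed"), SIMPLIFY = FALSE)
  random_factors <- mapply(mk_factor, random_factors, names(random_factors),
                           MoreArgs = list(role = "random"), SIMPLIFY = FALSE)
  continuous_covariates <- lapply(continuous_covariates, function(x) {
    x <- as.numeric(x)
    if (length(x) != N || anyNA(x) || any(!is.finite(x))) {
      stop("continuous covariates must be complete finite numeric vectors of length N",
           call. = FALSE)
    }
    x
  })
  if (is.null(ids)) ids <- as.character(seq_len(N))
  if (length(ids) != N) stop("ids must have one label per row", call. = FALSE)
  structure(list(values = values, tracer_names = tracer_names,
                 fixed_factors = fixed_factors, random_factors = random_factors,
                 continuous_covariates = continuous_covariates,
                 ids = as.character(ids)),
            class = "mixture_data")
}

#' @export
print.mixture_data <- function(x, ...) {
  cat(sprintf("mixture_data: %d consumers x %d tracers (%s)\n",
              nrow(x$values), ncol(x$values), paste(x$tracer_names, collapse = ", ")))
  if (length(x$fixed_factors))
    cat("  fixed factors:", paste(names(x$fixed_factors), collapse = ", "), "\n")
  if (length(x$random_factors))
    cat("  random factors:", paste(names(x$random_factors), collapse = ", "), "\n")
  if (length(x$continuous_covariates))
    cat("  continuous:", paste(names(x$continuous_covariates), collapse = ", "), "\n")
  invisible(x)
}

#' Source tracer data
#'
#' Per-source tracer information in one of three treatments:
#' * `"raw"`: one tracer sample per source individual; the model treats
#'   the true source means/variances as parameters informed by these
#'   samples (and can estimate tracer covariance);
#' * `"summary"`: mean, SD and sample size per source and tracer; the
#'   model still estimates true means/variances but assumes independent
#'   tracers;
#' * `"fixed"`: means/SDs taken as known, not updated (the classic
#'   MixSIR/SIAR behaviour, also approached by `summary` with huge n).
#'
#' @param treatment one of `"raw"`, `"summary"`, `"fixed"`.
#' @param means K x J matrix of source tracer means.
#' @param sds K x J matrix of source tracer SDs (> 0 for summary/fixed).
#' @param sample_sizes integer vector of K per-source sample sizes.
#' @param source_names character vector of K source labels.
#' @param tracer_names character vector of J tracer labels.
#' @param raw_samples for `treatment = "raw"`: named list of per-source
#'   `n_k x J` matrices, `n_k >= 2`.
#' @param concentrations optional K x J matrix of elemental concentration
#'   proportions in (0, 1]; percentages must be pre-divided by 100.
#' @return an object of class `source_data`.
#' @export
source_data <- function(treatment, means, sds, sample_sizes,
                        source_names = rownames(means),
                        tracer_names = colnames(means),
                        raw_samples = NULL, concentrations = NULL) {
  treatment <- match.arg(treatment, c("raw", "summary", "fixed"))
  means <- as.matrix(means); storage.mode(means) <- "double"
  sds <- as.matrix(sds); storage.mode(sds) <- "double"
  K <- nrow(means); J <- ncol(means)
  if (K < 2L) stop("a mixing model needs K >= 2 sources", call. = FALSE)
  if (!all(dim(sds) == c(K, J))) stop("sds must match the K x J shape of means", call. = FALSE)
  if (anyNA(means) || anyNA(sds)) stop("source means/sds must be complete", call. = FALSE)
  if (any(sds <= 0)) stop("source SDs must be strictly positive", call. = FALSE)
  if (is.null(source_names)) source_names <- paste0("source", seq_len(K))
  if (is.null(tracer_names)) tracer_names <- paste0("tracer", seq_len(J))
  sample_sizes <- as.integer(sample_sizes)
  if (length(sample_sizes) != K || anyNA(sample_sizes) || any(sample_sizes < 1L)) {
    stop("sample_sizes must be K positive integers", call. = FALSE)
  }
  if (treatment == "raw") {
    if (is.null(raw_samples) || length(raw_samples) != K) {
      stop("raw treatment requires one sample matrix per source", call. = FALSE)
    }
    raw_samples <- lapply(raw_samples, function(m) {
      m <- as.matrix(m); storage.mode(m) <- "double"
      if (ncol(m) != J || nrow(m) < 2L || anyNA(m)) {
        stop("each raw source needs >= 2 complete samples per tracer", call. = FALSE)
      }
      colnames(m) <- tracer_names
      m
    })
    names(raw_samples) <- source_names
    sample_sizes <- vapply(raw_samples, nrow, integer(1))
  } else {
    raw_samples <- NULL
  }
  if (!is.null(concentrations)) {
    concentrations <- as.matrix(concentrations)
    storage.mode(concentrations) <- "double"
    if (!all(dim(concentrations) == c(K, J))) {
      stop("concentrations must be a K x J matrix", call. = FALSE)
    }
    if (anyNA(concentrations) || any(concentrations <= 0) || any(concentrations > 1)) {
      stop("concentrations must lie in (0, 1]; divide percentages by 100", call. = FALSE)
    }
    dimnames(concentrations) <- list(source_names, tracer_names)
  }
  dimnames(means) <- dimnames(sds) <- list(source_names, tracer_names)
  structure(list(treatment = treatment, source_names = as.character(source_names),
                 tracer_names = as.character(tracer_names),
                 means = means, sds = sds, sample_sizes = sample_sizes,
                 raw_samples = raw_samples, concentrations = concentrations),
            class = "source_data")
}

#' @export
print.source_data <- function(x, ...) {
  cat(sprintf("source_data (%s): %d sources x %d tracers%s\n", x$treatment,
              length(x$source_names), length(x$tracer_names),
              if (is.null(x$concentrations)) "" else ", with concentrations"))
  print(data.frame(source = x$source_names, n = x$sample_sizes, x$means,
                   check.names = FALSE, row.names = NULL))
  invisible(x)
}

#' Discrimination (trophic enrichment) data
#'
#' The systematic per-source, per-tracer shift between source and mixture
#' tissue, with its uncertainty. All-zero matrices are valid (tracers
#' needing no discrimination correction).
#'
#' @param means K x J matrix of discrimination means (tracer units).
#' @param sds K x J matrix of discrimination SDs, `>= 0`.
#' @param source_names,tracer_names optional labels.
#' @return an object of class `discrimination_data`.
#' @export
discrimination_data <- function(means, sds = NULL,
                                source_names = rownames(means),
                                tracer_names = colnames(means)) {
  means <- as.matrix(means); storage.mode(means) <- "double"
  if (is.null(sds)) sds <- matrix(0, nrow(means), ncol(means))
  sds <- as.matrix(sds); storage.mode(sds) <- "double"
  if (!all(dim(sds) == dim(means))) stop("discrimination sds must match means", call. = FALSE)
  if (anyNA(means) || anyNA(sds) || any(sds < 0)) {
    stop("discrimination means must be complete; sds must be >= 0", call. = FALSE)
  }
  if (!is.null(source_names)) rownames(means) <- rownames(sds) <- source_names
  if (!is.null(tracer_names)) colnames(means) <- colnames(sds) <- tracer_names
  structure(list(means = means, sds = sds), class = "discrimination_data")
}

#' All-zero discrimination for a source set
#' @param source_obj a [source_data()] object.
#' @return a zero [discrimination_data()] with matching shape.
#' @export
zero_discrimination <- function(source_obj) {
  stopifnot(inherits(source_obj, "source_data"))
  z <- matrix(0, length(source_obj$source_names), length(source_obj$tracer_names),
              dimnames = list(source_obj$source_names, source_obj$tracer_names))
  discrimination_data(z, z)
}

# -- delimited-file plumbing -------------------------------------------------

# Apply a per-source summary returning a K x J matrix (J = 1 safe).
per_source_stat <- function(lst, f, J) {
  v <- vapply(lst, f, numeric(J))
  if (J == 1L) matrix(v, ncol = 1L) else t(v)
}

# Delimiter auto-detection is deliberately limited to comma and tab
# (decimal point only) for determinism.
detect_delim <- function(path) {
  header <- readLines(path, n = 1L)
  if (lengths(regmatches(header, gregexpr("\t", header))) >
      lengths(regmatches(header, gregexpr(",", header)))) "\t" else ","
}

read_delim_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  utils::read.table(path, header = TRUE, sep = detect_delim(path),
                    stringsAsFactors = FALSE, check.names = FALSE,
                    comment.char = "", quote = "\"")
}

require_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(sprintf("file '%s' is missing required column(s): %s",
                 path, paste(missing, collapse = ", ")), call. = FALSE)
  }
}

numeric_column <- function(df, col, path) {
  x <- df[[col]]
  xn <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(xn) & !is.na(x))
  if (length(bad)) {
    stop(sprintf("column '%s' of '%s' is not numeric at row %d (value '%s')",
                 col, path, bad[1L], x[bad[1L]]), call. = FALSE)
  }
  if (anyNA(xn)) {
    stop(sprintf("column '%s' of '%s' has missing values", col, path), call. = FALSE)
  }
  xn
}

#' Read a mixture (consumer) table
#'
#' One row per consumer; tracer columns are named by tracer (e.g. `d13C`).
#'
#' @param path CSV/TSV file path.
#' @param tracer_columns character vector of tracer column names.
#' @param factor_columns character vector of categorical covariate columns.
#' @param continuous_columns character vector of numeric covariate columns.
#' @param random_flags logical vector parallel to `factor_columns`:
#'   `TRUE` marks a factor as a random effect. Defaults to all fixed.
#' @param id_column optional name of a row-label column.
#' @return a [mixture_data()]; row order preserved.
#' @export
read_mixture_table <- function(path, tracer_columns, factor_columns = character(),
                               continuous_columns = character(),
                               random_flags = rep(FALSE, length(factor_columns)),
                               id_column = NULL) {
  df <- read_delim_table(path)
  require_columns(df, c(tracer_columns, factor_columns, continuous_columns, id_column), path)
  if (length(random_flags) != length(factor_columns)) {
    stop("random_flags must parallel factor_columns", call. = FALSE)
  }
  values <- vapply(tracer_columns, function(cl) numeric_column(df, cl, path),
                   numeric(nrow(df)))
  values <- matrix(values, nrow = nrow(df),
                   dimnames = list(NULL, tracer_columns))
  cont <- lapply(continuous_columns, function(cl) numeric_column(df, cl, path))
  names(cont) <- continuous_columns
  fixed <- as.list(df[factor_columns[!random_flags]])
  random <- as.list(df[factor_columns[random_flags]])
  ids <- if (is.null(id_column)) NULL else as.character(df[[id_column]])
  mixture_data(values, tracer_names = tracer_columns, fixed_factors = fixed,
               random_factors = random, continuous_covariates = cont, ids = ids)
}

#' Read a source table
#'
#' `mode = "summary"`: one row per source with columns `Mean<tracer>`,
#' `SD<tracer>`, `n`, and optionally `Conc<tracer>`. `mode = "raw"`: one
#' row per source sample with the tracer columns named directly, plus
#' optional `Conc<tracer>` columns (constant within source). Both need a
#' `Source` name column (configurable).
#'
#' @param path CSV/TSV file path.
#' @param mode `"summary"` or `"raw"`.
#' @param tracer_columns tracer names.
#' @param source_column name of the source-label column.
#' @return a [source_data()] with `treatment` set to `mode`.
#' @export
read_source_table <- function(path, mode, tracer_columns, source_column = "Source") {
  mode <- match.arg(mode, c("summary", "raw"))
  df <- read_delim_table(path)
  require_columns(df, source_column, path)
  conc_cols <- paste0("Conc", tracer_columns)
  has_conc <- all(conc_cols %in% names(df))
  if (mode == "summary") {
    mean_cols <- paste0("Mean", tracer_columns)
    sd_cols <- paste0("SD", tracer_columns)
    require_columns(df, c(mean_cols, sd_cols, "n"), path)
    K <- nrow(df)
    means <- sapply(mean_cols, function(cl) numeric_column(df, cl, path))
    sds <- sapply(sd_cols, function(cl) numeric_column(df, cl, path))
    means <- matrix(means, K); sds <- matrix(sds, K)
    if (any(sds <= 0)) stop(sprintf("file '%s' has SD <= 0", path), call. = FALSE)
    conc <- if (has_conc) {
      matrix(sapply(conc_cols, function(cl) numeric_column(df, cl, path)), K)
    } else NULL
    source_data("summary", means, sds, as.integer(numeric_column(df, "n", path)),
                source_names = as.character(df[[source_column]]),
                tracer_names = tracer_columns, concentrations = conc)
  } else {
    require_columns(df, tracer_columns, path)
    src <- factor(as.character(df[[source_column]]),
                  levels = unique(as.character(df[[source_column]])))
    vals <- sapply(tracer_columns, function(cl) numeric_column(df, cl, path))
    vals <- matrix(vals, nrow(df), dimnames = list(NULL, tracer_columns))
    raw <- lapply(levels(src), function(s) vals[src == s, , drop = FALSE])
    names(raw) <- levels(src)
    J <- length(tracer_columns)
    means <- per_source_stat(raw, colMeans, J)
    sds <- per_source_stat(raw, function(m) apply(m, 2L, stats::sd), J)
    conc <- if (has_conc) {
      cm <- matrix(sapply(conc_cols, function(cl) numeric_column(df, cl, path)), nrow(df))
      per_source_stat(levels(src), function(s) cm[src == s, , drop = FALSE][1L, ], J)
    } else NULL
    source_data("raw", means, sds, vapply(raw, nrow, integer(1)),
                source_names = levels(src), tracer_names = tracer_columns,
                raw_samples = raw, concentrations = conc)
  }
}

#' Read a discrimination table
#'
#' One row per source with columns `Mean<tracer>`, `SD<tracer>`. A
#' missing file yields all-zero discrimination (non-isotope tracers may
#' need none).
#'
#' @param path file path, or `NULL` for zero discrimination.
#' @param tracer_columns tracer names.
#' @param source_obj the matching [source_data()] (defines shape/order).
#' @param source_column name of the source-label column.
#' @return a [discrimination_data()].
#' @export
read_discrimination_table <- function(path, tracer_columns, source_obj,
                                      source_column = "Source") {
  stopifnot(inherits(source_obj, "source_data"))
  if (is.null(path)) return(zero_discrimination(source_obj))
  df <- read_delim_table(path)
  mean_cols <- paste0("Mean", tracer_columns)
  sd_cols <- paste0("SD", tracer_columns)
  require_columns(df, c(source_column, mean_cols, sd_cols), path)
  idx <- match(source_obj$source_names, as.character(df[[source_column]]))
  if (anyNA(idx)) {
    stop(sprintf("discrimination file '%s' lacks rows for: %s", path,
                 paste(source_obj$source_names[is.na(idx)], collapse = ", ")),
         call. = FALSE)
  }
  means <- matrix(sapply(mean_cols, function(cl) numeric_column(df, cl, path)),
                  nrow(df))[idx, , drop = FALSE]
  sds <- matrix(sapply(sd_cols, function(cl) numeric_column(df, cl, path)),
                nrow(df))[idx, , drop = FALSE]
  discrimination_data(means, sds, source_names = source_obj$source_names,
                      tracer_names = tracer_columns)
}

#' Freeze source parameters at their observed values
#'
#' Returns a copy with `treatment = "fixed"`: the model will treat the
#' source means and SDs as known rather than estimating them, which
#' approximates the older MixSIR/SIAR behaviour. Idempotent.
#'
#' @param source_obj a [source_data()].
#' @return a fixed-treatment [source_data()].
#' @export
as_fixed_sources <- function(source_obj) {
  stopifnot(inherits(source_obj, "source_data"))
  if (source_obj$treatment == "fixed") return(source_obj)
  source_data("fixed", source_obj$means, source_obj$sds, source_obj$sample_sizes,
              source_names = source_obj$source_names,
              tracer_names = source_obj$tracer_names,
              concentrations = source_obj$concentrations)
}

# -- writers (round-trip companions of the readers) --------------------------

fmt_num <- function(x) sprintf("%.17g", x)   # 17 significant digits round-trip doubles exactly

#' Write a mixture table
#' @param mix a [mixture_data()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_mixture_table <- function(mix, path) {
  stopifnot(inherits(mix, "mixture_data"))
  df <- as.data.frame(apply(mix$values, 2L, fmt_num), check.names = FALSE,
                      stringsAsFactors = FALSE)
  if (nrow(mix$values) == 1L) df <- as.data.frame(t(df), check.names = FALSE)
  for (nm in names(mix$fixed_factors)) df[[nm]] <- as.character(mix$fixed_factors[[nm]])
  for (nm in names(mix$random_factors)) df[[nm]] <- as.character(mix$random_factors[[nm]])
  for (nm in names(mix$continuous_covariates)) df[[nm]] <- fmt_num(mix$continuous_covariates[[nm]])
  df$ID <- mix$ids
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a source table in the dialect of [read_source_table()]
#' @param source_obj a [source_data()].
#' @param path output CSV path.
#' @param mode `"summary"` writes Mean/SD/n columns; `"raw"` writes one
#'   row per sample (raw treatment only).
#' @return `path`, invisibly.
#' @export
write_source_table <- function(source_obj, path, mode = source_obj$treatment) {
  stopifnot(inherits(source_obj, "source_data"))
  if (identical(mode, "fixed")) mode <- "summary"
  mode <- match.arg(mode, c("summary", "raw"))
  trn <- source_obj$tracer_names
  if (mode == "summary") {
    df <- data.frame(Source = source_obj$source_names, stringsAsFactors = FALSE)
    for (j in seq_along(trn)) {
      df[[paste0("Mean", trn[j])]] <- fmt_num(source_obj$means[, j])
      df[[paste0("SD", trn[j])]] <- fmt_num(source_obj$sds[, j])
    }
    if (!is.null(source_obj$concentrations)) {
      for (j in seq_along(trn)) {
        df[[paste0("Conc", trn[j])]] <- fmt_num(source_obj$concentrations[, j])
      }
    }
    df$n <- source_obj$sample_sizes
  } else {
    if (is.null(source_obj$raw_samples)) {
      stop("raw output requires raw treatment", call. = FALSE)
    }
    df <- do.call(rbind, lapply(source_obj$source_names, function(s) {
      m <- source_obj$raw_samples[[s]]
      out <- data.frame(Source = rep(s, nrow(m)), stringsAsFactors = FALSE)
      for (j in seq_along(trn)) out[[trn[j]]] <- fmt_num(m[, j])
      out
    }))
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a discrimination table
#' @param disc a [discrimination_data()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_discrimination_table <- function(disc, path) {
  stopifnot(inherits(disc, "discrimination_data"))
  trn <- colnames(disc$means)
  df <- data.frame(Source = rownames(disc$means), stringsAsFactors = FALSE)
  for (j in seq_along(trn)) {
    df[[paste0("Mean", trn[j])]] <- fmt_num(disc$means[, j])
    df[[paste0("SD", trn[j])]] <- fmt_num(disc$sds[, j])
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
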