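#' Isometric log-ratio (ILR) basis
#'
#' Returns the orthonormal contrast matrix of a fixed sequential binary
#' partition in source-input order: coordinate `t` balances part `t`
#' against parts `t+1, ..., K`. Columns are orthonormal clr vectors
#' (each sums to zero, unit length, mutually orthogonal).
#'
#' The basis is a package-wide convention: posterior proportions are
#' invariant to the choice of orthonormal basis, but ILR-space
#' coefficients are not, so reported coefficients always refer to this
#' partition.
#'
#' @param K number of parts (sources), `K >= 2`.
#' @return a `K x (K-1)` matrix `V` with `t(V) %*% V == I`.
#' @export
ilr_basis <- function(K) {
  K <- as.integer(K)
  if (is.na(K) || K < 2L) stop("ILR basis requires K >= 2 parts", call. = FALSE)
  V <- matrix(0, nrow = K, ncol = K - 1L)
  for (t in seq_len(K - 1L)) {
    r <- K - t                       # number of parts on the "minus" side
    V[t, t] <- sqrt(r / (r + 1))
    V[(t + 1L):K, t] <- -1 / sqrt(r * (r + 1))
  }
  V
}

#' ILR transform of a composition
#'
#' Maps a strictly positive K-part composition to K-1 unconstrained
#' Euclidean coordinates using the basis of [ilr_basis()]. The map is an
#' isometry between the Aitchison simplex and Euclidean space, which is
#' what makes linear modelling of proportions coherent.
#'
#' @param p numeric vector (or matrix with compositions in rows) on the
#'   simplex; every entry must be strictly positive.
#' @param tol tolerance for the sum-to-one check.
#' @return numeric vector of length K-1 (or matrix with K-1 columns).
#' @export
ilr_transform <- function(p, tol = 1e-10) {
  if (is.matrix(p)) {
    res <- apply(p, 1L, ilr_transform, tol = tol)
    return(if (is.null(dim(res))) matrix(res, ncol = 1L) else t(res))
  }
  p <- as.numeric(p)
  if (length(p) < 2L) stop("composition needs at least 2 parts", call. = FALSE)
  if (any(!is.finite(p)) || any(p <= 0)) {
    stop("ILR is undefined for boundary or non-positive compositions", call. = FALSE)
  }
  if (abs(sum(p) - 1) > tol) {
    stop(sprintf("composition must sum to 1 (got %.12f)", sum(p)), call. = FALSE)
  }
  V <- ilr_basis(length(p))
  lp <- log(p)
  as.numeric(crossprod(V, lp - mean(lp)))
}

#' Inverse ILR transform
#'
#' Maps K-1 ILR coordinates back to a strictly positive composition on
#' the K-part simplex.
#'
#' @param z numeric vector of length K-1 (or matrix with K-1 columns),
#'   all entries finite.
#' @return composition of length K summing to 1 (or matrix with K columns).
#' @export
inverse_ilr <- function(z) {
  if (is.matrix(z)) {
    return(t(apply(z, 1L, inverse_ilr)))
  }
  z <- as.numeric(z)
  if (any(!is.finite(z))) stop("ILR coordinates must be finite", call. = FALSE)
  V <- ilr_basis(length(z) + 1L)
  y <- as.numeric(V %*% z)
  y <- y - max(y)                    # guard overflow at extreme coordinates
  e <- exp(y)
  e / sum(e)
}

# log |d p / d z| of the inverse-ILR map: sqrt(K) * prod(p). Used to put a
# Dirichlet prior on the intercept composition while sampling in ILR space.
ilr_log_jacobian <- function(p) {
  0.5 * log(length(p)) + sum(log(p))
}
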