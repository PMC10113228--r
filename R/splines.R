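#' Cyclic cubic regression spline basis
#'
#' Builds a cyclic cubic regression spline over one period: a natural cubic
#' interpolating spline through values at `n_basis` knots whose value, first
#' and second derivative match at the two period endpoints. The basis is
#' value-parameterised (coefficients are the function values at the knots);
#' the knot second derivatives are the linear map `m = B^{-1} D beta` given
#' by the cyclic continuity equations, and the wiggliness penalty is the
#' integrated squared second derivative `S = D' B^{-1} D`.
#'
#' Knots are placed at sample quantiles of `x` (first knot at the period
#' start; the period wraps at its end), or uniformly via
#' `placement = "uniform"`.
#'
#' @param x Sample values used for knot placement (wrapped into the period).
#' @param n_basis Number of basis functions (= free knots), at least 4.
#' @param period_range Numeric `c(lo, hi)`: the period is `hi - lo` and
#'   evaluation wraps modulo the period.
#' @param placement `"quantile"` (default) or `"uniform"`.
#' @return An object of class `cyclic_basis`: a list with `knots`, `lo`,
#'   `hi`, `period`, `F` (values-to-second-derivatives map), and the penalty
#'   matrix `S`.
#' @seealso [cyclic_design()], [penalty_matrix()]
#' @export
cyclic_basis <- function(x, n_basis, period_range,
                         placement = c("quantile", "uniform")) {
  placement <- match.arg(placement)
  stop_if_not(is.numeric(n_basis) && n_basis >= 4, "`n_basis` must be >= 4")
  lo <- period_range[1]; hi <- period_range[2]
  stop_if_not(hi > lo, "`period_range` must satisfy hi > lo")
  period <- hi - lo
  K <- as.integer(n_basis)

  xw <- lo + (x - lo) %% period
  if (placement == "quantile") {
    stop_if_not(length(unique(xw)) >= K,
                "n_basis exceeds the number of distinct x values")
    kn <- c(lo, as.numeric(stats::quantile(xw, probs = (1:(K - 1)) / K,
                                           names = FALSE, type = 7)))
    if (any(diff(kn) <= 0) || any(kn >= hi)) {
      ## ties in the sample quantiles: fall back to uniform spacing
      kn <- lo + period * (0:(K - 1)) / K
    }
  } else {
    kn <- lo + period * (0:(K - 1)) / K
  }

  h <- c(diff(kn), lo + period - kn[K])        # K interval widths, cyclic
  B <- matrix(0, K, K); D <- matrix(0, K, K)
  for (i in seq_len(K)) {
    im <- if (i == 1L) K else i - 1L
    ip <- if (i == K) 1L else i + 1L
    B[i, im] <- B[i, im] + h[im] / 6
    B[i, i] <- B[i, i] + (h[im] + h[i]) / 3
    B[i, ip] <- B[i, ip] + h[i] / 6
    D[i, im] <- D[i, im] + 1 / h[im]
    D[i, i] <- D[i, i] - (1 / h[im] + 1 / h[i])
    D[i, ip] <- D[i, ip] + 1 / h[i]
  }
  Fm <- solve(B, D)
  S <- crossprod(D, Fm)
  S <- (S + t(S)) / 2                           # enforce exact symmetry

  structure(list(knots = kn, lo = lo, hi = hi, period = period,
                 n_basis = K, h = h, F = Fm, S = S),
            class = "cyclic_basis")
}

#' Evaluate a cyclic basis: design-matrix rows
#'
#' @param basis A [cyclic_basis()].
#' @param x Values at which to evaluate (wrapped into the period).
#' @return Matrix with `length(x)` rows and `n_basis` columns; each row sums
#'   to 1 (the constant function is `beta = 1`).
#' @export
cyclic_design <- function(basis, x) {
  kn <- basis$knots; K <- basis$n_basis
  xw <- basis$lo + (x - basis$lo) %% basis$period
  j <- findInterval(xw, kn)
  j[j < 1L] <- 1L                              # guard fp wrap at lo
  jn <- ifelse(j == K, 1L, j + 1L)
  t_j <- kn[j]
  t_n <- ifelse(j == K, basis$lo + basis$period, kn[jn])
  hj <- basis$h[j]
  a1 <- (t_n - xw) / hj
  a2 <- (xw - t_j) / hj
  c1 <- ((t_n - xw)^3 / hj - hj * (t_n - xw)) / 6
  c2 <- ((xw - t_j)^3 / hj - hj * (xw - t_j)) / 6
  X <- c1 * basis$F[j, , drop = FALSE] + c2 * basis$F[jn, , drop = FALSE]
  n <- length(xw)
  X[cbind(seq_len(n), j)] <- X[cbind(seq_len(n), j)] + a1
  X[cbind(seq_len(n), jn)] <- X[cbind(seq_len(n), jn)] + a2
  X
}

#' @export
print.cyclic_basis <- function(x, ...) {
  cat(sprintf("<cyclic_basis> %d basis functions over [%.3g, %.3g]\n",
              x$n_basis, x$lo, x$hi))
  invisible(x)
}

#' Wiggliness penalty of a cyclic basis
#'
#' The integrated squared second derivative of the spline over one period,
#' as a quadratic form in the basis coefficients. Symmetric positive
#' semi-definite with the constant function in its null space.
#'
#' @param basis A [cyclic_basis()].
#' @return A symmetric PSD matrix.
#' @export
penalty_matrix <- function(basis) basis$S

#' Weighted sum-to-zero constraint for a smooth block
#'
#' Reparameterises a basis matrix so that every column has zero weighted sum
#' over the sample, making the smooth identifiable alongside an intercept.
#' The constraint null-space basis `Z` (one fewer column) is returned so the
#' penalty can be transformed (`t(Z) %*% S %*% Z`) and fitted coefficients
#' mapped back to knot values (`Z %*% coef`).
#'
#' @param X Basis design matrix (n x K).
#' @param weights Optional observation weights (default 1).
#' @return `list(X, Z, constraint)`: the constrained design (n x (K-1)), the
#'   null-space transform, and the constraint row vector.
#' @export
apply_sum_to_zero <- function(X, weights = NULL) {
  w <- if (is.null(weights)) rep(1, nrow(X)) else weights
  C <- colSums(w * X)
  qr_c <- qr(matrix(C, ncol = 1))
  Z <- qr.Q(qr_c, complete = TRUE)[, -1, drop = FALSE]
  list(X = X %*% Z, Z = Z, constraint = C)
}

#' Tensor-product interaction basis of two cyclic smooths
#'
#' Builds the interaction-only (main-effects-excluded) tensor product of two
#' cyclic marginal bases: each margin is first reparameterised under its
#' sum-to-zero constraint on the supplied sample, then the constrained
#' margins are combined by row-wise Kronecker products. Because both margins
#' exclude the constant, the interaction space contains no marginal main
#' effects and is jointly identifiable next to `f1 + f2` and the intercept.
#' Two penalties are returned, one measuring wiggliness in each margin
#' direction.
#'
#' @param b1,b2 Marginal [cyclic_basis()] objects.
#' @param x1,x2 Sample values of the two covariates (same length), used for
#'   the marginal constraints.
#' @param weights Optional observation weights.
#' @return Object of class `tensor_basis`: `list(b1, b2, Z1, Z2, X, S1, S2)`
#'   where `X` is the n x (K1-1)(K2-1) design and `S1`, `S2` the two
#'   penalties on its columns.
#' @export
build_tensor_basis <- function(b1, b2, x1, x2, weights = NULL) {
  stop_if_not(length(x1) == length(x2), "`x1` and `x2` must have equal length")
  c1 <- apply_sum_to_zero(cyclic_design(b1, x1), weights)
  c2 <- apply_sum_to_zero(cyclic_design(b2, x2), weights)
  X <- tensor_rows(c1$X, c2$X)
  S1c <- crossprod(c1$Z, b1$S %*% c1$Z)
  S2c <- crossprod(c2$Z, b2$S %*% c2$Z)
  p1 <- ncol(c1$X); p2 <- ncol(c2$X)
  structure(list(b1 = b1, b2 = b2, Z1 = c1$Z, Z2 = c2$Z, X = X,
                 S1 = kronecker(S1c, diag(p2)),
                 S2 = kronecker(diag(p1), S2c)),
            class = "tensor_basis")
}

## Row-wise Kronecker product of two matrices with equal row counts.
tensor_rows <- function(A, B) {
  A[, rep(seq_len(ncol(A)), each = ncol(B)), drop = FALSE] *
    B[, rep(seq_len(ncol(B)), times = ncol(A)), drop = FALSE]
}

## Evaluate a fitted tensor basis at new covariate values.
tensor_design <- function(tb, x1, x2) {
  tensor_rows(cyclic_design(tb$b1, x1) %*% tb$Z1,
              cyclic_design(tb$b2, x2) %*% tb$Z2)
}
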