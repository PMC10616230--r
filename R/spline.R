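## Cubic regression spline basis for the age smooth: a natural cubic spline
## parameterised by its values at knots placed at covariate quantiles, with
## the integrated squared second derivative as penalty. The sum-to-zero
## identifiability constraint is absorbed by reparameterisation so the
## smooth carries no intercept.

#' Build a cubic regression spline basis with curvature penalty
#'
#' Knots are placed at the quantiles of `age_values`. The basis is the
#' cardinal natural cubic spline basis (coefficients are the function values
#' at the knots); the penalty is the integrated squared second derivative,
#' a symmetric positive semi-definite matrix of rank `basis_dim - 2` that
#' annihilates straight lines. The sum-to-zero constraint over the observed
#' values is absorbed into the returned reparameterised basis, leaving
#' `basis_dim - 1` columns.
#'
#' @param age_values Covariate values at which the basis is needed.
#' @param basis_dim Number of knots (>= 4). Reduced with a warning if there
#'   are fewer distinct covariate values.
#' @return A `crs_basis` list: `X` (constrained basis, n x (k-1)), `S`
#'   (constrained penalty), `knots`, `Z` (constraint null-space), `shift`
#'   (column means absorbed by the constraint), and `predict(x)` via
#'   [predict_crs()].
#' @export
build_spline_basis <- function(age_values, basis_dim = 10) {
  ux <- sort(unique(age_values))
  if (basis_dim < 4) stop_config("basis_dim must be >= 4")
  k <- basis_dim
  if (length(ux) < k) {
    k <- max(4L, length(ux))
    if (length(ux) < 4) stop_config("need >= 4 distinct age values")
    warning(sprintf("basis reduced to %d (only %d distinct ages)", k,
                    length(ux)), call. = FALSE)
  }
  knots <- unique(as.numeric(stats::quantile(age_values,
                                             probs = seq(0, 1, length.out = k),
                                             type = 7)))
  if (length(knots) < k) knots <- seq(min(ux), max(ux), length.out = k)
  h <- diff(knots)
  k <- length(knots)
  # D (k-2 x k) second-difference and B (k-2 x k-2) overlap matrices:
  # gamma = solve(B, D %*% beta) are the spline's second derivatives at
  # interior knots (natural end conditions), and S = D' B^-1 D.
  D <- matrix(0, k - 2, k)
  B <- matrix(0, k - 2, k - 2)
  for (i in seq_len(k - 2)) {
    D[i, i] <- 1 / h[i]
    D[i, i + 1] <- -1 / h[i] - 1 / h[i + 1]
    D[i, i + 2] <- 1 / h[i + 1]
    B[i, i] <- (h[i] + h[i + 1]) / 3
    if (i < k - 2) {
      B[i, i + 1] <- h[i + 1] / 6
      B[i + 1, i] <- h[i + 1] / 6
    }
  }
  Fmat <- rbind(0, solve(B, D), 0)  # k x k: maps values to 2nd derivatives
  S_full <- crossprod(D, solve(B, D))
  S_full <- (S_full + t(S_full)) / 2
  X_full <- crs_design(age_values, knots, Fmat)
  cmeans <- colMeans(X_full)
  # null space of the sum-to-zero constraint row
  qrC <- qr(matrix(cmeans, ncol = 1))
  Z <- qr.Q(qrC, complete = TRUE)[, -1, drop = FALSE]
  out <- list(X = X_full %*% Z,
              S = crossprod(Z, S_full %*% Z),
              knots = knots, Fmat = Fmat, Z = Z, cmeans = cmeans)
  class(out) <- "crs_basis"
  out
}

## Raw (unconstrained) cardinal natural-spline design matrix at x.
crs_design <- function(x, knots, Fmat) {
  k <- length(knots)
  h <- diff(knots)
  xc <- pmin(pmax(x, knots[1]), knots[k])  # linear-tail clamp outside range
  j <- findInterval(xc, knots, rightmost.closed = TRUE)
  j <- pmin(pmax(j, 1L), k - 1L)
  am <- (knots[j + 1] - xc) / h[j]
  ap <- (xc - knots[j]) / h[j]
  cm <- ((knots[j + 1] - xc)^3 / h[j] - h[j] * (knots[j + 1] - xc)) / 6
  cp <- ((xc - knots[j])^3 / h[j] - h[j] * (xc - knots[j])) / 6
  X <- matrix(0, length(x), k)
  for (i in seq_along(x)) {
    X[i, j[i]] <- X[i, j[i]] + am[i]
    X[i, j[i] + 1] <- X[i, j[i] + 1] + ap[i]
    X[i, ] <- X[i, ] + cm[i] * Fmat[j[i], ] + cp[i] * Fmat[j[i] + 1, ]
  }
  X
}

#' Evaluate a constrained spline basis at new covariate values
#'
#' @param basis A `crs_basis` from [build_spline_basis()].
#' @param x New covariate values (clamped to the knot range).
#' @return Matrix of constrained basis values, `length(x)` x (k-1).
#' @export
predict_crs <- function(basis, x) {
  crs_design(x, basis$knots, basis$Fmat) %*% basis$Z
}
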