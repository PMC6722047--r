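#' Penalized B-spline (P-spline) smoother matrix
#'
#' Builds the linear smoother ("hat") matrix of a P-spline regression on an
#' equally spaced grid: cubic B-spline basis with one knot per `knot_spacing`
#' grid points and a difference penalty of order `penalty_order` on adjacent
#' basis coefficients. The same matrix smooths any number of spectra on the
#' grid by a single matrix product, which is what makes per-pixel smoothing
#' of thousands of periodograms cheap.
#'
#' @param x numeric grid (strictly increasing, approximately equally spaced).
#' @param lambda penalty weight (>= 0); larger is smoother.
#' @param knot_spacing knot interval in grid steps (default one knot per
#'   grid point, which keeps the smoother bandwidth narrow relative to the
#'   2.5 Hz guard band of the beat-frequency search).
#' @param penalty_order order of the difference penalty (default 2).
#' @param degree spline degree (default 3, cubic).
#' @return an `length(x) x length(x)` smoother matrix `H`; `H %*% y` is the
#'   P-spline fit to `y`.
#' @export
pspline_hat <- function(x, lambda = 1, knot_spacing = 1L, penalty_order = 2L,
                        degree = 3L) {
  n <- length(x)
  if (n < degree + 2L) stop("grid too short for the spline basis")
  if (lambda < 0) stop("lambda must be nonnegative")
  h <- mean(diff(x)) * knot_spacing
  knots <- seq(min(x) - degree * h, max(x) + degree * h, by = h)
  B <- splines::splineDesign(knots, x, ord = degree + 1L)
  D <- diff(diag(ncol(B)), differences = penalty_order)
  M <- crossprod(B) + lambda * crossprod(D)
  B %*% solve(M, t(B))
}

#' Smooth one or more curves with a P-spline
#'
#' @param y numeric vector, or matrix with one curve per column, on grid `x`.
#' @param x the grid.
#' @param clip clip negative fitted values to 0 (spectral powers are
#'   nonnegative by definition).
#' @inheritParams pspline_hat
#' @return smoothed vector or matrix, same shape as `y`.
#' @export
pspline_smooth <- function(y, x, lambda = 1, knot_spacing = 1L,
                           penalty_order = 2L, clip = TRUE) {
  H <- pspline_hat(x, lambda = lambda, knot_spacing = knot_spacing,
                   penalty_order = penalty_order)
  out <- H %*% if (is.matrix(y)) y else cbind(y)
  if (clip) out[out < 0] <- 0
  if (is.matrix(y)) out else drop(out)
}
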