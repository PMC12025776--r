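#' B-spline space specification
#'
#' Defines the spline space used by the learnable activations of a
#' Kolmogorov-Arnold layer: `grid` uniform intervals over
#' `[domain_lo, domain_hi]` and polynomial degree `degree`. The knot vector
#' has `degree`-fold end-point extension so the basis functions form a
#' partition of unity over the whole domain, and the space dimension is
#' `n_basis = grid + degree`.
#'
#' @param grid Number of grid intervals G (>= 1).
#' @param degree Polynomial degree k (>= 0). This is what the KAN
#'   literature's "order" hyperparameter controls; higher degrees give
#'   smoother activations.
#' @param domain_lo,domain_hi Domain interval of the activation input.
#'   Defaults to \[0, 1\] because pipeline inputs are min-max scaled.
#' @return An object of class `spline_spec` with fields `grid_count`,
#'   `degree`, `domain_lo`, `domain_hi`, `knots`, `n_basis`.
#' @examples
#' sp <- spline_spec(grid = 3, degree = 5)
#' sp$n_basis  # 8
#' @export
spline_spec <- function(grid, degree, domain_lo = 0, domain_hi = 1) {
  grid <- assert_count(grid, "grid", min = 1)
  degree <- assert_count(degree, "degree", min = 0)
  assert_number(domain_lo, "domain_lo")
  assert_number(domain_hi, "domain_hi")
  if (domain_lo >= domain_hi) {
    stop("'domain_lo' must be strictly below 'domain_hi'", call. = FALSE)
  }
  spec <- structure(
    list(grid_count = grid, degree = degree,
         domain_lo = domain_lo, domain_hi = domain_hi),
    class = "spline_spec"
  )
  spec$knots <- make_knots(spec)
  spec$n_basis <- grid + degree
  spec
}

#' Knot sequence of a spline specification
#'
#' Uniform interior knots over the domain with `degree`-fold repetition of
#' both end points, giving an open (clamped) uniform knot vector.
#'
#' @param spec A [spline_spec()].
#' @return Non-decreasing numeric knot vector of length
#'   `grid + 2 * degree + 1`.
#' @export
make_knots <- function(spec) {
  if (!inherits(spec, "spline_spec")) {
    stop("'spec' must be a spline_spec", call. = FALSE)
  }
  g <- spec$grid_count
  k <- spec$degree
  interior <- seq(spec$domain_lo, spec$domain_hi, length.out = g + 1)
  c(rep(spec$domain_lo, k), interior, rep(spec$domain_hi, k))
}

# Vectorised Cox-de Boor evaluation of all basis functions of `degree` on
# `knots` at points x (assumed inside [knots[1], last knot]). Returns a
# length(x) x (length(knots) - degree - 1) matrix.
bspline_basis_on_knots <- function(x, knots, degree) {
  m <- length(knots)
  n0 <- m - 1L
  # degree-0: indicator of the half-open knot interval, with the rightmost
  # point folded into the last nonzero-width interval
  last <- max(which(knots < knots[m]))  # index of last interval start
  j <- findInterval(x, knots)
  j <- pmin(pmax(j, 1L), last)
  B <- matrix(0, length(x), n0)
  B[cbind(seq_along(x), j)] <- 1
  if (degree == 0L) return(B)
  for (d in seq_len(degree)) {
    ncols <- n0 - d
    Bn <- matrix(0, length(x), ncols)
    for (col in seq_len(ncols)) {
      den1 <- knots[col + d] - knots[col]
      den2 <- knots[col + d + 1L] - knots[col + 1L]
      v <- 0
      if (den1 > 0) v <- v + (x - knots[col]) / den1 * B[, col]
      if (den2 > 0) v <- v + (knots[col + d + 1L] - x) / den2 * B[, col + 1L]
      Bn[, col] <- v
    }
    B <- Bn
  }
  B
}

# Clamp points to the spline domain; optionally warn (user-facing entry
# points warn, inner training loops clamp silently).
clamp_to_domain <- function(x, spec, warn = FALSE) {
  out <- x < spec$domain_lo | x > spec$domain_hi
  if (any(out)) {
    if (warn) {
      warning(sprintf("%d point(s) outside the spline domain [%g, %g]; clamped",
                      sum(out), spec$domain_lo, spec$domain_hi))
    }
    x <- pmin(pmax(x, spec$domain_lo), spec$domain_hi)
  }
  x
}

#' Evaluate the B-spline basis at given points
#'
#' Returns the values of all `n_basis = grid + degree` basis functions.
#' The basis is non-negative, has local support (at most `degree + 1`
#' functions are nonzero at any point), and sums to one everywhere on the
#' domain. Points outside the domain are clamped to the nearer boundary
#' with a warning.
#'
#' @param x Numeric vector of evaluation points.
#' @param spec A [spline_spec()].
#' @return A `length(x) x n_basis` matrix of basis values.
#' @export
bspline_basis <- function(x, spec) {
  if (!inherits(spec, "spline_spec")) {
    stop("'spec' must be a spline_spec", call. = FALSE)
  }
  x <- clamp_to_domain(as.numeric(x), spec, warn = TRUE)
  bspline_basis_on_knots(x, spec$knots, spec$degree)
}

#' First derivative of the B-spline basis
#'
#' Evaluated through the standard lower-degree identity
#' `B'_{j,k} = k * (B_{j,k-1}/(t_{j+k}-t_j) - B_{j+1,k-1}/(t_{j+k+1}-t_{j+1}))`
#' with vanishing terms where a knot span has zero width. Used for
#' backpropagation through Kolmogorov-Arnold layers.
#'
#' @inheritParams bspline_basis
#' @return A `length(x) x n_basis` matrix of basis derivatives.
#' @export
bspline_basis_deriv <- function(x, spec) {
  if (!inherits(spec, "spline_spec")) {
    stop("'spec' must be a spline_spec", call. = FALSE)
  }
  x <- clamp_to_domain(as.numeric(x), spec)
  k <- spec$degree
  nb <- spec$n_basis
  if (k == 0L) return(matrix(0, length(x), nb))
  knots <- spec$knots
  Blow <- bspline_basis_on_knots(x, knots, k - 1L)  # nb + 1 columns
  D <- matrix(0, length(x), nb)
  for (col in seq_len(nb)) {
    den1 <- knots[col + k] - knots[col]
    den2 <- knots[col + k + 1L] - knots[col + 1L]
    v <- 0
    if (den1 > 0) v <- v + Blow[, col] / den1
    if (den2 > 0) v <- v - Blow[, col + 1L] / den2
    D[, col] <- k * v
  }
  D
}
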