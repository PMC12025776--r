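#' Construct a Kolmogorov-Arnold layer
#'
#' A KAN layer maps an `in_dim`-vector `x` to an `out_dim`-vector whose j-th
#' entry is the sum over inputs of learnable univariate activations,
#' `out_j = sum_i phi_{j,i}(x_i)`, with no fixed output nonlinearity. Each
#' activation is a linear combination of the B-spline basis defined by
#' `spec`; with `include_base = TRUE` (the parametrization used by the
#' published parameter counts and by common KAN implementations) every edge
#' additionally carries a residual base term `w_b * silu(x)` and a
#' multiplicative spline scaler, i.e.
#' `phi_{j,i}(x) = s_{j,i} * sum_m c_{j,i,m} B_m(x) + w_{j,i} * silu(x)`.
#'
#' @param in_dim,out_dim Layer dimensions n_l and n_{l+1}.
#' @param spec A [spline_spec()] shared by every edge of the layer.
#' @param include_base Add the residual base function and spline scaler per
#'   edge. Default `FALSE` (pure spline combination).
#' @param seed Seed for coefficient initialisation (independent zero-mean
#'   draws with standard deviation 0.1).
#' @return An object of class `kan_layer` with the coefficient array
#'   `coeffs` of dim `(out_dim, in_dim, n_basis)` and, when `include_base`,
#'   matrices `base_weight` and `spline_scaler` of dim `(out_dim, in_dim)`.
#' @examples
#' l <- kan_layer(2, 1, spline_spec(3, 2), seed = 1)
#' kan_layer_forward(c(0.2, 0.7), l)
#' @export
kan_layer <- function(in_dim, out_dim, spec, include_base = FALSE, seed = 1) {
  in_dim <- assert_count(in_dim, "in_dim", min = 1)
  out_dim <- assert_count(out_dim, "out_dim", min = 1)
  if (!inherits(spec, "spline_spec")) {
    stop("'spec' must be a spline_spec", call. = FALSE)
  }
  assert_flag(include_base, "include_base")
  nb <- spec$n_basis
  with_seed(seed, {
    layer <- list(
      in_dim = in_dim, out_dim = out_dim, spec = spec,
      include_base = include_base,
      coeffs = array(stats::rnorm(out_dim * in_dim * nb, sd = 0.1),
                     dim = c(out_dim, in_dim, nb))
    )
    if (include_base) {
      layer$base_weight <- matrix(stats::rnorm(out_dim * in_dim, sd = 0.1),
                                  out_dim, in_dim)
      layer$spline_scaler <- matrix(1, out_dim, in_dim)
    }
    structure(layer, class = "kan_layer")
  })
}

silu <- function(x) x / (1 + exp(-x))
silu_deriv <- function(x) {
  s <- 1 / (1 + exp(-x))
  s * (1 + x * (1 - s))
}

#' Evaluate one learnable KAN activation
#'
#' Computes `sum_m c_m B_m(x)` for a single edge's coefficient vector.
#'
#' @param x Numeric vector of in-domain evaluation points.
#' @param edge_coeffs Coefficient vector of length `spec$n_basis`.
#' @param spec A [spline_spec()].
#' @return Numeric vector of activation values.
#' @export
kan_activation <- function(x, edge_coeffs, spec) {
  if (!inherits(spec, "spline_spec")) {
    stop("'spec' must be a spline_spec", call. = FALSE)
  }
  if (length(edge_coeffs) != spec$n_basis) {
    stop(sprintf("expected %d coefficients, got %d", spec$n_basis,
                 length(edge_coeffs)), call. = FALSE)
  }
  drop(bspline_basis(x, spec) %*% edge_coeffs)
}

# Flattened coefficient matrix (out_dim x in_dim*n_basis) with the edge
# scaler folded in; column order is input-major blocks of n_basis.
kan_flat_coeffs <- function(layer) {
  nb <- layer$spec$n_basis
  co <- layer$coeffs
  if (layer$include_base) {
    co <- co * array(rep(layer$spline_scaler, nb),
                     dim = c(layer$out_dim, layer$in_dim, nb))
  }
  # (out, in, m) -> (out, (in, m)) with m fastest inside each input block
  matrix(aperm(co, c(1L, 3L, 2L)), nrow = layer$out_dim)
}

# Basis values for a batch X (B x in_dim), flattened to B x (in_dim*n_basis)
# in the same column order as kan_flat_coeffs().
kan_flat_basis <- function(X, spec, deriv = FALSE) {
  b <- nrow(X)
  n_in <- ncol(X)
  xv <- clamp_to_domain(as.vector(X), spec)
  M <- if (deriv) bspline_basis_deriv(xv, spec) else
    bspline_basis_on_knots(xv, spec$knots, spec$degree)
  # rows are (b, i) column-major; reorder to B x (i-major blocks of m)
  A <- array(M, dim = c(b, n_in, spec$n_basis))
  matrix(aperm(A, c(1L, 3L, 2L)), nrow = b)
}

#' Forward pass through one KAN layer
#'
#' @param x Numeric vector of length `in_dim`, or a matrix with `in_dim`
#'   columns (one row per case).
#' @param layer A [kan_layer()].
#' @return Numeric vector of length `out_dim` (or a matrix with `out_dim`
#'   columns for matrix input).
#' @export
kan_layer_forward <- function(x, layer) {
  if (!inherits(layer, "kan_layer")) {
    stop("'layer' must be a kan_layer", call. = FALSE)
  }
  vec_in <- is.null(dim(x))
  X <- if (vec_in) matrix(x, nrow = 1L) else as.matrix(x)
  if (ncol(X) != layer$in_dim) {
    stop(sprintf("input has %d values, layer expects %d", ncol(X),
                 layer$in_dim), call. = FALSE)
  }
  Bf <- kan_flat_basis(X, layer$spec)
  out <- Bf %*% t(kan_flat_coeffs(layer))
  if (layer$include_base) {
    Xc <- clamp_to_domain(X, layer$spec)
    out <- out + silu(Xc) %*% t(layer$base_weight)
  }
  if (vec_in) drop(out) else out
}

#' Forward pass through a stack of KAN layers
#'
#' Left-to-right composition `Phi_{L-1} o ... o Phi_0`, the functional form
#' of a Kolmogorov-Arnold network.
#'
#' @param x Input vector (or matrix, one row per case).
#' @param layers List of [kan_layer()] objects with compatible dimensions.
#' @return The output of the final layer.
#' @export
kan_forward <- function(x, layers) {
  if (!length(layers)) stop("'layers' must be non-empty", call. = FALSE)
  dims_out <- vapply(layers, function(l) l$out_dim, integer(1))
  dims_in <- vapply(layers, function(l) l$in_dim, integer(1))
  if (length(layers) > 1L &&
      any(dims_out[-length(layers)] != dims_in[-1L])) {
    stop("consecutive KAN layer dimensions are incompatible", call. = FALSE)
  }
  for (l in layers) x <- kan_layer_forward(x, l)
  x
}
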