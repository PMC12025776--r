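test_that("a KAN activation is the spline combination of its coefficients", {
  sp <- spline_spec(4, 3)
  x <- seq(0, 1, length.out = 20)
  # equal coefficients reduce to a constant by partition of unity
  expect_equal(kan_activation(x, rep(2.5, sp$n_basis), sp),
               rep(2.5, 20))
  expect_equal(kan_activation(x, rep(0, sp$n_basis), sp), rep(0, 20))

  set.seed(1)
  co <- rnorm(sp$n_basis)
  xs <- runif(100)
  expect_equal(kan_activation(xs, co, sp),
               vapply(xs, function(z) sum(cdb_basis_vector(z, sp) * co),
                      numeric(1)),
               tolerance = 1e-10)
  expect_error(kan_activation(0.5, rnorm(3), sp), "coefficients")
})

test_that("layer forward sums the per-edge activations", {
  sp <- spline_spec(3, 2)
  l <- kan_layer(2, 1, sp, seed = 4)
  l$coeffs[] <- 0
  expect_equal(kan_layer_forward(c(0.3, 0.8), l), 0)

  # every edge activation constant c -> each output is in_dim * c
  l2 <- kan_layer(2, 3, sp, seed = 5)
  l2$coeffs[] <- 1.5
  expect_equal(kan_layer_forward(c(0.1, 0.9), l2), rep(3, 3))

  # 2 -> 1 layer equals the sum of two independent activation evaluations
  l3 <- kan_layer(2, 1, sp, seed = 6)
  x <- c(0.25, 0.66)
  manual <- kan_activation(x[1], l3$coeffs[1, 1, ], sp) +
    kan_activation(x[2], l3$coeffs[1, 2, ], sp)
  expect_equal(kan_layer_forward(x, l3), manual, tolerance = 1e-12)

  expect_error(kan_layer_forward(c(1, 2, 3), l3), "expects")
})

test_that("stacked layers compose left to right", {
  sp <- spline_spec(3, 2)
  single <- kan_layer(3, 2, sp, seed = 7)
  x <- c(0.2, 0.5, 0.8)
  expect_equal(kan_forward(x, list(single)), kan_layer_forward(x, single))

  z1 <- kan_layer(3, 4, sp, seed = 8)
  z2 <- kan_layer(4, 1, sp, seed = 9)
  z1$coeffs[] <- 0
  z2$coeffs[] <- 0
  expect_equal(kan_forward(x, list(z1, z2)), 0)

  a <- kan_layer(3, 4, sp, seed = 10)
  b <- kan_layer(4, 1, sp, seed = 11)
  nested <- kan_layer_forward(kan_layer_forward(x, a), b)
  expect_equal(kan_forward(x, list(a, b)), nested, tolerance = 1e-12)

  bad <- kan_layer(5, 1, sp, seed = 12)
  expect_error(kan_forward(x, list(a, bad)), "incompatible")
})

test_that("layer gradients match finite differences", {
  # single random small layers; loss = sum(R * forward(x))
  for (base in c(FALSE, TRUE)) {
    set.seed(10 + base)
    sp <- spline_spec(4, 3, domain_lo = -1, domain_hi = 1)
    l <- ppgqc:::layer_kan(3, 2, sp, include_base = base)
    for (nm in names(l$params)) l$params[[nm]][] <- rnorm(length(l$params[[nm]]), sd = 0.3)
    X <- matrix(runif(4 * 3, -0.9, 0.9), 4, 3)
    R <- matrix(rnorm(4 * 2), 4, 2)
    fw <- ppgqc:::kan_apply_forward(l, X)
    bk <- ppgqc:::kan_apply_backward(l, X, fw$cache, R)
    eps <- 1e-6
    loss <- function(l, X) sum(R * ppgqc:::kan_apply_forward(l, X)$out)
    # parameter gradients (the activations are linear in every parameter
    # except base_weight, so these must be accurate to first order)
    for (nm in names(l$params)) {
      for (j in sample(length(l$params[[nm]]), 5)) {
        l2 <- l
        l2$params[[nm]][j] <- l2$params[[nm]][j] + eps
        lp <- loss(l2, X)
        l2$params[[nm]][j] <- l2$params[[nm]][j] - 2 * eps
        lm <- loss(l2, X)
        expect_equal(ppgqc:::param_leaves(bk$grads)[[nm]][j],
                     (lp - lm) / (2 * eps), tolerance = 1e-5)
      }
    }
    # input gradients (interior points, away from the domain clamp)
    for (j in sample(length(X), 5)) {
      X2 <- X
      X2[j] <- X2[j] + eps
      lp <- loss(l, X2)
      X2[j] <- X2[j] - 2 * eps
      lm <- loss(l, X2)
      expect_equal(bk$dinput[j], (lp - lm) / (2 * eps), tolerance = 1e-4)
    }
  }
})

test_that("end-to-end gradients through a KAN classifier are consistent", {
  # wide spline domain so no activation input sits on the clamp boundary
  cfg <- model_config("cnn_kan", input_length = 30, conv_channels = 2,
                      conv_kernel = 5, pool_size = 2, kan_width = 3,
                      kan_order = 3, kan_domain = c(-8, 8))
  expect_lt(gradcheck_network(cfg, seed = 3), 1e-4)
  cfg2 <- model_config("cnn_kan", input_length = 30, conv_channels = 2,
                       conv_kernel = 5, pool_size = 2, kan_width = 3,
                       kan_base = FALSE, kan_domain = c(-8, 8))
  expect_lt(gradcheck_network(cfg2, seed = 4), 1e-4)
})

test_that("a single spline activation can fit a smooth target closely", {
  # least-squares fit of sin(pi x) on [-1, 1] with G = 10, k = 3
  sp <- spline_spec(10, 3, domain_lo = -1, domain_hi = 1)
  xtr <- seq(-1, 1, length.out = 400)
  B <- bspline_basis(xtr, sp)
  co <- qr.solve(B, sin(pi * xtr))
  xte <- seq(-1, 1, length.out = 1000)
  err <- max(abs(kan_activation(xte, co, sp) - sin(pi * xte)))
  expect_lt(err, 0.01)
})
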