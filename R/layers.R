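# Internal neural-network engine.
#
# Sequence activations flow between layers as "seq tensors": a list with
#   data : (B*L) x C matrix, rows time-major (row = (t-1)*B + b)
#   B, L : batch size and sequence length
# so that all per-timestep work is plain matrix algebra. Feature-vector
# activations are ordinary B x F matrices. Every layer implements a forward
# returning (out, cache) and a backward returning (dinput, grads); gradients
# are verified against finite differences in the test suite.

seq_tensor <- function(data, B, L) list(data = data, B = B, L = L)

seq_rows <- function(B, times) {
  # rows of all batch members at the given time indices, time-major order
  as.vector(outer(seq_len(B), (times - 1L) * B, "+"))
}

glorot <- function(n_in, n_out, n) {
  lim <- sqrt(6 / (n_in + n_out))
  stats::runif(n, -lim, lim)
}

conv_out_len <- function(L, kernel, stride) {
  if (L < kernel) stop("sequence shorter than the convolution kernel",
                       call. = FALSE)
  (L - kernel) %/% stride + 1L
}

## ---- 1D convolution --------------------------------------------------------

layer_conv1d <- function(in_ch, out_ch, kernel, stride = 1L) {
  W <- array(glorot(in_ch * kernel, out_ch, kernel * in_ch * out_ch),
             dim = c(kernel, in_ch, out_ch))
  list(type = "conv1d", in_ch = in_ch, out_ch = out_ch,
       kernel = as.integer(kernel), stride = as.integer(stride),
       params = list(W = W, b = numeric(out_ch)))
}

conv1d_forward <- function(layer, x) {
  B <- x$B; L1 <- x$L; K <- layer$kernel; s <- layer$stride
  L2 <- conv_out_len(L1, K, s)
  starts <- (seq_len(L2) - 1L) * s
  out <- matrix(rep(layer$params$b, each = B * L2), B * L2, layer$out_ch)
  rows <- vector("list", K)
  for (k in seq_len(K)) {
    rows[[k]] <- seq_rows(B, starts + k)
    Wk <- matrix(layer$params$W[k, , ], layer$in_ch)
    out <- out + x$data[rows[[k]], , drop = FALSE] %*% Wk
  }
  list(out = seq_tensor(out, B, L2), cache = list(rows = rows))
}

conv1d_backward <- function(layer, x, cache, dout) {
  K <- layer$kernel
  dW <- array(0, dim = dim(layer$params$W))
  dx <- matrix(0, nrow(x$data), ncol(x$data))
  for (k in seq_len(K)) {
    r <- cache$rows[[k]]
    xk <- x$data[r, , drop = FALSE]
    dW[k, , ] <- crossprod(xk, dout$data)
    dx[r, ] <- dx[r, , drop = FALSE] +
      dout$data %*% t(matrix(layer$params$W[k, , ], layer$in_ch))
  }
  list(dinput = seq_tensor(dx, x$B, x$L),
       grads = list(W = dW, b = colSums(dout$data)))
}

## ---- batch normalisation ---------------------------------------------------

layer_batchnorm <- function(channels, affine = FALSE,
                            momentum = 0.1, eps = 1e-5) {
  params <- if (affine) {
    list(gamma = rep(1, channels), beta = numeric(channels))
  } else list()
  list(type = "batchnorm", channels = channels, affine = affine,
       momentum = momentum, eps = eps, params = params,
       buffers = list(running_mean = numeric(channels),
                      running_var = rep(1, channels)))
}

# Accepts a seq tensor (per-channel statistics over batch x time) or a plain
# feature matrix (per-feature statistics over the batch).
batchnorm_forward <- function(layer, x, training) {
  dat <- if (is.list(x)) x$data else x
  if (training) {
    mu <- colMeans(dat)
    v <- colMeans(sweep(dat, 2, mu)^2)
  } else {
    mu <- layer$buffers$running_mean
    v <- layer$buffers$running_var
  }
  inv <- 1 / sqrt(v + layer$eps)
  xhat <- sweep(sweep(dat, 2, mu), 2, inv, `*`)
  out <- if (layer$affine) {
    sweep(sweep(xhat, 2, layer$params$gamma, `*`), 2, layer$params$beta, `+`)
  } else xhat
  new_buffers <- NULL
  if (training) {
    m <- layer$momentum
    n <- nrow(dat)
    new_buffers <- list(
      running_mean = (1 - m) * layer$buffers$running_mean + m * mu,
      running_var = (1 - m) * layer$buffers$running_var +
        m * v * n / max(n - 1L, 1L))
  }
  list(out = if (is.list(x)) seq_tensor(out, x$B, x$L) else out,
       cache = list(xhat = xhat, inv = inv, training = training),
       buffers = new_buffers)
}

batchnorm_backward <- function(layer, x, cache, dout) {
  d <- if (is.list(dout)) dout$data else dout
  grads <- list()
  if (layer$affine) {
    grads$gamma <- colSums(d * cache$xhat)
    grads$beta <- colSums(d)
    d <- sweep(d, 2, layer$params$gamma, `*`)
  }
  if (cache$training) {
    n <- nrow(d)
    dx <- sweep(d - matrix(colMeans(d), n, ncol(d), byrow = TRUE) -
                  sweep(cache$xhat, 2, colMeans(d * cache$xhat), `*`),
                2, cache$inv, `*`)
  } else {
    dx <- sweep(d, 2, cache$inv, `*`)
  }
  list(dinput = if (is.list(x)) seq_tensor(dx, x$B, x$L) else dx,
       grads = grads)
}

## ---- max pooling (non-overlapping) ----------------------------------------

layer_maxpool <- function(window) {
  list(type = "maxpool", window = as.integer(window), params = list())
}

maxpool_forward <- function(layer, x) {
  p <- layer$window
  B <- x$B
  L2 <- x$L %/% p
  if (L2 < 1L) stop("sequence shorter than the pooling window", call. = FALSE)
  best <- x$data[seq_rows(B, (seq_len(L2) - 1L) * p + 1L), , drop = FALSE]
  arg <- matrix(1L, nrow(best), ncol(best))
  for (j in seq.int(2L, p)) {
    cand <- x$data[seq_rows(B, (seq_len(L2) - 1L) * p + j), , drop = FALSE]
    sel <- cand > best
    best[sel] <- cand[sel]
    arg[sel] <- j
  }
  list(out = seq_tensor(best, B, L2), cache = list(arg = arg))
}

maxpool_backward <- function(layer, x, cache, dout) {
  p <- layer$window; B <- x$B; L2 <- dout$L; C <- ncol(x$data)
  dx <- matrix(0, nrow(x$data), C)
  # row of the winning sample inside the pooled input
  b_idx <- rep(seq_len(B), L2)
  t_out <- rep(seq_len(L2), each = B)
  src_time <- matrix((t_out - 1L) * p, nrow(cache$arg), C) + cache$arg
  src_row <- (src_time - 1L) * B + b_idx
  lin <- as.vector(src_row + (rep(seq_len(C), each = nrow(src_row)) - 1L) *
                     nrow(dx))
  dx[lin] <- dx[lin] + as.vector(dout$data)
  list(dinput = seq_tensor(dx, B, x$L), grads = list())
}

## ---- channel average -------------------------------------------------------

layer_chanavg <- function() list(type = "chanavg", params = list())

chanavg_forward <- function(layer, x) {
  list(out = matrix(rowMeans(x$data), x$B, x$L), cache = NULL)
}

chanavg_backward <- function(layer, x, cache, dout) {
  C <- ncol(x$data)
  dx <- matrix(rep(as.vector(dout) / C, C), nrow = nrow(x$data), ncol = C)
  list(dinput = seq_tensor(dx, x$B, x$L), grads = list())
}

## ---- LSTM ------------------------------------------------------------------

# Gate layout inside the 4H-wide weight blocks: input, forget, cell, output.
# One bias vector per layer (the coupled-bias convention); forget-gate bias
# initialised to 1.
lstm_direction_params <- function(in_dim, hidden) {
  Wx <- matrix(glorot(in_dim, 4L * hidden, in_dim * 4L * hidden),
               in_dim, 4L * hidden)
  Wh <- matrix(glorot(hidden, 4L * hidden, hidden * 4L * hidden),
               hidden, 4L * hidden)
  b <- numeric(4L * hidden)
  b[(hidden + 1L):(2L * hidden)] <- 1
  list(Wx = Wx, Wh = Wh, b = b)
}

layer_lstm <- function(in_dim, hidden, n_layers = 1L, bidirectional = FALSE) {
  dirs <- if (bidirectional) 2L else 1L
  params <- list()
  for (l in seq_len(n_layers)) {
    d_in <- if (l == 1L) in_dim else hidden * dirs
    for (d in seq_len(dirs)) {
      params[[sprintf("l%dd%d", l, d)]] <- lstm_direction_params(d_in, hidden)
    }
  }
  list(type = "lstm", in_dim = in_dim, hidden = hidden,
       n_layers = as.integer(n_layers), bidirectional = bidirectional,
       params = params)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# One direction over a seq tensor; `rev_time` runs the recursion backwards
# in time but returns hidden states aligned with input time.
lstm_run_direction <- function(p, x, rev_time = FALSE) {
  B <- x$B; L <- x$L; H <- ncol(p$Wh)
  H <- H %/% 4L
  h <- matrix(0, B, H); cst <- matrix(0, B, H)
  hs <- matrix(0, B * L, H)
  cache <- vector("list", L)
  order_t <- if (rev_time) rev(seq_len(L)) else seq_len(L)
  for (t in order_t) {
    r <- seq_rows(B, t)
    xt <- x$data[r, , drop = FALSE]
    g <- xt %*% p$Wx + h %*% p$Wh +
      matrix(p$b, B, 4L * H, byrow = TRUE)
    i <- sigmoid(g[, 1:H, drop = FALSE])
    f <- sigmoid(g[, (H + 1L):(2L * H), drop = FALSE])
    gg <- tanh(g[, (2L * H + 1L):(3L * H), drop = FALSE])
    o <- sigmoid(g[, (3L * H + 1L):(4L * H), drop = FALSE])
    c_prev <- cst
    h_prev <- h
    cst <- f * c_prev + i * gg
    tc <- tanh(cst)
    h <- o * tc
    hs[r, ] <- h
    cache[[t]] <- list(xt = xt, i = i, f = f, g = gg, o = o,
                       c = cst, tc = tc, c_prev = c_prev, h_prev = h_prev)
  }
  list(hs = hs, cache = cache)
}

lstm_backprop_direction <- function(p, x, run, dhs, rev_time = FALSE) {
  B <- x$B; L <- x$L; H <- ncol(run$hs)
  dWx <- matrix(0, nrow(p$Wx), 4L * H)
  dWh <- matrix(0, H, 4L * H)
  db <- numeric(4L * H)
  dx <- matrix(0, nrow(x$data), nrow(p$Wx))
  dh_next <- matrix(0, B, H)
  dc_next <- matrix(0, B, H)
  order_t <- if (rev_time) seq_len(L) else rev(seq_len(L))
  for (t in order_t) {
    cc <- run$cache[[t]]
    r <- seq_rows(B, t)
    dh <- dhs[r, , drop = FALSE] + dh_next
    dc <- dc_next + dh * cc$o * (1 - cc$tc^2)
    di <- dc * cc$g * cc$i * (1 - cc$i)
    df <- dc * cc$c_prev * cc$f * (1 - cc$f)
    dg <- dc * cc$i * (1 - cc$g^2)
    do_ <- dh * cc$tc * cc$o * (1 - cc$o)
    dgates <- cbind(di, df, dg, do_)
    dWx <- dWx + crossprod(cc$xt, dgates)
    dWh <- dWh + crossprod(cc$h_prev, dgates)
    db <- db + colSums(dgates)
    dx[r, ] <- dgates %*% t(p$Wx)
    dh_next <- dgates %*% t(p$Wh)
    dc_next <- dc * cc$f
  }
  list(dx = dx, grads = list(Wx = dWx, Wh = dWh, b = db))
}

lstm_forward <- function(layer, x) {
  dirs <- if (layer$bidirectional) 2L else 1L
  inp <- x
  runs <- list()
  for (l in seq_len(layer$n_layers)) {
    outs <- vector("list", dirs)
    for (d in seq_len(dirs)) {
      key <- sprintf("l%dd%d", l, d)
      runs[[key]] <- lstm_run_direction(layer$params[[key]], inp,
                                        rev_time = (d == 2L))
      outs[[d]] <- runs[[key]]$hs
    }
    inp <- seq_tensor(do.call(cbind, outs), x$B, x$L)
    runs[[sprintf("in_l%d", l)]] <- inp  # input to the next layer
  }
  list(out = inp, cache = runs)
}

lstm_backward <- function(layer, x, cache, dout) {
  dirs <- if (layer$bidirectional) 2L else 1L
  H <- layer$hidden
  grads <- list()
  d_up <- dout$data
  for (l in rev(seq_len(layer$n_layers))) {
    inp <- if (l == 1L) x else cache[[sprintf("in_l%d", l - 1L)]]
    dx_l <- NULL
    for (d in seq_len(dirs)) {
      key <- sprintf("l%dd%d", l, d)
      dhs <- d_up[, ((d - 1L) * H + 1L):(d * H), drop = FALSE]
      bp <- lstm_backprop_direction(layer$params[[key]], inp,
                                    cache[[key]], dhs,
                                    rev_time = (d == 2L))
      grads[[key]] <- bp$grads
      dx_l <- if (is.null(dx_l)) bp$dx else dx_l + bp$dx
    }
    d_up <- dx_l
  }
  list(dinput = seq_tensor(d_up, x$B, x$L), grads = grads)
}

## ---- global average pooling over time --------------------------------------

layer_gap <- function() list(type = "gap", params = list())

gap_forward <- function(layer, x) {
  a <- array(x$data, dim = c(x$B, x$L, ncol(x$data)))
  out <- colMeans(aperm(a, c(2L, 1L, 3L)))  # (B x C)
  if (is.null(dim(out))) out <- matrix(out, nrow = x$B)
  list(out = out, cache = NULL)
}

gap_backward <- function(layer, x, cache, dout) {
  dx <- dout[rep(seq_len(x$B), x$L), , drop = FALSE] / x$L
  list(dinput = seq_tensor(dx, x$B, x$L), grads = list())
}

## ---- dense -----------------------------------------------------------------

layer_dense <- function(in_dim, out_dim, activation = c("none", "relu",
                                                        "sigmoid")) {
  activation <- match.arg(activation)
  list(type = "dense", in_dim = in_dim, out_dim = out_dim,
       activation = activation,
       params = list(W = matrix(glorot(in_dim, out_dim, in_dim * out_dim),
                                in_dim, out_dim),
                     b = numeric(out_dim)))
}

dense_apply_forward <- function(layer, x) {
  z <- x %*% layer$params$W + matrix(layer$params$b, nrow(x),
                                     layer$out_dim, byrow = TRUE)
  a <- switch(layer$activation,
              none = z, relu = pmax(z, 0), sigmoid = sigmoid(z))
  list(out = a, cache = list(z = z, a = a))
}

dense_apply_backward <- function(layer, x, cache, dout) {
  dz <- switch(layer$activation,
               none = dout,
               relu = dout * (cache$z > 0),
               sigmoid = dout * cache$a * (1 - cache$a))
  list(dinput = dz %*% t(layer$params$W),
       grads = list(W = crossprod(x, dz), b = colSums(dz)))
}

## ---- KAN layer (trainable wrapper) ----------------------------------------

layer_kan <- function(in_dim, out_dim, spec, include_base = FALSE) {
  nb <- spec$n_basis
  params <- list(coeffs = array(stats::rnorm(out_dim * in_dim * nb, sd = 0.1),
                                dim = c(out_dim, in_dim, nb)))
  if (include_base) {
    params$base_weight <- matrix(stats::rnorm(out_dim * in_dim, sd = 0.1),
                                 out_dim, in_dim)
    params$spline_scaler <- matrix(1, out_dim, in_dim)
  }
  # block indicator used to sum per-basis input gradients within each input
  ind <- matrix(0, in_dim * nb, in_dim)
  ind[cbind(seq_len(in_dim * nb), rep(seq_len(in_dim), each = nb))] <- 1
  list(type = "kan", in_dim = in_dim, out_dim = out_dim, spec = spec,
       include_base = include_base, block_ind = ind, params = params)
}

kan_as_layer_obj <- function(layer) {
  obj <- list(in_dim = layer$in_dim, out_dim = layer$out_dim,
              spec = layer$spec, include_base = layer$include_base,
              coeffs = layer$params$coeffs)
  if (layer$include_base) {
    obj$base_weight <- layer$params$base_weight
    obj$spline_scaler <- layer$params$spline_scaler
  }
  structure(obj, class = "kan_layer")
}

kan_apply_forward <- function(layer, x) {
  spec <- layer$spec
  xc <- clamp_to_domain(x, spec)
  Bf <- kan_flat_basis(xc, spec)
  Cf <- kan_flat_coeffs(kan_as_layer_obj(layer))
  out <- Bf %*% t(Cf)
  if (layer$include_base) out <- out + silu(xc) %*% t(layer$params$base_weight)
  list(out = out, cache = list(xc = xc, Bf = Bf, Cf = Cf,
                               inside = (x >= spec$domain_lo &
                                           x <= spec$domain_hi)))
}

kan_apply_backward <- function(layer, x, cache, dout) {
  spec <- layer$spec
  nb <- spec$n_basis
  dCf <- crossprod(dout, cache$Bf)  # out x (in*nb)
  dC_arr <- aperm(array(dCf, dim = c(layer$out_dim, nb, layer$in_dim)),
                  c(1L, 3L, 2L))
  grads <- list()
  if (layer$include_base) {
    sc <- array(rep(layer$params$spline_scaler, nb),
                dim = c(layer$out_dim, layer$in_dim, nb))
    grads$coeffs <- dC_arr * sc
    grads$spline_scaler <-
      apply(dC_arr * layer$params$coeffs, c(1L, 2L), sum)
    grads$base_weight <- crossprod(dout, silu(cache$xc))
  } else {
    grads$coeffs <- dC_arr
  }
  Bd <- kan_flat_basis(cache$xc, spec, deriv = TRUE)
  P <- dout %*% cache$Cf
  dx <- (P * Bd) %*% layer$block_ind
  if (layer$include_base) {
    dx <- dx + (dout %*% layer$params$base_weight) * silu_deriv(cache$xc)
  }
  dx <- dx * cache$inside  # clamped points contribute no input gradient
  list(dinput = dx, grads = grads)
}

## ---- generic dispatch ------------------------------------------------------

nn_forward_layer <- function(layer, input, training = FALSE) {
  switch(layer$type,
         conv1d = conv1d_forward(layer, input),
         batchnorm = batchnorm_forward(layer, input, training),
         maxpool = maxpool_forward(layer, input),
         chanavg = chanavg_forward(layer, input),
         lstm = lstm_forward(layer, input),
         gap = gap_forward(layer, input),
         dense = dense_apply_forward(layer, input),
         kan = kan_apply_forward(layer, input),
         stop("unknown layer type: ", layer$type))
}

nn_backward_layer <- function(layer, input, cache, dout) {
  switch(layer$type,
         conv1d = conv1d_backward(layer, input, cache, dout),
         batchnorm = batchnorm_backward(layer, input, cache, dout),
         maxpool = maxpool_backward(layer, input, cache, dout),
         chanavg = chanavg_backward(layer, input, cache, dout),
         lstm = lstm_backward(layer, input, cache, dout),
         gap = gap_backward(layer, input, cache, dout),
         dense = dense_apply_backward(layer, input, cache, dout),
         kan = kan_apply_backward(layer, input, cache, dout),
         stop("unknown layer type: ", layer$type))
}
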