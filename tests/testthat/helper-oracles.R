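# Independent oracles used to cross-check the implementation. These are
# deliberately naive (recursive / quadratic) and share no code with R/.

# Textbook recursive Cox-de Boor evaluation of a single B-spline basis
# function B_{j,k} on a knot vector.
cdb_recursive <- function(x, knots, j, k) {
  if (k == 0) {
    last <- max(which(knots < knots[length(knots)]))
    if (j == last && x == knots[length(knots)]) return(1)
    return(as.numeric(x >= knots[j] && x < knots[j + 1]))
  }
  w1 <- 0
  if (knots[j + k] > knots[j]) {
    w1 <- (x - knots[j]) / (knots[j + k] - knots[j]) *
      cdb_recursive(x, knots, j, k - 1)
  }
  w2 <- 0
  if (knots[j + k + 1] > knots[j + 1]) {
    w2 <- (knots[j + k + 1] - x) / (knots[j + k + 1] - knots[j + 1]) *
      cdb_recursive(x, knots, j + 1, k - 1)
  }
  w1 + w2
}

cdb_basis_vector <- function(x, spec) {
  vapply(seq_len(spec$n_basis), function(j) {
    cdb_recursive(x, spec$knots, j, spec$degree)
  }, numeric(1))
}

# O(n^2) pairwise-comparison AUC (Mann-Whitney), ties counted half.
pairwise_auc <- function(y, s) {
  pos <- s[y == 1]
  neg <- s[y == 0]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# loop-based matrix-vector product
naive_matvec <- function(W, x, b) {
  out <- numeric(nrow(W))
  for (i in seq_len(nrow(W))) {
    acc <- b[i]
    for (j in seq_len(ncol(W))) acc <- acc + W[i, j] * x[j]
    out[i] <- acc
  }
  out
}

# finite-difference gradient check of a built network against
# net_backward(), probing a few entries of every parameter tensor
gradcheck_network <- function(cfg, seed = 2, n = 3, probes = 4, eps = 1e-6) {
  net <- build_model(cfg, seed = seed)
  set.seed(seed + 100)
  X <- matrix(runif(n * cfg$input_length), n)
  y <- rep_len(c(1, 0), n)
  fwd <- net_forward(net, X, training = TRUE)
  gr <- ppgqc:::net_backward(net, fwd, y)
  loss_at <- function(net) bce_loss(y, net_forward(net, X, training = TRUE)$prob)
  modp <- function(params, path, j, d) {
    if (length(path) == 1) params[[path]][j] <- params[[path]][j] + d
    else params[[path[1]]] <- modp(params[[path[1]]], path[-1], j, d)
    params
  }
  maxerr <- 0
  for (li in seq_along(net$layers)) {
    leaves <- ppgqc:::param_leaves(net$layers[[li]]$params)
    gl <- ppgqc:::param_leaves(gr[[li]])
    for (nm in names(leaves)) {
      for (j in sample(length(leaves[[nm]]), min(probes,
                                                 length(leaves[[nm]])))) {
        path <- strsplit(nm, ".", fixed = TRUE)[[1]]
        net2 <- net
        net2$layers[[li]]$params <- modp(net$layers[[li]]$params, path, j, eps)
        lp <- loss_at(net2)
        net2$layers[[li]]$params <- modp(net$layers[[li]]$params, path, j, -eps)
        lm <- loss_at(net2)
        fd <- (lp - lm) / (2 * eps)
        an <- gl[[nm]][j]
        maxerr <- max(maxerr, abs(fd - an) / max(1e-8, abs(fd) + abs(an)))
      }
    }
  }
  maxerr
}

# small raw dataset shared by training-path tests
tiny_dataset <- function(n_good = 12, n_fair = 6, n_poor = 6, seed = 42) {
  generate_dataset(n_good, n_fair, n_poor, fs = 128, seed = seed,
                   duration_s = 2)
}

# compact model configs that train in seconds
tiny_config <- function(family, input_length) {
  switch(family,
    cnn_mlp = model_config("cnn_mlp", input_length = input_length,
                           conv_channels = 2, conv_kernel = 5,
                           ff_dims = c(8)),
    cnn_kan = model_config("cnn_kan", input_length = input_length,
                           conv_channels = 2, conv_kernel = 5,
                           kan_width = 4, kan_order = 3),
    cnn_lstm = model_config("cnn_lstm", input_length = input_length,
                            conv_channels = 2, conv_kernel = 5,
                            conv_stride = 4, lstm_hidden = 4,
                            lstm_layers = 1, ff_dims = c(8)))
}
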