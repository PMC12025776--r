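#' Classifier architecture configuration
#'
#' Describes one of the three binary PPG-quality classifiers. The defaults
#' of each family are the selected hyperparameters of the corresponding
#' published architecture (kernel 15, LSTM hidden 56, feed-forward
#' \[112, 64\] for the CNN-LSTM; feed-forward \[100, 50, 25, 10\] for the
#' CNN-MLP; grid 3, order 5, width 80 for the CNN-KAN), completed with the
#' channel/layer sizes fixed in the package vignette so that the trainable
#' parameter counts of the three default builds are 456,865 / 22,526 /
#' 127,206.
#'
#' @param family One of `"cnn_lstm"`, `"cnn_mlp"`, `"cnn_kan"`.
#' @param input_length Samples per segment after preprocessing (default 640,
#'   i.e. 5 s at 128 Hz).
#' @param conv_channels Integer vector of output channels of the 1D
#'   convolution stack.
#' @param conv_kernel Convolution kernel size (shared by the stack).
#' @param conv_stride Stride of the first convolution (later convolutions
#'   use stride 1).
#' @param lstm_hidden,lstm_layers,lstm_bidirectional LSTM size, depth and
#'   directionality (CNN-LSTM family).
#' @param ff_dims Hidden sizes of the fully connected stack; a final layer
#'   to one sigmoid unit is appended automatically.
#' @param pool_size Max-pooling window (CNN-MLP / CNN-KAN families).
#' @param kan_grid,kan_order KAN activation grid count and spline degree.
#' @param kan_width Hidden size of the two-layer KAN stack.
#' @param kan_base Include the per-edge residual base function and spline
#'   scaler (default `TRUE` for the CNN-KAN family, matching the published
#'   parameter count).
#' @param kan_domain Length-2 spline domain of the KAN activations.
#' @return An object of class `ppgq_model_config`.
#' @export
model_config <- function(family = c("cnn_lstm", "cnn_mlp", "cnn_kan"),
                         input_length = 640,
                         conv_channels = NULL, conv_kernel = NULL,
                         conv_stride = 1,
                         lstm_hidden = 56, lstm_layers = 2,
                         lstm_bidirectional = FALSE,
                         ff_dims = NULL, pool_size = 4,
                         kan_grid = 3, kan_order = 5, kan_width = 80,
                         kan_base = TRUE, kan_domain = NULL) {
  family <- match.arg(family)
  # KAN activations sit behind a parameter-free feature normalisation, so
  # their inputs are approximately standard normal; [-3, 3] covers them.
  kan_domain <- kan_domain %||% c(-3, 3)
  defaults <- switch(family,
    cnn_lstm = list(conv_channels = c(224L, 112L), conv_kernel = 15L,
                    ff_dims = c(112L, 64L)),
    cnn_mlp = list(conv_channels = 3L, conv_kernel = 9L,
                   ff_dims = c(100L, 50L, 25L, 10L)),
    cnn_kan = list(conv_channels = 62L, conv_kernel = 12L, ff_dims = integer())
  )
  conv_channels <- as.integer(conv_channels %||% defaults$conv_channels)
  conv_kernel <- assert_count(conv_kernel %||% defaults$conv_kernel,
                              "conv_kernel", min = 1)
  ff_dims <- as.integer(ff_dims %||% defaults$ff_dims)
  if (any(conv_channels < 1L)) stop("conv channels must be positive",
                                    call. = FALSE)
  assert_count(input_length, "input_length", min = 1)
  assert_count(conv_stride, "conv_stride", min = 1)
  assert_count(pool_size, "pool_size", min = 1)
  assert_count(lstm_hidden, "lstm_hidden", min = 1)
  assert_count(lstm_layers, "lstm_layers", min = 1)
  assert_flag(lstm_bidirectional, "lstm_bidirectional")
  assert_flag(kan_base, "kan_base")
  structure(
    list(family = family, input_length = as.integer(input_length),
         conv_channels = conv_channels, conv_kernel = conv_kernel,
         conv_stride = as.integer(conv_stride),
         lstm_hidden = as.integer(lstm_hidden),
         lstm_layers = as.integer(lstm_layers),
         lstm_bidirectional = lstm_bidirectional,
         ff_dims = ff_dims, pool_size = as.integer(pool_size),
         kan_spec = spline_spec(kan_grid, kan_order,
                                kan_domain[1], kan_domain[2]),
         kan_width = as.integer(kan_width), kan_base = kan_base),
    class = "ppgq_model_config"
  )
}

#' Build a quality classifier network
#'
#' Instantiates the architecture described by a [model_config()] with
#' seeded random initial weights. All three families share a convolutional
#' front end and end in a scalar score that is mapped through a sigmoid to
#' the probability of the "good" class:
#' * `cnn_lstm`: conv stack -> batch norm -> LSTM -> global average pooling
#'   over time -> fully connected stack -> sigmoid.
#' * `cnn_mlp`: conv -> max pooling -> channel average -> fully connected
#'   stack (ReLU hidden activations) -> sigmoid.
#' * `cnn_kan`: conv -> max pooling -> channel average -> two-layer
#'   Kolmogorov-Arnold stack (`feature_len -> kan_width -> 1`); the score is
#'   passed through a sigmoid for loss and prediction.
#'
#' @param cfg A [model_config()].
#' @param seed Integer seed for weight initialisation.
#' @return An object of class `ppgq_net`.
#' @export
build_model <- function(cfg, seed = 1) {
  if (!inherits(cfg, "ppgq_model_config")) {
    stop("'cfg' must come from model_config()", call. = FALSE)
  }
  with_seed(seed, {
    layers <- list()
    L <- cfg$input_length
    in_ch <- 1L
    for (i in seq_along(cfg$conv_channels)) {
      s <- if (i == 1L) cfg$conv_stride else 1L
      layers[[length(layers) + 1L]] <-
        layer_conv1d(in_ch, cfg$conv_channels[i], cfg$conv_kernel, s)
      L <- conv_out_len(L, cfg$conv_kernel, s)
      in_ch <- cfg$conv_channels[i]
    }
    if (cfg$family == "cnn_lstm") {
      layers[[length(layers) + 1L]] <- layer_batchnorm(in_ch, affine = FALSE)
      layers[[length(layers) + 1L]] <-
        layer_lstm(in_ch, cfg$lstm_hidden, cfg$lstm_layers,
                   cfg$lstm_bidirectional)
      feat <- cfg$lstm_hidden * (1L + cfg$lstm_bidirectional)
      layers[[length(layers) + 1L]] <- layer_gap()
      prev <- feat
      for (d in cfg$ff_dims) {
        layers[[length(layers) + 1L]] <- layer_dense(prev, d, "relu")
        prev <- d
      }
      layers[[length(layers) + 1L]] <- layer_dense(prev, 1L, "none")
    } else {
      layers[[length(layers) + 1L]] <- layer_maxpool(cfg$pool_size)
      L <- L %/% cfg$pool_size
      if (L < 1L) stop("config collapses the sequence to length 0",
                       call. = FALSE)
      layers[[length(layers) + 1L]] <- layer_chanavg()
      if (cfg$family == "cnn_mlp") {
        prev <- L
        for (d in cfg$ff_dims) {
          layers[[length(layers) + 1L]] <- layer_dense(prev, d, "relu")
          prev <- d
        }
        layers[[length(layers) + 1L]] <- layer_dense(prev, 1L, "none")
      } else {
        # parameter-free standardisation keeps the activation inputs inside
        # the spline domain (adds no trainable parameters)
        layers[[length(layers) + 1L]] <- layer_batchnorm(L, affine = FALSE)
        layers[[length(layers) + 1L]] <-
          layer_kan(L, cfg$kan_width, cfg$kan_spec, cfg$kan_base)
        layers[[length(layers) + 1L]] <-
          layer_batchnorm(cfg$kan_width, affine = FALSE)
        layers[[length(layers) + 1L]] <-
          layer_kan(cfg$kan_width, 1L, cfg$kan_spec, cfg$kan_base)
      }
    }
    structure(list(config = cfg, layers = layers, feature_len = L),
              class = "ppgq_net")
  })
}

#' Compact training configurations
#'
#' Scaled-down members of each architecture family used for experiments on
#' synthetic data at desk scale: the same layer structure as the family
#' default, with small channel counts and hidden sizes (and a strided first
#' convolution for the recurrent family) so that a full train/evaluate
#' cycle runs in seconds on one CPU.
#'
#' @param family Architecture family.
#' @param input_length Samples per preprocessed segment (default 640).
#' @return A [model_config()].
#' @export
compact_config <- function(family = c("cnn_lstm", "cnn_mlp", "cnn_kan"),
                           input_length = 640) {
  family <- match.arg(family)
  switch(family,
    cnn_lstm = model_config("cnn_lstm", input_length = input_length,
                            conv_channels = 8, conv_stride = 4,
                            lstm_hidden = 16, lstm_layers = 1,
                            ff_dims = c(16)),
    cnn_mlp = model_config("cnn_mlp", input_length = input_length,
                           conv_channels = 4, ff_dims = c(16, 8)),
    cnn_kan = model_config("cnn_kan", input_length = input_length,
                           conv_channels = 4, kan_width = 8))
}

#' @export
print.ppgq_net <- function(x, ...) {
  cat(sprintf("<ppgq_net: %s, %s trainable parameters>\n",
              x$config$family,
              format(count_trainable_parameters(x), big.mark = ",")))
  print(parameter_table(x))
  invisible(x)
}

#' Forward pass through a classifier network
#'
#' @param net A [build_model()] network.
#' @param X Matrix of input segments, one row per segment, with
#'   `config$input_length` columns (a single segment may be given as a
#'   vector).
#' @param training Use batch statistics in normalisation layers and keep
#'   caches for backpropagation.
#' @return A list with `prob` (vector of good-quality probabilities in
#'   (0,1)), `score` (pre-sigmoid scores), and, when `training`, the
#'   per-layer caches needed by `net_backward()`.
#' @export
net_forward <- function(net, X, training = FALSE) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  if (ncol(X) != net$config$input_length) {
    stop(sprintf("input has %d samples per row, model expects %d",
                 ncol(X), net$config$input_length), call. = FALSE)
  }
  act <- seq_tensor(matrix(as.vector(X), ncol = 1L), nrow(X), ncol(X))
  inputs <- vector("list", length(net$layers))
  caches <- vector("list", length(net$layers))
  for (i in seq_along(net$layers)) {
    inputs[[i]] <- act
    step <- nn_forward_layer(net$layers[[i]], act, training)
    caches[[i]] <- step$cache
    if (!is.null(step$buffers)) caches[[i]]$new_buffers <- step$buffers
    act <- step$out
  }
  score <- drop(act)
  list(prob = sigmoid(score), score = score,
       inputs = if (training) inputs, caches = if (training) caches)
}

# Gradient of the mean BCE loss with respect to every trainable parameter.
# `fwd` must come from net_forward(..., training = TRUE).
net_backward <- function(net, fwd, y) {
  n <- length(y)
  dscore <- matrix((fwd$prob - y) / n, ncol = 1L)
  grads <- vector("list", length(net$layers))
  dout <- dscore
  for (i in rev(seq_along(net$layers))) {
    bk <- nn_backward_layer(net$layers[[i]], fwd$inputs[[i]],
                            fwd$caches[[i]], dout)
    grads[[i]] <- bk$grads
    dout <- bk$dinput
  }
  grads
}

# Apply freshly computed batch-norm running statistics after a training step.
net_update_buffers <- function(net, fwd) {
  for (i in seq_along(net$layers)) {
    nb <- fwd$caches[[i]]$new_buffers
    if (!is.null(nb)) net$layers[[i]]$buffers <- nb
  }
  net
}

# Depth of nesting distinguishes plain layers (params = list of arrays) from
# LSTM layers (params = list of per-direction lists of arrays).
param_leaves <- function(params) {
  if (!length(params)) return(list())
  out <- list()
  for (nm in names(params)) {
    p <- params[[nm]]
    if (is.list(p)) {
      sub <- param_leaves(p)
      names(sub) <- paste(nm, names(sub), sep = ".")
      out <- c(out, sub)
    } else {
      out[[nm]] <- p
    }
  }
  out
}

#' Count the trainable parameters of a network
#'
#' Sums the sizes of every trainable tensor: convolution and dense weights
#' and biases, LSTM weight matrices and bias vectors, batch-norm affine
#' terms (when present), KAN spline coefficients and, when enabled, base
#' weights and spline scalers. Batch-norm running statistics are buffers,
#' not parameters, and are excluded.
#'
#' @param model A `ppgq_net` (or a bare internal layer list).
#' @return Integer parameter count.
#' @examples
#' cfg <- model_config("cnn_mlp")
#' count_trainable_parameters(build_model(cfg))  # 22526
#' @export
count_trainable_parameters <- function(model) {
  layers <- if (inherits(model, "ppgq_net")) model$layers else model
  sum(vapply(layers, function(l) {
    sum(vapply(param_leaves(l$params), length, integer(1)), 0L)
  }, numeric(1)))
}

#' Per-layer parameter table of a network
#'
#' @param net A `ppgq_net`.
#' @return A data frame with one row per layer: type, output shape note,
#'   and trainable parameter count. Counts are additive: they sum to
#'   [count_trainable_parameters()].
#' @export
parameter_table <- function(net) {
  if (!inherits(net, "ppgq_net")) stop("'net' must be a ppgq_net",
                                       call. = FALSE)
  data.frame(
    layer = seq_along(net$layers),
    type = vapply(net$layers, `[[`, "", "type"),
    parameters = vapply(net$layers, function(l) {
      sum(vapply(param_leaves(l$params), length, integer(1)), 0L)
    }, numeric(1))
  )
}
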