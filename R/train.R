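#' Training configuration
#'
#' Optimisation settings for [train_network()]: Adam with binary
#' cross-entropy loss, early stopping on validation loss, and checkpointing
#' of the best epoch. Defaults follow the study conditions: at most 200
#' epochs with patience 50.
#'
#' @param max_epochs Maximum number of epochs (default 200).
#' @param patience Consecutive epochs without strict validation-loss
#'   improvement before stopping (default 50); ties do not reset patience.
#' @param learning_rate Adam step size (default 1e-3).
#' @param batch_size Mini-batch size (default 32).
#' @param seed Seed controlling weight updates and shuffling.
#' @param split_fractions Train/validation/test fractions, summing to 1
#'   (default 0.4/0.3/0.3).
#' @param threshold Decision cutoff for thresholded metrics (default 0.5).
#' @return An object of class `ppgq_train_config`.
#' @export
train_control <- function(max_epochs = 200, patience = 50,
                          learning_rate = 1e-3, batch_size = 32,
                          seed = 1, split_fractions = c(0.4, 0.3, 0.3),
                          threshold = 0.5) {
  max_epochs <- assert_count(max_epochs, "max_epochs", min = 1)
  patience <- assert_count(patience, "patience", min = 1)
  if (patience > max_epochs) {
    stop("'patience' must not exceed 'max_epochs'", call. = FALSE)
  }
  assert_number(learning_rate, "learning_rate", min = 0, strict_min = TRUE)
  batch_size <- assert_count(batch_size, "batch_size", min = 1)
  if (length(split_fractions) != 3L || any(split_fractions <= 0) ||
      abs(sum(split_fractions) - 1) > 1e-8) {
    stop("'split_fractions' must be three positive numbers summing to 1",
         call. = FALSE)
  }
  assert_number(threshold, "threshold", min = 0, max = 1)
  if (threshold <= 0 || threshold >= 1) {
    stop("'threshold' must lie strictly inside (0, 1)", call. = FALSE)
  }
  structure(
    list(max_epochs = max_epochs, patience = patience,
         learning_rate = learning_rate, batch_size = batch_size,
         seed = seed, split_fractions = as.numeric(split_fractions),
         threshold = threshold),
    class = "ppgq_train_config"
  )
}

#' Binary cross-entropy loss
#'
#' `-(1/N) * sum(y * log(p) + (1 - y) * log(1 - p))`, with predicted
#' probabilities clipped to `[eps, 1 - eps]` so the logarithms stay finite.
#'
#' @param y Binary labels (0/1).
#' @param p Predicted probabilities.
#' @param eps Clipping epsilon (default 1e-7).
#' @return Non-negative scalar loss.
#' @examples
#' bce_loss(c(1, 0), c(0.8, 0.4))  # 0.366979
#' @export
bce_loss <- function(y, p, eps = 1e-7) {
  if (length(y) != length(p)) {
    stop("'y' and 'p' must have equal length", call. = FALSE)
  }
  if (!all(y %in% c(0, 1))) stop("'y' must be binary", call. = FALSE)
  p <- pmin(pmax(p, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Stratified train/validation/test split
#'
#' Partitions a labelled dataset into disjoint, exhaustive subsets whose
#' per-class proportions match the requested fractions to within one
#' sample. Stratification uses the 3-class quality label when present,
#' otherwise the binary label.
#'
#' @param dataset A `ppg_dataset`, or a plain vector of class labels (in
#'   which case index vectors are returned).
#' @param fractions Three positive fractions summing to 1.
#' @param seed Integer seed; the partition is deterministic per seed.
#' @return For a dataset: list of three `ppg_dataset`s (`train`, `val`,
#'   `test`), each carrying an `indices` attribute. For a label vector:
#'   list of three index vectors.
#' @export
stratified_split <- function(dataset, fractions = c(0.4, 0.3, 0.3),
                             seed = 1) {
  if (length(fractions) != 3L || any(fractions <= 0) ||
      abs(sum(fractions) - 1) > 1e-8) {
    stop("'fractions' must be three positive numbers summing to 1",
         call. = FALSE)
  }
  labels <- if (inherits(dataset, "ppg_dataset")) {
    vapply(dataset$signals, function(s) s$label, integer(1))
  } else dataset
  idx <- list(train = integer(), val = integer(), test = integer())
  classes <- sort(unique(labels))
  for (ci in seq_along(classes)) {
    members <- which(labels == classes[ci])
    n <- length(members)
    if (n < 3L) {
      stop(sprintf("class %s has only %d member(s); need at least 3",
                   classes[ci], n), call. = FALSE)
    }
    perm <- with_seed(child_seed(seed, ci), sample(members))
    n1 <- min(max(round(fractions[1] * n), 1L), n - 2L)
    n2 <- min(max(round(fractions[2] * n), 1L), n - n1 - 1L)
    idx$train <- c(idx$train, perm[seq_len(n1)])
    idx$val <- c(idx$val, perm[n1 + seq_len(n2)])
    idx$test <- c(idx$test, perm[(n1 + n2 + 1L):n])
  }
  idx <- lapply(idx, sort)
  if (!inherits(dataset, "ppg_dataset")) return(idx)
  lapply(idx, function(i) {
    d <- new_ppg_dataset(dataset$signals[i])
    attr(d, "indices") <- i
    d
  })
}

#' Dataset as model input matrix
#'
#' Stacks the segment samples of a dataset into a matrix (one row per
#' segment) alongside its binary labels. All signals must share one length.
#'
#' @param dataset A `ppg_dataset`.
#' @return List with `x` (matrix) and `y` (binary label vector).
#' @export
dataset_matrix <- function(dataset) {
  if (!inherits(dataset, "ppg_dataset")) {
    stop("'dataset' must be a ppg_dataset", call. = FALSE)
  }
  lens <- vapply(dataset$signals, function(s) length(s$samples), integer(1))
  if (length(unique(lens)) != 1L) {
    stop("all signals must have the same length to form a matrix",
         call. = FALSE)
  }
  list(x = do.call(rbind, lapply(dataset$signals, `[[`, "samples")),
       y = dataset$binary_labels)
}

#' Epoch at which early stopping halts training
#'
#' Pure form of the stopping rule used by [train_network()]: training halts
#' after `patience` consecutive epochs without a strictly lower validation
#' loss (ties do not reset the counter), or at the end of the history.
#'
#' @param val_losses Per-epoch validation losses.
#' @param patience Patience in epochs.
#' @return The 1-based epoch index after which training stops.
#' @examples
#' early_stop_epoch(c(1, 0.9, 0.8, rep(0.8, 60)), patience = 50)  # 53
#' @export
early_stop_epoch <- function(val_losses, patience) {
  best <- Inf
  wait <- 0L
  for (e in seq_along(val_losses)) {
    if (val_losses[e] < best) {
      best <- val_losses[e]
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) return(e)
    }
  }
  length(val_losses)
}

# ---- Adam ------------------------------------------------------------------

# params/grads are nested lists whose leaves are numeric arrays; walk them
# in parallel, updating moment estimates in place.
adam_step <- function(params, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (nm in names(params)) {
    p <- params[[nm]]
    g <- grads[[nm]]
    if (is.list(p)) {
      sub <- adam_step(p, g, state[[nm]] %||% list(), lr, t,
                       beta1, beta2, eps)
      params[[nm]] <- sub$params
      state[[nm]] <- sub$state
    } else {
      st <- state[[nm]] %||% list(m = 0 * p, v = 0 * p)
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g * g
      mhat <- st$m / (1 - beta1^t)
      vhat <- st$v / (1 - beta2^t)
      params[[nm]] <- p - lr * mhat / (sqrt(vhat) + eps)
      state[[nm]] <- st
    }
  }
  list(params = params, state = state)
}

#' Train a classifier with Adam, early stopping and checkpointing
#'
#' Minimises binary cross-entropy with mini-batch Adam. After each epoch
#' the validation loss is evaluated; training stops at `max_epochs` or once
#' the validation loss has not strictly improved for `patience` consecutive
#' epochs, and the weights from the epoch with the lowest validation loss
#' are returned. Fully deterministic for a fixed config seed.
#'
#' @param net A freshly built (or warm) `ppgq_net`.
#' @param train_set,val_set `ppg_dataset`s or lists with elements `x`
#'   (matrix) and `y` (binary labels); both must be non-empty.
#' @param cfg A [train_control()].
#' @param verbose Print per-epoch losses.
#' @return List with `net` (the best checkpoint), `history` (data frame of
#'   per-epoch train/val losses), `best_epoch`, `stopped_epoch`.
#' @export
train_network <- function(net, train_set, val_set, cfg = train_control(),
                          verbose = FALSE) {
  as_xy <- function(d) if (inherits(d, "ppg_dataset")) dataset_matrix(d) else d
  tr <- as_xy(train_set)
  va <- as_xy(val_set)
  if (!length(tr$y) || !length(va$y)) {
    stop("training and validation sets must be non-empty", call. = FALSE)
  }
  n <- length(tr$y)
  state <- vector("list", length(net$layers))
  step <- 0L
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())
  best <- Inf
  best_layers <- net$layers
  best_epoch <- 0L
  wait <- 0L
  stopped <- cfg$max_epochs

  with_seed(cfg$seed, {
    for (epoch in seq_len(cfg$max_epochs)) {
      perm <- sample(n)
      batch_losses <- numeric()
      for (start in seq(1L, n, by = cfg$batch_size)) {
        ix <- perm[start:min(start + cfg$batch_size - 1L, n)]
        fwd <- net_forward(net, tr$x[ix, , drop = FALSE], training = TRUE)
        batch_losses <- c(batch_losses,
                          bce_loss(tr$y[ix], fwd$prob))
        grads <- net_backward(net, fwd, tr$y[ix])
        step <- step + 1L
        for (li in seq_along(net$layers)) {
          if (!length(net$layers[[li]]$params)) next
          upd <- adam_step(net$layers[[li]]$params, grads[[li]],
                           state[[li]] %||% list(),
                           cfg$learning_rate, step)
          net$layers[[li]]$params <- upd$params
          state[[li]] <- upd$state
        }
        net <- net_update_buffers(net, fwd)
      }
      val_p <- net_forward(net, va$x)$prob
      vl <- bce_loss(va$y, val_p)
      history[epoch, ] <- list(epoch, mean(batch_losses), vl)
      if (verbose) {
        message(sprintf("epoch %3d  train %.5f  val %.5f", epoch,
                        mean(batch_losses), vl))
      }
      if (vl < best) {
        best <- vl
        best_layers <- net$layers
        best_epoch <- epoch
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= cfg$patience) {
          stopped <- epoch
          break
        }
      }
      stopped <- epoch
    }
  })
  net$layers <- best_layers
  list(net = net, history = history, best_epoch = best_epoch,
       stopped_epoch = stopped, best_val_loss = best)
}

#' Grid search over model configurations by validation AUC
#'
#' Trains every configuration in `space` on the training set, scores each
#' on the validation set by ROC AUC, and returns the best configuration
#' together with the full leaderboard. Ties are broken by fewer trainable
#' parameters, then by enumeration order. A configuration whose training
#' fails is recorded in the leaderboard and excluded from the argmax; the
#' search continues.
#'
#' @param space Non-empty list of [model_config()] objects.
#' @param train_set,val_set Labelled data as in [train_network()].
#' @param cfg A [train_control()].
#' @param verbose Print progress.
#' @return List with `best_config`, `best_fit` (its [train_network()]
#'   result), and `leaderboard` (data frame ordered best first).
#' @export
grid_search <- function(space, train_set, val_set, cfg = train_control(),
                        verbose = FALSE) {
  if (!length(space)) stop("'space' must be non-empty", call. = FALSE)
  rows <- vector("list", length(space))
  fits <- vector("list", length(space))
  for (i in seq_along(space)) {
    mc <- space[[i]]
    res <- tryCatch({
      net <- build_model(mc, seed = cfg$seed)
      fit <- train_network(net, train_set, val_set, cfg)
      va <- if (inherits(val_set, "ppg_dataset")) dataset_matrix(val_set)
        else val_set
      auc <- roc_auc(va$y, net_forward(fit$net, va$x)$prob)
      fits[[i]] <- fit
      list(auc = auc, params = count_trainable_parameters(fit$net),
           epochs = fit$stopped_epoch, status = "ok")
    }, error = function(e) {
      list(auc = NA_real_, params = NA_real_, epochs = NA_integer_,
           status = paste("failed:", conditionMessage(e)))
    })
    if (verbose) {
      message(sprintf("config %d/%d (%s): %s", i, length(space), mc$family,
                      if (is.na(res$auc)) res$status else
                        sprintf("val AUC %.4f", res$auc)))
    }
    rows[[i]] <- data.frame(config = i, family = mc$family,
                            val_auc = res$auc, parameters = res$params,
                            epochs = res$epochs, status = res$status)
  }
  lb <- do.call(rbind, rows)
  ok <- which(!is.na(lb$val_auc))
  if (!length(ok)) stop("every configuration failed to train", call. = FALSE)
  ord <- ok[order(-lb$val_auc[ok], lb$parameters[ok], lb$config[ok])]
  lb <- lb[c(ord, setdiff(seq_len(nrow(lb)), ord)), ]
  rownames(lb) <- NULL
  list(best_config = space[[ord[1]]], best_fit = fits[[ord[1]]],
       leaderboard = lb)
}
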