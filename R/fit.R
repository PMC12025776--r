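#' Fit a PPG quality classifier end to end
#'
#' One-call interface running the full study pipeline on a labelled
#' dataset: preprocessing, stratified 40/30/30 splitting, network training
#' with early stopping, and evaluation on the held-out test set.
#'
#' @param data A `ppg_dataset` of labelled raw segments (e.g. from
#'   [generate_dataset()] or [read_ppg_dataset()]).
#' @param family Classifier family, see [model_config()].
#' @param model A [model_config()]; when `NULL`, the family default is used
#'   with `input_length` matched to the preprocessed segments.
#' @param preprocess A [preprocess_config()], or `NULL` to skip
#'   preprocessing (data already preprocessed).
#' @param control A [train_control()].
#' @param seed Global seed; propagated to splitting, initialisation and
#'   optimisation.
#' @param verbose Print per-epoch losses.
#' @return An object of class `quality_fit` with methods [print()],
#'   [summary()], [predict()], [coef()], [residuals()], [simulate()] and
#'   [plot()].
#' @examples
#' \donttest{
#' d <- generate_dataset(20, 10, 10, fs = 128, seed = 7)
#' fit <- quality_fit(d, family = "cnn_mlp",
#'                    model = model_config("cnn_mlp", input_length = 640,
#'                                         conv_channels = 2),
#'                    preprocess = preprocess_config(target_fs = 128,
#'                                                   butter_cutoff = 40),
#'                    control = train_control(max_epochs = 5, patience = 5,
#'                                            seed = 7))
#' fit
#' }
#' @export
quality_fit <- function(data, family = c("cnn_lstm", "cnn_mlp", "cnn_kan"),
                        model = NULL, preprocess = preprocess_config(),
                        control = train_control(), seed = control$seed,
                        verbose = FALSE) {
  family <- match.arg(family)
  if (!inherits(data, "ppg_dataset")) {
    stop("'data' must be a ppg_dataset", call. = FALSE)
  }
  cl <- match.call()
  if (!is.null(preprocess)) data <- preprocess_dataset(data, preprocess)
  seg_len <- length(data$signals[[1]]$samples)
  if (is.null(model)) {
    model <- model_config(family, input_length = seg_len)
  } else if (model$input_length != seg_len) {
    stop(sprintf("model expects input_length %d but segments have %d samples",
                 model$input_length, seg_len), call. = FALSE)
  }
  if (model$family != family) {
    stop("'model$family' disagrees with 'family'", call. = FALSE)
  }
  control$seed <- seed
  splits <- stratified_split(data, control$split_fractions, seed)
  net <- build_model(model, seed = seed)
  fit <- train_network(net, splits$train, splits$val, control,
                       verbose = verbose)
  test_metrics <- evaluate_model(fit$net, splits$test,
                                 threshold = control$threshold)
  structure(
    list(net = fit$net, model = model, control = control,
         preprocess = preprocess, history = fit$history,
         best_epoch = fit$best_epoch, stopped_epoch = fit$stopped_epoch,
         splits = lapply(splits, attr, "indices"),
         train_data = splits$train, test_metrics = test_metrics,
         seed = seed, call = cl),
    class = "quality_fit"
  )
}

#' @export
print.quality_fit <- function(x, ...) {
  cat(sprintf("PPG quality classifier (%s)\n", x$model$family))
  cat(sprintf("  trainable parameters: %s\n",
              format(count_trainable_parameters(x$net), big.mark = ",")))
  cat(sprintf("  trained %d epoch(s), best validation loss %.4f at epoch %d\n",
              x$stopped_epoch, min(x$history$val_loss), x$best_epoch))
  cat(sprintf("  test: accuracy %.3f, AUC %.3f\n",
              x$test_metrics$accuracy, x$test_metrics$auc))
  invisible(x)
}

#' @export
summary.quality_fit <- function(object, ...) {
  m <- object$test_metrics
  structure(
    list(family = object$model$family,
         parameters = count_trainable_parameters(object$net),
         epochs = object$stopped_epoch, best_epoch = object$best_epoch,
         history = object$history,
         metrics = data.frame(
           metric = c("accuracy", "precision", "recall", "f1", "auc"),
           value = c(m$accuracy, m$precision, m$recall, m$f1, m$auc))),
    class = "summary.quality_fit"
  )
}

#' @export
print.summary.quality_fit <- function(x, ...) {
  cat(sprintf("Family: %s (%s trainable parameters)\n", x$family,
              format(x$parameters, big.mark = ",")))
  cat(sprintf("Epochs run: %d (best epoch %d)\n", x$epochs, x$best_epoch))
  cat("Test-set metrics:\n")
  print(x$metrics, row.names = FALSE)
  invisible(x)
}

#' Predict quality from a fitted classifier
#'
#' @param object A [quality_fit()] object.
#' @param newdata A `ppg_dataset` of raw segments (preprocessed with the
#'   fit's configuration) or a numeric matrix of already-preprocessed
#'   segments, one per row.
#' @param type `"response"` for good-quality probabilities, `"class"` for
#'   thresholded 0/1 labels.
#' @param ... Unused.
#' @return Numeric (or integer) vector, one value per segment.
#' @export
predict.quality_fit <- function(object, newdata,
                                type = c("response", "class"), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "ppg_dataset")) {
    if (!is.null(object$preprocess)) {
      newdata <- preprocess_dataset(newdata, object$preprocess)
    }
    newdata <- dataset_matrix(newdata)$x
  }
  p <- net_forward(object$net, newdata)$prob
  if (type == "class") as.integer(p >= object$control$threshold) else p
}

#' @export
coef.quality_fit <- function(object, ...) {
  unlist(lapply(seq_along(object$net$layers), function(i) {
    l <- object$net$layers[[i]]
    leaves <- param_leaves(l$params)
    if (!length(leaves)) return(NULL)
    names(leaves) <- sprintf("layer%d.%s.%s", i, l$type, names(leaves))
    unlist(leaves)
  }))
}

#' @export
residuals.quality_fit <- function(object, ...) {
  m <- dataset_matrix(object$train_data)
  m$y - net_forward(object$net, m$x)$prob
}

#' @export
simulate.quality_fit <- function(object, nsim = 1, seed = NULL, ...) {
  m <- dataset_matrix(object$train_data)
  p <- net_forward(object$net, m$x)$prob
  sims <- with_seed(seed %||% object$seed, {
    replicate(nsim, stats::rbinom(length(p), 1L, p))
  })
  as.data.frame(sims, col.names = paste0("sim_", seq_len(nsim)))
}

#' @export
plot.quality_fit <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1, col = c("grey40", "firebrick"),
                    xlab = "epoch", ylab = "binary cross-entropy", ...)
  graphics::abline(v = x$best_epoch, lty = 3)
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("grey40", "firebrick"), bty = "n")
  invisible(x)
}
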