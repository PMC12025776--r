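#' Write a PPG dataset to a delimited text file
#'
#' One row per signal: `id,label,fs,s0,s1,...` with a header row. An
#' optional sidecar file (`<path>.meta`, plain `key=value` lines) records
#' the seed and configuration that produced the dataset so every artifact
#' is traceable.
#'
#' @param dataset A `ppg_dataset`.
#' @param path Output file path.
#' @param meta Named list written to the sidecar; `NULL` skips the sidecar.
#' @return `path`, invisibly.
#' @export
write_ppg_dataset <- function(dataset, path, meta = NULL) {
  if (!inherits(dataset, "ppg_dataset")) {
    stop("'dataset' must be a ppg_dataset", call. = FALSE)
  }
  m <- dataset_matrix(dataset)
  dt <- data.table::data.table(
    id = vapply(dataset$signals, `[[`, "", "id"),
    label = vapply(dataset$signals, `[[`, integer(1), "label"),
    fs = vapply(dataset$signals, `[[`, numeric(1), "fs"))
  # format with 17 significant digits so finite doubles round-trip exactly
  samp <- data.table::as.data.table(matrix(sprintf("%.17g", m$x),
                                           nrow(m$x)))
  data.table::setnames(samp, sprintf("s%d", seq_len(ncol(m$x)) - 1L))
  data.table::fwrite(cbind(dt, samp), path)
  if (!is.null(meta)) {
    writeLines(sprintf("%s=%s", names(meta),
                       vapply(meta, function(v) paste(format(v), collapse = ","),
                              "")),
               paste0(path, ".meta"))
  }
  invisible(path)
}

#' Read a PPG dataset from a delimited text file
#'
#' Validates the on-disk format written by [write_ppg_dataset()]: every row
#' must carry a label in \{1, 2, 3\} and only finite sample values; a
#' malformed row is reported by its index. Round-trips with
#' [write_ppg_dataset()] bit-exactly for finite values.
#'
#' @param path Input file path.
#' @return A `ppg_dataset`.
#' @export
read_ppg_dataset <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (file.size(path) == 0L) {
    stop("empty dataset file: ", path, call. = FALSE)
  }
  dt <- data.table::fread(path, header = TRUE)
  if (nrow(dt) == 0L) stop("dataset file has no signal rows", call. = FALSE)
  need <- c("id", "label", "fs")
  if (!all(need %in% names(dt))) {
    stop("dataset file must have columns id, label, fs, s0, ...",
         call. = FALSE)
  }
  sample_cols <- setdiff(names(dt), need)
  signals <- vector("list", nrow(dt))
  for (i in seq_len(nrow(dt))) {
    lab <- dt$label[i]
    if (!lab %in% c(1, 2, 3)) {
      stop(sprintf("row %d: invalid label %s (expected 1, 2 or 3)", i,
                   format(lab)), call. = FALSE)
    }
    x <- as.numeric(dt[i, sample_cols, with = FALSE])
    if (!all(is.finite(x))) {
      stop(sprintf("row %d: non-finite sample values", i), call. = FALSE)
    }
    signals[[i]] <- ppg_signal(x, fs = dt$fs[i], label = as.integer(lab),
                               id = as.character(dt$id[i]))
  }
  new_ppg_dataset(signals)
}

#' Plot a signal (optionally before/after preprocessing) to an image file
#'
#' Renders amplitude against time in seconds. With `before` given, draws
#' two panels sharing the time axis, mirroring the usual before/after
#' preprocessing comparison.
#'
#' @param signal A [ppg_signal] (the "after" panel when `before` is given).
#' @param before Optional [ppg_signal] shown in the upper panel.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
plot_signal <- function(signal, before = NULL, path) {
  assert_signal(signal)
  grDevices::png(path, width = 900, height = if (is.null(before)) 350 else 600)
  on.exit(grDevices::dev.off())
  if (is.null(before)) {
    plot(signal, main = signal$id)
  } else {
    op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
    on.exit(graphics::par(op), add = TRUE, after = FALSE)
    plot(before, main = "before preprocessing")
    plot(signal, main = "after preprocessing")
  }
  invisible(path)
}

#' Run a complete experiment from a single configuration
#'
#' Generates (or loads) a labelled dataset, preprocesses it, fits the
#' requested classifier via [quality_fit()], and writes a metrics report,
#' the fitted model, and a log, all stamped with the seed and
#' configuration.
#'
#' @param n_good,n_fair,n_poor Synthetic class counts (ignored when
#'   `data_path` is given).
#' @param data_path Optional path of an existing dataset file.
#' @param family Classifier family.
#' @param fs Sampling rate of generated data.
#' @param model,preprocess,control Optional configuration objects; family
#'   defaults are used when `NULL`.
#' @param seed Global seed for every stage.
#' @param out_dir Output directory for report/checkpoint/log; `NULL`
#'   writes nothing.
#' @return A list with the `quality_fit` object, the metrics report data
#'   frame and the output paths.
#' @export
run_experiment <- function(n_good = 100, n_fair = 50, n_poor = 50,
                           data_path = NULL,
                           family = c("cnn_lstm", "cnn_mlp", "cnn_kan"),
                           fs = 512, model = NULL,
                           preprocess = preprocess_config(),
                           control = train_control(), seed = 1,
                           out_dir = NULL) {
  family <- match.arg(family)
  data <- if (is.null(data_path)) {
    generate_dataset(n_good, n_fair, n_poor, fs = fs, seed = seed)
  } else {
    read_ppg_dataset(data_path)
  }
  fit <- quality_fit(data, family = family, model = model,
                     preprocess = preprocess, control = control, seed = seed)
  m <- fit$test_metrics
  report <- data.frame(
    metric = c("accuracy", "precision", "recall", "f1", "auc",
               "trainable_parameters", "epochs", "best_epoch", "seed"),
    value = c(m$accuracy, m$precision, m$recall, m$f1, m$auc,
              count_trainable_parameters(fit$net), fit$stopped_epoch,
              fit$best_epoch, seed))
  paths <- list()
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths$report <- file.path(out_dir, sprintf("report_%s.csv", family))
    utils::write.csv(report, paths$report, row.names = FALSE)
    paths$roc <- file.path(out_dir, sprintf("roc_%s.csv", family))
    utils::write.csv(m$roc_points, paths$roc, row.names = FALSE)
    paths$model <- file.path(out_dir, sprintf("model_%s.rds", family))
    saveRDS(fit, paths$model)
  }
  list(fit = fit, report = report, paths = paths)
}
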