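#' Construct a PPG signal object
#'
#' A `ppg_signal` bundles one segment of photoplethysmogram amplitude samples
#' with its sampling rate and, optionally, a manual quality label
#' (1 = good, 2 = fair, 3 = poor).
#'
#' @param samples Numeric vector of amplitude values (arbitrary units).
#' @param fs Sampling rate in Hz; must be positive.
#' @param label Optional quality class, one of 1, 2, 3, or `NA`.
#' @param id Opaque identifier string.
#' @return An object of class `ppg_signal`: a list with elements `samples`,
#'   `fs`, `label`, `id`.
#' @examples
#' s <- ppg_signal(sin(seq(0, 2 * pi, length.out = 100)), fs = 20)
#' print(s)
#' @export
ppg_signal <- function(samples, fs, label = NA_integer_, id = "") {
  samples <- as.numeric(samples)
  if (length(samples) == 0L) {
    stop("a ppg_signal needs at least one sample", call. = FALSE)
  }
  if (!all(is.finite(samples))) {
    stop("all samples must be finite", call. = FALSE)
  }
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("'fs' must be a positive number (Hz)", call. = FALSE)
  }
  if (!is.na(label) && !label %in% c(1L, 2L, 3L)) {
    stop("'label' must be 1 (good), 2 (fair), 3 (poor), or NA", call. = FALSE)
  }
  structure(
    list(samples = samples, fs = as.numeric(fs),
         label = as.integer(label), id = as.character(id)),
    class = "ppg_signal"
  )
}

#' @export
print.ppg_signal <- function(x, ...) {
  dur <- length(x$samples) / x$fs
  lab <- if (is.na(x$label)) "unlabelled" else
    c("good", "fair", "poor")[x$label]
  cat(sprintf("<ppg_signal%s: %d samples @ %g Hz (%.2f s), %s>\n",
              if (nzchar(x$id)) paste0(" ", x$id) else "",
              length(x$samples), x$fs, dur, lab))
  invisible(x)
}

#' @export
length.ppg_signal <- function(x) length(x$samples)

#' @export
plot.ppg_signal <- function(x, ...) {
  t <- (seq_along(x$samples) - 1) / x$fs
  graphics::plot(t, x$samples, type = "l", xlab = "time [s]",
                 ylab = "amplitude [a.u.]", ...)
  invisible(x)
}

# internal: sample n at time n/fs seconds, 0-based
signal_times <- function(sig) (seq_along(sig$samples) - 1) / sig$fs

assert_signal <- function(sig) {
  if (!inherits(sig, "ppg_signal")) {
    stop("expected a 'ppg_signal' object", call. = FALSE)
  }
  invisible(sig)
}
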