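#' Preprocessing configuration
#'
#' Parameters of the four-stage preprocessing chain applied by
#' [preprocess_pipeline()]: anti-aliased downsampling, centred moving-average
#' smoothing, Butterworth low-pass filtering, and per-signal min-max scaling.
#'
#' @param target_fs Sampling rate in Hz after downsampling. The downsampling
#'   factor is `source fs / target_fs` and must be a positive integer.
#' @param ma_window Moving-average window length in samples; odd, >= 1.
#' @param butter_order Butterworth filter order (default 4).
#' @param butter_cutoff Low-pass cutoff in Hz (default 50); must stay below
#'   the post-downsampling Nyquist frequency.
#' @param zero_phase Apply the filter forward and backward (no phase
#'   distortion, squared magnitude response). Default `TRUE`.
#' @param scale_lo,scale_hi Output amplitude bounds of the min-max stage.
#' @return An object of class `ppg_preprocess_config`.
#' @export
preprocess_config <- function(target_fs = 128, ma_window = 5,
                              butter_order = 4, butter_cutoff = 50,
                              zero_phase = TRUE,
                              scale_lo = 0, scale_hi = 1) {
  assert_number(target_fs, "target_fs", min = 0, strict_min = TRUE)
  assert_count(ma_window, "ma_window", min = 1)
  if (ma_window %% 2 == 0) {
    stop("'ma_window' must be odd", call. = FALSE)
  }
  assert_count(butter_order, "butter_order", min = 1)
  assert_number(butter_cutoff, "butter_cutoff", min = 0, strict_min = TRUE)
  assert_flag(zero_phase, "zero_phase")
  assert_number(scale_lo, "scale_lo")
  assert_number(scale_hi, "scale_hi")
  if (scale_lo >= scale_hi) {
    stop("'scale_lo' must be strictly below 'scale_hi'", call. = FALSE)
  }
  structure(
    list(target_fs = target_fs, ma_window = as.integer(ma_window),
         butter_order = as.integer(butter_order),
         butter_cutoff = butter_cutoff, zero_phase = zero_phase,
         scale_lo = scale_lo, scale_hi = scale_hi),
    class = "ppg_preprocess_config"
  )
}

#' Anti-aliased integer downsampling
#'
#' Low-pass filters the signal (8th-order Butterworth at 80% of the output
#' Nyquist frequency, applied forward-backward so peak and trough timing of
#' sub-Nyquist content is preserved) and then keeps every `factor`-th sample.
#'
#' @param signal A [ppg_signal].
#' @param factor Positive integer decimation factor.
#' @return A [ppg_signal] with `fs = signal$fs / factor` and
#'   `ceiling(length / factor)` samples.
#' @export
antialias_downsample <- function(signal, factor) {
  assert_signal(signal)
  factor <- assert_count(factor, "factor", min = 1)
  if (factor > length(signal$samples)) {
    stop("'factor' exceeds the signal length", call. = FALSE)
  }
  if (factor == 1L) return(signal)
  x <- signal$samples
  # anti-aliasing low-pass at 0.8 x the decimated Nyquist, zero-phase
  wc <- 0.8 / factor
  bf <- signal::butter(8, wc, type = "low")
  xf <- signal::filtfilt(bf, x)
  y <- xf[seq(1, length(xf), by = factor)]
  ppg_signal(y, fs = signal$fs / factor, label = signal$label, id = signal$id)
}

#' Centred moving-average smoothing
#'
#' Replaces each sample with the mean of a centred window. At the edges the
#' window truncates to the available samples, so the output has the same
#' length as the input.
#'
#' @param signal A [ppg_signal].
#' @param window Odd window length in samples, between 1 and the signal
#'   length.
#' @return A smoothed [ppg_signal] of identical length.
#' @examples
#' s <- ppg_signal(c(1, 2, 3, 4, 5), fs = 1)
#' moving_average(s, 3)$samples  # 1.5 2 3 4 4.5
#' @export
moving_average <- function(signal, window) {
  assert_signal(signal)
  window <- assert_count(window, "window", min = 1)
  if (window %% 2 == 0) stop("'window' must be odd", call. = FALSE)
  n <- length(signal$samples)
  if (window > n) stop("'window' exceeds the signal length", call. = FALSE)
  if (window == 1L) return(signal)
  h <- (window - 1L) %/% 2L
  # cumulative-sum rolling mean with edge truncation
  cs <- c(0, cumsum(signal$samples))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  y <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  ppg_signal(y, fs = signal$fs, label = signal$label, id = signal$id)
}

#' Butterworth low-pass filtering
#'
#' Filters the signal with a digital Butterworth low-pass designed via the
#' bilinear transform, so the single-pass gain at the cutoff frequency is
#' exactly 1/sqrt(2) (1/2 when applied forward-backward). The passband
#' magnitude response is maximally flat.
#'
#' @param signal A [ppg_signal].
#' @param cfg A [preprocess_config()]; uses `butter_order`, `butter_cutoff`
#'   and `zero_phase`.
#' @return A filtered [ppg_signal] of identical length and rate.
#' @export
butterworth_lowpass <- function(signal, cfg = preprocess_config()) {
  assert_signal(signal)
  nyq <- signal$fs / 2
  if (cfg$butter_cutoff >= nyq) {
    stop(sprintf("cutoff (%g Hz) must be below the Nyquist frequency (%g Hz)",
                 cfg$butter_cutoff, nyq), call. = FALSE)
  }
  bf <- signal::butter(cfg$butter_order, cfg$butter_cutoff / nyq,
                       type = "low")
  y <- if (cfg$zero_phase) {
    signal::filtfilt(bf, signal$samples)
  } else {
    as.numeric(signal::filter(bf, signal$samples))
  }
  ppg_signal(y, fs = signal$fs, label = signal$label, id = signal$id)
}

#' Per-signal min-max scaling
#'
#' Affinely maps the signal amplitude onto `[lo, hi]`. A constant signal has
#' no dynamic range; it is mapped to `lo` with a warning rather than
#' dividing by zero.
#'
#' @param signal A [ppg_signal].
#' @param lo,hi Output bounds, `lo < hi`.
#' @return A rescaled [ppg_signal].
#' @export
minmax_scale <- function(signal, lo = 0, hi = 1) {
  assert_signal(signal)
  if (lo >= hi) stop("'lo' must be strictly below 'hi'", call. = FALSE)
  x <- signal$samples
  rng <- range(x)
  if (rng[1] == rng[2]) {
    warning("constant signal: min-max scaling maps it to the lower bound")
    y <- rep(lo, length(x))
  } else {
    y <- lo + (hi - lo) * (x - rng[1]) / (rng[2] - rng[1])
  }
  ppg_signal(y, fs = signal$fs, label = signal$label, id = signal$id)
}

#' Run the four-stage preprocessing chain
#'
#' Applies, in order: anti-aliased downsampling to `cfg$target_fs`,
#' moving-average smoothing, Butterworth low-pass filtering, and per-signal
#' min-max scaling to `[cfg$scale_lo, cfg$scale_hi]`.
#'
#' @param signal A [ppg_signal].
#' @param cfg A [preprocess_config()].
#' @return The preprocessed [ppg_signal].
#' @export
preprocess_pipeline <- function(signal, cfg = preprocess_config()) {
  assert_signal(signal)
  if (signal$fs < cfg$target_fs) {
    stop("'target_fs' exceeds the source sampling rate", call. = FALSE)
  }
  factor <- signal$fs / cfg$target_fs
  if (abs(factor - round(factor)) > 1e-9) {
    stop("source fs must be an integer multiple of 'target_fs'",
         call. = FALSE)
  }
  s <- antialias_downsample(signal, round(factor))
  s <- moving_average(s, cfg$ma_window)
  s <- butterworth_lowpass(s, cfg)
  minmax_scale(s, cfg$scale_lo, cfg$scale_hi)
}

#' Preprocess every signal in a dataset
#'
#' @param dataset A `ppg_dataset`.
#' @param cfg A [preprocess_config()].
#' @return A `ppg_dataset` of preprocessed signals.
#' @export
preprocess_dataset <- function(dataset, cfg = preprocess_config()) {
  if (!inherits(dataset, "ppg_dataset")) {
    stop("'dataset' must be a ppg_dataset", call. = FALSE)
  }
  dataset$signals <- lapply(dataset$signals, preprocess_pipeline, cfg = cfg)
  dataset
}
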