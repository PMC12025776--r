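#' Artifact configuration for synthetic PPG corruption
#'
#' Controls the four corruption modes applied by [corrupt_ppg()]: additive
#' white noise, sinusoidal baseline wander, Poisson-placed motion spikes, and
#' amplitude clipping. All amplitudes are relative to the peak-to-peak range
#' of the clean signal, which keeps the artifact strength meaningful after
#' arbitrary rescaling.
#'
#' @param noise_sd Standard deviation of additive Gaussian noise, as a
#'   fraction of the signal's peak-to-peak range.
#' @param wander_amp Amplitude of the baseline-wander sinusoid (fraction of
#'   peak-to-peak range).
#' @param wander_freq Baseline-wander frequency in Hz. Respiratory-range
#'   values (0.15-0.4 Hz) are typical.
#' @param spike_rate Expected number of motion spikes per second (Poisson).
#' @param spike_amp Spike magnitude (fraction of peak-to-peak range).
#' @param clip_fraction Fraction of the dynamic range retained before
#'   saturation clips; 1 disables clipping. Must lie in (0, 1].
#' @return An object of class `ppg_artifact_config`.
#' @seealso [corrupt_ppg()], [generate_dataset()]
#' @export
artifact_config <- function(noise_sd = 0, wander_amp = 0, wander_freq = 0.3,
                            spike_rate = 0, spike_amp = 0,
                            clip_fraction = 1) {
  assert_number(noise_sd, "noise_sd", min = 0)
  assert_number(wander_amp, "wander_amp", min = 0)
  assert_number(wander_freq, "wander_freq", min = 0)
  assert_number(spike_rate, "spike_rate", min = 0)
  assert_number(spike_amp, "spike_amp", min = 0)
  assert_number(clip_fraction, "clip_fraction", min = 0, max = 1,
                strict_min = TRUE)
  structure(
    list(noise_sd = noise_sd, wander_amp = wander_amp,
         wander_freq = wander_freq, spike_rate = spike_rate,
         spike_amp = spike_amp, clip_fraction = clip_fraction),
    class = "ppg_artifact_config"
  )
}

# Fixed per-class artifact strengths used by generate_dataset(). Class 1 is
# near-clean, class 2 adds moderate noise plus respiratory-band wander,
# class 3 adds heavy noise, wander, motion spikes and saturation.
class_artifact_config <- function(class) {
  switch(as.character(class),
    "1" = artifact_config(noise_sd = 0.02),
    "2" = artifact_config(noise_sd = 0.15, wander_amp = 0.25,
                          wander_freq = 0.3),
    "3" = artifact_config(noise_sd = 0.4, wander_amp = 0.5,
                          wander_freq = 0.25, spike_rate = 1.5,
                          spike_amp = 1.5, clip_fraction = 0.8),
    stop("unknown quality class: ", class, call. = FALSE)
  )
}

#' Generate a clean synthetic PPG segment
#'
#' Builds a quasi-periodic pulse waveform with one systolic peak and one
#' smaller dicrotic bump per cardiac period. Each beat is the sum of two
#' Gaussians (systolic amplitude 1.0 at 25% of the period, dicrotic amplitude
#' 0.3 at 55%), and each beat period is independently jittered by up to
#' +/- 3% so the waveform is quasi- rather than perfectly periodic.
#'
#' @param duration_s Segment duration in seconds (positive).
#' @param fs Sampling rate in Hz (positive).
#' @param heart_rate_bpm Heart rate in beats per minute, in \[30, 220\].
#' @param seed Integer seed; output is a pure function of the arguments.
#' @return A [ppg_signal] of `round(duration_s * fs)` samples.
#' @examples
#' s <- generate_clean_ppg(5, 512, 72, seed = 1)
#' length(s$samples)  # 2560
#' @export
generate_clean_ppg <- function(duration_s, fs, heart_rate_bpm, seed) {
  assert_number(duration_s, "duration_s", min = 0, strict_min = TRUE)
  assert_number(fs, "fs", min = 0, strict_min = TRUE)
  assert_number(heart_rate_bpm, "heart_rate_bpm", min = 30, max = 220)
  n <- round(duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  period <- 60 / heart_rate_bpm

  with_seed(seed, {
    # beat onsets with +/-3% uniform period jitter; overgenerate past the end
    n_beats <- ceiling(duration_s / period) + 3L
    periods <- period * stats::runif(n_beats, 0.97, 1.03)
    onsets <- c(-period, -period + cumsum(periods))
    x <- numeric(n)
    for (b in seq_along(onsets)) {
      p <- if (b < length(onsets)) onsets[b + 1] - onsets[b] else period
      mu_sys <- onsets[b] + 0.25 * p
      mu_dic <- onsets[b] + 0.55 * p
      sd_sys <- 0.06 * p
      sd_dic <- 0.09 * p
      x <- x + exp(-0.5 * ((t - mu_sys) / sd_sys)^2) +
        0.3 * exp(-0.5 * ((t - mu_dic) / sd_dic)^2)
    }
    ppg_signal(x, fs = fs, label = NA_integer_,
               id = sprintf("clean_hr%g_seed%d", heart_rate_bpm,
                            as.integer(seed)))
  })
}

#' Corrupt a PPG segment with configurable artifacts
#'
#' Applies, in order: additive white Gaussian noise, sinusoidal baseline
#' wander with a random phase, Poisson-placed biphasic motion spikes, and
#' symmetric amplitude clipping at `clip_fraction` of the (post-artifact)
#' dynamic range. All artifact amplitudes scale with the input's peak-to-peak
#' range. The output is a pure function of `(signal, cfg, seed)`.
#'
#' @param signal A [ppg_signal].
#' @param cfg An [artifact_config()].
#' @param seed Integer seed.
#' @return A [ppg_signal] with the same length, `fs` and label.
#' @export
corrupt_ppg <- function(signal, cfg, seed) {
  assert_signal(signal)
  if (!inherits(cfg, "ppg_artifact_config")) {
    stop("'cfg' must come from artifact_config()", call. = FALSE)
  }
  x <- signal$samples
  n <- length(x)
  rng <- diff(range(x))
  if (rng == 0) rng <- 1  # degenerate constant input: use unit scale
  t <- signal_times(signal)

  y <- with_seed(seed, {
    y <- x
    if (cfg$noise_sd > 0) {
      y <- y + stats::rnorm(n, sd = cfg$noise_sd * rng)
    }
    if (cfg$wander_amp > 0) {
      phase <- stats::runif(1, 0, 2 * pi)
      y <- y + cfg$wander_amp * rng * sin(2 * pi * cfg$wander_freq * t + phase)
    }
    n_spikes <- 0L
    if (cfg$spike_rate > 0 && cfg$spike_amp > 0) {
      dur <- n / signal$fs
      k <- stats::rpois(1, cfg$spike_rate * dur)
      n_spikes <- k
      if (k > 0) {
        centers <- stats::runif(k, 0, dur)
        signs <- sample(c(-1, 1), k, replace = TRUE)
        tau <- 0.015  # spike decay time constant [s]
        for (j in seq_len(k)) {
          y <- y + signs[j] * cfg$spike_amp * rng *
            exp(-abs(t - centers[j]) / tau)
        }
      }
    }
    attr(y, "n_spikes") <- n_spikes
    y
  })

  n_spikes <- attr(y, "n_spikes")
  if (cfg$clip_fraction < 1) {
    mid <- mean(range(y))
    half <- cfg$clip_fraction * diff(range(y)) / 2
    y <- pmin(pmax(y, mid - half), mid + half)
  }
  out <- ppg_signal(as.numeric(y), fs = signal$fs, label = signal$label,
                    id = signal$id)
  attr(out, "n_spikes") <- n_spikes  # realised Poisson spike count
  out
}

#' Generate a labelled synthetic PPG dataset
#'
#' Produces `n_good` class-1 (near-clean), `n_fair` class-2 (moderate
#' corruption) and `n_poor` class-3 (severe corruption) five-second segments,
#' with heart rates drawn uniformly from 55-95 bpm. Three-class labels are
#' merged to the binary target with class 1 mapped to 1 (good) and classes
#' 2 and 3 to 0 (fair/poor). A single global seed expands to per-signal
#' seeds through a counter, so generation is reproducible.
#'
#' @param n_good,n_fair,n_poor Segment counts per quality class (>= 0, not
#'   all zero).
#' @param fs Sampling rate in Hz.
#' @param seed Global integer seed.
#' @param duration_s Segment duration in seconds (default 5).
#' @return An object of class `ppg_dataset`: a list with `signals` (list of
#'   [ppg_signal]) and `binary_labels` (integer vector, 1 = good).
#' @examples
#' d <- generate_dataset(4, 2, 2, fs = 128, seed = 1)
#' sum(d$binary_labels)  # 4
#' @export
generate_dataset <- function(n_good, n_fair, n_poor, fs = 512, seed = 1,
                             duration_s = 5) {
  n_good <- assert_count(n_good, "n_good")
  n_fair <- assert_count(n_fair, "n_fair")
  n_poor <- assert_count(n_poor, "n_poor")
  if (n_good + n_fair + n_poor == 0L) {
    stop("at least one class count must be positive", call. = FALSE)
  }
  classes <- rep(c(1L, 2L, 3L), times = c(n_good, n_fair, n_poor))
  signals <- vector("list", length(classes))
  for (i in seq_along(classes)) {
    s_clean <- child_seed(seed, 2L * i)
    s_corr <- child_seed(seed, 2L * i + 1L)
    hr <- with_seed(s_clean, stats::runif(1, 55, 95))
    clean <- generate_clean_ppg(duration_s, fs, hr, seed = s_clean)
    sig <- corrupt_ppg(clean, class_artifact_config(classes[i]),
                       seed = s_corr)
    sig$label <- classes[i]
    sig$id <- sprintf("sig%04d_c%d", i, classes[i])
    signals[[i]] <- sig
  }
  new_ppg_dataset(signals)
}

#' @export
print.ppg_dataset <- function(x, ...) {
  labs <- vapply(x$signals, function(s) s$label, integer(1))
  cat(sprintf(
    "<ppg_dataset: %d signals (%d good / %d fair / %d poor), %d binary-good>\n",
    length(x$signals), sum(labs == 1L, na.rm = TRUE),
    sum(labs == 2L, na.rm = TRUE), sum(labs == 3L, na.rm = TRUE),
    sum(x$binary_labels)))
  invisible(x)
}

# Dataset constructor: derives the binary labels from the 3-class labels by
# the fixed merge rule (1 -> 1 good; 2,3 -> 0 fair/poor).
new_ppg_dataset <- function(signals) {
  labs <- vapply(signals, function(s) s$label, integer(1))
  if (anyNA(labs)) {
    stop("all signals in a dataset must carry a quality label", call. = FALSE)
  }
  structure(
    list(signals = signals, binary_labels = as.integer(labs == 1L)),
    class = "ppg_dataset"
  )
}

#' Merge a 3-class quality label to the binary target
#'
#' Class 1 (good) maps to 1; classes 2 and 3 (fair/poor) map to 0.
#'
#' @param label Integer vector of quality classes in \{1, 2, 3\}.
#' @return Integer vector of binary labels.
#' @export
merge_quality_label <- function(label) {
  if (!all(label %in% c(1L, 2L, 3L))) {
    stop("labels must be 1, 2 or 3", call. = FALSE)
  }
  as.integer(label == 1L)
}
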