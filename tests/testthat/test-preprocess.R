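test_that("downsampling keeps sub-Nyquist content and fixes length/rate", {
  s <- generate_clean_ppg(5, 512, 72, seed = 1)
  expect_identical(antialias_downsample(s, 1), s)

  d <- antialias_downsample(s, 4)
  expect_length(d$samples, 640)
  expect_equal(d$fs, 128)

  # pure 2 Hz sinusoid against the analytically resampled oracle
  t <- seq(0, 5 - 1 / 512, by = 1 / 512)
  sine <- ppg_signal(sin(2 * pi * 2 * t), 512)
  ds <- antialias_downsample(sine, 4)
  oracle <- sin(2 * pi * 2 * (seq_along(ds$samples) - 1) / 128)
  expect_gte(cor(ds$samples, oracle), 0.999)

  expect_error(antialias_downsample(ppg_signal(1:3, 10), 5))
})

test_that("moving average follows the edge-truncation convention", {
  s <- ppg_signal(c(1, 2, 3, 4, 5), fs = 1)
  expect_equal(moving_average(s, 3)$samples, c(1.5, 2, 3, 4, 4.5))
  expect_identical(moving_average(s, 1), s)

  const <- ppg_signal(rep(2.5, 50), fs = 10)
  expect_equal(moving_average(const, 7)$samples, const$samples)

  expect_error(moving_average(s, 2))
  expect_error(moving_average(s, 7))

  # variance never increases for white noise, any window
  set.seed(1)
  x <- ppg_signal(rnorm(500), fs = 100)
  for (w in c(1, 3, 9, 21)) {
    expect_lte(var(moving_average(x, w)$samples), var(x$samples))
  }
})

test_that("Butterworth gain matches the analytic magnitude response", {
  fs <- 512
  t <- seq(0, 4, by = 1 / fs)
  dc <- ppg_signal(rep(1, length(t)), fs)
  cfg1 <- preprocess_config(butter_order = 4, butter_cutoff = 50,
                            zero_phase = FALSE)
  out <- butterworth_lowpass(dc, cfg1)$samples
  expect_lt(max(abs(out[1000:length(out)] - 1)), 1e-6)

  # steady-state amplitude at the cutoff: 1/sqrt(2) per pass, within 1%
  sine <- ppg_signal(sin(2 * pi * 50 * t), fs)
  y <- butterworth_lowpass(sine, cfg1)$samples
  amp <- max(abs(y[(length(y) / 2):length(y)]))
  expect_equal(amp, 1 / sqrt(2), tolerance = 0.01)

  # 2x cutoff, order 4: |H| = 1/sqrt(1 + (f/fc)^(2n)) within 5%
  fs2 <- 2048
  t2 <- seq(0, 4, by = 1 / fs2)
  sine2 <- ppg_signal(sin(2 * pi * 100 * t2), fs2)
  y2 <- butterworth_lowpass(sine2, cfg1)$samples
  amp2 <- max(abs(y2[(length(y2) / 2):length(y2)]))
  expect_equal(amp2, 1 / sqrt(1 + 2^8), tolerance = 0.05)

  expect_error(butterworth_lowpass(ppg_signal(rnorm(100), fs = 80), cfg1))
})

test_that("the filter is linear", {
  set.seed(2)
  s <- ppg_signal(rnorm(400), fs = 512)
  cfg <- preprocess_config()
  one <- butterworth_lowpass(s, cfg)$samples
  scaled <- butterworth_lowpass(ppg_signal(7.3 * s$samples, 512), cfg)$samples
  expect_equal(scaled, 7.3 * one, tolerance = 1e-9)
})

test_that("min-max scaling maps onto the requested range", {
  expect_equal(minmax_scale(ppg_signal(c(0, 5, 10), 1))$samples,
               c(0, 0.5, 1))
  already <- ppg_signal(c(0, 0.25, 1), 1)
  expect_equal(minmax_scale(already)$samples, already$samples)
  expect_warning(out <- minmax_scale(ppg_signal(c(3, 3, 3), 1)),
                 "constant")
  expect_equal(out$samples, c(0, 0, 0))
})

test_that("the four-stage pipeline composes in order with bounded output", {
  s <- generate_clean_ppg(5, 512, 72, seed = 4)
  corr <- corrupt_ppg(s, artifact_config(noise_sd = 0.2, wander_amp = 0.3),
                      seed = 4)
  out <- preprocess_pipeline(corr, preprocess_config())
  expect_length(out$samples, 640)  # only downsampling changes length
  expect_equal(out$fs, 128)
  expect_equal(min(out$samples), 0)
  expect_equal(max(out$samples), 1)

  # deterministic
  out2 <- preprocess_pipeline(corr, preprocess_config())
  expect_identical(out$samples, out2$samples)

  # near-identity configuration reduces to plain min-max scaling
  s128 <- generate_clean_ppg(5, 128, 72, seed = 2)
  ni <- preprocess_config(target_fs = 128, ma_window = 1,
                          butter_cutoff = 63.9)
  expect_equal(preprocess_pipeline(s128, ni)$samples,
               minmax_scale(s128)$samples, tolerance = 1e-3)

  # invalid configurations propagate errors
  expect_error(preprocess_pipeline(s128, preprocess_config(target_fs = 256)))
})
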