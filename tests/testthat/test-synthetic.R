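test_that("clean PPG generation has the right length, rate and determinism", {
  s <- generate_clean_ppg(5, 512, 72, seed = 1)
  expect_s3_class(s, "ppg_signal")
  expect_length(s$samples, 2560)
  expect_equal(s$fs, 512)
  expect_true(all(is.finite(s$samples)))

  s2 <- generate_clean_ppg(5, 512, 72, seed = 1)
  expect_identical(s$samples, s2$samples)
  s3 <- generate_clean_ppg(5, 512, 72, seed = 2)
  expect_false(identical(s$samples, s3$samples))

  expect_error(generate_clean_ppg(0, 512, 72, seed = 1))
  expect_error(generate_clean_ppg(5, -10, 72, seed = 1))
  expect_error(generate_clean_ppg(5, 512, 300, seed = 1))
})

test_that("dominant spectral peak sits at the cardiac fundamental", {
  # 72 bpm = 1.2 Hz; discrete Fourier magnitude as the oracle
  s <- generate_clean_ppg(10, 512, 72, seed = 5)
  x <- s$samples - mean(s$samples)
  mag <- Mod(stats::fft(x))[2:(length(x) / 2)]
  freqs <- (1:(length(x) / 2 - 1)) / 10
  expect_lt(abs(freqs[which.max(mag)] - 1.2), 0.2)
})

test_that("beat morphology shows a systolic peak and a dicrotic bump", {
  s <- generate_clean_ppg(5, 512, 60, seed = 3)
  # count local maxima well above the baseline: about one strong (systolic)
  # and one weaker (dicrotic) per 1 s beat
  x <- s$samples
  locmax <- which(diff(sign(diff(x))) == -2) + 1
  strong <- sum(x[locmax] > 0.8 * max(x))
  weak <- sum(x[locmax] > 0.2 * max(x) & x[locmax] < 0.6 * max(x))
  expect_gte(strong, 4)
  expect_gte(weak, 4)
})

test_that("the identity artifact configuration leaves the signal unchanged", {
  s <- generate_clean_ppg(2, 128, 70, seed = 7)
  out <- corrupt_ppg(s, artifact_config(), seed = 9)
  expect_equal(out$samples, s$samples)
})

test_that("stronger noise lowers the correlation with the clean signal", {
  s <- generate_clean_ppg(5, 128, 70, seed = 7)
  weak <- corrupt_ppg(s, artifact_config(noise_sd = 0.05), seed = 11)
  strong <- corrupt_ppg(s, artifact_config(noise_sd = 0.5), seed = 11)
  expect_lt(cor(strong$samples, s$samples), cor(weak$samples, s$samples))
})

test_that("spike placement follows the configured Poisson process", {
  s <- generate_clean_ppg(5, 128, 70, seed = 7)
  cfg <- artifact_config(spike_rate = 2, spike_amp = 1)
  counts <- vapply(1:200, function(sd) {
    attr(corrupt_ppg(s, cfg, seed = sd), "n_spikes")
  }, integer(1))
  # total of 200 Poisson(10) draws is Poisson(2000); 99% interval
  total <- sum(counts)
  expect_gte(total, qpois(0.005, 2000))
  expect_lte(total, qpois(0.995, 2000))
  expect_equal(mean(counts), 10, tolerance = 0.15)
})

test_that("corruption is deterministic per seed and preserves shape", {
  s <- generate_clean_ppg(2, 128, 80, seed = 1)
  cfg <- artifact_config(noise_sd = 0.2, wander_amp = 0.3, spike_rate = 1,
                         spike_amp = 1, clip_fraction = 0.9)
  a <- corrupt_ppg(s, cfg, seed = 5)
  b <- corrupt_ppg(s, cfg, seed = 5)
  expect_identical(a$samples, b$samples)
  expect_length(a$samples, length(s$samples))
  expect_equal(a$fs, s$fs)
})

test_that("dataset generation merges labels by the fixed rule", {
  d <- generate_dataset(10, 5, 5, fs = 128, seed = 3, duration_s = 2)
  expect_length(d$signals, 20)
  expect_equal(sum(d$binary_labels), 10)
  labs <- vapply(d$signals, function(s) s$label, integer(1))
  # every class-2 (and class-3) signal carries binary label 0
  expect_true(all(d$binary_labels[labs == 2L] == 0L))
  expect_true(all(d$binary_labels[labs == 3L] == 0L))
  expect_true(all(d$binary_labels[labs == 1L] == 1L))
  expect_identical(merge_quality_label(c(1L, 2L, 3L)), c(1L, 0L, 0L))
  expect_error(generate_dataset(0, 0, 0, fs = 128, seed = 1))
})

test_that("a fixed seed yields a byte-identical serialised dataset", {
  f1 <- tempfile(fileext = ".csv")
  f2 <- tempfile(fileext = ".csv")
  write_ppg_dataset(generate_dataset(3, 3, 3, fs = 64, seed = 9,
                                     duration_s = 1), f1)
  write_ppg_dataset(generate_dataset(3, 3, 3, fs = 64, seed = 9,
                                     duration_s = 1), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("severe corruption dwarfs the near-clean residuals", {
  # mean per-signal residual sd, class 3 vs class 1, on 100 seeded signals
  res_sd <- function(class, seeds) {
    vapply(seeds, function(sd) {
      clean <- generate_clean_ppg(2, 128, 70, seed = sd)
      cor <- corrupt_ppg(clean, ppgqc:::class_artifact_config(class),
                         seed = sd + 1000)
      sd(cor$samples - clean$samples)
    }, numeric(1))
  }
  r1 <- res_sd(1, 1:50)
  r3 <- res_sd(3, 51:100)
  expect_gte(mean(r3), 5 * mean(r1))
})
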