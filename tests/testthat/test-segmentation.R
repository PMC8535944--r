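# Wavelet thresholding -------------------------------------------------------

test_that("adaptive threshold follows the mean + f * sd rule", {
  expect_equal(adaptive_threshold(c(1, 1, 1, 1), f = 3), 1)     # zero variance
  expect_equal(adaptive_threshold(c(0, 2), f = 1), 2)           # mu 1, pop sd 1
  set.seed(2)
  cvec <- stats::rnorm(50)
  expect_equal(adaptive_threshold(cvec, f = 0), mean(abs(cvec)))
  expect_error(adaptive_threshold(numeric(0), 1), class = "heartkit_empty_input")
})

test_that("coefficient thresholding uses strict comparison on magnitudes", {
  expect_equal(threshold_coeffs(c(0.5, 3), 1, keep_mode = "below"), c(0.5, 0))
  expect_equal(threshold_coeffs(c(-5, 0.1), 1, keep_mode = "below"), c(0, 0.1))
  # boundary: all magnitudes equal the threshold -> all zero under strict <
  expect_equal(threshold_coeffs(c(2, -2, 2), 2, keep_mode = "below"), c(0, 0, 0))
  # keep-above retains the large coefficients instead
  expect_equal(threshold_coeffs(c(0.5, 3), 1, keep_mode = "above"), c(0, 3))
})

test_that("decompose-reconstruct without thresholding is the identity", {
  set.seed(9)
  for (n in c(1000, 4096, 2030)) {
    x <- stats::rnorm(n)
    dec <- wavelet_decompose(x, wavelet_config())
    expect_lt(sqrt(mean((wavelet_reconstruct(dec) - x)^2)), 1e-8)
  }
  z <- pcg_recording(numeric(2000) + 0, 2000)
  expect_true(all(wavelet_low_freq_extract(z)$samples == 0))
})

test_that("too-deep decomposition of a short signal raises a depth error", {
  expect_error(wavelet_decompose(stats::rnorm(64), wavelet_config(levels = 5)),
               class = "heartkit_depth_error")
})

test_that("low-frequency extraction lowers the spectral centroid of a noisy beat train", {
  out <- clean_recording(bpm = 75, duration = 6, snr_db = 5, seed = 12)
  rec <- normalize_amplitude(out$recording)
  low <- wavelet_low_freq_extract(rec)
  centroid <- function(x, fs) {
    sp <- abs(stats::fft(x))[1:(length(x) %/% 2)]
    fr <- (seq_along(sp) - 1) * fs / length(x)
    sum(fr * sp) / sum(sp)
  }
  expect_lt(centroid(low$samples, 2000), centroid(rec$samples, 2000))
})

# Shannon envelope ------------------------------------------------------------

test_that("Shannon energy handles degenerate frames by convention", {
  z <- pcg_recording(numeric(80) + 0, 2000)
  expect_equal(shannon_envelope(z, 40, 20)$values, c(0, 0, 0))
  pm <- pcg_recording(rep(c(1, -1), 40), 2000)
  expect_equal(shannon_envelope(pm, 40, 20)$values, c(0, 0, 0))
})

test_that("Shannon energy matches direct summation on a seeded frame", {
  set.seed(31)
  x <- stats::rnorm(40)
  env <- shannon_envelope(pcg_recording(x, 2000), 40, 20)
  manual <- -sum(x^2 * log(x^2)) / 40
  expect_equal(env$values[1], manual, tolerance = 1e-12)
})

test_that("incomplete tail frames are dropped per the framing formula", {
  x <- pcg_recording(stats::rnorm(105), 2000)
  expect_length(shannon_envelope(x, 40, 20)$values, floor((105 - 40) / 20) + 1)
  expect_error(shannon_envelope(pcg_recording(stats::rnorm(30), 2000), 40, 20),
               class = "heartkit_empty_envelope")
})

test_that("standardized envelopes have mean 0 and sd 1; affine invariance holds", {
  set.seed(17)
  for (i in 1:20) {
    rec <- pcg_recording(stats::rnorm(2000 + i * 10), 2000)
    env <- standardize_envelope(shannon_envelope(rec))
    expect_lt(abs(mean(env$values)), 1e-9)
    expect_lt(abs(stats::sd(env$values) - 1), 1e-9)
  }
  rec <- pcg_recording(stats::rnorm(4000), 2000)
  env <- shannon_envelope(rec)
  env_affine <- env
  env_affine$values <- 3.5 * env$values + 11
  expect_equal(standardize_envelope(env_affine)$values,
               standardize_envelope(env)$values, tolerance = 1e-9)

  const <- env
  const$values <- rep(2, length(env$values))
  expect_error(standardize_envelope(const), class = "heartkit_constant_envelope")
})

# Cycle estimation ------------------------------------------------------------

test_that("UACF recovers the period of an impulse train at unit hop", {
  v <- numeric(10000)
  v[seq(1, 10000, by = 2000)] <- 1
  env <- structure(list(values = v - mean(v), frame_len = 1, hop = 1,
                        sample_rate = 2000, times = (seq_along(v) - 1) / 2000,
                        standardized = TRUE),
                   class = "envelope_series")
  env$values <- env$values / stats::sd(env$values)
  cyc <- estimate_cycle_uacf(env)
  expect_lte(abs(cyc$period_samples - 2000), 1)
  expect_gt(cyc$confidence, 0)
  expect_lte(cyc$confidence, 1)
})

test_that("UACF recovers a 75 bpm synthetic heart rhythm within 5%", {
  out <- clean_recording(bpm = 75, duration = 10, snr_db = 25, seed = 4)
  rec <- normalize_amplitude(out$recording)
  sp <- segment_pipeline(rec)
  expect_lt(abs(sp$cycle$period_seconds - 0.8) / 0.8, 0.05)
})

test_that("a constant envelope has no periodicity", {
  env <- structure(list(values = numeric(500), frame_len = 1, hop = 1,
                        sample_rate = 100, times = (0:499) / 100,
                        standardized = TRUE),
                   class = "envelope_series")
  expect_error(estimate_cycle_uacf(env), class = "heartkit_no_periodicity")
})

# Segment cutting -------------------------------------------------------------

test_that("a clean 8-beat recording yields 8 S1-anchored segments", {
  out <- clean_recording(bpm = 60, duration = 8, snr_db = 30, seed = 7)
  rec <- normalize_amplitude(out$recording)
  sp <- segment_pipeline(rec)
  expect_length(sp$segments, 8)
  starts_s <- vapply(sp$segments, `[[`, numeric(1), "start") / 2000
  for (s in starts_s) {
    expect_lt(min(abs(s - out$truth$s1_times)), 0.025)
  }
})

test_that("segments are disjoint, ordered and within the recording", {
  out <- clean_recording(bpm = 90, duration = 10, snr_db = 15, seed = 22,
                         class_label = "murmur")
  rec <- normalize_amplitude(out$recording)
  sp <- segment_pipeline(rec)
  segs <- sp$segments
  expect_gt(length(segs), 0)
  starts <- vapply(segs, `[[`, numeric(1), "start")
  ends <- vapply(segs, `[[`, numeric(1), "end")
  expect_true(all(starts < ends))
  expect_true(all(ends <= length(rec$samples)))
  expect_true(all(starts >= 0))
  if (length(segs) > 1) {
    expect_true(all(diff(starts) > 0))
    expect_true(all(ends[-length(ends)] <= starts[-1]))
  }
  expect_equal(vapply(segs, function(s) length(s$samples), numeric(1)),
               ends - starts)
})

test_that("a recording shorter than one period yields no segments, with a warning", {
  out <- clean_recording(bpm = 40, duration = 8, snr_db = 30, seed = 3)
  rec <- normalize_amplitude(out$recording)
  low <- wavelet_low_freq_extract(rec)
  env <- standardize_envelope(shannon_envelope(low))
  cyc <- estimate_cycle_uacf(env)
  short <- pcg_recording(rec$samples[1:1000], 2000, id = "short")
  env_short <- standardize_envelope(shannon_envelope(
    wavelet_low_freq_extract(short)))
  fake_cyc <- cyc
  fake_cyc$period_samples <- 4000L  # 2 s period > 0.5 s recording
  expect_warning(segs <- segment_recording(short, env_short, fake_cyc),
                 class = "heartkit_no_cycles")
  expect_length(segs, 0)
})
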