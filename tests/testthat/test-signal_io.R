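test_that("WAV round trip preserves a seeded signal within quantization", {
  set.seed(11)
  x <- stats::runif(4000, -0.9, 0.9)
  rec <- pcg_recording(x, 2000, id = "rt")
  p16 <- withr::local_tempfile(fileext = ".wav")
  write_wav(rec, p16, bits = 16)
  back <- read_wav(p16)
  expect_equal(back$sample_rate, 2000)
  expect_equal(length(back$samples), 4000)
  expect_lt(max(abs(back$samples - x)), 2 / 2^15)

  p32 <- withr::local_tempfile(fileext = ".wav")
  write_wav(rec, p32, bits = 32)
  expect_lt(max(abs(read_wav(p32)$samples - x)), 1e-6)
})

test_that("a file of zeros decodes to zeros and stereo channels average to mono", {
  pz <- withr::local_tempfile(fileext = ".wav")
  write_wav(pcg_recording(numeric(2000) + 0, 2000), pz)
  z <- read_wav(pz)
  expect_equal(length(z$samples), 2000)
  expect_true(all(z$samples == 0))

  set.seed(3)
  x <- stats::runif(500, -0.5, 0.5)
  ps <- withr::local_tempfile(fileext = ".wav")
  write_wav(rbind(x, -x), ps, sample_rate = 1000, bits = 32)
  st <- read_wav(ps)
  expect_equal(length(st$samples), 500)
  expect_lt(max(abs(st$samples)), 1e-7)
})

test_that("unreadable input raises a decode error", {
  p <- withr::local_tempfile(fileext = ".wav")
  writeLines("not a wav", p)
  expect_error(read_wav(p), class = "heartkit_decode_error")
  expect_error(read_wav(file.path(tempdir(), "does_not_exist.wav")),
               class = "heartkit_decode_error")
})

test_that("resampling preserves duration and spectral content", {
  t <- seq(0, 1, length.out = 44101)[1:44100]
  rec <- pcg_recording(sin(2 * pi * 100 * t), 44100, id = "tone")
  down <- resample_recording(rec, 2000)
  expect_equal(length(down$samples), 2000)
  expect_equal(down$sample_rate, 2000)
  spec <- abs(stats::fft(down$samples))[2:1000]
  expect_equal(which.max(spec) + 1, 101)  # bin 101 = 100 Hz at 1 Hz resolution

  expect_identical(resample_recording(down, 2000), down)
  expect_warning(resample_recording(down, 4000), class = "heartkit_upsample")

  # band-limited tone survives a down-up round trip within one FFT bin
  up <- suppressWarnings(resample_recording(down, 44100))
  spec_up <- abs(stats::fft(up$samples[1:44100]))[2:2000]
  expect_lt(abs((which.max(spec_up) + 1) - 101), 2)
})

test_that("amplitude normalization follows the peak rule and is idempotent", {
  rec <- pcg_recording(c(2, -4, 1), 100)
  nm <- normalize_amplitude(rec)
  expect_equal(nm$samples, c(0.5, -1.0, 0.25))

  already <- pcg_recording(c(0.3, -1, 0.2), 100)
  expect_equal(normalize_amplitude(already)$samples, already$samples)
  expect_equal(normalize_amplitude(nm)$samples, nm$samples)

  expect_error(normalize_amplitude(pcg_recording(c(0, 0, 0), 100)),
               class = "heartkit_silent_signal")
})

test_that("manifest merge reproduces the challenge-corpus class totals", {
  merged <- merge_manifest(pascal_count_manifest())
  totals <- stats::setNames(merged$count, merged$label)
  expect_equal(totals[["normal"]], 231)        # 31 + 200, noisy_normal excluded
  expect_equal(totals[["murmur"]], 129)        # 34 + 66 + 29
  expect_equal(totals[["extrasystole"]], 65)   # 19 + 46
})

test_that("merged totals equal brute-force sums over contributing splits", {
  contributing <- list(normal = c("A", "B"),
                       murmur = c("A", "B", "noisy_murmur"),
                       extrasystole = c("A", "B"))
  set.seed(21)
  for (rep in 1:20) {
    m <- data.frame(
      split = sample(c("A", "B", "noisy_murmur", "noisy_normal"), 12, TRUE),
      label = sample(c("normal", "murmur", "extrasystole"), 12, TRUE),
      count = sample(0:50, 12, TRUE),
      stringsAsFactors = FALSE
    )
    merged <- merge_manifest(m)
    for (lab in merged$label) {
      manual <- sum(m$count[m$label == lab & m$split %in% contributing[[lab]]])
      expect_equal(merged$count[merged$label == lab], manual)
    }
  }
})

test_that("unknown split labels are rejected", {
  bad <- data.frame(split = "C", label = "normal", count = 5)
  expect_error(merge_manifest(bad), class = "heartkit_manifest_error")
})

test_that("segment accounting appends selected + ignored totals", {
  acc <- segment_accounting(data.frame(
    label = c("normal", "murmur", "extrasystole"),
    selected = c(323, 317, 62),
    ignored = c(33, 14, 44)
  ))
  expect_equal(acc$total, c(356, 331, 106))
})
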