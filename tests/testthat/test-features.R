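test_that("frame counts follow floor((L - window)/hop) + 1", {
  cfg <- mfcc_config()
  expect_equal(nrow(frame_signal(numeric(5120), cfg)), 9)
  expect_equal(nrow(frame_signal(numeric(1024), cfg)), 1)
  # property sweep
  set.seed(6)
  for (i in 1:25) {
    wl <- sample(8:64, 1)
    hp <- sample(1:wl, 1)
    L <- sample(wl:500, 1)
    cfg_i <- mfcc_config(window_len = wl, hop = hp, n_fft = 64,
                         n_mels = 8, n_coeffs = 4)
    expect_equal(nrow(frame_signal(numeric(L), cfg_i)),
                 floor((L - wl) / hp) + 1)
  }
  # shorter-than-window input zero-pads to one frame
  expect_equal(nrow(frame_signal(numeric(100), cfg)), 1)
})

test_that("framing applies the Hamming window", {
  cfg <- mfcc_config(window_len = 64, hop = 32, n_fft = 64, n_mels = 8,
                     n_coeffs = 4)
  fr <- frame_signal(rep(2, 64), cfg)
  w <- 0.54 - 0.46 * cos(2 * pi * (0:63) / 63)
  expect_equal(as.numeric(fr[1, ]), 2 * w, tolerance = 1e-12)
})

test_that("an all-zero segment yields identical floor-valued frames", {
  cfg <- mfcc_config(window_len = 256, hop = 128, n_fft = 256, n_mels = 12,
                     n_coeffs = 6)
  m <- mfcc(numeric(1024), cfg, sample_rate = 2000)
  expect_equal(nrow(m$coeffs), 7)
  for (r in 2:nrow(m$coeffs)) {
    expect_equal(m$coeffs[r, ], m$coeffs[1, ], tolerance = 1e-12)
  }
})

test_that("a tone at a mel filter center maximizes that filter's energy", {
  fs <- 2000; n_fft <- 512; n_mels <- 12
  fb <- mel_filterbank(n_mels, n_fft, fs)
  freqs <- (0:(n_fft / 2)) * fs / n_fft
  m_target <- 6
  center_bin <- which.max(fb[m_target, ])
  tone <- sin(2 * pi * freqs[center_bin] * (0:(n_fft - 1)) / fs)
  spec <- abs(stats::fft(tone))[1:(n_fft / 2 + 1)]
  energies <- as.numeric(fb %*% spec)
  expect_equal(which.max(energies), m_target)
})

test_that("MFCC equals an independent step-by-step computation", {
  cfg <- mfcc_config(window_len = 64, hop = 32, n_fft = 64, n_mels = 10,
                     n_coeffs = 5)
  fs <- 2000
  for (seed in 1:3) {
    set.seed(seed)
    x <- stats::rnorm(200)
    got <- mfcc(x, cfg, sample_rate = fs)$coeffs

    # reference: explicit DFT by summation, filterbank and DCT from scratch
    w <- 0.54 - 0.46 * cos(2 * pi * (0:63) / 63)
    n_frames <- floor((200 - 64) / 32) + 1
    hz2mel <- function(f) 2595 * log10(1 + f / 700)
    mel2hz <- function(m) 700 * (10^(m / 2595) - 1)
    edges <- mel2hz(seq(0, hz2mel(fs / 2), length.out = 12))
    bins <- (0:32) * fs / 64
    ref <- matrix(0, n_frames, 5)
    for (fr in seq_len(n_frames)) {
      seg <- x[((fr - 1) * 32 + 1):((fr - 1) * 32 + 64)] * w
      amp <- vapply(0:32, function(k) {
        Mod(sum(seg * exp(-2i * pi * k * (0:63) / 64)))
      }, numeric(1))
      logamp <- log(pmax(amp, 1e-10))
      smoothed <- vapply(seq_len(10), function(m) {
        lo <- edges[m]; c0 <- edges[m + 1]; hi <- edges[m + 2]
        tri <- pmax(0, pmin((bins - lo) / (c0 - lo), (hi - bins) / (hi - c0)))
        sum(tri * logamp) / sum(tri)
      }, numeric(1))
      ref[fr, ] <- vapply(0:4, function(k) {
        sum(smoothed * cos(pi * k * (2 * (0:9) + 1) / 20))
      }, numeric(1))
    }
    expect_equal(got, ref, tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("a hop-shifted signal gives frame-shifted MFCCs in the interior", {
  cfg <- mfcc_config(window_len = 64, hop = 32, n_fft = 64, n_mels = 10,
                     n_coeffs = 5)
  set.seed(8)
  x <- stats::rnorm(400)
  a <- mfcc(x, cfg, sample_rate = 2000)$coeffs
  b <- mfcc(x[33:400], cfg, sample_rate = 2000)$coeffs
  expect_equal(b[1:(nrow(a) - 1), ], a[2:nrow(a), ], tolerance = 1e-10)
})

test_that("rendered spectrogram images are 480 x 640 x 3 and deterministic", {
  m <- mfcc(seeded_segment(1600, 2), mfcc_config())
  img <- render_png(m)
  expect_equal(dim(img$pixels), c(480, 640, 3))
  expect_true(all(img$pixels >= 0 & img$pixels <= 255))

  p1 <- withr::local_tempfile(fileext = ".png")
  p2 <- withr::local_tempfile(fileext = ".png")
  write_spectrogram_png(img, p1)
  write_spectrogram_png(render_png(mfcc(seeded_segment(1600, 2), mfcc_config())), p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
})

test_that("a single-valued matrix renders as uniform mid-gray", {
  m <- mfcc(numeric(1024), mfcc_config(), sample_rate = 2000)
  m$coeffs[] <- 7
  img <- render_png(m)
  expect_true(all(img$pixels == 128L))
})

test_that("summary features are per-coefficient means and sds", {
  cfg <- mfcc_config(window_len = 64, hop = 32, n_fft = 64, n_mels = 10,
                     n_coeffs = 5)
  single <- mfcc(stats::rnorm(64), cfg, sample_rate = 2000)
  sf <- summarize_segment_features(single)
  expect_equal(as.numeric(sf[1:5]), as.numeric(single$coeffs[1, ]))
  expect_equal(as.numeric(sf[6:10]), rep(0, 5))

  dup <- single
  dup$coeffs <- rbind(single$coeffs, single$coeffs)
  expect_equal(as.numeric(summarize_segment_features(dup)[6:10]), rep(0, 5))

  set.seed(14)
  m <- single
  m$coeffs <- matrix(stats::rnorm(40), 8, 5)
  sf2 <- summarize_segment_features(m)
  pop_sd_col <- apply(m$coeffs, 2, function(v) sqrt(mean((v - mean(v))^2)))
  expect_equal(as.numeric(sf2), c(colMeans(m$coeffs), pop_sd_col),
               tolerance = 1e-12)
})
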