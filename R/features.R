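#' MFCC extraction configuration
#'
#' @param window_len Analysis window in samples. Default 1024.
#' @param hop Window stride in samples. Default 512 (50% overlap).
#' @param n_fft DFT length (>= window_len). Default 1024.
#' @param n_mels Number of triangular mel filters spanning 0-Nyquist.
#'   Default 26.
#' @param n_coeffs Cepstral coefficients retained (<= n_mels). Default 13.
#' @param window Window function; only `"hamming"`.
#' @return An object of class `mfcc_config`.
#' @export
mfcc_config <- function(window_len = 1024, hop = 512, n_fft = 1024,
                        n_mels = 26, n_coeffs = 13, window = "hamming") {
  if (window_len > n_fft) hk_stop("config_error", "window_len must be <= n_fft")
  if (n_coeffs > n_mels) hk_stop("config_error", "n_coeffs must be <= n_mels")
  if (hop < 1 || window_len < 2) hk_stop("config_error", "invalid framing")
  window <- match.arg(window, "hamming")
  structure(
    list(window_len = window_len, hop = hop, n_fft = n_fft,
         n_mels = n_mels, n_coeffs = n_coeffs, window = window),
    class = "mfcc_config"
  )
}

seg_samples <- function(seg) {
  if (inherits(seg, "heart_cycle_segment")) seg$samples
  else if (inherits(seg, "pcg_recording")) seg$samples
  else as.numeric(seg)
}

seg_id <- function(seg) {
  if (inherits(seg, "heart_cycle_segment")) {
    sprintf("%s_%d_%d", seg$recording_id, seg$start, seg$end)
  } else if (inherits(seg, "pcg_recording")) seg$id else "segment"
}

#' Slice a segment into Hamming-windowed frames
#'
#' Segments shorter than one window are zero-padded to `window_len`.
#'
#' @param seg A `heart_cycle_segment`, [pcg_recording()] or numeric vector.
#' @param cfg An [mfcc_config()].
#' @return A matrix of windowed frames (rows), `floor((L - window_len)/hop) + 1`
#'   of them for signal length `L >= window_len`.
#' @export
frame_signal <- function(seg, cfg = mfcc_config()) {
  x <- seg_samples(seg)
  if (length(x) < cfg$window_len) x <- c(x, numeric(cfg$window_len - length(x)))
  L <- length(x)
  n_frames <- floor((L - cfg$window_len) / cfg$hop) + 1L
  starts <- (seq_len(n_frames) - 1L) * cfg$hop
  idx <- outer(starts, seq_len(cfg$window_len), "+")
  win <- hamming_window(cfg$window_len)
  matrix(x[idx], nrow = n_frames) * rep(win, each = n_frames)
}

# Symmetric Hamming window, the 0.54/0.46 convention.
hamming_window <- function(n) {
  0.54 - 0.46 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
}

hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

#' Triangular mel filterbank
#'
#' `n_mels` unit-sum triangular filters with centers equally spaced on the
#' mel scale between 0 Hz and Nyquist, evaluated on the `n_fft/2 + 1`
#' non-negative DFT bins. Unit-sum normalization makes each filter a
#' weighted average, so applying the bank to a log spectrum smooths it.
#'
#' @param n_mels Number of filters.
#' @param n_fft DFT length.
#' @param sample_rate Sampling rate in Hz.
#' @return An `n_mels x (n_fft/2 + 1)` matrix.
#' @export
mel_filterbank <- function(n_mels, n_fft, sample_rate) {
  n_bins <- n_fft / 2 + 1
  freqs <- (seq_len(n_bins) - 1) * sample_rate / n_fft
  edges <- mel_to_hz(seq(0, hz_to_mel(sample_rate / 2), length.out = n_mels + 2))
  fb <- matrix(0, n_mels, n_bins)
  for (m in seq_len(n_mels)) {
    lo <- edges[m]; c0 <- edges[m + 1]; hi <- edges[m + 2]
    up <- (freqs - lo) / (c0 - lo)
    down <- (hi - freqs) / (hi - c0)
    fb[m, ] <- pmax(0, pmin(up, down))
    s <- sum(fb[m, ])
    if (s > 0) fb[m, ] <- fb[m, ] / s
  }
  fb
}

# Plain DCT-II matrix (k x m), c_k = sum_m v_m cos(pi*k*(2m+1)/(2M)).
dct2_matrix <- function(n_out, n_in) {
  k <- seq_len(n_out) - 1
  m <- seq_len(n_in) - 1
  outer(k, m, function(k, m) cos(pi * k * (2 * m + 1) / (2 * n_in)))
}

#' Mel-frequency cepstral coefficients of a heart-cycle segment
#'
#' Per frame: DFT amplitude spectrum, log (floored at `eps`), mel-filterbank
#' smoothing of the log spectrum, then a type-II DCT keeping the first
#' `n_coeffs` coefficients. The log is taken before the filterbank, so the
#' bank acts as a spectrum smoother on the (approximately logarithmic)
#' loudness representation.
#'
#' @param seg A `heart_cycle_segment`, [pcg_recording()] or numeric vector.
#' @param cfg An [mfcc_config()].
#' @param sample_rate Required when `seg` carries no rate.
#' @param eps Floor applied to the amplitude spectrum before the log.
#' @return An object of class `mfcc_matrix` with `coeffs`
#'   (frames x n_coeffs) and `segment_id`.
#' @export
mfcc <- function(seg, cfg = mfcc_config(), sample_rate = NULL, eps = 1e-10) {
  if (is.null(sample_rate)) {
    sample_rate <- if (inherits(seg, c("heart_cycle_segment", "pcg_recording"))) {
      seg$sample_rate
    } else {
      hk_stop("config_error", "sample_rate required for bare numeric input")
    }
  }
  frames <- frame_signal(seg, cfg)
  n_bins <- cfg$n_fft / 2 + 1
  padded <- cbind(frames, matrix(0, nrow(frames), cfg$n_fft - ncol(frames)))
  spec <- t(apply(padded, 1, function(fr) abs(stats::fft(fr))[seq_len(n_bins)]))
  if (nrow(frames) == 1) spec <- matrix(spec, nrow = 1)
  log_spec <- log(pmax(spec, eps))
  fb <- mel_filterbank(cfg$n_mels, cfg$n_fft, sample_rate)
  mel_smoothed <- log_spec %*% t(fb)                  # frames x n_mels
  dct <- dct2_matrix(cfg$n_coeffs, cfg$n_mels)
  coeffs <- mel_smoothed %*% t(dct)                   # frames x n_coeffs
  structure(
    list(coeffs = coeffs, segment_id = seg_id(seg), cfg = cfg,
         sample_rate = sample_rate),
    class = "mfcc_matrix"
  )
}

#' Render an MFCC matrix as a fixed-size RGB spectrogram image
#'
#' Coefficient values are mapped linearly (min to 0, max to 255) onto a fixed
#' 256-level viridis colormap and resized (nearest neighbor) to the target
#' dimensions, coefficient index on the vertical axis (first coefficient at
#' the bottom) and frame time on the horizontal. A single-valued matrix maps
#' to uniform mid-gray. Output is deterministic for identical input.
#'
#' @param m An [mfcc()] result.
#' @param height,width Output size in pixels; defaults 480 x 640.
#' @return An object of class `spectrogram_image`: integer array
#'   `height x width x 3` with values 0-255, plus `segment_id`.
#' @export
render_png <- function(m, height = 480, width = 640) {
  stopifnot(inherits(m, "mfcc_matrix"))
  co <- m$coeffs
  if (length(co) == 0) hk_stop("empty_input", "empty MFCC matrix")
  rng <- range(co)
  pal <- t(grDevices::col2rgb(grDevices::hcl.colors(256, "viridis")))
  if (rng[1] == rng[2]) {
    arr <- array(128L, dim = c(height, width, 3))
  } else {
    levels <- matrix(as.integer(pmin(floor((co - rng[1]) / (rng[2] - rng[1]) * 256), 255)),
                     nrow = nrow(co))
    # source cell for each output pixel: rows span coefficients (bottom-up),
    # columns span frames
    src_col <- floor((seq_len(width) - 0.5) / width * nrow(co)) + 1L
    src_row <- floor((seq_len(height) - 0.5) / height * ncol(co)) + 1L
    lv <- levels[src_col, rev(src_row), drop = FALSE]   # width x height
    arr <- array(0L, dim = c(height, width, 3))
    for (ch in 1:3) {
      arr[, , ch] <- t(matrix(pal[lv + 1L, ch], nrow = width))
    }
  }
  structure(list(pixels = arr, segment_id = m$segment_id),
            class = "spectrogram_image")
}

#' Write a spectrogram image to a PNG file
#'
#' @param img A `spectrogram_image` from [render_png()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectrogram_png <- function(img, path) {
  stopifnot(inherits(img, "spectrogram_image"))
  png::writePNG(img$pixels / 255, path)
  invisible(path)
}

#' Per-segment summary feature vector
#'
#' Concatenates the per-coefficient mean and population standard deviation
#' across frames, giving a `2 * n_coeffs` vector used for segment clustering
#' and the logistic baseline classifier.
#'
#' @param m An [mfcc()] result.
#' @return Named numeric vector `c(mean_1..mean_k, sd_1..sd_k)`.
#' @export
summarize_segment_features <- function(m) {
  stopifnot(inherits(m, "mfcc_matrix"))
  co <- m$coeffs
  if (length(co) == 0) hk_stop("empty_input", "empty MFCC matrix")
  mu <- colMeans(co)
  sdev <- sqrt(colMeans(co^2) - mu^2)
  sdev[sdev < 0 | !is.finite(sdev)] <- 0
  k <- ncol(co)
  stats::setNames(c(mu, sdev),
                  c(paste0("mean_", seq_len(k)), paste0("sd_", seq_len(k))))
}
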