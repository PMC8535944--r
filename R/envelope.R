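#' Frame-wise Shannon energy envelope
#'
#' Computes, per frame of the low-frequency heart-sound signal,
#' `SE = -(1/N) * sum(e_j * log(e_j))` with `e_j` the squared sample
#' (energy convention, so the log argument is non-negative) and the
#' `0 * log(0) := 0` limit. Frames are tiled at stride `hop`; an incomplete
#' tail frame is dropped. Shannon energy emphasizes medium-intensity
#' components, which makes the S1/S2 transients stand out against both
#' low-level noise and isolated spikes.
#'
#' @param rec A [pcg_recording()] (typically the wavelet low-frequency
#'   reconstruction at 2 kHz).
#' @param frame_len Frame length in samples (>= 2). Default 40 (20 ms at 2 kHz).
#' @param hop Frame stride in samples (>= 1). Default 20.
#' @return An object of class `envelope_series` with fields `values`,
#'   `frame_len`, `hop`, `sample_rate`, `times` (frame-center times, s) and
#'   `standardized` (FALSE).
#' @export
shannon_envelope <- function(rec, frame_len = 40, hop = 20) {
  stopifnot(inherits(rec, "pcg_recording"))
  if (frame_len < 2) hk_stop("empty_envelope", "frame_len must be >= 2")
  if (hop < 1) hk_stop("empty_envelope", "hop must be >= 1")
  x <- rec$samples
  L <- length(x)
  if (frame_len > L) {
    hk_stop("empty_envelope", "frame_len %d exceeds signal length %d", frame_len, L)
  }
  n_frames <- floor((L - frame_len) / hop) + 1L
  starts <- (seq_len(n_frames) - 1L) * hop          # 0-based frame starts
  idx <- outer(starts, seq_len(frame_len), "+")      # n_frames x frame_len
  e <- matrix(x[idx]^2, nrow = n_frames)
  term <- e * log(e)
  term[e == 0] <- 0
  values <- -rowSums(term) / frame_len
  structure(
    list(values = values, frame_len = frame_len, hop = hop,
         sample_rate = rec$sample_rate,
         times = (starts + (frame_len - 1) / 2) / rec$sample_rate,
         standardized = FALSE),
    class = "envelope_series"
  )
}

#' Standardize an envelope to zero mean and unit standard deviation
#'
#' @param env An `envelope_series` from [shannon_envelope()] with at least
#'   two frames and nonzero variance.
#' @return The envelope with `values` replaced by their z-scores
#'   (`standardized = TRUE`).
#' @export
standardize_envelope <- function(env) {
  stopifnot(inherits(env, "envelope_series"))
  v <- env$values
  if (length(v) < 2) hk_stop("constant_envelope", "need at least two frames")
  s <- stats::sd(v)
  if (s == 0) hk_stop("constant_envelope", "envelope has zero variance")
  env$values <- (v - mean(v)) / s
  env$standardized <- TRUE
  env
}
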