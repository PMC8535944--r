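#' Estimate the cardiac-cycle period from the envelope autocorrelation
#'
#' Computes the unbiased autocorrelation of the (standardized) envelope,
#' `r(tau) = 1/(L - tau) * sum_t x_t * x_{t+tau}`, and returns the lag of
#' its highest positive peak inside the physiological window. Because the
#' autocorrelation of a periodic envelope peaks equally at the period and
#' its multiples, the estimator prefers the smallest lag among local maxima
#' whose height is at least `subpeak_frac` of the global maximum — this
#' resolves period-doubling at high heart rates without affecting the
#' fundamental peak.
#'
#' @param env A standardized `envelope_series` (see [standardize_envelope()]).
#' @param min_period,max_period Physiological period window in seconds.
#'   Defaults 0.4-1.6 s (about 37-150 bpm).
#' @param subpeak_frac Fraction of the top peak above which an earlier local
#'   maximum is taken as the fundamental. Default 0.85.
#' @return An object of class `cycle_estimate` with `period_samples` (at the
#'   recording rate), `period_seconds` and `confidence = r(tau*) / r(0)`
#'   clipped to `[0, 1]`.
#' @export
estimate_cycle_uacf <- function(env, min_period = 0.4, max_period = 1.6,
                                subpeak_frac = 0.85) {
  stopifnot(inherits(env, "envelope_series"))
  x <- env$values
  L <- length(x)
  env_rate <- env$sample_rate / env$hop
  if (L / env_rate <= 2 * max_period) {
    hk_stop("no_periodicity",
            "envelope duration %.2f s must exceed twice the maximum period (%g s)",
            L / env_rate, max_period)
  }
  lag_min <- max(1L, ceiling(min_period * env_rate))
  lag_max <- min(L - 1L, floor(max_period * env_rate))
  r0 <- mean(x^2)
  if (r0 == 0) hk_stop("no_periodicity", "constant envelope has no periodicity")
  lags <- lag_min:lag_max
  r <- vapply(lags, function(tau) {
    sum(x[1:(L - tau)] * x[(tau + 1):L]) / (L - tau)
  }, numeric(1))
  # local maxima with positive correlation
  n <- length(r)
  is_peak <- r > 0 &
    r >= c(-Inf, r[-n]) &
    r >= c(r[-1], -Inf)
  if (!any(is_peak)) hk_stop("no_periodicity", "no positive autocorrelation peak in window")
  peaks <- which(is_peak)
  top <- max(r[peaks])
  cand <- peaks[r[peaks] >= subpeak_frac * top]
  best <- cand[1]                                   # earliest qualifying peak
  lag_env <- lags[best]
  period_samples <- as.integer(round(lag_env * env$hop))
  structure(
    list(period_samples = period_samples,
         period_seconds = period_samples / env$sample_rate,
         confidence = min(max(r[best] / r0, 0), 1)),
    class = "cycle_estimate"
  )
}

#' Cut a recording into single heart-cycle segments
#'
#' S1 onset candidates are local maxima of the standardized envelope above 0,
#' thinned so accepted peaks are at least `0.6 * period` apart (higher peaks
#' win; equal peaks resolve to the earlier one). Each segment spans
#' `[onset, onset + period)` in 0-based half-open sample coordinates, clipped
#' to the recording and truncated at the next onset so segments never overlap.
#' A trailing partial cycle shorter than half a period is discarded.
#'
#' @param rec The [pcg_recording()] being segmented.
#' @param env The standardized `envelope_series` computed from it.
#' @param cyc A `cycle_estimate` from [estimate_cycle_uacf()].
#' @param peak_threshold Minimum standardized envelope value for an S1 peak.
#'   Default 0.
#' @return A list of `heart_cycle_segment` objects (possibly empty, with a
#'   warning, when no complete cycle fits).
#' @export
segment_recording <- function(rec, env, cyc, peak_threshold = 0) {
  stopifnot(inherits(rec, "pcg_recording"), inherits(env, "envelope_series"),
            inherits(cyc, "cycle_estimate"))
  v <- env$values
  n <- length(v)
  L <- length(rec$samples)
  period <- cyc$period_samples
  min_sep_env <- 0.6 * period / env$hop

  is_peak <- v > peak_threshold &
    v >= c(-Inf, v[-n]) &
    v >= c(v[-1], -Inf)
  peaks <- which(is_peak)
  if (length(peaks) == 0) {
    hk_warn("no_cycles", "no envelope peaks above threshold; returning no segments")
    return(list())
  }
  # greedy non-maximum suppression: highest first, ties to the earlier peak
  ord <- peaks[order(-v[peaks], peaks)]
  accepted <- integer(0)
  for (p in ord) {
    if (all(abs(accepted - p) >= min_sep_env)) accepted <- c(accepted, p)
  }
  accepted <- sort(accepted)

  # envelope frame index -> sample index of the frame center
  onset <- round((accepted - 1L) * env$hop + (env$frame_len - 1) / 2)
  onset <- onset[onset < L]
  if (length(onset) == 0) {
    hk_warn("no_cycles", "no complete heart cycle found")
    return(list())
  }
  starts <- onset
  ends <- pmin(starts + period, L)
  if (length(starts) > 1) {
    ends[-length(ends)] <- pmin(ends[-length(ends)], starts[-1])
  }
  keep <- (ends - starts) >= 0.5 * period
  starts <- starts[keep]; ends <- ends[keep]
  if (length(starts) == 0) {
    hk_warn("no_cycles", "no complete heart cycle found")
    return(list())
  }
  lapply(seq_along(starts), function(i) {
    structure(
      list(recording_id = rec$id, start = starts[i], end = ends[i],
           samples = rec$samples[(starts[i] + 1):ends[i]],
           sample_rate = rec$sample_rate, label = rec$label),
      class = "heart_cycle_segment"
    )
  })
}

#' @export
print.heart_cycle_segment <- function(x, ...) {
  cat(sprintf("<heart_cycle_segment %s [%d, %d) %s>\n",
              x$recording_id, x$start, x$end, x$label))
  invisible(x)
}

#' Run the full segmentation stage on one recording
#'
#' Convenience wrapper chaining [wavelet_low_freq_extract()],
#' [shannon_envelope()], [standardize_envelope()], [estimate_cycle_uacf()] and
#' [segment_recording()]. Input is expected denoised, resampled to the
#' working rate, and amplitude-normalized.
#'
#' @param rec A [pcg_recording()] at the working rate.
#' @param wavelet A [wavelet_config()].
#' @param frame_len,hop Envelope framing (samples).
#' @param min_period,max_period Period search window (seconds).
#' @return A list with `segments`, `envelope` and `cycle`.
#' @export
segment_pipeline <- function(rec, wavelet = wavelet_config(),
                             frame_len = 40, hop = 20,
                             min_period = 0.4, max_period = 1.6) {
  low <- wavelet_low_freq_extract(rec, wavelet)
  # Reference the low-frequency signal to half full scale before the Shannon
  # transform: -e*log(e) is increasing only for e = x^2 < 1/e, so keeping
  # |x| <= 0.5 leaves the envelope monotone in amplitude and the louder S1
  # always outranks S2.
  peak <- max(abs(low$samples))
  if (peak > 0) low$samples <- low$samples / (2 * peak)
  env <- standardize_envelope(shannon_envelope(low, frame_len, hop))
  cyc <- estimate_cycle_uacf(env, min_period, max_period)
  segs <- segment_recording(rec, env, cyc)
  list(segments = segs, envelope = env, cycle = cyc)
}
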