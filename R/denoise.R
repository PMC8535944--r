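#' IIR filter specification
#'
#' Butterworth filter settings for out-of-band noise removal. The default is
#' a 4th-order zero-phase bandpass over 25-600 Hz: the primary heart sounds
#' carry most energy in roughly 25-120 Hz, while murmurs extend well above,
#' so the upper edge keeps murmur content while rejecting rumble and hiss.
#'
#' @param kind `"bandpass"`, `"lowpass"` or `"highpass"`.
#' @param order Filter order (>= 1). Default 4.
#' @param low_cut Lower cutoff in Hz (bandpass/highpass).
#' @param high_cut Upper cutoff in Hz (bandpass/lowpass).
#' @param zero_phase Apply forward-backward for zero phase distortion
#'   (default TRUE). Note the magnitude response is then applied twice.
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(kind = c("bandpass", "lowpass", "highpass"),
                        order = 4, low_cut = 25, high_cut = 600,
                        zero_phase = TRUE) {
  kind <- match.arg(kind)
  if (order < 1 || order != round(order)) {
    hk_stop("filter_spec_error", "order must be a positive integer")
  }
  if (kind == "bandpass" && !(low_cut > 0 && low_cut < high_cut)) {
    hk_stop("filter_spec_error", "bandpass requires 0 < low_cut < high_cut")
  }
  structure(
    list(kind = kind, order = order, low_cut = low_cut, high_cut = high_cut,
         zero_phase = isTRUE(zero_phase)),
    class = "filter_spec"
  )
}

#' Denoise a recording with an IIR (Butterworth) filter
#'
#' @param rec A [pcg_recording()].
#' @param spec A [filter_spec()]; cutoffs must lie below the recording's
#'   Nyquist frequency.
#' @return The filtered recording, same length and rate.
#' @export
iir_denoise <- function(rec, spec = filter_spec()) {
  stopifnot(inherits(rec, "pcg_recording"), inherits(spec, "filter_spec"))
  nyq <- rec$sample_rate / 2
  hi_needed <- spec$kind %in% c("bandpass", "lowpass")
  if (hi_needed && spec$high_cut >= nyq) {
    hk_stop("filter_spec_error",
            "high cutoff %g Hz is at or above Nyquist (%g Hz)", spec$high_cut, nyq)
  }
  if (spec$kind %in% c("bandpass", "highpass") && spec$low_cut >= nyq) {
    hk_stop("filter_spec_error",
            "low cutoff %g Hz is at or above Nyquist (%g Hz)", spec$low_cut, nyq)
  }
  W <- switch(spec$kind,
    bandpass = c(spec$low_cut, spec$high_cut) / nyq,
    lowpass = spec$high_cut / nyq,
    highpass = spec$low_cut / nyq
  )
  type <- switch(spec$kind, bandpass = "pass", lowpass = "low", highpass = "high")
  bt <- signal::butter(spec$order, W, type = type)
  x <- rec$samples
  y <- if (spec$zero_phase) signal::filtfilt(bt, x) else
    as.numeric(signal::filter(bt, x))
  if (any(!is.finite(y))) {
    hk_stop("numerical_error",
            "IIR filter output diverged (order %d, cutoffs %g-%g Hz at %g Hz)",
            spec$order, spec$low_cut, spec$high_cut, rec$sample_rate)
  }
  pcg_recording(y, rec$sample_rate, id = rec$id, label = rec$label)
}
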