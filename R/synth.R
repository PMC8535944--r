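#' Synthetic PCG generator configuration
#'
#' Parameters of the quasi-periodic S1/S2 heart-sound model used to make
#' labeled test recordings with ground-truth beat annotations. Defaults are
#' textbook heart-sound values: S1 around 40 Hz lasting about 70 ms, the
#' softer S2 around 60 Hz lasting about 50 ms, systole occupying roughly a
#' third of the cycle.
#'
#' @param duration Recording length in seconds. Default 10.
#' @param bpm Heart rate in beats/min (30-200). Default 75.
#' @param s1_freq,s2_freq Carrier frequencies in Hz. Defaults 40 and 60.
#' @param s1_width,s2_width Transient durations in seconds. Defaults 0.07 and
#'   0.05.
#' @param s1_amp,s2_amp Peak amplitudes. Defaults 1 and 0.7.
#' @param systole_fraction S1-to-S2 spacing as a fraction of the cycle.
#'   Default 0.35.
#' @param murmur_level Relative amplitude of the systolic band-limited
#'   (120-400 Hz) murmur noise. Default 0.4.
#' @param extrasystole_prob Per-beat probability of a premature beat (applies
#'   to the extrasystole class). Default 0.25.
#' @param premature_fraction A premature interval as a fraction of the normal
#'   one. Default 0.5.
#' @param snr_db Additive white-noise level as signal-to-noise ratio in dB.
#'   Default 20.
#' @param sample_rate Sampling rate in Hz. Default 2000.
#' @param seed RNG seed driving all randomness. Default 1.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(duration = 10, bpm = 75, s1_freq = 40, s2_freq = 60,
                         s1_width = 0.07, s2_width = 0.05,
                         s1_amp = 1, s2_amp = 0.7,
                         systole_fraction = 0.35, murmur_level = 0.4,
                         extrasystole_prob = 0.25, premature_fraction = 0.5,
                         snr_db = 20, sample_rate = 2000, seed = 1) {
  if (bpm < 30 || bpm > 200) hk_stop("config_error", "bpm must be in [30, 200]")
  if (!is.finite(snr_db)) hk_stop("config_error", "snr_db must be finite")
  for (p in c(extrasystole_prob, premature_fraction, systole_fraction)) {
    if (p < 0 || p > 1) hk_stop("config_error", "fractions/probabilities must be in [0, 1]")
  }
  if (duration <= 0 || sample_rate <= 0) {
    hk_stop("config_error", "duration and sample_rate must be positive")
  }
  structure(
    list(duration = duration, bpm = bpm, s1_freq = s1_freq, s2_freq = s2_freq,
         s1_width = s1_width, s2_width = s2_width, s1_amp = s1_amp,
         s2_amp = s2_amp, systole_fraction = systole_fraction,
         murmur_level = murmur_level, extrasystole_prob = extrasystole_prob,
         premature_fraction = premature_fraction, snr_db = snr_db,
         sample_rate = sample_rate, seed = as.integer(seed)),
    class = "synth_config"
  )
}

# Gaussian-windowed cosine transient centered at `center` (s), evaluated at
# sample times t (s). The window sigma is width/4 so the bump spans ~width.
gauss_tone <- function(t, center, width, freq, amp) {
  amp * exp(-0.5 * ((t - center) / (width / 4))^2) * cos(2 * pi * freq * (t - center))
}

# Band-limited (120-400 Hz) noise burst over [t0, t1), tapered with a raised
# cosine and scaled to peak amplitude `level`.
murmur_burst <- function(t, t0, t1, level, sample_rate) {
  if (level <= 0 || t1 <= t0) return(numeric(length(t)))
  in_burst <- t >= t0 & t < t1
  n_b <- sum(in_burst)
  if (n_b < 8) return(numeric(length(t)))
  noise <- stats::rnorm(n_b)
  nyq <- sample_rate / 2
  hi <- min(400, 0.9 * nyq)
  bt <- signal::butter(4, c(120, hi) / nyq, type = "pass")
  shaped <- signal::filtfilt(bt, noise)
  taper <- 0.5 - 0.5 * cos(2 * pi * seq(0, 1, length.out = n_b))
  shaped <- shaped * taper
  peak <- max(abs(shaped))
  if (peak > 0) shaped <- shaped / peak * level
  out <- numeric(length(t))
  out[in_burst] <- shaped
  out
}

#' Synthesize a single heart-beat cycle
#'
#' One cycle holds an S1 transient with its peak at the cycle start (phase 0)
#' and a shorter, softer S2 at `systole_fraction` of the period. For the
#' murmur class, band-limited 120-400 Hz noise of amplitude `murmur_level`
#' fills the S1-to-S2 interval.
#'
#' @param cfg A [synth_config()].
#' @param class_label `"normal"` or `"murmur"`.
#' @return A list with `samples`, `s1_time` (0), `s2_time` and
#'   `period` (seconds).
#' @export
synth_beat <- function(cfg, class_label = "normal") {
  stopifnot(inherits(cfg, "synth_config"))
  period <- 60 / cfg$bpm
  n <- round(period * cfg$sample_rate)
  t <- (seq_len(n) - 1) / cfg$sample_rate
  s2_time <- cfg$systole_fraction * period
  x <- gauss_tone(t, 0, cfg$s1_width, cfg$s1_freq, cfg$s1_amp) +
    gauss_tone(t, s2_time, cfg$s2_width, cfg$s2_freq, cfg$s2_amp)
  if (identical(class_label, "murmur") && cfg$murmur_level > 0) {
    x <- x + hk_with_seed(cfg$seed, murmur_burst(
      t, cfg$s1_width / 2, s2_time - cfg$s2_width / 2,
      cfg$murmur_level, cfg$sample_rate))
  }
  list(samples = x, s1_time = 0, s2_time = s2_time, period = period)
}

#' Synthesize a full labeled recording with ground truth
#'
#' Beats are placed on a nominal grid of period `60/bpm`; for the
#' extrasystole class each inter-beat interval is shortened to
#' `premature_fraction` of nominal with probability `extrasystole_prob`
#' (the early beat is labeled `extrasystole`). A beat is emitted only when
#' its complete cycle fits within the recording, so with no extrasystoles
#' the beat count is `floor(duration * bpm / 60)`. S1 transients are
#' centered exactly on the onset times reported in the ground truth.
#' White noise is added at `snr_db` relative to the clean signal power.
#'
#' @param cfg A [synth_config()].
#' @param class_label `"normal"`, `"murmur"` or `"extrasystole"`.
#' @return A list with `recording` (a [pcg_recording()]) and `truth`
#'   (`s1_times`, `s2_times`, `beat_labels`, `class`, `bpm`, `period`).
#' @export
synth_recording <- function(cfg, class_label = c("normal", "murmur", "extrasystole")) {
  stopifnot(inherits(cfg, "synth_config"))
  class_label <- match.arg(class_label)
  fs <- cfg$sample_rate
  period <- 60 / cfg$bpm
  n <- round(cfg$duration * fs)
  t <- (seq_len(n) - 1) / fs

  hk_with_seed(cfg$seed, {
    onsets <- numeric(0)
    labels <- character(0)
    cur <- 0
    while (cur + period <= cfg$duration + 1e-12) {
      onsets <- c(onsets, cur)
      premature <- class_label == "extrasystole" &&
        stats::runif(1) < cfg$extrasystole_prob
      if (premature) {
        step <- period * cfg$premature_fraction
        labels <- c(labels, "pre_extrasystole")
      } else {
        step <- period
        labels <- c(labels, "normal")
      }
      cur <- cur + step
    }
    # a beat *following* a shortened interval is the premature one
    beat_labels <- c("normal",
                     ifelse(labels[-length(labels)] == "pre_extrasystole",
                            "extrasystole", "normal"))

    clean <- numeric(n)
    s2_times <- onsets + cfg$systole_fraction * period
    for (i in seq_along(onsets)) {
      clean <- clean + gauss_tone(t, onsets[i], cfg$s1_width, cfg$s1_freq, cfg$s1_amp)
      clean <- clean + gauss_tone(t, s2_times[i], cfg$s2_width, cfg$s2_freq, cfg$s2_amp)
      if (class_label == "murmur" && cfg$murmur_level > 0) {
        clean <- clean + murmur_burst(
          t, onsets[i] + cfg$s1_width / 2, s2_times[i] - cfg$s2_width / 2,
          cfg$murmur_level, fs)
      }
    }
    p_sig <- mean(clean^2)
    sigma <- sqrt(p_sig / 10^(cfg$snr_db / 10))
    x <- clean + stats::rnorm(n, sd = sigma)

    list(
      recording = pcg_recording(x, fs, id = sprintf("synth_%s_%d", class_label, cfg$seed),
                                label = class_label),
      truth = list(s1_times = onsets, s2_times = s2_times,
                   beat_labels = beat_labels, class = class_label,
                   bpm = cfg$bpm, period = period)
    )
  })
}

#' Generate a balanced synthetic corpus
#'
#' Creates `n_per_class` recordings for each of the normal, murmur and
#' extrasystole classes, with per-recording jittered heart rate (uniform
#' 60-100 bpm) and SNR (uniform 15-25 dB). Deterministic given `seed`.
#'
#' @param n_per_class Recordings per class (>= 1).
#' @param base_cfg A [synth_config()] supplying all non-jittered parameters.
#' @param seed Corpus-level seed.
#' @param out_dir Optional directory; when given, WAV files, a
#'   `manifest.csv` (`split,label,path`) and `ground_truth.json` are written
#'   there.
#' @return A list with `recordings`, `truths` and `manifest` (data frame).
#' @export
make_dataset <- function(n_per_class, base_cfg = synth_config(), seed = 1,
                         out_dir = NULL) {
  if (n_per_class < 1) hk_stop("config_error", "n_per_class must be >= 1")
  classes <- c("normal", "murmur", "extrasystole")
  recordings <- list()
  truths <- list()
  rows <- list()
  k <- 0
  for (ci in seq_along(classes)) {
    for (i in seq_len(n_per_class)) {
      k <- k + 1
      rec_seed <- (as.integer(seed) %% 10000L) * 100000L + ci * 1000L + i
      jit <- hk_with_seed(rec_seed * 7L, list(bpm = stats::runif(1, 60, 100),
                                              snr = stats::runif(1, 15, 25)))
      cfg_i <- base_cfg
      cfg_i$bpm <- jit$bpm
      cfg_i$snr_db <- jit$snr
      cfg_i$seed <- rec_seed
      out <- synth_recording(cfg_i, classes[ci])
      rec_id <- sprintf("%s_%03d", classes[ci], i)
      out$recording$id <- rec_id
      recordings[[rec_id]] <- out$recording
      truths[[rec_id]] <- out$truth
      rows[[k]] <- data.frame(split = "A", label = classes[ci],
                              path = paste0(rec_id, ".wav"),
                              stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (rec_id in names(recordings)) {
      write_wav(recordings[[rec_id]], file.path(out_dir, paste0(rec_id, ".wav")))
    }
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
    jsonlite::write_json(truths, file.path(out_dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(recordings = recordings, truths = truths, manifest = manifest)
}
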