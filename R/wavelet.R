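# Daubechies scaling (lowpass decomposition) filters, orders 1-10.
# Standard published coefficients, lowest-index tap first.
.db_filters <- list(
  db1 = c(0.70710678118654757, 0.70710678118654757),
  db2 = c(-0.12940952255126037, 0.22414386804201339, 0.83651630373780794,
          0.48296291314453416),
  db3 = c(0.035226291885709533, -0.085441273882026658, -0.13501102001025458,
          0.45987750211849154, 0.80689150931109255, 0.33267055295008263),
  db4 = c(-0.010597401785069032, 0.032883011666885197, 0.030841381835560764,
          -0.18703481171909309, -0.027983769416859854, 0.63088076792985892,
          0.71484657055291567, 0.23037781330889651),
  db5 = c(0.0033357252854737712, -0.012580751999081999, -0.0062414902127982744,
          0.077571493840045719, -0.032244869584638375, -0.24229488706638203,
          0.13842814590132074, 0.72430852843777294, 0.60382926979718965,
          0.16010239797419293),
  db6 = c(-0.0010773010853084796, 0.0047772575109455108, 0.00055384220116149613,
          -0.03158203931748603, 0.027522865530305727, 0.097501605587323043,
          -0.12976686756726194, -0.22626469396543983, 0.31525035170919763,
          0.75113390802109536, 0.49462389039845306, 0.11154074335010947),
  db7 = c(0.00035371379997452024, -0.0018016407040474908, 0.00042957797292136651,
          0.01255099855609984, -0.016574541630666881, -0.038029936935014413,
          0.080612609151083078, 0.071309219266830259, -0.22403618499387498,
          -0.14390600392856498, 0.46978228740519312, 0.72913209084623509,
          0.39653931948191729, 0.077852054085009184),
  db8 = c(-0.00011747678412476953, 0.00067544940645056933, -0.00039174037337694705,
          -0.0048703529934515741, 0.0087460940474057766, 0.013981027917398282,
          -0.044088253930794755, -0.017369301001807547, 0.12874742662047847,
          0.00047248457391328279, -0.28401554296154691, -0.015829105256349306,
          0.58535468365420673, 0.67563073629728976, 0.31287159091429995,
          0.054415842243104008),
  db9 = c(3.9347320316271603e-05, -0.00025196318894271012, 0.00023038576352319597,
          0.0018476468830562265, -0.0042815036824634303, -0.0047232047577513972,
          0.022361662123679096, 0.00025094711483145197, -0.067632829061329974,
          0.03072568147933338, 0.14854074933810638, -0.096840783222976456,
          -0.29327378327917492, 0.13319738582500756, 0.65728807805130052,
          0.60482312369011115, 0.24383467461259034, 0.038077947363878345),
  db10 = c(-1.3264202894521244e-05, 9.3588670320069592e-05, -0.00011646685512928545,
           -0.00068585669495971162, 0.0019924052951850561, 0.0013953517470529011,
           -0.010733175483330575, 0.0036065535669561697, 0.033212674059341002,
           -0.029457536821875813, -0.071394147166397082, 0.093057364603572348,
           0.12736934033579325, -0.19594627437737705, -0.24984642432731538,
           0.28117234366057747, 0.68845903945360354, 0.52720118893172563,
           0.1881768000776915, 0.026670057900555554)
)

db_scaling_filter <- function(order) {
  key <- paste0("db", order)
  if (!key %in% names(.db_filters)) {
    hk_stop("filter_spec_error", "Daubechies order must be in 1..10, got %s", order)
  }
  .db_filters[[key]]
}

#' Wavelet envelope-extraction configuration
#'
#' Settings for the Daubechies decomposition used to isolate the low-frequency
#' heart-sound content before envelope detection. Each subband is thresholded
#' with the adaptive rule `thr = mean(C) + f * sd(C)` computed on that band's
#' coefficients (on their magnitudes when `magnitude = TRUE`).
#'
#' @param family_order Daubechies order (1-10). Default 6.
#' @param levels Decomposition depth. Default 5 (approximation band roughly
#'   0-31 Hz at a 2 kHz working rate).
#' @param f Threshold multiplier in `thr = mean + f * sd`. Default 1.
#' @param keep_mode `"above"` (default) keeps coefficients whose compared
#'   value is strictly above the threshold and zeroes the rest — the standard
#'   denoising convention that preserves the strong S1/S2 transients;
#'   `"below"` is the converse.
#' @param magnitude Compare `|c|` (default) rather than the signed coefficient.
#' @return An object of class `wavelet_config`.
#' @export
wavelet_config <- function(family_order = 6, levels = 5, f = 1.0,
                           keep_mode = c("above", "below"), magnitude = TRUE) {
  keep_mode <- match.arg(keep_mode)
  if (family_order < 1 || family_order > 10 || family_order != round(family_order)) {
    hk_stop("filter_spec_error", "family_order must be an integer in 1..10")
  }
  if (levels < 1 || levels != round(levels)) {
    hk_stop("filter_spec_error", "levels must be a positive integer")
  }
  if (!is.finite(f)) hk_stop("filter_spec_error", "f must be finite")
  structure(
    list(family_order = family_order, levels = levels, f = f,
         keep_mode = keep_mode, magnitude = isTRUE(magnitude)),
    class = "wavelet_config"
  )
}

# One analysis step of the periodized orthogonal filter bank.
# x must have even length; h is the scaling filter.
dwt_step <- function(x, h) {
  n <- length(x)
  half <- n / 2L
  L <- length(h)
  g <- rev(h) * (-1)^(seq_len(L) - 1)   # quadrature mirror highpass
  a <- numeric(half)
  d <- numeric(half)
  base <- 2L * (seq_len(half) - 1L)     # 0-based even offsets
  for (j in seq_len(L)) {
    idx <- (base + (j - 1L)) %% n + 1L
    a <- a + h[j] * x[idx]
    d <- d + g[j] * x[idx]
  }
  list(approx = a, detail = d)
}

idwt_step <- function(a, d, h) {
  half <- length(a)
  n <- 2L * half
  L <- length(h)
  g <- rev(h) * (-1)^(seq_len(L) - 1)
  x <- numeric(n)
  base <- 2L * (seq_len(half) - 1L)
  for (j in seq_len(L)) {
    idx <- (base + (j - 1L)) %% n + 1L
    contrib <- h[j] * a + g[j] * d
    # scatter-add; idx values are distinct within one j
    x[idx] <- x[idx] + contrib
  }
  x
}

#' Multi-level periodized Daubechies decomposition
#'
#' The signal is zero-padded at the tail to a multiple of `2^levels` (the
#' original length is recorded and restored on reconstruction).
#'
#' @param x Numeric signal.
#' @param cfg A [wavelet_config()].
#' @return A list with `approx`, `details` (coarsest first), `n` (original
#'   length), and the config.
#' @export
wavelet_decompose <- function(x, cfg = wavelet_config()) {
  h <- db_scaling_filter(cfg$family_order)
  n0 <- length(x)
  block <- 2^cfg$levels
  n_pad <- ceiling(n0 / block) * block
  if (n_pad / block < length(h)) {
    hk_stop("depth_error",
            "signal of length %d too short for %d levels with a %d-tap filter",
            n0, cfg$levels, length(h))
  }
  xp <- c(x, numeric(n_pad - n0))
  details <- vector("list", cfg$levels)
  cur <- xp
  for (lev in seq_len(cfg$levels)) {
    st <- dwt_step(cur, h)
    details[[cfg$levels - lev + 1L]] <- st$detail  # store coarsest first
    cur <- st$approx
  }
  list(approx = cur, details = details, n = n0, cfg = cfg)
}

#' Reconstruct a signal from a [wavelet_decompose()] object
#' @param dec Decomposition as returned by [wavelet_decompose()].
#' @return Numeric signal of the original length.
#' @export
wavelet_reconstruct <- function(dec) {
  h <- db_scaling_filter(dec$cfg$family_order)
  cur <- dec$approx
  for (lev in seq_along(dec$details)) {
    cur <- idwt_step(cur, dec$details[[lev]], h)
  }
  cur[seq_len(dec$n)]
}

#' Adaptive coefficient threshold
#'
#' Computes `thr = mean(C) + f * sd(C)` with the population standard
#' deviation, where `C` is taken as `|coeffs|` when `magnitude = TRUE`.
#'
#' @param coeffs Nonempty numeric coefficient vector.
#' @param f Threshold multiplier.
#' @param magnitude Use coefficient magnitudes (default TRUE).
#' @return The scalar threshold.
#' @export
adaptive_threshold <- function(coeffs, f, magnitude = TRUE) {
  if (length(coeffs) == 0) hk_stop("empty_input", "empty coefficient vector")
  cs <- if (magnitude) abs(coeffs) else coeffs
  mean(cs) + f * pop_sd(cs)
}

#' Threshold wavelet coefficients
#'
#' In `keep_mode = "below"` a coefficient survives when its compared value is
#' strictly below `thr` and is zeroed otherwise; `"above"` keeps the strict
#' complement. The comparison uses `|c|` under magnitude mode.
#'
#' @param coeffs Numeric coefficient vector.
#' @param thr Finite threshold.
#' @param keep_mode `"below"` or `"above"`.
#' @param magnitude Compare magnitudes (default TRUE).
#' @return Thresholded coefficients, same length.
#' @export
threshold_coeffs <- function(coeffs, thr, keep_mode = c("below", "above"),
                             magnitude = TRUE) {
  keep_mode <- match.arg(keep_mode)
  if (!is.finite(thr)) hk_stop("filter_spec_error", "thr must be finite")
  cmp <- if (magnitude) abs(coeffs) else coeffs
  keep <- if (keep_mode == "below") cmp < thr else cmp > thr
  out <- coeffs
  out[!keep] <- 0
  out
}

#' Extract the low-frequency heart-sound signal
#'
#' Decomposes the recording with a Daubechies wavelet, applies the adaptive
#' threshold band by band (each subband gets its own `thr = mean + f * sd`),
#' and reconstructs. The result feeds Shannon-energy envelope detection.
#'
#' @param rec A [pcg_recording()], typically at the 2 kHz working rate.
#' @param cfg A [wavelet_config()].
#' @return A [pcg_recording()] of the same length and rate.
#' @export
wavelet_low_freq_extract <- function(rec, cfg = wavelet_config()) {
  stopifnot(inherits(rec, "pcg_recording"))
  dec <- wavelet_decompose(rec$samples, cfg)
  shrink <- function(band) {
    thr <- adaptive_threshold(band, cfg$f, cfg$magnitude)
    threshold_coeffs(band, thr, cfg$keep_mode, cfg$magnitude)
  }
  dec$approx <- shrink(dec$approx)
  dec$details <- lapply(dec$details, shrink)
  out <- wavelet_reconstruct(dec)
  pcg_recording(out, rec$sample_rate, id = rec$id, label = rec$label)
}
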