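.pcg_labels <- c("normal", "murmur", "extrasystole", "abnormal", "unlabeled")

#' PCG recording container
#'
#' A labeled mono heart-sound signal. Amplitudes are dimensionless reals;
#' integer PCM input is scaled to `[-1, 1]` on read.
#'
#' @param samples Numeric vector, length >= 1.
#' @param sample_rate Sampling rate in Hz (positive).
#' @param id Provenance identifier.
#' @param label One of `"normal"`, `"murmur"`, `"extrasystole"`, `"abnormal"`,
#'   `"unlabeled"`.
#' @return An object of class `pcg_recording`.
#' @export
pcg_recording <- function(samples, sample_rate, id = "rec", label = "unlabeled") {
  if (length(samples) < 1) hk_stop("empty_signal", "recording has no samples")
  if (!is.numeric(sample_rate) || sample_rate <= 0) {
    hk_stop("decode_error", "sample_rate must be positive")
  }
  label <- match.arg(label, .pcg_labels)
  structure(
    list(id = as.character(id), samples = as.numeric(samples),
         sample_rate = sample_rate, label = label),
    class = "pcg_recording"
  )
}

#' @export
print.pcg_recording <- function(x, ...) {
  cat(sprintf("<pcg_recording '%s': %d samples @ %g Hz (%.2f s), label=%s>\n",
              x$id, length(x$samples), x$sample_rate,
              length(x$samples) / x$sample_rate, x$label))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec A [pcg_recording()].
#' @return Duration in seconds.
#' @export
recording_duration <- function(rec) length(rec$samples) / rec$sample_rate

# ---- WAV (RIFF) codec -------------------------------------------------------
# Minimal RIFF/WAVE reader: PCM (format 1) at 8/16/24/32 bit, IEEE float
# (format 3) at 32/64 bit, and the WAVE_FORMAT_EXTENSIBLE wrapper around
# either. Multichannel audio is averaged to mono.

#' Read a WAV file as a PCG recording
#'
#' @param path Path to a RIFF/WAVE file.
#' @param id Recording id; defaults to the file name without extension.
#' @param label Class label to attach.
#' @return A [pcg_recording()]. Multichannel input is averaged to mono and
#'   integer PCM is scaled by `1 / 2^(bits - 1)`.
#' @export
read_wav <- function(path, id = NULL, label = "unlabeled") {
  if (!file.exists(path)) hk_stop("decode_error", "file not found: %s", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) hk_stop("decode_error", "not a RIFF file: %s", path)
  readBin(con, "integer", 1, 4, endian = "little")  # chunk size, unused
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) hk_stop("decode_error", "not a WAVE file: %s", path)

  fmt <- NULL
  data_raw <- NULL
  repeat {
    cid <- readChar(con, 4, useBytes = TRUE)
    if (length(cid) == 0 || nchar(cid) < 4) break
    csize <- readBin(con, "integer", 1, 4, endian = "little")
    if (length(csize) == 0) break
    if (identical(cid, "fmt ")) {
      body <- readBin(con, "raw", csize)
      fmt <- list(
        format = readBin(body[1:2], "integer", 1, 2, signed = FALSE, endian = "little"),
        channels = readBin(body[3:4], "integer", 1, 2, signed = FALSE, endian = "little"),
        rate = readBin(body[5:8], "integer", 1, 4, endian = "little"),
        bits = readBin(body[15:16], "integer", 1, 2, signed = FALSE, endian = "little")
      )
      if (fmt$format == 65534L && csize >= 40) {  # extensible: subformat GUID
        fmt$format <- readBin(body[25:26], "integer", 1, 2, signed = FALSE,
                              endian = "little")
      }
    } else if (identical(cid, "data")) {
      data_raw <- readBin(con, "raw", csize)
    } else {
      seek(con, csize + csize %% 2, origin = "current")
      next
    }
    if (csize %% 2 == 1) readBin(con, "raw", 1)  # chunk padding byte
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt)) hk_stop("decode_error", "no fmt chunk in %s", path)
  if (is.null(data_raw) || length(data_raw) == 0) {
    hk_stop("empty_signal", "zero-length audio in %s", path)
  }

  bytes <- fmt$bits / 8
  n_total <- floor(length(data_raw) / bytes)
  if (n_total == 0) hk_stop("empty_signal", "zero-length audio in %s", path)
  x <- if (fmt$format == 1L) {
    if (fmt$bits == 8) {
      (as.numeric(readBin(data_raw, "integer", n_total, 1, signed = FALSE)) - 128) / 128
    } else if (fmt$bits == 16) {
      readBin(data_raw, "integer", n_total, 2, signed = TRUE, endian = "little") / 2^15
    } else if (fmt$bits == 24) {
      b <- as.integer(data_raw)
      i1 <- b[seq(1, 3 * n_total, 3)]
      i2 <- b[seq(2, 3 * n_total, 3)]
      i3 <- b[seq(3, 3 * n_total, 3)]
      v <- i1 + 256 * i2 + 65536 * i3
      v <- ifelse(v >= 2^23, v - 2^24, v)
      v / 2^23
    } else if (fmt$bits == 32) {
      readBin(data_raw, "integer", n_total, 4, signed = TRUE, endian = "little") / 2^31
    } else {
      hk_stop("decode_error", "unsupported PCM bit depth %d", fmt$bits)
    }
  } else if (fmt$format == 3L) {
    readBin(data_raw, "double", n_total, bytes, endian = "little")
  } else {
    hk_stop("decode_error", "unsupported WAV format code %d", fmt$format)
  }

  if (fmt$channels > 1) {
    n_frames <- floor(length(x) / fmt$channels)
    x <- colMeans(matrix(x[seq_len(n_frames * fmt$channels)], nrow = fmt$channels))
  }
  if (length(x) == 0) hk_stop("empty_signal", "zero-length audio in %s", path)
  if (is.null(id)) id <- tools::file_path_sans_ext(basename(path))
  pcg_recording(x, fmt$rate, id = id, label = label)
}

#' Write a recording (or multichannel matrix) to a WAV file
#'
#' @param rec A [pcg_recording()], a numeric vector, or a channels-by-samples
#'   numeric matrix (multichannel).
#' @param path Output path.
#' @param sample_rate Required when `rec` is not a `pcg_recording`.
#' @param bits 16 (PCM) or 32 (IEEE float).
#' @return `path`, invisibly.
#' @export
write_wav <- function(rec, path, sample_rate = NULL, bits = 16) {
  if (inherits(rec, "pcg_recording")) {
    x <- matrix(rec$samples, nrow = 1)
    sample_rate <- rec$sample_rate
  } else if (is.matrix(rec)) {
    x <- rec
  } else {
    x <- matrix(as.numeric(rec), nrow = 1)
  }
  if (is.null(sample_rate)) hk_stop("decode_error", "sample_rate required")
  channels <- nrow(x)
  interleaved <- as.numeric(x)  # column-major = frame-interleaved
  if (!bits %in% c(16, 32)) hk_stop("decode_error", "bits must be 16 or 32")
  fmt_code <- if (bits == 16) 1L else 3L
  bytes <- bits / 8
  data_size <- length(interleaved) * bytes

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(fmt_code, con, 2, endian = "little")
  writeBin(as.integer(channels), con, 2, endian = "little")
  writeBin(as.integer(sample_rate), con, 4, endian = "little")
  writeBin(as.integer(sample_rate * channels * bytes), con, 4, endian = "little")
  writeBin(as.integer(channels * bytes), con, 2, endian = "little")
  writeBin(as.integer(bits), con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, 4, endian = "little")
  if (bits == 16) {
    q <- as.integer(round(pmax(pmin(interleaved, 1), -1) * (2^15 - 1)))
    writeBin(q, con, 2, endian = "little")
  } else {
    writeBin(interleaved, con, 4, endian = "little")
  }
  invisible(path)
}

# ---- Resampling and normalization ------------------------------------------

#' Resample a recording with polyphase anti-aliased conversion
#'
#' @param rec A [pcg_recording()].
#' @param target_rate Target rate in Hz (positive integer).
#' @param allow_upsample Emit a warning (not an error) when raising the rate
#'   without this flag.
#' @return The recording at `target_rate`; output length is
#'   `round(n * target_rate / sample_rate)`. Returned unchanged when already
#'   at the target rate.
#' @export
resample_recording <- function(rec, target_rate, allow_upsample = FALSE) {
  stopifnot(inherits(rec, "pcg_recording"))
  if (target_rate <= 0) hk_stop("decode_error", "target_rate must be positive")
  if (target_rate == rec$sample_rate) return(rec)
  if (target_rate > rec$sample_rate && !allow_upsample) {
    hk_warn("upsample", "target rate %g above native rate %g; upsampling",
            target_rate, rec$sample_rate)
  }
  g <- .gcd(round(target_rate), round(rec$sample_rate))
  p <- round(target_rate) / g
  q <- round(rec$sample_rate) / g
  y <- signal::resample(rec$samples, p, q)
  n_out <- round(length(rec$samples) * target_rate / rec$sample_rate)
  if (length(y) >= n_out) y <- y[seq_len(n_out)] else y <- c(y, numeric(n_out - length(y)))
  pcg_recording(y, target_rate, id = rec$id, label = rec$label)
}

.gcd <- function(a, b) if (b == 0) a else .gcd(b, a %% b)

#' Normalize a recording to unit peak amplitude
#'
#' Divides every sample by `max(|s|)` so the peak magnitude is exactly 1.
#'
#' @param rec A [pcg_recording()].
#' @return The normalized recording.
#' @export
normalize_amplitude <- function(rec) {
  stopifnot(inherits(rec, "pcg_recording"))
  peak <- max(abs(rec$samples))
  if (peak == 0) hk_stop("silent_signal", "all-zero signal cannot be normalized")
  pcg_recording(rec$samples / peak, rec$sample_rate, id = rec$id, label = rec$label)
}

# ---- Dataset manifests ------------------------------------------------------

.manifest_splits <- c("A", "B", "noisy_murmur", "noisy_normal")

#' Read a dataset manifest
#'
#' A CSV with columns `split,label,path` (file manifest) or
#' `split,label,count` (count-only manifest). Splits follow the public
#' heart-sound challenge layout: training sets `A` and `B` plus the
#' `noisy_murmur` / `noisy_normal` folders.
#'
#' @param path CSV path.
#' @return A `data.frame` manifest.
#' @export
read_manifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_manifest(m)
  m
}

validate_manifest <- function(m) {
  if (!all(c("split", "label") %in% names(m)) ||
      !any(c("path", "count") %in% names(m))) {
    hk_stop("manifest_error",
            "manifest needs columns split,label and one of path,count")
  }
  bad <- setdiff(unique(m$split), .manifest_splits)
  if (length(bad)) {
    hk_stop("manifest_error", "unknown split label(s): %s",
            paste(bad, collapse = ", "))
  }
  if ("count" %in% names(m) && any(m$count < 0)) {
    hk_stop("manifest_error", "counts must be non-negative")
  }
  invisible(m)
}

#' Merge a split manifest into per-class totals
#'
#' Applies the challenge-corpus merge rules: `normal = A + B` (the
#' `noisy_normal` folder is excluded), `murmur = A + B + noisy_murmur`,
#' `extrasystole = A + B`.
#'
#' @param manifest A manifest `data.frame` (see [read_manifest()]).
#' @return A `data.frame` with columns `label` and `count` giving merged
#'   class totals.
#' @export
merge_manifest <- function(manifest) {
  validate_manifest(manifest)
  counts <- if ("count" %in% names(manifest)) manifest$count else rep(1L, nrow(manifest))
  contributing <- list(
    normal = c("A", "B"),
    murmur = c("A", "B", "noisy_murmur"),
    extrasystole = c("A", "B")
  )
  totals <- vapply(names(contributing), function(lab) {
    sel <- manifest$label == lab & manifest$split %in% contributing[[lab]]
    sum(counts[sel])
  }, numeric(1))
  data.frame(label = names(contributing), count = as.integer(totals),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-class segment accounting totals
#'
#' Sums selected and ignored segment counts into per-class totals, the
#' bookkeeping used when reporting how many heart-cycle segments the
#' selection step kept and discarded.
#'
#' @param accounting A `data.frame` with columns `label`, `selected`,
#'   `ignored`.
#' @return The input with a `total = selected + ignored` column appended.
#' @export
segment_accounting <- function(accounting) {
  need <- c("label", "selected", "ignored")
  if (!all(need %in% names(accounting))) {
    hk_stop("manifest_error", "accounting needs columns label,selected,ignored")
  }
  if (any(accounting$selected < 0) || any(accounting$ignored < 0)) {
    hk_stop("manifest_error", "segment counts must be non-negative")
  }
  accounting$total <- accounting$selected + accounting$ignored
  accounting
}
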