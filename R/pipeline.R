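#' Default run configuration
#'
#' A nested list covering every pipeline stage, serializable to a single
#' JSON document. The global `seed` fans out to per-stage seeds by fixed
#' offsets (selection: seed + 101, training: seed + 202, synthesis:
#' seed + 303) so each stage is individually reproducible from one knob.
#'
#' @return Nested configuration list of class `run_config`.
#' @export
default_config <- function() {
  structure(list(
    seed = 13,
    out_dir = ".",
    save_images = FALSE,
    io = list(target_rate = 2000),
    filter = list(kind = "bandpass", order = 4, low_cut = 25, high_cut = 600,
                  zero_phase = TRUE),
    wavelet = list(family_order = 6, levels = 5, f = 1.0,
                   keep_mode = "above", magnitude = TRUE),
    envelope = list(frame_len = 40, hop = 20),
    period = list(min_period = 0.4, max_period = 1.6),
    mfcc = list(window_len = 1024, hop = 512, n_fft = 1024, n_mels = 26,
                n_coeffs = 13, window = "hamming"),
    selection = list(enabled = TRUE, per_class = TRUE, tol = 1e-6,
                     max_iter = 200, n_init = 5),
    train = list(backend = "logistic_baseline", learning_rate = 1e-4,
                 momentum = 0, batch_size = 5, epochs = 100, folds = 3,
                 n_filters = 8),
    synth = list(duration = 10, bpm = 75, s1_freq = 40, s2_freq = 60,
                 s1_width = 0.07, s2_width = 0.05, s1_amp = 1, s2_amp = 0.7,
                 systole_fraction = 0.35, murmur_level = 0.4,
                 extrasystole_prob = 0.25, premature_fraction = 0.5,
                 snr_db = 20, sample_rate = 2000)
  ), class = "run_config")
}

merge_config <- function(defaults, doc, path = "$") {
  if (is.null(doc)) return(defaults)
  unknown <- setdiff(names(doc), names(defaults))
  if (length(unknown)) {
    hk_stop("config_error", "unknown config key(s) at %s: %s",
            path, paste(unknown, collapse = ", "))
  }
  for (nm in names(doc)) {
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]]))) {
      if (!is.list(doc[[nm]])) {
        hk_stop("config_error", "%s.%s must be an object", path, nm)
      }
      defaults[[nm]] <- merge_config(defaults[[nm]], doc[[nm]],
                                     paste0(path, ".", nm))
    } else {
      defaults[[nm]] <- doc[[nm]]
    }
  }
  defaults
}

#' Validate a configuration document
#'
#' Fills defaults for missing keys, rejects unknown keys, and checks the
#' cross-field invariants; violations are reported with their JSON path.
#'
#' @param doc A (possibly partial) configuration list, e.g. parsed from
#'   JSON with `jsonlite::fromJSON(..., simplifyVector = TRUE)`. `NULL` or
#'   an empty list yields the full default configuration.
#' @return A complete `run_config`.
#' @export
validate_config <- function(doc = NULL) {
  cfg <- merge_config(default_config(), doc)
  if (cfg$train$folds < 2) hk_stop("config_error", "$.train.folds must be >= 2")
  if (cfg$train$epochs < 1) hk_stop("config_error", "$.train.epochs must be >= 1")
  if (cfg$io$target_rate <= 0) hk_stop("config_error", "$.io.target_rate must be positive")
  if (cfg$synth$bpm < 30 || cfg$synth$bpm > 200) {
    hk_stop("config_error", "$.synth.bpm must be in [30, 200]")
  }
  if (!cfg$train$backend %in% c("logistic_baseline", "small_cnn",
                                "external_pretrained")) {
    hk_stop("config_error", "$.train.backend is not a known backend")
  }
  if (cfg$wavelet$levels < 1) hk_stop("config_error", "$.wavelet.levels must be >= 1")
  if (cfg$mfcc$n_coeffs > cfg$mfcc$n_mels) {
    hk_stop("config_error", "$.mfcc.n_coeffs must be <= $.mfcc.n_mels")
  }
  structure(cfg, class = "run_config")
}

#' Read and validate a JSON run configuration
#' @param path JSON file path.
#' @return A complete `run_config`.
#' @export
read_config <- function(path) {
  validate_config(jsonlite::fromJSON(path, simplifyVector = TRUE))
}

synth_config_from <- function(cfg, seed) {
  do.call(synth_config, c(cfg$synth, list(seed = seed)))
}

#' Run the full screening pipeline
#'
#' Executes denoise, resample, normalize, segment, MFCC features, mixture
#' selection and k-fold train/evaluate in order, persisting intermediates
#' and a JSON-lines stage log under `cfg$out_dir` (when not `NULL`). The
#' pipeline is deterministic: the same configuration, seed and corpus give
#' a byte-identical report.
#'
#' @param cfg A `run_config` (see [validate_config()]).
#' @param manifest Either a manifest `data.frame` with columns
#'   `split,label,path` (paths resolved against `manifest_dir`) or a named
#'   list of [pcg_recording()] objects.
#' @param manifest_dir Directory WAV paths are relative to.
#' @return A list with `report` (an `evaluation_report`), `segments`,
#'   `features`, `selection` and `stage_counts`.
#' @export
run_pipeline <- function(cfg = validate_config(), manifest,
                         manifest_dir = ".") {
  stopifnot(inherits(cfg, "run_config"))
  out_dir <- cfg$out_dir
  persist <- !is.null(out_dir) && nzchar(out_dir)
  if (persist) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  log_stage <- function(stage, ...) {
    rec <- c(list(stage = stage), list(...))
    log_lines <<- c(log_lines, jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA))
  }
  stage_guard <- function(stage, item, expr) {
    tryCatch(expr, error = function(e) {
      hk_stop("pipeline_error", "stage '%s' failed for item '%s': %s",
              stage, item, conditionMessage(e))
    })
  }

  # ---- ingest ---------------------------------------------------------------
  recordings <- if (is.data.frame(manifest)) {
    validate_manifest(manifest)
    recs <- lapply(seq_len(nrow(manifest)), function(i) {
      stage_guard("ingest", manifest$path[i],
                  read_wav(file.path(manifest_dir, manifest$path[i]),
                           label = manifest$label[i]))
    })
    stats::setNames(recs, vapply(recs, `[[`, character(1), "id"))
  } else {
    manifest
  }
  log_stage("ingest", recordings = length(recordings))

  fspec <- do.call(filter_spec, cfg$filter)
  wcfg <- do.call(wavelet_config, cfg$wavelet)
  mcfg <- do.call(mfcc_config, cfg$mfcc)

  # ---- per-recording preprocessing + segmentation ---------------------------
  segments <- list()
  seg_meta <- list()
  for (rec_id in names(recordings)) {
    rec <- recordings[[rec_id]]
    rec <- stage_guard("denoise", rec_id, iir_denoise(rec, fspec))
    rec <- stage_guard("resample", rec_id,
                       resample_recording(rec, cfg$io$target_rate))
    rec <- stage_guard("normalize", rec_id, normalize_amplitude(rec))
    sp <- stage_guard("segment", rec_id, segment_pipeline(
      rec, wavelet = wcfg,
      frame_len = cfg$envelope$frame_len, hop = cfg$envelope$hop,
      min_period = cfg$period$min_period, max_period = cfg$period$max_period))
    for (s in sp$segments) segments[[length(segments) + 1]] <- s
    seg_meta[[rec_id]] <- list(
      recording = rec_id, n_segments = length(sp$segments),
      period_seconds = sp$cycle$period_seconds,
      confidence = sp$cycle$confidence)
  }
  log_stage("segment", recordings = length(recordings),
            segments = length(segments))
  if (persist) {
    jsonlite::write_json(seg_meta, file.path(out_dir, "segments.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  # ---- features -------------------------------------------------------------
  feats <- t(vapply(segments,
                    function(s) summarize_segment_features(mfcc(s, mcfg)),
                    numeric(2 * mcfg$n_coeffs)))
  seg_ids <- vapply(segments, seg_id, character(1))
  rownames(feats) <- seg_ids
  seg_labels <- vapply(segments, `[[`, character(1), "label")
  seg_recs <- vapply(segments, `[[`, character(1), "recording_id")
  log_stage("features", segments = length(segments), dims = ncol(feats))
  if (persist) {
    utils::write.csv(
      data.frame(segment = seg_ids, recording = seg_recs, label = seg_labels,
                 feats, check.names = FALSE),
      file.path(out_dir, "features.csv"), row.names = FALSE)
  }
  if (persist && isTRUE(cfg$save_images)) {
    img_dir <- file.path(out_dir, "images")
    dir.create(img_dir, showWarnings = FALSE)
    for (i in seq_along(segments)) {
      write_spectrogram_png(render_png(mfcc(segments[[i]], mcfg)),
                            file.path(img_dir, paste0(seg_ids[i], ".png")))
    }
  }

  # ---- selection ------------------------------------------------------------
  if (isTRUE(cfg$selection$enabled) && length(segments) >= 2) {
    sel_seed <- cfg$seed + 101
    if (isTRUE(cfg$selection$per_class)) {
      kept_ids <- character(0); ignored_ids <- character(0)
      for (cls in sort(unique(seg_labels))) {
        in_cls <- seg_labels == cls
        if (sum(in_cls) < 2) { kept_ids <- c(kept_ids, seg_ids[in_cls]); next }
        sel <- select_segments(feats[in_cls, , drop = FALSE], seed = sel_seed)
        kept_ids <- c(kept_ids, sel$kept)
        ignored_ids <- c(ignored_ids, sel$ignored)
      }
    } else {
      sel <- select_segments(feats, seed = sel_seed)
      kept_ids <- sel$kept; ignored_ids <- sel$ignored
    }
  } else {
    kept_ids <- seg_ids; ignored_ids <- character(0)
  }
  keep_mask <- seg_ids %in% kept_ids
  log_stage("selection", produced = length(segments),
            kept = sum(keep_mask), ignored = sum(!keep_mask))
  if (persist) {
    jsonlite::write_json(list(kept = seg_ids[keep_mask],
                              ignored = seg_ids[!keep_mask]),
                         file.path(out_dir, "selection.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  # ---- train / evaluate -----------------------------------------------------
  tr_labels <- seg_labels[keep_mask]
  tr_recs <- seg_recs[keep_mask]
  tcfg <- do.call(train_config, c(cfg$train, list(seed = cfg$seed + 202)))
  use_images <- tcfg$backend == "small_cnn"
  tr_x <- if (use_images) {
    kept_segments <- segments[keep_mask]
    lapply(kept_segments, function(s) render_png(mfcc(s, mcfg)))
  } else {
    feats[keep_mask, , drop = FALSE]
  }
  folds <- kfold_split(tr_labels, tr_recs, folds = tcfg$folds, seed = tcfg$seed)
  fold_reports <- lapply(seq_along(folds), function(f) {
    tr <- folds[[f]]$train; va <- folds[[f]]$validation
    xtr <- if (use_images) tr_x[tr] else tr_x[tr, , drop = FALSE]
    xva <- if (use_images) tr_x[va] else tr_x[va, , drop = FALSE]
    model <- stage_guard("train", sprintf("fold%d", f),
                         train_backend(xtr, tr_labels[tr], tcfg))
    cm <- stage_guard("evaluate", sprintf("fold%d", f),
                      evaluate(model, xva, tr_labels[va]))
    compute_metrics(cm)
  })
  report <- aggregate_folds(fold_reports)
  log_stage("evaluate", folds = length(folds),
            classes_avg_accuracy = report$classes_avg[["accuracy"]])

  if (persist) {
    jsonlite::write_json(
      list(fold_avg = report$fold_avg,
           classes_avg = as.list(report$classes_avg),
           overall_accuracy = report$overall_accuracy,
           table = report_table(report)),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
    utils::write.csv(report_table(report), file.path(out_dir, "report.csv"),
                     row.names = FALSE)
    writeLines(log_lines, file.path(out_dir, "run_log.jsonl"))
  }

  list(report = report,
       segments = segments,
       features = feats,
       selection = list(kept = seg_ids[keep_mask], ignored = seg_ids[!keep_mask]),
       stage_counts = list(recordings = length(recordings),
                           segments_produced = length(segments),
                           segments_kept = sum(keep_mask),
                           segments_ignored = sum(!keep_mask)))
}
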