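#' Training configuration
#'
#' Defaults follow the reference training setup: SGD with learning rate
#' 1e-4, momentum 0 (the optimizer's default), batch size 5, 100 epochs and
#' 3 cross-validation folds.
#'
#' @param backend `"logistic_baseline"`, `"small_cnn"` or
#'   `"external_pretrained"`.
#' @param learning_rate SGD learning rate. Default 1e-4.
#' @param momentum SGD momentum. Default 0.
#' @param batch_size Mini-batch size. Default 5.
#' @param epochs Training epochs (>= 1). Default 100.
#' @param folds Cross-validation folds (>= 2). Default 3.
#' @param seed RNG seed. Default 13.
#' @param n_filters Trunk filters for the small CNN. Default 8.
#' @param trunk_size Input size `c(height, width)` the small CNN downscales
#'   images to. Default `c(48, 64)`.
#' @return An object of class `train_config`.
#' @export
train_config <- function(backend = c("logistic_baseline", "small_cnn",
                                     "external_pretrained"),
                         learning_rate = 1e-4, momentum = 0, batch_size = 5,
                         epochs = 100, folds = 3, seed = 13,
                         n_filters = 8, trunk_size = c(48, 64)) {
  backend <- match.arg(backend)
  if (folds < 2) hk_stop("config_error", "folds must be >= 2")
  if (epochs < 1) hk_stop("config_error", "epochs must be >= 1")
  structure(
    list(backend = backend, learning_rate = learning_rate, momentum = momentum,
         batch_size = batch_size, epochs = epochs, folds = folds, seed = seed,
         n_filters = n_filters, trunk_size = trunk_size),
    class = "train_config"
  )
}

#' Stratified, recording-grouped k-fold partitions
#'
#' Items (heart-cycle segments) are grouped by their source recording so no
#' recording's cycles straddle a train/validation boundary, then recordings
#' are stratified by class and dealt round-robin into folds after a seeded
#' shuffle.
#'
#' @param labels Character vector of item class labels.
#' @param recording_ids Character vector of item source-recording ids.
#' @param folds Number of folds (>= 2).
#' @param seed RNG seed; identical seeds give identical splits.
#' @return A list of `folds` elements, each `list(train, validation)` of
#'   item indices. The validation sets partition `seq_along(labels)`.
#' @export
kfold_split <- function(labels, recording_ids = NULL, folds = 3, seed = 13) {
  n <- length(labels)
  if (is.null(recording_ids)) recording_ids <- as.character(seq_len(n))
  stopifnot(length(recording_ids) == n)
  rec_label <- tapply(labels, recording_ids, function(l) l[1])
  recs <- names(rec_label)
  fold_of <- stats::setNames(integer(length(recs)), recs)
  hk_with_seed(seed, {
    for (cls in sort(unique(as.character(rec_label)))) {
      members <- recs[rec_label == cls]
      if (length(members) < folds) {
        hk_stop("stratification_error",
                "class '%s' has %d recording(s), need at least %d",
                cls, length(members), folds)
      }
      members <- sample(members)
      fold_of[members] <- rep_len(seq_len(folds), length(members))
    }
  })
  item_fold <- unname(fold_of[recording_ids])
  lapply(seq_len(folds), function(f) {
    list(train = which(item_fold != f), validation = which(item_fold == f))
  })
}

#' Train a classification backend
#'
#' * `logistic_baseline` — multinomial logistic regression
#'   (`nnet::multinom`) on segment summary-feature vectors.
#' * `small_cnn` — a compact convolutional network: one 3x3 convolution
#'   (stride 2, ReLU) over downscaled spectrogram images, global average
#'   pooling, dense 1024 and dense 512 (ReLU) layers and a softmax output,
#'   trained by mini-batch SGD with the configured learning rate and
#'   momentum.
#' * `external_pretrained` — adapter hook: supply `external_fn(x, y, cfg)`
#'   returning an object with a `predict(model, x)` method.
#'
#' @param x Feature matrix (logistic) or list of `spectrogram_image` /
#'   pixel arrays (CNN).
#' @param y Item labels (character or factor).
#' @param cfg A [train_config()].
#' @param external_fn Optional training function for the
#'   `external_pretrained` backend.
#' @return An object of class `heartkit_model`.
#' @export
train_backend <- function(x, y, cfg = train_config(), external_fn = NULL) {
  y <- as.character(y)
  classes <- sort(unique(y))
  if (length(classes) < 2) {
    hk_stop("training_error", "training set has a single class: %s", classes)
  }
  fit <- switch(cfg$backend,
    logistic_baseline = {
      X <- as.matrix(x)
      df <- data.frame(X)
      df$.y <- factor(y, levels = classes)
      hk_with_seed(cfg$seed,
        nnet::multinom(.y ~ ., data = df, trace = FALSE, maxit = 500,
                       MaxNWts = 100000))
    },
    small_cnn = cnn_train(x, y, classes, cfg),
    external_pretrained = {
      if (is.null(external_fn)) {
        hk_stop("training_error",
                "external_pretrained backend needs an external_fn adapter")
      }
      external_fn(x, y, cfg)
    }
  )
  structure(list(backend = cfg$backend, fit = fit, classes = classes, cfg = cfg),
            class = "heartkit_model")
}

#' Predict class labels with a trained model
#' @param object A `heartkit_model`.
#' @param newdata Features in the backend's input form.
#' @param ... Unused.
#' @return Character vector of predicted labels.
#' @export
predict.heartkit_model <- function(object, newdata, ...) {
  switch(object$backend,
    logistic_baseline = {
      df <- data.frame(as.matrix(newdata))
      as.character(stats::predict(object$fit, newdata = df))
    },
    small_cnn = cnn_predict(object$fit, newdata, object$classes),
    external_pretrained = as.character(stats::predict(object$fit, newdata))
  )
}

#' Evaluate a model on a validation set
#'
#' @param model A trained `heartkit_model`.
#' @param x Validation features.
#' @param y True labels; every label must be known to the model.
#' @return An object of class `confusion_matrix`: `counts` (true x
#'   predicted) and `class_names`.
#' @export
evaluate <- function(model, x, y) {
  y <- as.character(y)
  unseen <- setdiff(unique(y), model$classes)
  if (length(unseen)) {
    hk_stop("label_error", "unseen class label(s): %s", paste(unseen, collapse = ", "))
  }
  pred <- predict(model, x)
  cls <- model$classes
  counts <- table(factor(y, levels = cls), factor(pred, levels = cls))
  structure(list(counts = unclass(as.matrix(counts)), class_names = cls),
            class = "confusion_matrix")
}

#' Per-class and micro metrics of a confusion matrix
#'
#' For each class `c`, one-vs-rest: sensitivity `TPR = TP/(TP+FN)`, precision
#' `PPV = TP/(TP+FP)`, specificity `TNR = TN/(TN+FP)` and binarized accuracy
#' `(TP+TN)/total`. Ratios with a zero denominator are reported as `NA`
#' (absent), never coerced to 0. Micro values are the unweighted mean of the
#' defined per-class values. The plain multiclass accuracy
#' (`trace / total`) is reported separately as `overall_accuracy`.
#'
#' @param cm A `confusion_matrix`.
#' @return A list with `per_class` (data frame of accuracy/TPR/PPV/TNR),
#'   `micro` (named vector) and `overall_accuracy`.
#' @export
compute_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  counts <- cm$counts
  total <- sum(counts)
  if (total == 0) hk_stop("empty_input", "empty confusion matrix")
  K <- nrow(counts)
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  per <- lapply(seq_len(K), function(c) {
    TP <- counts[c, c]
    FN <- sum(counts[c, ]) - TP
    FP <- sum(counts[, c]) - TP
    TN <- total - TP - FN - FP
    data.frame(class = cm$class_names[c],
               accuracy = (TP + TN) / total,
               tpr = ratio(TP, TP + FN),
               ppv = ratio(TP, TP + FP),
               tnr = ratio(TN, TN + FP),
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  micro <- vapply(c("accuracy", "tpr", "ppv", "tnr"),
                  function(m) mean(per[[m]], na.rm = TRUE), numeric(1))
  list(per_class = per, micro = micro,
       overall_accuracy = sum(diag(counts)) / total)
}

#' Aggregate per-fold metric reports
#'
#' Takes the unweighted mean of each per-class metric across folds (the
#' "folds average"), then averages across classes (the "classes average").
#' `NA` entries (undefined ratios) are omitted from the means.
#'
#' @param reports List of [compute_metrics()] results, one per fold.
#' @return An object of class `evaluation_report` with `per_fold`,
#'   `fold_avg` (per-class data frame) and `classes_avg` (named vector of
#'   micro metrics).
#' @export
aggregate_folds <- function(reports) {
  if (length(reports) < 1) hk_stop("empty_input", "no fold reports")
  metrics <- c("accuracy", "tpr", "ppv", "tnr")
  classes <- reports[[1]]$per_class$class
  fold_avg <- data.frame(class = classes, stringsAsFactors = FALSE)
  for (m in metrics) {
    vals <- sapply(reports, function(r) r$per_class[[m]])
    vals <- matrix(vals, nrow = length(classes))
    fold_avg[[m]] <- apply(vals, 1, mean, na.rm = TRUE)
  }
  classes_avg <- vapply(metrics, function(m) mean(fold_avg[[m]], na.rm = TRUE),
                        numeric(1))
  structure(
    list(per_fold = reports, fold_avg = fold_avg, classes_avg = classes_avg,
         overall_accuracy = mean(vapply(reports, `[[`, numeric(1),
                                        "overall_accuracy"))),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("Evaluation report (", length(x$per_fold), "folds )\n")
  print(x$fold_avg, row.names = FALSE, digits = 3)
  cat("Classes avg:",
      paste(sprintf("%s=%.3f", names(x$classes_avg), x$classes_avg),
            collapse = "  "), "\n")
  invisible(x)
}

#' Serialize an evaluation report as a metrics table
#'
#' One row per fold per class plus the folds-average and classes-average
#' rows, columns `fold, class, accuracy, tpr, ppv, tnr`.
#'
#' @param report An `evaluation_report`.
#' @return A data frame.
#' @export
report_table <- function(report) {
  rows <- list()
  for (f in seq_along(report$per_fold)) {
    pc <- report$per_fold[[f]]$per_class
    pc <- cbind(fold = sprintf("fold%d", f), pc)
    rows[[length(rows) + 1]] <- pc
  }
  fa <- cbind(fold = "folds_avg", report$fold_avg)
  rows[[length(rows) + 1]] <- fa
  ca <- data.frame(fold = "classes_avg", class = "all",
                   accuracy = report$classes_avg[["accuracy"]],
                   tpr = report$classes_avg[["tpr"]],
                   ppv = report$classes_avg[["ppv"]],
                   tnr = report$classes_avg[["tnr"]],
                   stringsAsFactors = FALSE)
  rows[[length(rows) + 1]] <- ca
  do.call(rbind, rows)
}
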