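test_that("stratified folds partition items one-per-class at the boundary", {
  labels <- rep(c("a", "b", "c"), each = 3)
  folds <- kfold_split(labels, folds = 3, seed = 1)
  for (f in folds) {
    expect_length(f$validation, 3)
    expect_setequal(labels[f$validation], c("a", "b", "c"))
  }
  all_val <- sort(unlist(lapply(folds, `[[`, "validation")))
  expect_equal(all_val, seq_along(labels))
  expect_length(unique(unlist(lapply(folds, `[[`, "validation"))), 9)
})

test_that("folds are deterministic in the seed and recording-grouped", {
  labels <- rep(c("normal", "murmur"), each = 12)
  recs <- rep(sprintf("r%02d", 1:8), each = 3)
  f1 <- kfold_split(labels, recs, folds = 3, seed = 42)
  f2 <- kfold_split(labels, recs, folds = 3, seed = 42)
  expect_identical(f1, f2)
  for (f in f1) {
    expect_length(intersect(recs[f$train], recs[f$validation]), 0)
  }
  expect_error(kfold_split(c("a", "a", "b"), folds = 3, seed = 1),
               class = "heartkit_stratification_error")
})

test_that("the logistic baseline separates linearly separable classes", {
  set.seed(10)
  X <- rbind(matrix(stats::rnorm(40, -3), 20, 2),
             matrix(stats::rnorm(40, 3), 20, 2))
  y <- rep(c("neg", "pos"), each = 20)
  cfg <- train_config(backend = "logistic_baseline", seed = 2)
  model <- train_backend(X, y, cfg)
  expect_equal(predict(model, X), y)
  model2 <- train_backend(X, y, cfg)
  expect_identical(predict(model2, X), predict(model, X))
  expect_error(train_backend(X, rep("one", 40), cfg),
               class = "heartkit_training_error")
})

test_that("confusion matrices count true by predicted with conservation", {
  set.seed(11)
  X <- rbind(matrix(stats::rnorm(30, -3), 15, 2),
             matrix(stats::rnorm(30, 3), 15, 2))
  y <- rep(c("neg", "pos"), each = 15)
  model <- train_backend(X, y, train_config(seed = 3))
  cm <- evaluate(model, X, y)
  expect_equal(sum(cm$counts), 30)
  expect_equal(cm$counts, diag(c(15, 15)), ignore_attr = TRUE)
  expect_error(evaluate(model, X, rep("mystery", 30)),
               class = "heartkit_label_error")
})

test_that("per-class metrics match hand-computed values", {
  cm <- structure(list(counts = matrix(c(8, 3, 2, 7), 2, 2),
                       class_names = c("c0", "c1")),
                  class = "confusion_matrix")
  # counts: true c0 -> (8 pred c0, 2 pred c1); true c1 -> (3 pred c0, 7 pred c1)
  met <- compute_metrics(cm)
  expect_equal(met$per_class$tpr, c(0.8, 0.7))
  expect_equal(met$per_class$ppv[1], 8 / 11)
  expect_equal(met$per_class$tnr[1], 0.7)
  expect_equal(met$per_class$accuracy, c(0.75, 0.75))
  expect_equal(met$overall_accuracy, 0.75)
  expect_true(all(unlist(met$per_class[-1]) >= 0 &
                    unlist(met$per_class[-1]) <= 1))

  perfect <- structure(list(counts = diag(c(4, 5, 6)),
                            class_names = c("a", "b", "c")),
                       class = "confusion_matrix")
  pm <- compute_metrics(perfect)
  expect_true(all(unlist(pm$per_class[-1]) == 1))
  expect_equal(unname(pm$micro), rep(1, 4))

  # constant predictor: one nonzero column; PPV undefined for silent classes
  const <- structure(list(counts = matrix(c(5, 5, 0, 0), 2, 2),
                          class_names = c("a", "b")),
                     class = "confusion_matrix")
  cmm <- compute_metrics(const)
  expect_true(is.na(cmm$per_class$ppv[2]))  # no predicted positives for b
  expect_equal(cmm$per_class$tpr, c(1, 0))
})

test_that("fold aggregation averages folds then classes", {
  mk <- function(acc) {
    structure(list(counts = matrix(round(c(acc, 1 - acc, 1 - acc, acc) * 10), 2),
                   class_names = c("x", "y")), class = "confusion_matrix")
  }
  r1 <- compute_metrics(mk(0.8))
  r2 <- compute_metrics(mk(0.9))
  agg <- aggregate_folds(list(r1, r2))
  expect_equal(agg$fold_avg$tpr, c(0.85, 0.85))

  same <- aggregate_folds(list(r1, r1))
  expect_equal(same$fold_avg$tpr, r1$per_class$tpr)
  expect_equal(same$classes_avg[["tpr"]], mean(r1$per_class$tpr))

  # double-loop oracle
  reports <- list(r1, r2)
  manual <- mean(vapply(c("x", "y"), function(cl) {
    mean(vapply(reports, function(r) {
      r$per_class$tpr[r$per_class$class == cl]
    }, numeric(1)))
  }, numeric(1)))
  expect_equal(agg$classes_avg[["tpr"]], manual)
})

test_that("the small CNN can overfit a tiny two-class image set", {
  set.seed(12)
  cfgs <- synth_config(duration = 1.6, bpm = 75, snr_db = 15, seed = 1)
  imgs <- list()
  y <- character(0)
  for (i in 1:10) {
    cfg_i <- synth_config(duration = 1.6, bpm = 75, snr_db = 15, seed = i)
    bn <- synth_beat(cfg_i, "normal")
    bm <- synth_beat(cfg_i, "murmur")
    imgs[[length(imgs) + 1]] <- render_png(mfcc(bn$samples, mfcc_config(),
                                                sample_rate = 2000))
    y <- c(y, "normal")
    imgs[[length(imgs) + 1]] <- render_png(mfcc(bm$samples, mfcc_config(),
                                                sample_rate = 2000))
    y <- c(y, "murmur")
  }
  tc <- train_config(backend = "small_cnn", learning_rate = 0.05,
                     epochs = 200, batch_size = 5, seed = 9)
  model <- train_backend(imgs, y, tc)
  expect_equal(mean(predict(model, imgs) == y), 1)
  model2 <- train_backend(imgs, y, tc)
  expect_identical(predict(model2, imgs), predict(model, imgs))
})
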