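# Small convolutional backend, implemented directly in R matrix code.
#
# Architecture: images are downscaled (nearest neighbor) to cfg$trunk_size,
# passed through one 3x3 convolution with stride 2 and ReLU, globally
# average-pooled to one value per filter, then through dense 1024 and dense
# 512 layers (ReLU) and a softmax output. Training is mini-batch SGD with
# momentum on the cross-entropy loss. Everything is deterministic given the
# config seed.

cnn_prep_image <- function(img, trunk_size) {
  px <- if (inherits(img, "spectrogram_image")) img$pixels else img
  d <- dim(px)
  h <- trunk_size[1]; w <- trunk_size[2]
  sr <- floor((seq_len(h) - 0.5) / h * d[1]) + 1L
  sc <- floor((seq_len(w) - 0.5) / w * d[2]) + 1L
  small <- px[sr, sc, , drop = FALSE]
  array(as.numeric(small) / 255, dim = c(h, w, 3))
}

# im2col for 3x3 stride-2 valid convolution: rows = output positions,
# cols = 27 patch values.
cnn_im2col <- function(img3) {
  d <- dim(img3)
  oh <- floor((d[1] - 3) / 2) + 1L
  ow <- floor((d[2] - 3) / 2) + 1L
  cols <- matrix(0, oh * ow, 27)
  j <- 0
  for (ch in 1:3) for (dc in 0:2) for (dr in 0:2) {
    j <- j + 1
    rows_idx <- seq(1 + dr, by = 2, length.out = oh)
    cols_idx <- seq(1 + dc, by = 2, length.out = ow)
    cols[, j] <- as.numeric(img3[rows_idx, cols_idx, ch])
  }
  cols
}

cnn_forward <- function(P_list, W, train_idx = NULL) {
  idx <- if (is.null(train_idx)) seq_along(P_list) else train_idx
  n <- length(idx)
  nf <- ncol(W$Wc)
  feats <- matrix(0, n, nf)
  conv_cache <- vector("list", n)
  for (i in seq_len(n)) {
    conv <- P_list[[idx[i]]] %*% W$Wc + rep(W$bc, each = nrow(P_list[[idx[i]]]))
    relu <- pmax(conv, 0)
    conv_cache[[i]] <- list(P = P_list[[idx[i]]], mask = conv > 0,
                            npos = nrow(conv))
    feats[i, ] <- colMeans(relu)
  }
  h1 <- pmax(feats %*% W$W1 + rep(W$b1, each = n), 0)
  h2 <- pmax(h1 %*% W$W2 + rep(W$b2, each = n), 0)
  logits <- h2 %*% W$W3 + rep(W$b3, each = n)
  mx <- apply(logits, 1, max)
  ex <- exp(logits - mx)
  probs <- ex / rowSums(ex)
  list(feats = feats, h1 = h1, h2 = h2, probs = probs, conv_cache = conv_cache)
}

cnn_init_weights <- function(nf, K) {
  he <- function(nin, nout) matrix(stats::rnorm(nin * nout, sd = sqrt(2 / nin)),
                                   nin, nout)
  list(Wc = he(27, nf), bc = numeric(nf),
       W1 = he(nf, 1024), b1 = numeric(1024),
       W2 = he(1024, 512), b2 = numeric(512),
       W3 = he(512, K), b3 = numeric(K))
}

cnn_train <- function(x, y, classes, cfg) {
  K <- length(classes)
  y_idx <- match(y, classes)
  hk_with_seed(cfg$seed, {
    P_list <- lapply(x, function(img) cnn_im2col(cnn_prep_image(img, cfg$trunk_size)))
    # widen the trunk if configured
    nf <- cfg$n_filters
    W <- cnn_init_weights(nf, K)
    V <- lapply(W, function(w) w * 0)
    n <- length(P_list)
    lr <- cfg$learning_rate; mom <- cfg$momentum
    for (epoch in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      for (start in seq(1, n, by = cfg$batch_size)) {
        batch <- ord[start:min(start + cfg$batch_size - 1, n)]
        fw <- cnn_forward(P_list, W, batch)
        b <- length(batch)
        Y <- matrix(0, b, K); Y[cbind(seq_len(b), y_idx[batch])] <- 1
        dlogits <- (fw$probs - Y) / b
        g <- list()
        g$W3 <- t(fw$h2) %*% dlogits; g$b3 <- colSums(dlogits)
        dh2 <- (dlogits %*% t(W$W3)) * (fw$h2 > 0)
        g$W2 <- t(fw$h1) %*% dh2; g$b2 <- colSums(dh2)
        dh1 <- (dh2 %*% t(W$W2)) * (fw$h1 > 0)
        g$W1 <- t(fw$feats) %*% dh1; g$b1 <- colSums(dh1)
        dfeats <- dh1 %*% t(W$W1)
        g$Wc <- matrix(0, 27, nf); g$bc <- numeric(nf)
        for (i in seq_len(b)) {
          cc <- fw$conv_cache[[i]]
          dconv <- matrix(rep(dfeats[i, ] / cc$npos, each = cc$npos),
                          cc$npos, nf) * cc$mask
          g$Wc <- g$Wc + t(cc$P) %*% dconv
          g$bc <- g$bc + colSums(dconv)
        }
        for (nm in names(W)) {
          V[[nm]] <- mom * V[[nm]] - lr * g[[nm]]
          W[[nm]] <- W[[nm]] + V[[nm]]
        }
      }
    }
    list(W = W, trunk_size = cfg$trunk_size)
  })
}

cnn_predict <- function(fit, x, classes) {
  P_list <- lapply(x, function(img) cnn_im2col(cnn_prep_image(img, fit$trunk_size)))
  fw <- cnn_forward(P_list, fit$W)
  classes[max.col(fw$probs, ties.method = "first")]
}
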