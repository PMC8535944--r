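#' Gaussian mixture parameter container
#'
#' @param weights Mixture weights, non-negative, summing to 1.
#' @param means `M x d` matrix of component means.
#' @param variances `M x d` matrix of per-dimension (diagonal) variances,
#'   all positive.
#' @return An object of class `gmm_params`.
#' @export
gmm_params <- function(weights, means, variances) {
  means <- rbind(means); variances <- rbind(variances)
  M <- length(weights)
  if (nrow(means) != M || nrow(variances) != M || any(dim(means) != dim(variances))) {
    hk_stop("shape_error", "weights, means and variances disagree in shape")
  }
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-8) {
    hk_stop("shape_error", "weights must be non-negative and sum to 1")
  }
  if (any(variances <= 0)) hk_stop("shape_error", "variances must be positive")
  structure(list(M = M, d = ncol(means), weights = weights, means = means,
                 variances = variances),
            class = "gmm_params")
}

# log N(x | mu, diag(sigma2)) for all components at once; X is n x d.
gmm_log_comp <- function(X, params) {
  n <- nrow(X)
  out <- matrix(0, n, params$M)
  for (k in seq_len(params$M)) {
    v <- params$variances[k, ]
    centered <- sweep(X, 2, params$means[k, ])
    out[, k] <- -0.5 * (sum(log(2 * pi * v)) +
                          rowSums(sweep(centered^2, 2, v, "/")))
  }
  out
}

#' Gaussian mixture density
#'
#' Evaluates `f(x) = sum_k pi_k N(x | mu_k, sigma2_k)` with diagonal
#' covariances.
#'
#' @param x Numeric vector of dimension `d` (or an `n x d` matrix).
#' @param params A [gmm_params()].
#' @return The density value(s), strictly positive.
#' @export
gmm_pdf <- function(x, params) {
  stopifnot(inherits(params, "gmm_params"))
  X <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  if (ncol(X) != params$d) {
    hk_stop("shape_error", "x has dimension %d, expected %d", ncol(X), params$d)
  }
  lc <- gmm_log_comp(X, params)
  dens <- as.numeric(exp(lc) %*% params$weights)
  if (length(dens) == 1) dens[1] else dens
}

# k-means++-style seeding: first center uniform, then distance-weighted.
kmeanspp_centers <- function(X, M) {
  n <- nrow(X)
  centers <- matrix(0, M, ncol(X))
  first <- sample.int(n, 1)
  centers[1, ] <- X[first, ]
  if (M > 1) {
    d2 <- rowSums(sweep(X, 2, centers[1, ])^2)
    for (k in 2:M) {
      probs <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      pick <- sample.int(n, 1, prob = probs)
      centers[k, ] <- X[pick, ]
      d2 <- pmin(d2, rowSums(sweep(X, 2, centers[k, ])^2))
    }
  }
  centers
}

em_once <- function(X, M, tol, max_iter, var_floor) {
  n <- nrow(X); d <- ncol(X)
  global_var <- pmax(apply(X, 2, stats::var) * (n - 1) / n, var_floor)
  params <- gmm_params(rep(1 / M, M), kmeanspp_centers(X, M),
                       matrix(rep(global_var, each = M), M, d))
  loglik <- numeric(0)
  reinit_used <- FALSE
  t_mat <- NULL
  for (it in seq_len(max_iter)) {
    # estimation: responsibilities via log-sum-exp
    lc <- sweep(gmm_log_comp(X, params), 2, log(params$weights), "+")
    mx <- apply(lc, 1, max)
    lse <- mx + log(rowSums(exp(lc - mx)))
    t_mat <- exp(lc - lse)
    loglik <- c(loglik, sum(lse))
    if (it > 1 && abs(loglik[it] - loglik[it - 1]) < tol) break
    # maximization
    nk <- colSums(t_mat)
    nk <- pmax(nk, 1e-12)
    weights <- nk / n
    means <- (t(t_mat) %*% X) / nk
    variances <- matrix(0, M, d)
    for (k in seq_len(M)) {
      centered <- sweep(X, 2, means[k, ])
      variances[k, ] <- colSums(t_mat[, k] * centered^2) / nk[k]
    }
    # a component has collapsed when it degenerates in every dimension that
    # carries variance at all (globally flat dimensions are just clamped)
    live_dims <- global_var > var_floor
    collapsed <- apply(variances, 1, function(v) {
      if (any(live_dims)) all(v[live_dims] < var_floor) else all(v < var_floor)
    })
    if (any(collapsed)) {
      if (reinit_used) {
        hk_stop("variance_collapse",
                "component variance collapsed twice during EM")
      }
      reinit_used <- TRUE
      for (k in which(collapsed)) {
        means[k, ] <- X[sample.int(n, 1), ]
        variances[k, ] <- global_var
        weights[k] <- 1 / M
      }
      weights <- weights / sum(weights)
    }
    variances <- pmax(variances, var_floor)
    params <- gmm_params(weights, means, variances)
  }
  hard <- max.col(t_mat, ties.method = "first")
  list(params = params,
       responsibilities = list(t = t_mat, hard_labels = hard),
       loglik = loglik)
}

#' Fit a Gaussian mixture by expectation-maximization
#'
#' Alternates the estimation step (responsibilities
#' `t(i,k) = pi_k N(x_i|theta_k) / sum_j pi_j N(x_i|theta_j)`) with the
#' maximization updates `pi_k = mean_i t(i,k)`,
#' `mu_k = sum_i t(i,k) x_i / sum_i t(i,k)` and the matching
#' responsibility-weighted variances, until the log-likelihood improvement
#' falls below `tol` or `max_iter` is reached. Components use diagonal
#' covariances. Initialization is k-means++-style seeding from the given
#' seed; `n_init` restarts are run and the best final log-likelihood kept.
#' A component whose variance collapses below `var_floor` is re-initialized
#' once; a second collapse raises an error.
#'
#' @param X Numeric matrix (items x features) with at least `M` distinct rows.
#' @param M Number of components (>= 1).
#' @param seed RNG seed for initialization.
#' @param tol Convergence tolerance on the log-likelihood. Default 1e-6.
#' @param max_iter Maximum EM iterations. Default 200.
#' @param n_init Number of random restarts. Default 5.
#' @param var_floor Variance floor. Default 1e-8.
#' @return A list with `params` ([gmm_params()]), `responsibilities`
#'   (`t` matrix and `hard_labels`), and `loglik` (per-iteration trace of
#'   the best run).
#' @export
em_fit <- function(X, M, seed = 1, tol = 1e-6, max_iter = 200, n_init = 5,
                   var_floor = 1e-8) {
  X <- as.matrix(X)
  if (M < 1) hk_stop("config_error", "M must be >= 1")
  if (nrow(unique(X)) < M) {
    hk_stop("config_error", "need at least M distinct rows to fit M components")
  }
  hk_with_seed(seed, {
    best <- NULL
    for (r in seq_len(n_init)) {
      fit <- em_once(X, M, tol, max_iter, var_floor)
      if (is.null(best) || max(fit$loglik) > max(best$loglik)) best <- fit
    }
    best
  })
}

#' Select heart-cycle segments by mixture biclustering
#'
#' Fits a two-component Gaussian mixture to the per-segment feature vectors
#' (z-scored per dimension first), hard-assigns each segment to its most
#' probable component, keeps every segment of the larger cluster and ignores
#' the smaller one — the working hypothesis being that the majority of
#' segments are mutually consistent while a noisy minority is not. An exact
#' size tie is resolved toward the cluster whose members have the higher
#' total log-density under their own component.
#'
#' @param features Items-by-features matrix (or data frame) of segment
#'   summary vectors; row names are used as segment ids.
#' @param seed RNG seed for the EM initialization.
#' @param ids Optional segment ids overriding row names.
#' @return An object of class `selection_result` with `kept`, `ignored`
#'   (segment ids), `kept_cluster`, `hard_labels` and the fitted `params`.
#'   With fewer than two segments, selection is skipped (all kept) with a
#'   warning.
#' @export
select_segments <- function(features, seed = 1, ids = NULL) {
  X <- as.matrix(features)
  n <- nrow(X)
  if (is.null(ids)) {
    ids <- if (!is.null(rownames(X))) rownames(X) else as.character(seq_len(n))
  }
  if (n < 2) {
    hk_warn("selection_skipped", "fewer than 2 segments; selection skipped")
    return(structure(list(kept = ids, ignored = character(0),
                          kept_cluster = 1L, hard_labels = rep(1L, n),
                          params = NULL),
                     class = "selection_result"))
  }
  mu <- colMeans(X)
  sdev <- apply(X, 2, stats::sd)
  live <- sdev > 0 & is.finite(sdev)
  if (!any(live)) {
    hk_warn("selection_skipped", "all feature dimensions constant; selection skipped")
    return(structure(list(kept = ids, ignored = character(0),
                          kept_cluster = 1L, hard_labels = rep(1L, n),
                          params = NULL),
                     class = "selection_result"))
  }
  Z <- sweep(sweep(X[, live, drop = FALSE], 2, mu[live]), 2, sdev[live], "/")
  fit <- em_fit(Z, M = 2, seed = seed)
  hard <- fit$responsibilities$hard_labels
  sizes <- tabulate(hard, nbins = 2)
  keep_k <- if (sizes[1] != sizes[2]) {
    which.max(sizes)
  } else {
    lc <- gmm_log_comp(Z, fit$params)
    scores <- vapply(1:2, function(k) sum(lc[hard == k, k]), numeric(1))
    which.max(scores)
  }
  structure(
    list(kept = ids[hard == keep_k], ignored = ids[hard != keep_k],
         kept_cluster = keep_k, hard_labels = hard, params = fit$params),
    class = "selection_result"
  )
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result: kept %d, ignored %d (cluster %d kept)>\n",
              length(x$kept), length(x$ignored), x$kept_cluster))
  invisible(x)
}
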