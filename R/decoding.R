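# Category decoding: preprocessing (z-scoring, whole-trial baseline, pooled
# PCA, running-average smoothing), regularized LDA with ROC-AUC scoring,
# fivefold cross-validated localizer decoding, wake-to-sleep temporal
# generalization with shuffled-label surrogates, and a channel searchlight.
#
# Pipeline order (audited through the history attribute):
#   baseline -> z-score -> pooled PCA -> smooth -> classify

#' Z-score epochs across trials
#'
#' For every channel x timepoint feature, subtracts the across-trial mean
#' and divides by the across-trial standard deviation (sample SD, n - 1).
#' Features with zero variance are set to 0 and counted in a warning.
#'
#' @param epochs an [epoch_set()] with at least 2 events.
#' @return z-scored `epoch_set`.
#' @export
zscore_epochs <- function(epochs) {
  d <- dim(epochs$data)
  if (d[1] < 2L) stop("z-scoring needs at least 2 trials")
  M <- matrix(epochs$data, d[1], d[2] * d[3])
  mu <- colMeans(M)
  sdv <- sqrt(colSums(sweep(M, 2L, mu, "-")^2) / (d[1] - 1L))
  zero <- sdv < 1e-12
  sdv[zero] <- 1
  Z <- sweep(sweep(M, 2L, mu, "-"), 2L, sdv, "/")
  if (any(zero)) {
    Z[, zero] <- 0
    warning(sum(zero), " zero-variance feature(s) set to 0")
  }
  out <- epochs
  out$data <- array(Z, dim = d)
  add_history(out, "zscore_epochs")
}

#' Whole-trial baseline correction
#'
#' Per trial and channel, subtracts the mean over `window` (the whole epoch
#' by default).
#'
#' @param epochs an [epoch_set()].
#' @param window length-2 numeric window in seconds, or `NULL` for the
#'   whole trial.
#' @return baseline-corrected `epoch_set`.
#' @export
baseline_correct <- function(epochs, window = NULL) {
  t <- epochs$times
  sel <- if (is.null(window)) seq_along(t)
         else which(t >= window[1] - 1e-9 & t <= window[2] + 1e-9)
  if (!length(sel)) stop("baseline window outside the epoch")
  d <- dim(epochs$data)
  bl <- rowMeans(matrix(epochs$data[, , sel, drop = FALSE], d[1] * d[2],
                        length(sel)))
  out <- epochs
  out$data <- epochs$data - array(bl, dim = d)
  add_history(out, sprintf("baseline_correct(%s)",
                           if (is.null(window)) "whole-trial"
                           else paste(window, collapse = ":")))
}

#' PCA on pooled wake and sleep data
#'
#' Estimates principal components on the channel-space samples of both
#' epoch sets pooled (every trial x timepoint contributes one observation),
#' retains the first `k` components and projects both sets into component
#' space.
#'
#' @param wake,sleep [epoch_set()]s sharing the channel axis; `sleep` may be
#'   `NULL` for a single-set PCA (e.g. localizer-only decoding).
#' @param k number of components to retain (default 30).
#' @return list of class `pooled_pca` with `rotation` (channels x k),
#'   `center`, `explained` (variance ratios, all components), and the
#'   transformed `wake` and `sleep` epoch sets (`sleep` `NULL` if absent).
#' @export
fit_pca_pooled <- function(wake, sleep = NULL, k = 30L) {
  if (!is.null(sleep) && !identical(wake$ch_names, sleep$ch_names))
    stop("wake and sleep epochs must share the same channels")
  dw <- dim(wake$data)
  nch <- dw[2]
  obs <- matrix(aperm(wake$data, c(1, 3, 2)), dw[1] * dw[3], nch)
  if (!is.null(sleep)) {
    ds <- dim(sleep$data)
    obs <- rbind(obs,
                 matrix(aperm(sleep$data, c(1, 3, 2)), ds[1] * ds[3], nch))
  }
  if (nrow(obs) <= k) stop("pooled sample count must exceed k")
  ctr <- colMeans(obs)
  obs <- sweep(obs, 2L, ctr, "-")
  cv <- crossprod(obs) / (nrow(obs) - 1L)
  eg <- eigen(cv, symmetric = TRUE)
  rank_ <- sum(eg$values > max(eg$values) * 1e-10)
  if (k > rank_) stop("k = ", k, " exceeds the rank (", rank_, ") of the data")
  rot <- eg$vectors[, seq_len(k), drop = FALSE]
  transform <- function(ep) {
    d <- dim(ep$data)
    M <- matrix(aperm(ep$data, c(1, 3, 2)), d[1] * d[3], nch)
    S <- sweep(M, 2L, ctr, "-") %*% rot
    out <- ep
    out$data <- aperm(array(S, dim = c(d[1], d[3], k)), c(1, 3, 2))
    out$ch_names <- sprintf("PC%02d", seq_len(k))
    add_history(out, sprintf("pca_pooled(k=%d)", k))
  }
  structure(list(rotation = rot, center = ctr,
                 explained = eg$values / sum(eg$values),
                 wake = transform(wake),
                 sleep = if (is.null(sleep)) NULL else transform(sleep)),
            class = "pooled_pca")
}

#' Back-project component epochs to sensor space
#'
#' @param epochs component-space [epoch_set()] produced by
#'   [fit_pca_pooled()].
#' @param pca the `pooled_pca` object.
#' @param ch_names sensor names to restore.
#' @return sensor-space `epoch_set`.
#' @export
backproject_pca <- function(epochs, pca, ch_names = NULL) {
  d <- dim(epochs$data)
  k <- ncol(pca$rotation)
  if (d[2] != k) stop("epochs are not in this PCA's component space")
  M <- matrix(aperm(epochs$data, c(1, 3, 2)), d[1] * d[3], k)
  X <- sweep(M %*% t(pca$rotation), 2L, pca$center, "+")
  nch <- nrow(pca$rotation)
  out <- epochs
  out$data <- aperm(array(X, dim = c(d[1], d[3], nch)), c(1, 3, 2))
  out$ch_names <- ch_names %||% sprintf("ch%02d", seq_len(nch))
  add_history(out, "backproject_pca")
}

#' Running-average smoothing along time
#'
#' Centered moving average per trial and channel; windows shrink at the
#' epoch edges.
#'
#' @param epochs an [epoch_set()].
#' @param width window width in seconds (default 0.15).
#' @return smoothed `epoch_set`.
#' @export
smooth_running_average <- function(epochs, width = 0.15) {
  w <- max(1L, as.integer(round(width * epochs$sfreq)))
  d <- dim(epochs$data)
  out <- epochs
  for (i in seq_len(d[1]))
    for (j in seq_len(d[2]))
      out$data[i, j, ] <- moving_average(epochs$data[i, j, ], w)
  add_history(out, sprintf("smooth_running_average(%g s)", width))
}

# ---------------------------------------------------------------------------
# LDA + AUC internals

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC: the probability that a random
#' positive-class score exceeds a random negative-class score, with ties
#' counted 1/2.
#'
#' @param scores numeric decision scores (higher = more positive-class).
#' @param y logical or 0/1 vector of class membership.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, y) {
  y <- as.logical(y)
  n1 <- sum(y)
  n0 <- sum(!y)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# AUC of every column of a score matrix
auc_cols <- function(S, y) {
  y <- as.logical(y)
  n1 <- sum(y)
  n0 <- sum(!y)
  apply(S, 2L, function(s) (sum(rank(s)[y]) - n1 * (n1 + 1) / 2) / (n1 * n0))
}

# LDA weight vector from sufficient statistics of the training slice:
# G = X'X, s_all = colSums(X), s1 = colSums over class-1 rows.
# Pooled within-class covariance is shrunk toward a scaled identity.
lda_weights <- function(G, s_all, s1, n, n1, gamma) {
  n0 <- n - n1
  m1 <- s1 / n1
  m0 <- (s_all - s1) / n0
  Sw <- (G - n0 * tcrossprod(m0) - n1 * tcrossprod(m1)) / (n - 2L)
  nu <- mean(diag(Sw))
  S <- (1 - gamma) * Sw
  diag(S) <- diag(S) + gamma * nu
  solve(S, m1 - m0)
}

# AUC time courses for one train/test split and a list of training-label
# vectors (first entry usually the true labels, the rest shuffles).
# X: trials x p x T; label_sets: list of full-length 0/1 vectors;
# y_true: full-length 0/1 used for test AUC. Returns n_sets x T matrix.
decode_fold_times <- function(X, train, test, label_sets, y_true, gamma) {
  d <- dim(X)
  n_sets <- length(label_sets)
  out <- matrix(NA_real_, n_sets, d[3])
  yte <- as.logical(y_true[test])
  n1te <- sum(yte)
  n0te <- sum(!yte)
  for (t in seq_len(d[3])) {
    Xtr <- X[train, , t, drop = TRUE]
    Xte <- X[test, , t, drop = TRUE]
    if (is.null(dim(Xtr))) {
      Xtr <- matrix(Xtr, ncol = d[2])
      Xte <- matrix(Xte, ncol = d[2])
    }
    G <- crossprod(Xtr)
    s_all <- colSums(Xtr)
    for (k in seq_len(n_sets)) {
      ytr <- label_sets[[k]][train]
      n1 <- sum(ytr)
      if (n1 == 0L || n1 == length(train)) next
      s1 <- colSums(Xtr[ytr == 1L, , drop = FALSE])
      w <- lda_weights(G, s_all, s1, length(train), n1, gamma)
      sc <- Xte %*% w
      r <- rank(sc)
      out[k, t] <- (sum(r[yte]) - n1te * (n1te + 1) / 2) / (n1te * n0te)
    }
  }
  out
}

# stratified fold assignment
stratified_folds <- function(y, folds) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold
}

# coerce labels to 0/1 with the second factor level as positive class
labels01 <- function(labels) {
  f <- factor(labels)
  if (nlevels(f) != 2L) stop("exactly two classes required, got ",
                             nlevels(f))
  structure(as.integer(f) - 1L, levels = levels(f))
}

#' Cross-validated decoding time course with surrogate baseline
#'
#' Trains a regularized LDA per timepoint under stratified fivefold
#' cross-validation, averages the ROC-AUC over folds and over `repeats`
#' re-randomized fold assignments, and estimates a per-participant chance
#' baseline by shuffling the training labels `n_shuffles` times (test
#' labels stay intact) and averaging the resulting AUC.
#'
#' @param epochs an [epoch_set()] (typically baseline-corrected, z-scored,
#'   PCA-reduced and smoothed).
#' @param labels two-class per-event labels (default `epochs$labels`).
#' @param folds number of CV folds.
#' @param repeats number of repeated fold randomizations averaged.
#' @param n_shuffles number of training-label shuffles for the surrogate.
#' @param gamma LDA covariance shrinkage toward a scaled identity.
#' @return list of class `decoding_timecourse` with `times`, `auc`,
#'   `surrogate` (mean shuffled-label AUC per timepoint), `surrogate_mean`
#'   (grand mean over time) and `n_shuffles`.
#' @export
cv_decode_timecourse <- function(epochs, labels = epochs$labels, folds = 5L,
                                 repeats = 5L, n_shuffles = 250L,
                                 gamma = 0.01) {
  y <- labels01(labels)
  X <- epochs$data
  n <- dim(X)[1]
  auc_acc <- matrix(0, 0, dim(X)[3])
  fold1 <- NULL
  for (r in seq_len(repeats)) {
    fold <- stratified_folds(y, folds)
    if (r == 1L) fold1 <- fold
    for (f in seq_len(folds)) {
      tr <- which(fold != f)
      te <- which(fold == f)
      auc_acc <- rbind(auc_acc,
                       decode_fold_times(X, tr, te, list(y), y, gamma))
    }
  }
  auc <- colMeans(auc_acc, na.rm = TRUE)
  surrogate <- NULL
  if (n_shuffles > 0L) {
    shuffles <- lapply(seq_len(n_shuffles), function(i) sample(y))
    sur_acc <- array(NA_real_, dim = c(n_shuffles, dim(X)[3], folds))
    for (f in seq_len(folds)) {
      tr <- which(fold1 != f)
      te <- which(fold1 == f)
      sur_acc[, , f] <- decode_fold_times(X, tr, te, shuffles, y, gamma)
    }
    shuffle_means <- apply(sur_acc, c(1, 2), mean, na.rm = TRUE) # n_sh x T
    surrogate <- colMeans(shuffle_means, na.rm = TRUE)
  }
  structure(list(times = epochs$times, auc = auc, surrogate = surrogate,
                 surrogate_mean = if (is.null(surrogate)) NA_real_
                                  else mean(surrogate),
                 n_shuffles = n_shuffles,
                 classes = attr(y, "levels")),
            class = "decoding_timecourse")
}

#' @export
print.decoding_timecourse <- function(x, ...) {
  cat(sprintf("<decoding_timecourse> %d timepoints; peak AUC %.3f at %.3f s; surrogate mean %.3f (%d shuffles)\n",
              length(x$times), max(x$auc), x$times[which.max(x$auc)],
              x$surrogate_mean, x$n_shuffles))
  invisible(x)
}

#' Temporal generalization from wake to sleep
#'
#' Trains an LDA on the localizer at every training timepoint and applies
#' it to every timepoint of the sleep epochs (no cross-validation: the two
#' datasets are independent). Sleep test labels are the learned category of
#' each epoch's session, so AUC > 0.5 means endogenous activity resembling
#' the just-learned category. A surrogate map is built by shuffling the
#' localizer training labels `n_shuffles` times and averaging.
#'
#' @param localizer component-space localizer [epoch_set()] with two-class
#'   labels.
#' @param sleep sleep [epoch_set()] in the same feature space (pooled PCA),
#'   with per-epoch learned-category labels.
#' @param loc_labels,sleep_labels labels (defaults from the epoch sets).
#' @param n_shuffles number of training-label shuffles.
#' @param gamma LDA shrinkage.
#' @param train_window,test_window optional time windows (s) restricting
#'   the train/test axes.
#' @param train_decim,test_decim integer decimation steps along each axis.
#' @return list of class `decoding_map` with `auc` (train x test), matching
#'   `surrogate`, `train_times`, `test_times`, `n_shuffles`.
#' @export
temporal_generalization <- function(localizer, sleep,
                                    loc_labels = localizer$labels,
                                    sleep_labels = sleep$labels,
                                    n_shuffles = 250L, gamma = 0.01,
                                    train_window = NULL, test_window = NULL,
                                    train_decim = 1L, test_decim = 1L) {
  if (!identical(localizer$ch_names, sleep$ch_names))
    stop("localizer and sleep epochs are in different feature spaces")
  y <- labels01(loc_labels)
  ys <- labels01(sleep_labels)
  tr_idx <- seq_along(localizer$times)
  if (!is.null(train_window))
    tr_idx <- tr_idx[localizer$times >= train_window[1] - 1e-9 &
                     localizer$times <= train_window[2] + 1e-9]
  tr_idx <- tr_idx[seq(1L, length(tr_idx), by = train_decim)]
  te_idx <- seq_along(sleep$times)
  if (!is.null(test_window))
    te_idx <- te_idx[sleep$times >= test_window[1] - 1e-9 &
                     sleep$times <= test_window[2] + 1e-9]
  te_idx <- te_idx[seq(1L, length(te_idx), by = test_decim)]
  X <- localizer$data
  ds <- dim(sleep$data)
  p <- ds[2]
  # sleep data flattened to (trials*test_times) x p for one-GEMM scoring
  SP <- matrix(aperm(sleep$data[, , te_idx, drop = FALSE], c(1, 3, 2)),
               ds[1] * length(te_idx), p)
  ysl <- as.logical(ys)
  n1 <- sum(ysl)
  n0 <- sum(!ysl)
  label_sets <- c(list(y), lapply(seq_len(n_shuffles), function(i) sample(y)))
  n_sets <- length(label_sets)
  auc <- matrix(NA_real_, length(tr_idx), length(te_idx))
  sur <- matrix(0, length(tr_idx), length(te_idx))
  n_tr <- dim(X)[1]
  for (ti in seq_along(tr_idx)) {
    Xt <- X[, , tr_idx[ti], drop = TRUE]
    if (is.null(dim(Xt))) Xt <- matrix(Xt, ncol = p)
    G <- crossprod(Xt)
    s_all <- colSums(Xt)
    for (k in seq_len(n_sets)) {
      ytr <- label_sets[[k]]
      nk1 <- sum(ytr)
      if (nk1 == 0L || nk1 == n_tr) next
      s1 <- colSums(Xt[ytr == 1L, , drop = FALSE])
      w <- lda_weights(G, s_all, s1, n_tr, nk1, gamma)
      S <- matrix(SP %*% w, ds[1], length(te_idx))
      a <- auc_cols(S, ysl)
      if (k == 1L) auc[ti, ] <- a else sur[ti, ] <- sur[ti, ] + a
    }
  }
  if (n_shuffles > 0L) sur <- sur / n_shuffles else sur[] <- NA_real_
  structure(list(auc = auc, surrogate = sur,
                 train_times = localizer$times[tr_idx],
                 test_times = sleep$times[te_idx],
                 n_shuffles = n_shuffles, classes = attr(y, "levels")),
            class = "decoding_map")
}

#' @export
print.decoding_map <- function(x, ...) {
  cat(sprintf("<decoding_map> %d train x %d test times; max AUC %.3f; %d shuffles\n",
              nrow(x$auc), ncol(x$auc), max(x$auc, na.rm = TRUE),
              x$n_shuffles))
  invisible(x)
}

#' Channel-searchlight decoding
#'
#' Repeats the wake-to-sleep temporal generalization with small spatial
#' neighborhoods of sensors as features (component data must be
#' back-projected to sensor space first, see [backproject_pca()]), and
#' collapses the AUC over configured train/test windows to one value per
#' center channel. Neighborhoods with fewer than 2 channels are skipped.
#'
#' @param localizer,sleep sensor-space [epoch_set()]s.
#' @param neighborhoods list of channel-index vectors per center channel,
#'   e.g. from [searchlight_neighborhoods()].
#' @param train_window,test_window collapse windows in seconds.
#' @param loc_labels,sleep_labels two-class labels.
#' @param gamma LDA shrinkage.
#' @param train_decim,test_decim decimation along each time axis.
#' @return data.frame with `channel`, `n_features`, `auc`.
#' @export
searchlight_decode <- function(localizer, sleep, neighborhoods,
                               train_window, test_window,
                               loc_labels = localizer$labels,
                               sleep_labels = sleep$labels,
                               gamma = 0.01,
                               train_decim = 1L, test_decim = 1L) {
  out <- data.frame(channel = names(neighborhoods),
                    n_features = lengths(neighborhoods),
                    auc = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_along(neighborhoods)) {
    nb <- neighborhoods[[i]]
    if (length(nb) < 2L) {
      message("searchlight: skipping ", names(neighborhoods)[i],
              " (neighborhood smaller than 2 channels)")
      next
    }
    loc_i <- localizer
    loc_i$data <- localizer$data[, nb, , drop = FALSE]
    loc_i$ch_names <- localizer$ch_names[nb]
    sl_i <- sleep
    sl_i$data <- sleep$data[, nb, , drop = FALSE]
    sl_i$ch_names <- sleep$ch_names[nb]
    map <- temporal_generalization(loc_i, sl_i, loc_labels, sleep_labels,
                                   n_shuffles = 0L, gamma = gamma,
                                   train_window = train_window,
                                   test_window = test_window,
                                   train_decim = train_decim,
                                   test_decim = test_decim)
    out$auc[i] <- mean(map$auc, na.rm = TRUE)
  }
  out
}
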