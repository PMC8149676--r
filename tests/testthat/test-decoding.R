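# Decoding preprocessing, LDA/AUC machinery, temporal generalization,
# searchlight.

toy_epochs <- function(data3d, sfreq = 200, labels = NULL) {
  d <- dim(data3d)
  epoch_set(data3d, seq(0, by = 1 / sfreq, length.out = d[3]), sfreq,
            sprintf("ch%02d", seq_len(d[2])), labels = labels)
}

test_that("z-scoring standardizes every channel x timepoint feature", {
  set.seed(20)
  ep <- toy_epochs(array(rnorm(10 * 3 * 7, mean = 5, sd = 2), c(10, 3, 7)))
  z <- zscore_epochs(ep)
  M <- matrix(z$data, 10, 21)
  expect_equal(colMeans(M), rep(0, 21), tolerance = 1e-12)
  expect_equal(apply(M, 2, sd), rep(1, 21), tolerance = 1e-12)
  # hand-computed 3-trial toy with sample SD
  ep3 <- toy_epochs(array(c(1, 2, 3), c(3, 1, 1)))
  expect_equal(as.numeric(zscore_epochs(ep3)$data), c(-1, 0, 1))
  # degenerate: identical trials -> all zeros with a warning
  flat <- toy_epochs(array(rep(1:6, each = 4), c(4, 2, 3)))
  expect_warning(zf <- zscore_epochs(flat), "zero-variance")
  expect_true(all(zf$data == 0))
})

test_that("whole-trial baseline correction removes offsets, keeps shape", {
  fs <- 100
  t <- seq(0, 1 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * 3 * t)
  ep <- toy_epochs(array(rep(x + 2.5, each = 2), c(2, 1, length(t))), fs)
  bc <- baseline_correct(ep)
  expect_equal(as.numeric(bc$data[1, 1, ]), x - mean(x), tolerance = 1e-12)
  expect_equal(mean(bc$data[2, 1, ]), 0, tolerance = 1e-12)
  # constant trial becomes zero
  cst <- baseline_correct(toy_epochs(array(7, c(1, 2, 5))))
  expect_true(all(cst$data == 0))
  # window restriction: mean over the window is zero afterwards
  wb <- baseline_correct(ep, window = c(0, 0.5))
  sel <- ep$times >= 0 & ep$times <= 0.5
  expect_equal(mean(wb$data[1, 1, sel]), 0, tolerance = 1e-12)
  expect_error(baseline_correct(ep, c(5, 6)), "outside")
})

test_that("pooled PCA keeps orthonormal ordered components and exact low rank", {
  set.seed(21)
  base <- matrix(rnorm(5 * 8), 5, 8)               # rank-5 channel space
  mk <- function(n) {
    arr <- array(0, c(n, 8, 12))
    for (e in seq_len(n)) arr[e, , ] <- t(matrix(rnorm(12 * 5), 12, 5) %*% base)
    toy_epochs(arr)
  }
  wake <- mk(10); sleep <- mk(8)
  pca <- fit_pca_pooled(wake, sleep, k = 5)
  expect_equal(crossprod(pca$rotation), diag(5), tolerance = 1e-9)
  expect_true(all(diff(pca$explained) <= 1e-12))
  expect_gt(sum(pca$explained[1:5]), 1 - 1e-9)     # exact low rank
  # back-projection reconstructs rank-5 data exactly
  rec <- backproject_pca(pca$wake, pca)
  expect_equal(rec$data, wake$data, tolerance = 1e-6)
  expect_error(fit_pca_pooled(wake, sleep, k = 7), "rank")
})

test_that("running-average smoothing has the documented impulse response", {
  fs <- 200
  imp <- array(0, c(1, 1, 101)); imp[1, 1, 51] <- 1
  sm <- smooth_running_average(toy_epochs(imp, fs), 0.15)  # 31 samples
  expect_equal(max(sm$data), 1 / 31, tolerance = 1e-12)
  expect_equal(sum(sm$data[1, 1, 36:66] > 0), 31)
  # constant input unchanged
  cst <- smooth_running_average(toy_epochs(array(3, c(2, 1, 50)), fs))
  expect_true(all(abs(cst$data - 3) < 1e-12))
  # white-noise variance shrinks by ~the window length
  set.seed(22)
  wn <- toy_epochs(array(rnorm(4000), c(1, 1, 4000)), fs)
  smw <- smooth_running_average(wn, 0.15)
  ratio <- var(smw$data[1, 1, 100:3900]) / var(wn$data[1, 1, ])
  expect_lt(abs(ratio - 1 / 31), 0.01)
})

test_that("AUC equals the pair-counting oracle and is rank-invariant", {
  scores <- c(0.2, 1.4, -0.5, 2.2, 0.9, -1.0, 0.4, 1.1)
  y <- c(0, 1, 0, 1, 1, 0, 0, 1)
  # brute force: fraction of concordant (pos, neg) pairs, ties counted half
  pos <- scores[y == 1]; neg <- scores[y == 0]
  oracle <- mean(outer(pos, neg, function(a, b)
    (a > b) + 0.5 * (a == b)))
  expect_equal(auc_score(scores, y), oracle)
  # invariance under strictly monotone transforms of the scores
  expect_equal(auc_score(exp(scores), y), oracle)
  expect_equal(auc_score(rank(scores), y), oracle)
  expect_equal(auc_score(-scores, 1 - y), oracle)
  expect_error(auc_score(scores, rep(1, 8)), "both classes")
})

test_that("cross-validated LDA separates blobs and is at chance when shuffled", {
  set.seed(23)
  n <- 40; p <- 6; n_t <- 20
  y <- rep(c("A", "B"), each = n / 2)
  arr <- array(rnorm(n * p * n_t), c(n, p, n_t))
  arr[y == "B", 1:2, ] <- arr[y == "B", 1:2, ] + 8     # distant blobs
  dec <- cv_decode_timecourse(toy_epochs(arr, labels = y), repeats = 2,
                              n_shuffles = 40)
  expect_true(all(dec$auc == 1))
  expect_lt(abs(dec$surrogate_mean - 0.5), 0.05)
  # no signal: observed AUC is at chance too
  arr0 <- array(rnorm(n * p * n_t), c(n, p, n_t))
  dec0 <- cv_decode_timecourse(toy_epochs(arr0, labels = sample(y)),
                               repeats = 2, n_shuffles = 0)
  expect_lt(abs(mean(dec0$auc) - 0.5), 0.06)
  expect_error(cv_decode_timecourse(toy_epochs(arr, labels = rep("A", n))),
               "two classes")
})

test_that("temporal generalization recovers a planted reactivation lag", {
  set.seed(24)
  n_ch <- 12
  pat <- rnorm(n_ch); pat <- pat / sqrt(sum(pat^2))
  fs <- 100
  make <- function(n, n_t, sig_idx, amp) {
    arr <- array(rnorm(n * n_ch * n_t), c(n, n_ch, n_t))
    lab <- rep(c("A", "B"), length.out = n)
    for (e in which(lab == "A"))
      arr[e, , sig_idx] <- arr[e, , sig_idx] + amp * pat
    toy_epochs(arr, fs, labels = lab)
  }
  loc <- make(60, 60, 20:35, 2)           # pattern at 0.2-0.35 s
  slp <- make(50, 80, 55:70, 2)           # same pattern at 0.55-0.70 s
  map <- temporal_generalization(loc, slp, n_shuffles = 10)
  expect_identical(dim(map$auc), c(60L, 80L))
  ridge <- mean(map$auc[20:35, 55:70])
  off <- mean(map$auc[20:35, 10:25])
  expect_gt(ridge, 0.8)
  expect_gt(ridge - off, 0.25)
  expect_lt(abs(mean(map$surrogate) - 0.5), 0.03)
  # feature-space mismatch is refused
  bad <- slp; bad$ch_names <- paste0("x", seq_len(n_ch))
  expect_error(temporal_generalization(loc, bad), "feature space")
})

test_that("searchlight decoding localizes a spatially confined pattern", {
  set.seed(25)
  lay <- channel_layout_64()
  post <- which(lay$x < -0.6)              # posterior patch
  ant <- which(lay$x > 0.6)
  n_ch <- 64
  pat <- numeric(n_ch); pat[post] <- 1.5
  make <- function(n, n_t) {
    arr <- array(rnorm(n * n_ch * n_t), c(n, n_ch, n_t))
    lab <- rep(c("A", "B"), length.out = n)
    for (e in which(lab == "A")) arr[e, , ] <- arr[e, , ] + pat
    toy_epochs(arr, 100, labels = lab)
  }
  loc <- make(40, 12); slp <- make(30, 12)
  nb <- searchlight_neighborhoods(lay)
  res <- searchlight_decode(loc, slp, nb,
                            train_window = c(0, 0.1), test_window = c(0, 0.1),
                            train_decim = 2, test_decim = 2)
  expect_true(all(res$n_features >= 5 & res$n_features <= 9))
  expect_gt(mean(res$auc[post]), mean(res$auc[ant]) + 0.15)
  expect_gt(mean(res$auc[post]), 0.75)
  expect_lt(abs(mean(res$auc[ant]) - 0.5), 0.12)
})

test_that("the preprocessing order is auditable from the history log", {
  set.seed(26)
  ep <- toy_epochs(array(rnorm(6 * 4 * 30), c(6, 4, 30)))
  ep2 <- toy_epochs(array(rnorm(4 * 4 * 30), c(4, 4, 30)))
  pca <- fit_pca_pooled(zscore_epochs(baseline_correct(ep)),
                        zscore_epochs(baseline_correct(ep2)), k = 3)
  final <- smooth_running_average(pca$wake)
  h <- processing_history(final)
  expect_equal(grep("baseline", h), 1L)
  expect_equal(grep("zscore", h), 2L)
  expect_equal(grep("pca", h), 3L)
  expect_equal(grep("smooth", h), 4L)
})
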