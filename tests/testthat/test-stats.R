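# Cluster-based permutation inference, behavioral scoring, correlations.

test_that("cluster permutation finds a planted contiguous effect", {
  set.seed(30)
  n <- 20; m <- 60
  obs <- matrix(rnorm(n * m, sd = 1), n, m)
  obs[, 25:35] <- obs[, 25:35] + 1.2        # strong contiguous block
  res <- cluster_permutation(obs, 0, n_perm = 1000)
  pos <- res$clusters[res$clusters$sign > 0, ]
  best <- pos[which.max(pos$stat), ]
  expect_equal(best$p, 1 / 1001, tolerance = 1e-12)
  hit <- which(res$masks == best$id)
  expect_true(all(25:35 %in% hit))
  # identical observed and baseline: nothing survives
  base <- matrix(rnorm(n * m), n, m)
  none <- cluster_permutation(base, base + 0, n_perm = 200)
  expect_identical(nrow(none$clusters), 0L)
  expect_error(cluster_permutation(obs, 0, n_perm = 0), "n_perm")
})

test_that("Monte-Carlo cluster p matches full sign-flip enumeration at small n", {
  set.seed(31)
  n <- 8; m <- 30
  obs <- matrix(rnorm(n * m), n, m)
  obs[, 10:16] <- obs[, 10:16] + 1.1
  ex <- cluster_permutation(obs, 0, exact = TRUE)
  expect_identical(ex$n_perm, 256L)
  mc <- cluster_permutation(obs, 0, n_perm = 4000)
  expect_gt(nrow(ex$clusters), 0)
  for (i in seq_len(nrow(ex$clusters))) {
    j <- which(mc$clusters$id == ex$clusters$id[i])
    expect_lt(abs(ex$clusters$p[i] - mc$clusters$p[j]), 0.05)
  }
  # the Monte-Carlo floor is 1/(n_perm + 1)
  expect_true(all(mc$clusters$p >= 1 / 4001))
  expect_true(all(ex$clusters$p >= 1 / 2^8))
})

test_that("2-D cluster labeling uses 4-connectivity", {
  n <- 12
  obs <- array(rnorm(n * 8 * 9, sd = 0.3), c(n, 8, 9))
  obs[, 2:4, 2:4] <- obs[, 2:4, 2:4] + 3     # block A
  obs[, 7:8, 7:9] <- obs[, 7:8, 7:9] + 3     # block B, diagonal from A
  res <- cluster_permutation(obs, 0, n_perm = 200)
  pos <- res$clusters[res$clusters$sign > 0 & res$clusters$size >= 6, ]
  expect_gte(nrow(pos), 2)                   # separate clusters, not merged
  lab_a <- res$masks[3, 3]; lab_b <- res$masks[8, 8]
  expect_true(lab_a != 0 && lab_b != 0 && lab_a != lab_b)
})

test_that("d-prime follows signal detection theory with the 1/2N correction", {
  expect_equal(dprime(30, 30, 60, 60), 0)
  # perfect performance: both rates corrected by 1/2N
  expect_equal(dprime(60, 0, 60, 60), 2 * qnorm(119 / 120))
  expect_equal(dprime(60, 0, 60, 60), 4.79, tolerance = 0.005)
  expect_equal(dprime(45, 6, 60, 60), qnorm(0.75) - qnorm(0.1))
  # antisymmetry under swapping hits and false alarms
  set.seed(32)
  for (i in 1:10) {
    h <- sample(0:60, 1); f <- sample(0:60, 1)
    expect_equal(dprime(h, f, 60, 60), -dprime(f, h, 60, 60))
  }
  expect_error(dprime(1, 1, 0, 10), "positive")
  expect_error(dprime(70, 0, 60, 60), "out of bounds")
})

test_that("recall percentage and retention index follow their definitions", {
  tab <- data.frame(participant = 1, session = 1:2, n_old = 60, n_new = 60,
                    hits = c(50, 52), false_alarms = c(5, 8),
                    recalled_pre = c(32, 10), hits_pre = c(50, 25),
                    recalled_post = c(16, 10), hits_post = c(32, 25))
  # session 1: pre 64%, post 50% -> retention 78.125
  sc <- recall_and_retention(tab[1, ])
  expect_equal(sc$retention_index, 78.125)
  # equal pre/post rates -> retention 100
  sc2 <- recall_and_retention(tab[2, ])
  expect_equal(sc2$retention_index, 100)
  # sessions collapse by averaging
  both <- recall_and_retention(tab)
  expect_equal(both$retention_index, (78.125 + 100) / 2)
  bad <- tab[1, ]; bad$recalled_post <- 40
  expect_error(recall_and_retention(bad), "invariant")
  # zero denominator -> flagged missing, not an error
  z <- tab[1, ]; z$recalled_pre <- 0
  expect_message(zs <- recall_and_retention(z), "zero denominator")
  expect_true(is.na(zs$retention_index))
})

test_that("Spearman and partial Spearman match reference computations", {
  expect_equal(spearman_test(1:4, c(2, 1, 4, 3))$rho, 0.6)
  # monotone transform -> rho = 1, p = 0
  s <- spearman_test(1:10, exp(1:10))
  expect_equal(s$rho, 1)
  expect_equal(s$p, 0)
  # agreement with cor.test on untied data
  set.seed(33)
  x <- rnorm(30); y <- 0.5 * x + rnorm(30)
  ours <- spearman_test(x, y)
  ref <- suppressWarnings(cor.test(x, y, method = "spearman"))
  expect_equal(ours$rho, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(ours$p, ref$p.value, tolerance = 0.01)
  # an association carried entirely by the covariate vanishes when partialled
  set.seed(34)
  cv <- rnorm(200)
  x2 <- cv + rnorm(200, sd = 0.5)
  y2 <- 2 * cv + rnorm(200, sd = 0.5)
  expect_gt(spearman_test(x2, y2)$rho, 0.5)
  expect_lt(abs(partial_spearman_test(x2, y2, covariate = cv)$rho), 0.2)
  expect_error(partial_spearman_test(x2, y2, rep(1, 200)), "constant")
  big <- partial_spearman_test(x, y, covariate = rnorm(30))
  expect_equal(big$rho, ours$rho, tolerance = 0.2)
  expect_error(spearman_test(rep(1, 10), 1:10), "constant")
})

test_that("reactivation strength averages the map over mask or window", {
  mk <- function(val) {
    structure(list(auc = matrix(val, 4, 5),
                   train_times = seq(0, 0.3, by = 0.1),
                   test_times = seq(-0.2, 0.2, by = 0.1)),
              class = "decoding_map")
  }
  maps <- list(mk(0.6), mk(0.7))
  full <- matrix(TRUE, 4, 5)
  expect_equal(reactivation_strength(maps, full), c(0.6, 0.7))
  single <- matrix(FALSE, 4, 5); single[2, 3] <- TRUE
  expect_equal(reactivation_strength(maps, single), c(0.6, 0.7))
  bywin <- reactivation_strength(maps, train_window = c(0, 0.1),
                                 test_window = c(-0.1, 0.1))
  expect_equal(bywin, c(0.6, 0.7))
  expect_error(reactivation_strength(maps, matrix(FALSE, 4, 5)), "empty mask")
})

test_that("Steiger's z is null when the compared correlations are equal", {
  expect_equal(steiger_z(0.5, 0.5, 0.3, 20)$z, 0)
  st <- steiger_z(0.45, 0.02, 0.1, 20)
  expect_gt(st$z, 0)
  expect_true(st$p > 0 && st$p < 1)
})
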