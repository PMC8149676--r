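# Group-level inference (cluster-based permutation over decoding maps),
# behavioral scoring (d-prime, cued recall, retention index) and
# participant-level correlations.

# label contiguous TRUE runs of a logical vector; returns integer labels
clusters_1d <- function(supra) {
  lab <- integer(length(supra))
  r <- rle(supra)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- 0L
  for (i in seq_along(r$values)) if (r$values[i]) {
    k <- k + 1L
    lab[starts[i]:ends[i]] <- k
  }
  lab
}

# label 4-connected TRUE components of a logical matrix (igraph backend)
clusters_2d <- function(supra, n1, n2) {
  A <- matrix(supra, n1, n2)
  idx <- which(A)
  lab <- integer(n1 * n2)
  if (!length(idx)) return(lab)
  # horizontal edges
  fh <- which(A[, -n2, drop = FALSE] & A[, -1L, drop = FALSE])
  r <- (fh - 1L) %% n1 + 1L
  cc <- (fh - 1L) %/% n1 + 1L
  e_h <- cbind(r + (cc - 1L) * n1, r + cc * n1)
  # vertical edges
  fv <- which(A[-n1, , drop = FALSE] & A[-1L, , drop = FALSE])
  r <- (fv - 1L) %% (n1 - 1L) + 1L
  cc <- (fv - 1L) %/% (n1 - 1L) + 1L
  e_v <- cbind(r + (cc - 1L) * n1, r + 1L + (cc - 1L) * n1)
  edges <- rbind(e_h, e_v)
  local <- match(edges, idx)
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (nrow(edges))
    g <- igraph::add_edges(g, t(matrix(local, ncol = 2L)))
  comp <- igraph::components(g)$membership
  lab[idx] <- comp
  lab
}

# maximum cluster-mass magnitude of one t map (both signs)
max_cluster_stat <- function(tv, tcrit, dims) {
  best <- 0
  for (sgn in c(1, -1)) {
    supra <- sgn * tv > tcrit
    if (!any(supra)) next
    lab <- if (length(dims) == 1L) clusters_1d(supra)
           else clusters_2d(supra, dims[1], dims[2])
    if (!max(lab)) next
    sums <- abs(vapply(seq_len(max(lab)),
                       function(k) sum(tv[lab == k]), 0))
    best <- max(best, sums)
  }
  best
}

#' Cluster-based permutation test for paired decoding maps
#'
#' Dependent-samples t values are computed at every point of the
#' participant-wise difference between `observed` and `baseline` maps;
#' points exceeding the two-tailed `cluster_alpha` t threshold are grouped
#' by contiguity (adjacent samples in 1-D, 4-connectivity in 2-D) and each
#' cluster is summarized by the sum of its t values (maxsum). The null
#' distribution of the maximum cluster-mass magnitude is built by randomly
#' sign-flipping the participant difference maps (equivalent to swapping
#' the paired conditions); the two-tailed Monte Carlo p of a cluster is
#' `(b + 1) / (n_perm + 1)` where `b` counts permutations whose maximum
#' cluster mass reaches the observed cluster's magnitude. With
#' `exact = TRUE` all `2^n` sign patterns are enumerated instead.
#'
#' @param observed numeric array: participants x time (1-D maps) or
#'   participants x train-times x test-times (2-D maps).
#' @param baseline matching array of per-participant baselines (e.g.
#'   surrogate maps), or a single number.
#' @param cluster_alpha two-tailed sample-level threshold (default 0.05).
#' @param n_perm number of random sign flips (ignored when `exact`).
#' @param exact enumerate all sign patterns (requires <= 16 participants).
#' @return list of class `cluster_result` with `t` (point-wise t map),
#'   `threshold`, `clusters` (data.frame `id`, `sign`, `stat`, `size`,
#'   `p`), `masks` (integer label array, 0 = background), `null_max`,
#'   `n_perm`.
#' @export
cluster_permutation <- function(observed, baseline = 0,
                                cluster_alpha = 0.05, n_perm = 1000L,
                                exact = FALSE) {
  if (n_perm < 1L) stop("n_perm must be at least 1")
  obs <- as.array(observed)
  dims_all <- dim(obs)
  n <- dims_all[1]
  if (is.null(dims_all) || n < 2L) stop("need at least 2 participants")
  dims <- dims_all[-1]
  m <- prod(dims)
  D <- matrix(obs, n, m) - if (length(baseline) == 1L) baseline
                           else matrix(as.array(baseline), n, m)
  mu <- colMeans(D)
  ss <- colSums(D^2)
  se <- sqrt((ss - n * mu^2) / (n - 1) / n)
  tv <- mu / pmax(se, 1e-300)
  tcrit <- stats::qt(1 - cluster_alpha / 2, df = n - 1)
  # observed clusters
  lab_all <- integer(m)
  rows <- list()
  k_off <- 0L
  for (sgn in c(1, -1)) {
    supra <- sgn * tv > tcrit
    lab <- if (length(dims) == 1L) clusters_1d(supra)
           else clusters_2d(supra, dims[1], dims[2])
    if (!max(lab)) next
    for (k in seq_len(max(lab))) {
      sel <- lab == k
      rows[[length(rows) + 1L]] <- data.frame(
        id = k_off + k, sign = sgn, stat = sum(tv[sel]), size = sum(sel))
      lab_all[sel] <- k_off + k
    }
    k_off <- k_off + max(lab)
  }
  # permutation null of the maximum cluster mass
  if (exact) {
    if (n > 16L) stop("exact enumeration limited to 16 participants")
    flips <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    n_eff <- nrow(flips)
  } else {
    flips <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
    n_eff <- n_perm
  }
  mu_p <- flips %*% D / n
  null_max <- numeric(n_eff)
  for (i in seq_len(n_eff)) {
    se_i <- sqrt((ss - n * mu_p[i, ]^2) / (n - 1) / n)
    tp <- mu_p[i, ] / pmax(se_i, 1e-300)
    null_max[i] <- max_cluster_stat(tp, tcrit, dims)
  }
  clusters <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = integer(0), sign = numeric(0), stat = numeric(0),
               size = integer(0))
  if (nrow(clusters)) {
    clusters$p <- vapply(clusters$stat, function(s) {
      if (exact) mean(null_max >= abs(s) - 1e-12)
      else (1 + sum(null_max >= abs(s) - 1e-12)) / (n_eff + 1)
    }, 0)
  } else clusters$p <- numeric(0)
  structure(list(t = array(tv, dim = dims), threshold = tcrit,
                 clusters = clusters, masks = array(lab_all, dim = dims),
                 null_max = null_max,
                 n_perm = n_eff, exact = exact),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d cluster(s); threshold |t| > %.3f; %s permutations\n",
              nrow(x$clusters), x$threshold,
              if (x$exact) paste0(x$n_perm, " (exact)") else x$n_perm))
  if (nrow(x$clusters)) print(x$clusters, row.names = FALSE)
  invisible(x)
}

#' Signal-detection sensitivity d'
#'
#' `d' = z(hit rate) - z(false-alarm rate)`, with proportions of 0 and 1
#' replaced by `1/(2N)` and `1 - 1/(2N)` where `N` is the trial count of
#' the respective proportion.
#'
#' @param hits,false_alarms counts (vectorized).
#' @param n_old,n_new trial counts underlying the two proportions.
#' @return numeric d' values.
#' @export
dprime <- function(hits, false_alarms, n_old, n_new) {
  if (any(n_old == 0) || any(n_new == 0))
    stop("n_old and n_new must be positive")
  if (any(hits < 0 | hits > n_old) || any(false_alarms < 0 |
                                          false_alarms > n_new))
    stop("counts out of bounds")
  hr <- hits / n_old
  fa <- false_alarms / n_new
  hr <- ifelse(hr == 0, 1 / (2 * n_old), ifelse(hr == 1, 1 - 1 / (2 * n_old), hr))
  fa <- ifelse(fa == 0, 1 / (2 * n_new), ifelse(fa == 1, 1 - 1 / (2 * n_new), fa))
  stats::qnorm(hr) - stats::qnorm(fa)
}

#' Cued-recall percentages and retention index
#'
#' Per session, cued recall is scored relative to recognized items
#' (`recalled / hits * 100`); the retention index is the post-sleep
#' recall-of-hits percentage in relation to the pre-sleep percentage
#' (`post / pre * 100`). Sessions are collapsed per participant by
#' averaging. Sessions with a zero denominator are flagged missing and
#' excluded from the average with a message.
#'
#' @param table behavior data.frame with columns `participant`, `session`,
#'   `n_old`, `n_new`, `hits`, `false_alarms`, `recalled_pre`, `hits_pre`,
#'   `recalled_post`, `hits_post` (see [simulate_behavior()]).
#' @return data.frame per participant with `dprime`, `recall_pre`,
#'   `recall_post` (percent) and `retention_index` (percent).
#' @export
recall_and_retention <- function(table) {
  with(table, {
    if (any(hits > n_old) || any(false_alarms > n_new) ||
        any(recalled_pre > hits_pre) || any(recalled_post > hits_post))
      stop("invariant violation: recalled counts exceed hits (or hits exceed items)")
  })
  bad <- table$hits_pre == 0 | table$recalled_pre == 0 | table$hits_post == 0
  if (any(bad))
    message(sum(bad), " session(s) with zero denominator excluded from retention")
  table$recall_pre_pct <- 100 * table$recalled_pre / pmax(table$hits_pre, 1)
  table$recall_post_pct <- 100 * table$recalled_post / pmax(table$hits_post, 1)
  table$retention <- ifelse(bad, NA_real_,
                            100 * table$recall_post_pct / table$recall_pre_pct)
  table$d <- dprime(table$hits, table$false_alarms, table$n_old, table$n_new)
  agg <- function(v) tapply(v, table$participant, mean, na.rm = TRUE)
  out <- data.frame(participant = sort(unique(table$participant)),
                    dprime = as.numeric(agg(table$d)),
                    recall_pre = as.numeric(agg(table$recall_pre_pct)),
                    recall_post = as.numeric(agg(table$recall_post_pct)),
                    retention_index = as.numeric(agg(table$retention)))
  out$retention_index[is.nan(out$retention_index)] <- NA_real_
  out
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties; the p value uses the t
#' approximation with `n - 2` degrees of freedom.
#'
#' @param x,y numeric vectors, `n >= 4`, non-constant.
#' @return list with `rho`, `p`, `n`.
#' @export
spearman_test <- function(x, y) {
  n <- length(x)
  if (n != length(y)) stop("x and y must have equal length")
  if (n < 4L) stop("need at least 4 observations")
  if (stats::sd(x) < 1e-12 || stats::sd(y) < 1e-12)
    stop("degenerate input: constant variable")
  rho <- stats::cor(rank(x), rank(y))
  p <- if (abs(rho) >= 1) 0 else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tt), df = n - 2)
  }
  list(rho = rho, p = p, n = n)
}

#' Partial Spearman correlation
#'
#' Pearson partial correlation computed on ranks: `x` and `y` ranks are
#' residualized on the covariate's ranks, and the correlation of the
#' residuals is tested with a t approximation on `n - 3` degrees of
#' freedom.
#'
#' @param x,y numeric vectors of interest.
#' @param covariate numeric nuisance vector, non-constant.
#' @return list with `rho`, `p`, `n`.
#' @export
partial_spearman_test <- function(x, y, covariate) {
  n <- length(x)
  if (n != length(y) || n != length(covariate))
    stop("x, y and covariate must have equal length")
  if (n < 5L) stop("need at least 5 observations")
  if (stats::sd(covariate) < 1e-12)
    stop("degenerate input: constant covariate")
  rx <- rank(x); ry <- rank(y); rc <- rank(covariate)
  res <- function(v) stats::lm.fit(cbind(1, rc), v)$residuals
  ex <- res(rx); ey <- res(ry)
  if (stats::sd(ex) < 1e-12 || stats::sd(ey) < 1e-12)
    stop("degenerate input after partialling")
  rho <- stats::cor(ex, ey)
  p <- if (abs(rho) >= 1) 0 else {
    tt <- rho * sqrt((n - 3) / (1 - rho^2))
    2 * stats::pt(-abs(tt), df = n - 3)
  }
  list(rho = rho, p = p, n = n)
}

#' Per-participant reactivation strength
#'
#' Mean AUC over a cluster mask or a train/test window, per participant.
#'
#' @param maps list of [temporal_generalization()] `decoding_map`s, one per
#'   participant (sharing axes).
#' @param mask logical or 0/1 matrix over train x test times (e.g.
#'   `cluster_result$masks > 0`), or `NULL` to use `train_window` /
#'   `test_window`.
#' @param train_window,test_window windows in seconds used when `mask` is
#'   `NULL`.
#' @return numeric vector, one mean AUC per participant.
#' @export
reactivation_strength <- function(maps, mask = NULL, train_window = NULL,
                                  test_window = NULL) {
  stopifnot(length(maps) >= 1L)
  tt <- maps[[1]]$train_times
  ts <- maps[[1]]$test_times
  if (is.null(mask)) {
    if (is.null(train_window) || is.null(test_window))
      stop("either a mask or both windows must be given")
    mask <- outer(tt >= train_window[1] & tt <= train_window[2],
                  ts >= test_window[1] & ts <= test_window[2])
  }
  mask <- mask > 0
  if (!any(mask)) stop("empty mask")
  vapply(maps, function(m) mean(m$auc[mask]), 0)
}

#' Steiger's z for two dependent correlations sharing a variable
#'
#' Compares `cor(x, y1)` with `cor(x, y2)` given `cor(y1, y2)`, using
#' Steiger's (1980) modification of Williams' test on Fisher-z transformed
#' correlations.
#'
#' @param r12,r13 the two correlations sharing variable 1.
#' @param r23 correlation between variables 2 and 3.
#' @param n sample size.
#' @return list with `z` and two-tailed `p`.
#' @export
steiger_z <- function(r12, r13, r23, n) {
  rm2 <- (r12^2 + r13^2) / 2
  f <- min((1 - r23) / (2 * (1 - rm2)), 1)
  h <- (1 - f * rm2) / (1 - rm2)
  z <- (atanh(r12) - atanh(r13)) *
    sqrt((n - 3) / (2 * (1 - r23) * h))
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}
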