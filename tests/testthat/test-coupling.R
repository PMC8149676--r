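# Coupling phase extraction and circular statistics.

test_that("phase convention: upstate = 0, down-to-up transition = -pi/2", {
  # spindle envelope peak at the SO maximum
  up <- periodic_so_epoch(peak_t = 0)
  expect_angle_equal(event_coupling_phase(up), 0, 0.1)
  # envelope peak at the ascending (down-to-up) zero crossing: 3T/4 = 1.0 s
  d2u <- periodic_so_epoch(peak_t = 1.0)
  expect_angle_equal(event_coupling_phase(d2u), -pi / 2, 0.1)
  # envelope peak at the trough
  down <- periodic_so_epoch(peak_t = 1 / 0.75 / 2)
  expect_gt(abs(event_coupling_phase(down)), pi - 0.15)
  # epochs narrower than the +/-1.5 s analysis window are rejected
  narrow <- periodic_so_epoch(0, window = c(-1, 1))
  expect_error(event_coupling_phase(narrow), "1.5")
})

test_that("planted coupling phase is recovered from synthetic complexes", {
  cfg <- test_cfg(coupling_mu = -0.64)
  ce <- simulate_complex_epochs(cfg, 1, n_events = 300, channels = "Cz",
                                kappa = Inf)
  ph <- event_coupling_phase(ce$epochs)
  expect_angle_equal(circular_mean_and_R(ph)$mean, -0.64, 0.08)
  expect_gt(circular_mean_and_R(ph)$R, 0.8)
})

test_that("circular mean and resultant length follow their definitions", {
  all_eq <- circular_mean_and_R(rep(1.2, 7))
  expect_equal(all_eq$mean, 1.2)
  expect_equal(all_eq$R, 1)
  anti <- circular_mean_and_R(c(0, pi))
  expect_lt(anti$R, 1e-12)
  expect_false(anti$mean_reliable)
  expect_true(is.na(anti$mean))
  expect_error(circular_mean_and_R(numeric(0)), "empty")
  set.seed(10)
  th <- rvonmises(10000, 0.5, 2)
  cm <- circular_mean_and_R(th)
  expect_angle_equal(cm$mean, 0.5, 0.05)
  expect_lt(abs(cm$R - besselI(2, 1) / besselI(2, 0)), 0.02)
})

test_that("Rayleigh statistic equals n R^2 and reproduces reference values", {
  # uniform grid: no concentration
  grid <- seq(0, 2 * pi, length.out = 21)[1:20]
  ray0 <- rayleigh_test(grid)
  expect_lt(ray0$z, 1e-10)
  expect_equal(ray0$p, 1, tolerance = 1e-6)
  # identical angles: R = 1, z = n
  ray1 <- rayleigh_test(rep(0.7, 20))
  expect_equal(ray1$z, 20)
  expect_lt(ray1$p, 1e-10)
  # phases at +/- acos(0.914) have R = 0.914 exactly, so z = 20 * 0.914^2
  a <- acos(0.914)
  ray2 <- rayleigh_test(rep(c(a, -a), 10))
  expect_equal(ray2$R, 0.914, tolerance = 1e-12)
  expect_equal(ray2$z, 20 * 0.914^2, tolerance = 1e-9)
  expect_equal(ray2$z, 16.71, tolerance = 0.01)
  # z = n R^2 exactly, for arbitrary inputs
  set.seed(11)
  for (i in 1:20) {
    th <- runif(sample(2:50, 1), -pi, pi)
    ray <- rayleigh_test(th)
    expect_equal(ray$z, length(th) * ray$R^2, tolerance = 1e-12)
  }
  expect_error(rayleigh_test(1), "at least 2")
})

test_that("circular-linear correlation matches its closed form", {
  set.seed(12)
  th <- runif(50, -pi, pi)
  perfect <- circ_linear_corr(th, cos(th))
  expect_equal(perfect$r, 1, tolerance = 1e-9)
  expect_lt(perfect$p, 1e-10)
  # independent variables: vanishing correlation
  null <- circ_linear_corr(runif(10000, -pi, pi), rnorm(10000))
  expect_lt(null$r, 0.05)
  # brute-force evaluation of the published formula on a small set
  th8 <- c(0.3, -1.2, 2.8, 0.9, -0.4, 1.7, -2.2, 0.1)
  x8 <- c(1.2, 0.8, -0.3, 2.0, 0.5, -1.0, 0.7, 1.5)
  rcx <- cor(cos(th8), x8); rsx <- cor(sin(th8), x8)
  rcs <- cor(cos(th8), sin(th8))
  oracle <- sqrt((rcx^2 + rsx^2 - 2 * rcx * rsx * rcs) / (1 - rcs^2))
  got <- circ_linear_corr(th8, x8)
  expect_equal(got$r, oracle, tolerance = 1e-12)
  expect_equal(got$p, pchisq(8 * oracle^2, 2, lower.tail = FALSE))
  expect_error(circ_linear_corr(th8, rep(1, 8)), "degenerate|constant")
  expect_error(circ_linear_corr(rep(0.5, 8), x8), "degenerate")
})

test_that("partial circular-linear correlation removes the covariate", {
  set.seed(13)
  n <- 400
  th <- runif(n, -pi, pi)
  x <- cos(th) + rnorm(n, sd = 0.3)
  noise_cov <- rnorm(n)
  plain <- circ_linear_corr(th, x)
  part <- partial_circ_linear_corr(th, x, noise_cov)
  expect_lt(abs(plain$r - part$r), 0.05)
  # x fully determined by the covariate: nothing left to correlate
  cov2 <- rnorm(n)
  x2 <- 2 * cov2 - 1
  part2 <- partial_circ_linear_corr(th, x2, cov2)
  expect_lt(part2$r, 0.15)
  expect_error(partial_circ_linear_corr(th, x, rep(3, n)), "constant covariate")
})

test_that("participant-level coupling summary bundles the statistics", {
  set.seed(14)
  th <- rvonmises(80, -0.6, 3)
  res <- coupling_result(th)
  expect_s3_class(res, "coupling_result")
  expect_equal(res$rayleigh_z, res$n * res$resultant_length^2,
               tolerance = 1e-12)
  expect_angle_equal(res$preferred_phase, -0.6, 0.3)
  expect_lt(res$rayleigh_p, 0.001)
})
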