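test_that("mean pairwise correlation handles exact and degenerate cases", {
  m <- cbind(c(1, 2, 3), c(2, 4, 6), c(0, 1, 2))  # all perfectly correlated
  expect_equal(mean_pairwise_correlation(m), 1)
  m2 <- cbind(c(1, 2, 3), c(3, 2, 1))
  expect_equal(mean_pairwise_correlation(m2), -1)
  m3 <- cbind(c(1, 1, 1), c(2, 2, 2))             # no variance anywhere
  expect_true(is.na(mean_pairwise_correlation(m3)))
  expect_error(mean_pairwise_correlation(m[1, , drop = FALSE]), "2 trials")

  set.seed(1)
  indep <- matrix(rpois(1e4 * 6, 5), ncol = 6)
  expect_lt(abs(mean_pairwise_correlation(indep)), 0.02)
})

test_that("single-neuron Fano factors use the unbiased variance and drop silent neurons", {
  m <- cbind(c(0, 2), c(5, 5), c(0, 0))
  fs <- fano_single(m)
  expect_equal(fs$ff[1], 2)        # var (0,2) = 2, mean 1
  expect_equal(fs$ff[2], 0)
  expect_true(is.na(fs$ff[3]))
  expect_equal(fs$mean_ff, 1)

  set.seed(2)
  pois <- matrix(rpois(1e5, 10), ncol = 1)
  expect_equal(fano_single(pois)$mean_ff, 1, tolerance = 0.02)
})

test_that("population Fano decomposition is an exact identity", {
  set.seed(3)
  for (i in 1:10) {
    m <- matrix(rpois(40 * 7, sample(1:20, 1)), 40, 7)
    fp <- fano_population(m)
    expect_equal(fp$fano, fp$decomposition, tolerance = 1e-12)
  }
})

test_that("population Fano limiting cases: duplicated neurons and independence", {
  set.seed(4)
  x <- rpois(500, 8)
  dup <- matrix(rep(x, 6), ncol = 6)          # r = 1 copies
  fp <- fano_population(dup)
  expect_equal(fp$fano, 6 * fano_single(dup)$mean_ff, tolerance = 1e-10)
  expect_equal(fp$approx_homogeneous, fp$fano, tolerance = 1e-10)

  indep <- matrix(rpois(2e4 * 5, 10), ncol = 5)
  fi <- fano_population(indep)
  # sampled covariance terms vanish at the 1/sqrt(trials) scale
  expect_equal(fi$fano, sum(apply(indep, 2, var)) / sum(colMeans(indep)),
               tolerance = 0.02)
  expect_lt(abs(fi$mean_covariance) / fi$mean_variance, 0.02)

  zero <- matrix(0L, 5, 3)
  expect_true(is.na(fano_population(zero)$fano))
})

test_that("io curve interpolation is exact at knots and linear between them", {
  cfg <- tiny_config(background = FALSE)
  conn <- build_connectivity(cfg, 20)
  ens <- run_ensemble(cfg, conn, lambda_max = 2, n_stimuli = 5,
                      n_trials = 4, base_seed = 5)
  io <- fit_io_curve(ens, n_dense = 401)
  tot <- vapply(ens$counts, function(cm) mean(rowSums(cm)), numeric(1))
  idx <- vapply(ens$lambda_grid, function(l) which.min(abs(io$lambda - l)),
                integer(1))
  expect_equal(io$mu[idx], tot, tolerance = 1e-10)

  # synthetic linear knots stay linear on the dense grid
  fake <- ens
  fake$counts <- lapply(seq_along(ens$lambda_grid), function(s)
    matrix(rep(c(10, 20) * s, each = 25), 2, 50, byrow = FALSE))
  io2 <- fit_io_curve(fake, n_dense = 101)
  mid <- (io2$mu[1] + io2$mu[101]) / 2
  expect_equal(io2$mu[51], mid, tolerance = 1e-9)
})

test_that("gain recovers analytic derivatives", {
  io <- list(lambda = seq(0, 2, length.out = 2001),
             mu = 10 * seq(0, 2, length.out = 2001),
             var = rep(1, 2001))
  expect_equal(gain(io, 1), 10, tolerance = 1e-9)
  io$mu <- io$lambda^2
  expect_equal(gain(io, 1), 2, tolerance = 1e-4)
  io$mu <- rep(3, 2001)
  expect_true(all(abs(gain(io)) < 1e-12))
  expect_error(gain(io, 5), "outside")
})

test_that("discretized Gaussian channel rows are normalized with matching moments", {
  io <- list(lambda = c(1, 2, 3), mu = c(50, 100, 150), var = c(16, 25, 36))
  ch <- discretized_gaussian_channel(io)
  expect_true(all(abs(rowSums(ch$F) - 1) < 1e-12))
  m <- as.numeric(ch$F %*% ch$outputs)
  expect_true(all(abs(m - io$mu) < 0.1))
  v <- as.numeric(ch$F %*% ch$outputs^2) - m^2
  expect_true(all(abs(v - io$var) / io$var < 0.05))

  # zero-variance row degenerates to a point mass
  io0 <- list(lambda = 1:2, mu = c(10.4, 20), var = c(0, 4))
  ch0 <- discretized_gaussian_channel(io0)
  expect_equal(ch0$F[1, 11], 1)    # round(10.4) = 10, 0-based outputs
})

test_that("exponential tuning mean matches quadrature and grows with input spread", {
  direct <- integrate(function(x) exp(dnorm(x, 0, 1, log = TRUE) + x),
                      -40, 40, rel.tol = 1e-10)$value
  expect_equal(exponential_tuning_mean(1, 1, 0, 1), direct, tolerance = 1e-8)
  expect_equal(exponential_tuning_mean(2, 0.5, 1, 0), 2 * exp(0.5))
  sig <- seq(0, 2, by = 0.25)
  vals <- exponential_tuning_mean(1, 0.7, 1, sig)
  expect_true(all(diff(vals) > 0))
})

test_that("channel CSV round trip preserves the conditional matrix", {
  io <- list(lambda = c(0.5, 1), mu = c(5, 9), var = c(2, 3))
  ch <- discretized_gaussian_channel(io)
  path <- tempfile(fileext = ".csv")
  write_channel_csv(ch, path)
  back <- read_channel_csv(path)
  expect_equal(back$F, ch$F, tolerance = 1e-12)
  expect_equal(back$lambda, ch$lambda)
})

test_that("shared input raises the population Fano factor in a feedforward network", {
  # same per-neuron mean drive at both connection probabilities; more
  # sharing means more correlated counts and a larger population Fano
  ff_at <- function(P) {
    cfg <- tiny_config(P_ext = P, P_rec = 0, n_ext = 100L)
    conn <- build_connectivity(cfg, 61)
    cm <- do.call(rbind, lapply(1:30, function(t)
      simulate_trial(cfg, conn, 0.6, seed = 7000 + t)$counts))
    fano_population(cm)$fano
  }
  expect_gt(ff_at(0.9), ff_at(0.1))
})
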