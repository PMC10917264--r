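test_that("connectivity respects limiting probabilities and amplitudes", {
  cfg <- tiny_config(P_ext = 1, P_rec = 0)
  conn <- build_connectivity(cfg, 1)
  expect_true(all(conn$W_ext == cfg$a_ext))
  expect_equal(dim(conn$W_ext), c(50L, 50L))
  expect_true(all(conn$W_exc == 0))   # feedforward
  expect_true(all(conn$W_inh == 0))

  cfg2 <- tiny_config(P_rec = 0.5, a_rec = 0.2, alpha = 20)
  conn2 <- build_connectivity(cfg2, 2)
  expect_true(all(conn2$W_exc %in% c(0, 0.2)))
  expect_true(all(conn2$W_inh %in% c(0, 20 * 0.2)))
})

test_that("random-mode external in-degree matches n_ext * P_ext on average", {
  cfg <- tiny_config(P_ext = 0.3)
  degs <- unlist(lapply(1:20, function(s) {
    rowSums(build_connectivity(cfg, s)$W_ext != 0)
  }))
  # binomial mean 15, sd ~3.24; 1000 draws
  expect_equal(mean(degs), cfg$n_ext * cfg$P_ext, tolerance = 0.03)
  expect_gt(stats::var(degs), 0)
})

test_that("fixed in-degree mode gives exactly k external inputs per neuron", {
  cfg <- tiny_config(P_ext = 0.2, connection_mode = "fixed_in_degree")
  conn <- build_connectivity(cfg, 3)
  expect_true(all(rowSums(conn$W_ext != 0) == 10L))
  expect_warning(
    build_connectivity(tiny_config(P_ext = 0.123,
                                   connection_mode = "fixed_in_degree"), 4),
    "not an integer")
})

test_that("config validation rejects out-of-range probabilities", {
  expect_error(tiny_config(P_ext = 1.2), "P_ext")
  expect_error(tiny_config(P_rec = -0.1), "P_rec")
  expect_error(external_rate_per_neuron(1, tiny_config(P_ext = 0)),
               "positive")
})

test_that("external rate scaling keeps the mean per-neuron input fixed", {
  # Monte-Carlo oracle: expected summed input rate through the realized
  # connectivity equals lambda_ext regardless of P_ext
  for (P in c(0.5, 1)) {
    cfg <- tiny_config(P_ext = P, n_ext = 200L)
    lam0 <- external_rate_per_neuron(1, cfg)   # kHz per external neuron
    expect_equal(lam0, 1 / (200 * P))
    indeg <- unlist(lapply(1:30, function(s)
      rowSums(build_connectivity(cfg, s)$W_ext != 0)))
    expect_equal(mean(indeg) * lam0, 1, tolerance = 0.03)
  }
  expect_identical(external_rate_per_neuron(0, tiny_config()), 0)
})

test_that("OU background parameters match the moments of simulated OU noise", {
  # long-run empirical moments of an exact-update OU simulation
  pars <- ou_background_params(a = 1, tau = 5, lambda_bcg = 0.5)
  expect_equal(pars$mu, 2.5)
  expect_equal(pars$sigma, sqrt(1.25))

  set.seed(99)
  n <- 2e5; dt <- 0.1; tau <- 5
  ou <- numeric(n); ou[1] <- pars$mu
  a_dec <- exp(-dt / tau)
  innov <- pars$sigma * sqrt(1 - a_dec^2)
  for (i in 2:n)
    ou[i] <- pars$mu + (ou[i - 1] - pars$mu) * a_dec + innov * rnorm(1)
  expect_equal(mean(ou), pars$mu, tolerance = 0.02)
  expect_equal(sd(ou), pars$sigma, tolerance = 0.02)

  z <- ou_background_params(1, 5, 0)
  expect_identical(c(z$mu, z$sigma), c(0, 0))
})

test_that("quiet network stays at the resting potential fixed point", {
  cfg <- tiny_config(background = FALSE)
  conn <- build_connectivity(cfg, 5)
  tr <- simulate_trial(cfg, conn, lambda_ext = 0, seed = 1)
  expect_identical(sum(tr$counts), 0L)
  expect_true(all(abs(tr$V_final - cfg$E_L) < 1e-12))
})

test_that("single-neuron firing rate matches closed form and a refined-step reference", {
  # one neuron, no synapses, constant current above rheobase
  cfg <- network_config(n_ext = 0L, n_exc = 1L, n_inh = 0L, P_ext = 0.5,
                        P_rec = 0, background = FALSE, I_inj = 400,
                        warmup = 0)
  conn <- build_connectivity(cfg, 1)
  tr <- simulate_trial(cfg, conn, 0, duration = 5, seed = 1)
  rate_sim <- sum(tr$counts) / 5

  tau_m <- cfg$C_m / cfg$g_L
  t_isi <- tau_m * log(cfg$I_inj /
                         (cfg$I_inj - cfg$g_L * (cfg$theta_exc - cfg$E_L)))
  rate_closed <- 1000 / t_isi
  rate_ref <- lif_reference_rate(cfg, 400, t_total_ms = 5000, dt_ms = 0.001)

  expect_equal(rate_sim, rate_ref, tolerance = 0.01)
  expect_equal(rate_sim, rate_closed, tolerance = 0.01)
})

test_that("identical seeds give bit-identical trials", {
  cfg <- tiny_config()
  conn <- build_connectivity(cfg, 6)
  a <- simulate_trial(cfg, conn, 0.5, seed = 42, record_spikes = TRUE)
  b <- simulate_trial(cfg, conn, 0.5, seed = 42, record_spikes = TRUE)
  expect_identical(a$counts, b$counts)
  expect_identical(a$spike_time, b$spike_time)
  expect_identical(a$mean_I_Na, b$mean_I_Na)
  d <- simulate_trial(cfg, conn, 0.5, seed = 43)
  expect_false(identical(a$counts, d$counts))
})

test_that("spike times are strictly increasing per neuron", {
  cfg <- tiny_config()
  conn <- build_connectivity(cfg, 7)
  tr <- simulate_trial(cfg, conn, 1, seed = 8, record_spikes = TRUE)
  for (i in unique(tr$spike_id)) {
    ts <- tr$spike_time[tr$spike_id == i]
    expect_true(all(diff(ts) > 0))
  }
})

test_that("background conductance means match the OU parameterization", {
  cfg <- tiny_config()
  conn <- build_connectivity(cfg, 8)
  tr <- simulate_trial(cfg, conn, 0, duration = 4, seed = 9)
  bg_e <- ou_background_params(cfg$a_ext, cfg$tau_exc, cfg$lambda_bcg_exc)
  bg_i <- ou_background_params(cfg$alpha * cfg$a_ext, cfg$tau_inh,
                               cfg$lambda_bcg_inh)
  # 50 neurons x 40k steps, strongly autocorrelated; 3-sigma-of-mean band
  se_e <- bg_e$sigma / sqrt(50 * 4000 / (2 * cfg$tau_exc / cfg$dt))
  se_i <- bg_i$sigma / sqrt(50 * 4000 / (2 * cfg$tau_inh / cfg$dt))
  expect_lt(abs(tr$mean_g_bcg_exc - bg_e$mu), 3 * se_e + 0.01)
  expect_lt(abs(tr$mean_g_bcg_inh - bg_i$mu), 3 * se_i + 0.05)
})

test_that("stronger inhibitory scaling makes the net recurrent current more negative", {
  mk <- function(alpha) {
    cfg <- tiny_config(a_rec = 0.5, alpha = alpha)
    conn <- build_connectivity(cfg, 10)
    mean(vapply(1:4, function(s)
      mean(simulate_trial(cfg, conn, 1, seed = s)$mean_I_rec), numeric(1)))
  }
  expect_gt(mk(5), mk(25))
})

test_that("find_lambda_max inverts a deterministic surrogate and rejects bad targets", {
  cfg <- tiny_config()
  lam <- find_lambda_max(cfg, rate_fn = function(l) 10 * l, target_rate = 30)
  expect_equal(lam, 3, tolerance = 1e-6)
  expect_error(find_lambda_max(cfg, rate_fn = function(l) 5 + 10 * l,
                               target_rate = 4),
               "already reaches")
  expect_error(find_lambda_max(cfg, rate_fn = function(l) l / 1000,
                               target_rate = 30, ceiling = 100),
               "bracket")
})

test_that("run_ensemble is reproducible with an equidistant grid including endpoints", {
  cfg <- tiny_config()
  conn <- build_connectivity(cfg, 11)
  e1 <- run_ensemble(cfg, conn, lambda_max = 1, n_stimuli = 5, n_trials = 3,
                     base_seed = 3)
  e2 <- run_ensemble(cfg, conn, lambda_max = 1, n_stimuli = 5, n_trials = 3,
                     base_seed = 3)
  expect_identical(e1$counts, e2$counts)
  expect_equal(e1$lambda_grid, seq(0, 1, length.out = 5))
  expect_error(run_ensemble(cfg, conn, 1, n_trials = 1), "at least 2")

  quiet <- tiny_config(background = FALSE)
  qconn <- build_connectivity(quiet, 12)
  eq <- run_ensemble(quiet, qconn, lambda_max = 0.05, n_stimuli = 3,
                     n_trials = 2, base_seed = 4)
  expect_true(all(eq$counts[[1]] == 0))
})
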