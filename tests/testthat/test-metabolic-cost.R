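test_that("action potential cost reproduces the reference ATP accounting", {
  ap <- action_potential_cost()
  expect_equal(ap$charge, 1.5e-11)
  expect_equal(ap$min_na_ions, 9.375e7)
  expect_equal(ap$ionic_cost_atp, 1.25e8)
  expect_equal(ap$total_atp, 5.0e8)
  # geometry: 69-micron cell at 1 uF/cm^2 rounds to 150 pF
  expect_equal(round(capacitance_from_geometry(69, 1)), 150)
})

test_that("sodium split solves the two-channel system", {
  # independent linear-system oracle
  G <- 3.7; V <- -60
  A <- rbind(c(V - 90, V + 105), c(1, 1))
  b <- c(G * (V - 0), G)
  ref <- solve(A, b)
  split <- sodium_current_split(V, G)
  expect_equal(split$g_Na, ref[1], tolerance = 1e-12)
  expect_equal(split$g_Na / G, 105 / 195, tolerance = 1e-12)
  expect_equal(split$I_Na, ref[1] * (V - 90), tolerance = 1e-12)

  expect_equal(sodium_current_split(90, 5)$I_Na, 0)
  expect_equal(sodium_current_split(-60, 0)$g_Na, 0)
  expect_error(sodium_current_split(-60, 1, E_Na = -105, E_K = -105))
})

test_that("synaptic current cost converts charge to ATP linearly", {
  expect_equal(synaptic_current_cost(0, 1), 0)
  # 4.8e-19 A = 3 elementary charges per second = 1 ATP per second
  expect_equal(synaptic_current_cost(4.8e-19 * 1e12, 1), 1)
  expect_equal(synaptic_current_cost(10, 2), 2 * synaptic_current_cost(10, 1))
  expect_error(synaptic_current_cost(1, 0), "positive")
})

test_that("activity cost assembles the action-potential and synaptic terms", {
  io <- list(lambda = seq(0, 1, length.out = 11),
             mu = 100 * seq(0, 1, length.out = 11),
             var = rep(4, 11),
             rate_exc = 10 * seq(0, 1, length.out = 11),
             rate_inh = 20 * seq(0, 1, length.out = 11),
             I_Na_exc = rep(-50, 11), I_Na_inh = rep(-80, 11),
             Delta_T = 1)
  cfg <- tiny_config(P_ext = 0.5)
  cost <- activity_cost(io, cfg, ap_cost = 5e8)
  # components sum exactly
  expect_equal(cost$w, cost$ap_evoked + cost$ap_external + cost$synaptic)
  expect_true(all(diff(cost$w) > 0))
  expect_equal(cost$W0, cost$w[1])
  # halving P_ext doubles only the external-AP component
  cfg2 <- tiny_config(P_ext = 0.25)
  cost2 <- activity_cost(io, cfg2, ap_cost = 5e8)
  expect_equal(cost2$ap_external, 2 * cost$ap_external)
  expect_equal(cost2$synaptic, cost$synaptic)

  # quiet network costs nothing
  io0 <- io
  io0$rate_exc <- io0$rate_inh <- rep(0, 11)
  io0$I_Na_exc <- io0$I_Na_inh <- rep(0, 11)
  c0 <- activity_cost(io0, cfg, ap_cost = 5e8)
  expect_equal(c0$w[1], 0)
})

test_that("background-on resting cost is positive and composed of non-external terms", {
  cfg <- tiny_config()
  conn <- build_connectivity(cfg, 31)
  ens <- run_ensemble(cfg, conn, lambda_max = 0.5, n_stimuli = 3,
                      n_trials = 6, base_seed = 7)
  io <- fit_io_curve(ens, n_dense = 31)
  cost <- activity_cost(io, cfg)
  expect_gt(cost$W0, 0)
  expect_equal(cost$ap_external[1], 0)       # no stimulus at rest
  expect_gt(cost$synaptic[1], 0)             # background-driven Na current
})

test_that("cost slope recovers linear parameters and the per-spike cost", {
  lam <- seq(0, 2, length.out = 201)
  io <- list(lambda = lam, mu = 10 * lam, var = rep(1, 201))
  cost <- structure(list(lambda = lam, w = 5 * lam + 2, W0 = 2),
                    class = "cost_curve")
  cs <- cost_slope(cost, io)
  expect_true(all(abs(cs$w0 - 5) < 1e-9))
  expect_equal(cs$W0, 2)
  expect_true(all(abs(cs$w_AP - 0.5) < 1e-9))
  expect_equal(cs$w0_ls, 5, tolerance = 1e-9)
  expect_equal(cs$w_AP_ls, 0.5, tolerance = 1e-9)

  # convex cost has nondecreasing per-lambda slope
  cost2 <- structure(list(lambda = lam, w = lam^2, W0 = 0),
                     class = "cost_curve")
  cs2 <- cost_slope(cost2, io)
  expect_true(all(diff(cs2$w0) > -1e-9))
})

test_that("stronger recurrence raises the cost of reaching the same output", {
  # inhibition-dominated recurrence lowers the gain, so matching a given
  # mean output needs more drive and more ATP
  curves <- lapply(c(0, 1), function(a_rec) {
    cfg <- tiny_config(a_rec = a_rec, n_ext = 100L)
    conn <- build_connectivity(cfg, 62)
    ens <- run_ensemble(cfg, conn, lambda_max = 0.8, n_stimuli = 4,
                        n_trials = 8, base_seed = 9)
    io <- fit_io_curve(ens, n_dense = 41)
    list(mu = io$mu, w = activity_cost(io, cfg)$w)
  })
  # compare at one mean output level inside both response ranges
  mu_ref <- 0.7 * min(vapply(curves, function(cu) max(cu$mu), numeric(1)))
  w_at <- vapply(curves, function(cu)
    approx(cu$mu, cu$w, xout = mu_ref, ties = "ordered")$y, numeric(1))
  expect_gt(w_at[2], w_at[1])
})
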