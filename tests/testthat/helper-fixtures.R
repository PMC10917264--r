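# Shared fixtures, built in code at test time.

# a tiny network small enough for many repeated simulations
tiny_config <- function(...) {
  args <- list(...)
  defaults <- list(n_ext = 50L, n_exc = 40L, n_inh = 10L, P_ext = 0.2)
  do.call(enercode::network_config, utils::modifyList(defaults, args))
}

# random row-stochastic channel for information-theory property tests
random_channel <- function(K, M, seed) {
  set.seed(seed)
  F <- matrix(stats::rexp(K * M), K, M)
  F <- F / rowSums(F)
  list(F = F, lambda = seq_len(K), outputs = seq_len(M) - 1L)
}

# exhaustive grid search over the 2-simplex for 3-input channels
simplex_grid_capacity <- function(F, w = NULL, W = Inf, step = 1e-3) {
  p1 <- seq(0, 1, by = step)
  grid <- expand.grid(p1 = p1, p2 = p1)
  grid <- grid[grid$p1 + grid$p2 <= 1 + 1e-12, ]
  P <- cbind(grid$p1, grid$p2, pmax(0, 1 - grid$p1 - grid$p2))
  Hrow <- -rowSums(ifelse(F > 0, F * log2(F), 0))
  Q <- P %*% F
  Hq <- -rowSums(ifelse(Q > 0, Q * log2(Q), 0))
  I <- Hq - as.numeric(P %*% Hrow)
  if (!is.null(w)) I[as.numeric(P %*% w) > W] <- -Inf
  max(I)
}

# reference high-resolution single-neuron LIF integrator (plain R),
# independent of the compiled simulator
lif_reference_rate <- function(config, I_inj, t_total_ms, dt_ms) {
  v <- config$E_L
  n_spikes <- 0L
  steps <- round(t_total_ms / dt_ms)
  for (i in seq_len(steps)) {
    dv <- dt_ms / config$C_m *
      (config$g_L * (config$E_L - v) + I_inj)
    v <- v + dv
    if (v >= config$theta_exc) {
      v <- config$E_L
      n_spikes <- n_spikes + 1L
    }
  }
  n_spikes / (t_total_ms / 1000)
}
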