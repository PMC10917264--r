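#' Simulate one trial of the spiking network
#'
#' Forward-integrates the conductance-based LIF network at time step
#' `config$dt`.  The run consists of a warm-up interval (`config$warmup`,
#' discarded) followed by a recording window of `duration` seconds over
#' which spike counts, the time-averaged excitatory synaptic Na+ current
#' per neuron (for the metabolic cost model) and the net recurrent current
#' are accumulated.  Initial conditions: membrane potentials at `E_L`,
#' synaptic conductances at zero, OU background states at their means.
#'
#' @param config a [network_config()].
#' @param conn a [build_connectivity()] result.
#' @param lambda_ext stimulus: mean external input rate per postsynaptic
#'   neuron (kHz).
#' @param duration recording window (s); defaults to `config$Delta_T`.
#' @param seed integer seed; identical seeds give identical trials.
#' @param record_spikes keep individual spike times (ms) in the result.
#' @return An object of class `spike_data`: spike ids/times, per-neuron
#'   spike `counts` over the window, `mean_I_Na` (pA, per neuron, negative
#'   for inward current), `mean_I_rec` (pA), background conductance means,
#'   external spike count and metadata.
#' @export
simulate_trial <- function(config, conn, lambda_ext, duration = config$Delta_T,
                           seed = 1L, record_spikes = FALSE) {
  validate_network_config(config)
  if (duration <= 0) stop("duration must be positive")
  if (lambda_ext < 0) stop("lambda_ext must be non-negative")

  lambda0 <- if (lambda_ext > 0) external_rate_per_neuron(lambda_ext, config) else 0
  bg_e <- ou_background_params(config$a_ext, config$tau_exc, config$lambda_bcg_exc)
  bg_i <- ou_background_params(config$alpha * config$a_ext, config$tau_inh,
                               config$lambda_bcg_inh)

  n_steps <- as.integer(round((config$warmup + duration) * 1000 / config$dt))
  record_start <- as.integer(round(config$warmup * 1000 / config$dt))

  flat <- conn_flatten(conn)
  ion <- sodium_reversals()
  na_frac <- (ion$E_K - config$E_e) / (ion$E_K - ion$E_Na)

  set.seed(as.integer(seed %% 2147483647))
  res <- simulate_lif_cpp(
    config$n_exc, config$n_inh, config$n_ext,
    flat$ext_ptr, flat$ext_idx, config$a_ext,
    flat$exc_ptr, flat$exc_idx, config$a_rec,
    flat$inh_ptr, flat$inh_idx, config$alpha * config$a_rec,
    config$C_m, config$g_L, config$E_L, config$E_e, config$E_i,
    config$tau_exc, config$tau_inh, config$theta_exc, config$theta_inh,
    bg_e$mu, bg_e$sigma, bg_i$mu, bg_i$sigma, config$background,
    config$clip_background,
    lambda0, config$dt, n_steps, record_start, config$I_inj,
    na_frac, ion$E_Na, record_spikes)

  res$duration <- duration
  res$lambda_ext <- lambda_ext
  res$seed <- seed
  class(res) <- "spike_data"
  res
}

# Flatten adjacency (pre -> 0-based post indices) for the C++ core.
conn_flatten <- function(conn) {
  flat_one <- function(W) {
    nz <- which(W != 0, arr.ind = TRUE)
    ord <- order(nz[, 2L], nz[, 1L])
    idx <- nz[ord, 1L] - 1L
    ptr <- c(0L, cumsum(tabulate(nz[, 2L], nbins = ncol(W))))
    list(ptr = as.integer(ptr), idx = as.integer(idx))
  }
  e <- flat_one(conn$W_ext); x <- flat_one(conn$W_exc); i <- flat_one(conn$W_inh)
  list(ext_ptr = e$ptr, ext_idx = e$idx,
       exc_ptr = x$ptr, exc_idx = x$idx,
       inh_ptr = i$ptr, inh_idx = i$idx)
}

#' Mean total population output rate at a given stimulus
#'
#' Simulates `n_trials` independent trials and returns the mean summed
#' excitatory + inhibitory spike rate (kHz).
#'
#' @inheritParams simulate_trial
#' @param n_trials number of trials to average.
#' @param base_seed seed from which per-trial seeds are derived.
#' @return Mean total output rate (kHz).
#' @export
population_rate <- function(config, conn, lambda_ext, n_trials = 6,
                            base_seed = 1L) {
  rates <- vapply(seq_len(n_trials), function(t) {
    sd <- derive_seed(base_seed, "probe", t * 131071 + round(lambda_ext * 1e6) %% 65536)
    trial <- simulate_trial(config, conn, lambda_ext, seed = sd)
    sum(trial$counts) / trial$duration / 1000  # kHz
  }, numeric(1))
  mean(rates)
}

#' Find the stimulus driving the network to a target output rate
#'
#' Brackets and bisects the (assumed monotone nondecreasing) relationship
#' between the external input rate and the mean total population output
#' rate, then refines with a local linear fit over probes around the
#' optimum.  The default target corresponds to a 30 Hz mean single-neuron
#' rate, i.e. `0.03 * (n_exc + n_inh)` kHz of total output.
#'
#' @param config a [network_config()].
#' @param conn a [build_connectivity()] result (ignored when `rate_fn` is
#'   supplied).
#' @param target_rate target total output rate (kHz).
#' @param trials_per_probe trials averaged per bisection probe.
#' @param ceiling largest admissible stimulus (kHz); failure to bracket the
#'   target below it is an error.
#' @param rate_fn optional function `lambda -> rate (kHz)` replacing the
#'   simulator (used for deterministic surrogates).
#' @param base_seed seed for probe-trial derivation.
#' @param tol relative tolerance on the achieved rate (default 2%).
#' @return The stimulus `lambda_max` (kHz).
#' @export
find_lambda_max <- function(config, conn = NULL,
                            target_rate = 0.03 * (config$n_exc + config$n_inh),
                            trials_per_probe = 8, ceiling = 500,
                            rate_fn = NULL, base_seed = 1L, tol = 0.02) {
  if (target_rate <= 0) stop("target_rate must be positive")
  if (is.null(rate_fn)) {
    force(conn)
    rate_fn <- function(lambda, n_trials = trials_per_probe)
      population_rate(config, conn, lambda, n_trials = n_trials,
                      base_seed = base_seed)
  } else {
    fn <- rate_fn
    rate_fn <- function(lambda, n_trials = trials_per_probe) fn(lambda)
  }

  r0 <- rate_fn(0)
  if (r0 >= target_rate)
    stop("output at lambda = 0 already reaches the target rate")

  lo <- 0; hi <- 1; r_hi <- rate_fn(hi)
  while (r_hi < target_rate) {
    lo <- hi
    hi <- hi * 2
    if (hi > ceiling)
      stop("could not bracket the target rate below the stimulus ceiling")
    r_hi <- rate_fn(hi)
  }

  for (iter in seq_len(14)) {
    mid <- (lo + hi) / 2
    r_mid <- rate_fn(mid)
    if (r_mid < target_rate) lo <- mid else hi <- mid
    if ((hi - lo) < 0.005 * (hi + lo) / 2) break
  }
  lam <- (lo + hi) / 2

  # local linear refinement against probe noise
  probes <- lam * c(0.92, 1, 1.08)
  rates <- vapply(probes, function(l) rate_fn(l, n_trials = 3 * trials_per_probe),
                  numeric(1))
  fit <- stats::lm(rates ~ probes)
  slope <- stats::coef(fit)[[2]]
  if (is.finite(slope) && slope > 0) {
    cand <- (target_rate - stats::coef(fit)[[1]]) / slope
    if (cand > 0.8 * lam && cand < 1.25 * lam) lam <- cand
  }
  lam
}

#' Simulate a trial ensemble over an equidistant stimulus grid
#'
#' With one frozen connectivity, simulates `n_trials` independent trials at
#' each of `n_stimuli` equidistant stimulus intensities from 0 to
#' `lambda_max`.  Per-trial seeds are derived deterministically from
#' `base_seed`, so the whole ensemble is reproducible and any single trial
#' can be re-run in isolation.
#'
#' @param config a [network_config()].
#' @param conn a [build_connectivity()] result, shared by all trials.
#' @param lambda_max largest stimulus on the grid (kHz); see
#'   [find_lambda_max()].
#' @param n_stimuli number of grid points (including 0 and `lambda_max`).
#' @param n_trials trials per stimulus (at least 2).
#' @param base_seed integer seed for the trial-seed streams.
#' @return An object of class `trial_ensemble`: `lambda_grid` (kHz),
#'   `counts` (list of trials x neurons integer matrices), per-stimulus
#'   mean excitatory-synaptic Na+ currents per neuron (`I_Na_exc`,
#'   `I_Na_inh`, pA), the config and seeds.
#' @export
run_ensemble <- function(config, conn, lambda_max, n_stimuli = 31L,
                         n_trials = 100L, base_seed = 1L) {
  if (n_trials < 2) stop("n_trials must be at least 2 (variance undefined)")
  if (n_stimuli < 2) stop("n_stimuli must be at least 2")
  lambda_grid <- seq(0, lambda_max, length.out = n_stimuli)
  n_tot <- config$n_exc + config$n_inh
  exc_idx <- seq_len(config$n_exc)
  inh_idx <- config$n_exc + seq_len(config$n_inh)

  counts <- vector("list", n_stimuli)
  I_Na_exc <- numeric(n_stimuli)
  I_Na_inh <- numeric(n_stimuli)
  for (s in seq_len(n_stimuli)) {
    cmat <- matrix(0L, n_trials, n_tot)
    ina_e <- 0; ina_i <- 0
    for (t in seq_len(n_trials)) {
      sd <- derive_seed(base_seed, "trial", (s - 1L) * n_trials + t)
      trial <- simulate_trial(config, conn, lambda_grid[s], seed = sd)
      cmat[t, ] <- trial$counts
      ina_e <- ina_e + mean(trial$mean_I_Na[exc_idx])
      ina_i <- ina_i + mean(trial$mean_I_Na[inh_idx])
    }
    counts[[s]] <- cmat
    I_Na_exc[s] <- ina_e / n_trials
    I_Na_inh[s] <- ina_i / n_trials
  }

  structure(list(lambda_grid = lambda_grid, counts = counts,
                 I_Na_exc = I_Na_exc, I_Na_inh = I_Na_inh,
                 config = config, conn_seed = conn$seed,
                 base_seed = base_seed, Delta_T = config$Delta_T),
            class = "trial_ensemble")
}

#' Per-stimulus summary statistics of an ensemble
#'
#' @param ensemble a [run_ensemble()] result.
#' @return A data.frame with, per stimulus: mean and variance of the total
#'   population count, per-population mean rates (Hz per neuron), mean
#'   pairwise correlation and population Fano factor.
#' @export
summarize_ensemble <- function(ensemble) {
  cfg <- ensemble$config
  exc_idx <- seq_len(cfg$n_exc)
  inh_idx <- cfg$n_exc + seq_len(cfg$n_inh)
  rows <- lapply(seq_along(ensemble$lambda_grid), function(s) {
    cm <- ensemble$counts[[s]]
    tot <- rowSums(cm)
    fp <- fano_population(cm)
    data.frame(
      lambda_ext = ensemble$lambda_grid[s],
      mu_total = mean(tot), var_total = stats::var(tot),
      rate_exc = mean(cm[, exc_idx]) / ensemble$Delta_T,
      rate_inh = mean(cm[, inh_idx]) / ensemble$Delta_T,
      mean_pairwise_corr = mean_pairwise_correlation(cm),
      fano_population = fp$fano,
      I_Na_exc = ensemble$I_Na_exc[s],
      I_Na_inh = ensemble$I_Na_inh[s])
  })
  do.call(rbind, rows)
}

#' Export a spike raster as a two-column CSV
#'
#' @param spikes a [simulate_trial()] result with `record_spikes = TRUE`.
#' @param path output file.
#' @export
write_spike_raster <- function(spikes, path) {
  utils::write.csv(data.frame(neuron_id = spikes$spike_id + 1L,
                              time_ms = spikes$spike_time),
                   path, row.names = FALSE)
  invisible(path)
}
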