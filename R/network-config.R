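#' Network configuration for the recurrent LIF model
#'
#' Builds a validated parameter set for the three-population network:
#' an external population of Poisson neurons projecting onto excitatory and
#' inhibitory leaky integrate-and-fire (LIF) populations with conductance
#' based synapses and Ornstein-Uhlenbeck (OU) background input.  Defaults
#' are the standard cortical parameter set used throughout the package.
#'
#' Synaptic amplitudes are conductance increments (nS) applied to an
#' exponentially decaying synaptic conductance on each presynaptic spike.
#' Recurrent excitatory synapses have amplitude `a_rec`; recurrent
#' inhibitory synapses are scaled by `alpha` (`a_inh = alpha * a_rec`), as
#' are the inhibitory background amplitudes (`alpha * a_ext`).
#'
#' @param n_ext,n_exc,n_inh population sizes (external, excitatory,
#'   inhibitory).
#' @param P_ext probability of a connection from an external neuron onto a
#'   network neuron; controls how much input is shared across neurons.
#' @param P_rec probability of each recurrent connection (exc-exc, exc-inh,
#'   inh-inh, inh-exc).
#' @param a_ext external synaptic amplitude (nS).
#' @param a_rec recurrent excitatory synaptic amplitude (nS).
#' @param alpha inhibitory scaling factor (dimensionless); inhibitory
#'   amplitudes are `alpha` times their excitatory counterparts.
#' @param C_m membrane capacitance (pF).
#' @param g_L leak conductance (nS).
#' @param E_L,E_e,E_i resting, excitatory-reversal and inhibitory-reversal
#'   potentials (mV).
#' @param tau_exc,tau_inh excitatory and inhibitory synaptic decay time
#'   constants (ms).
#' @param theta_exc,theta_inh firing thresholds of excitatory and
#'   inhibitory neurons (mV).
#' @param lambda_bcg_exc,lambda_bcg_inh rates (kHz) of the Poisson shot
#'   noise whose first two moments the OU background reproduces.
#' @param dt integration time step (ms).
#' @param Delta_T spike-counting window (s).
#' @param warmup warm-up interval (s) discarded before counting.
#' @param connection_mode `"random"` for independent Bernoulli(P) wiring or
#'   `"fixed_in_degree"` for exactly `round(n_ext * P_ext)` external inputs
#'   per neuron.
#' @param I_inj constant injected current (pA), a single-neuron testing
#'   probe; 0 in all network analyses.
#' @param background logical; if `FALSE` the OU background is disabled.
#' @param clip_background logical; if `TRUE`, negative excursions of the
#'   OU background conductances are clipped to zero where they enter a
#'   synaptic current (the OU state itself is never clipped).  The
#'   default `FALSE` integrates the stated background equations as
#'   written, which is required to reproduce the 0.5-1 Hz spontaneous
#'   rate of the reference parameterization.
#'
#' @return An object of class `network_config` (a named list).
#' @examples
#' cfg <- network_config()
#' cfg$alpha * cfg$a_rec  # inhibitory recurrent amplitude (nS)
#' @export
network_config <- function(n_ext = 1000L, n_exc = 800L, n_inh = 200L,
                           P_ext = 0.2, P_rec = 0.2,
                           a_ext = 1, a_rec = 0.01, alpha = 20,
                           C_m = 150, g_L = 10,
                           E_L = -80, E_e = 0, E_i = -80,
                           tau_exc = 5, tau_inh = 5,
                           theta_exc = -55, theta_inh = -60,
                           lambda_bcg_exc = 0.5, lambda_bcg_inh = 0.125,
                           dt = 0.1, Delta_T = 1, warmup = 0.2,
                           connection_mode = c("random", "fixed_in_degree"),
                           I_inj = 0, background = TRUE,
                           clip_background = FALSE) {
  connection_mode <- match.arg(connection_mode)
  cfg <- list(
    n_ext = as.integer(n_ext), n_exc = as.integer(n_exc),
    n_inh = as.integer(n_inh),
    P_ext = P_ext, P_rec = P_rec,
    a_ext = a_ext, a_rec = a_rec, alpha = alpha,
    C_m = C_m, g_L = g_L, E_L = E_L, E_e = E_e, E_i = E_i,
    tau_exc = tau_exc, tau_inh = tau_inh,
    theta_exc = theta_exc, theta_inh = theta_inh,
    lambda_bcg_exc = lambda_bcg_exc, lambda_bcg_inh = lambda_bcg_inh,
    dt = dt, Delta_T = Delta_T, warmup = warmup,
    connection_mode = connection_mode,
    I_inj = I_inj, background = isTRUE(background),
    clip_background = isTRUE(clip_background)
  )
  class(cfg) <- "network_config"
  validate_network_config(cfg)
  cfg
}

validate_network_config <- function(cfg) {
  stopifnot(
    cfg$n_ext >= 0, cfg$n_exc >= 0, cfg$n_inh >= 0,
    cfg$a_ext >= 0, cfg$a_rec >= 0, cfg$alpha >= 0,
    cfg$C_m > 0, cfg$g_L >= 0,
    cfg$tau_exc > 0, cfg$tau_inh > 0,
    cfg$lambda_bcg_exc >= 0, cfg$lambda_bcg_inh >= 0,
    cfg$dt > 0, cfg$Delta_T > 0, cfg$warmup >= 0
  )
  if (cfg$P_ext < 0 || cfg$P_ext > 1) stop("P_ext must lie in [0, 1]")
  if (cfg$P_rec < 0 || cfg$P_rec > 1) stop("P_rec must lie in [0, 1]")
  if (!(cfg$E_i <= cfg$E_L)) stop("E_i must not exceed E_L")
  if (!(cfg$E_L < cfg$theta_inh && cfg$E_L < cfg$theta_exc))
    stop("E_L must lie below both firing thresholds")
  if (!(cfg$theta_exc < cfg$E_e && cfg$theta_inh < cfg$E_e))
    stop("firing thresholds must lie below E_e")
  invisible(cfg)
}

#' Scaled-down network configuration
#'
#' A 1:5 scaled version of the default network (200 external, 160
#' excitatory, 40 inhibitory neurons) used for desk-scale analyses and
#' tests.  All single-neuron parameters are unchanged; only population
#' sizes shrink, so per-neuron input statistics are preserved by the
#' external-rate scaling.
#'
#' @param ... overrides passed on to [network_config()].
#' @return A `network_config`.
#' @export
mini_network_config <- function(...) {
  args <- list(...)
  defaults <- list(n_ext = 200L, n_exc = 160L, n_inh = 40L)
  do.call(network_config, utils::modifyList(defaults, args))
}

#' Per-neuron rate of the external population
#'
#' The stimulus is parametrized by `lambda_ext`, the mean summed synaptic
#' input rate received by one postsynaptic neuron.  Each of the `n_ext`
#' external Poisson neurons therefore fires at
#' `lambda_ext / (n_ext * P_ext)` so that the expected input through an
#' expected in-degree of `n_ext * P_ext` synapses equals `lambda_ext`
#' regardless of the connection probability.  The total external
#' population rate is then `lambda_ext / P_ext`.
#'
#' @param lambda_ext mean input rate per postsynaptic neuron (kHz).
#' @param config a [network_config()].
#' @return Single-external-neuron firing rate (kHz).
#' @export
external_rate_per_neuron <- function(lambda_ext, config) {
  stopifnot(lambda_ext >= 0)
  if (config$P_ext <= 0) stop("P_ext must be positive to scale external rates")
  lambda_ext / (config$n_ext * config$P_ext)
}

#' Ornstein-Uhlenbeck background parameters
#'
#' Mean and stationary standard deviation of the OU background conductance
#' chosen to match the first two moments of exponentially filtered Poisson
#' shot noise with amplitude `a`, decay `tau` and rate `lambda_bcg`:
#' `mu = a * tau * lambda_bcg`, `sigma = a * sqrt(lambda_bcg * tau / 2)`.
#'
#' @param a synaptic amplitude (nS).
#' @param tau synaptic decay constant (ms).
#' @param lambda_bcg shot-noise rate (kHz).
#' @return Named list with `mu` and `sigma` (nS).
#' @export
ou_background_params <- function(a, tau, lambda_bcg) {
  stopifnot(a >= 0, tau >= 0, lambda_bcg >= 0)
  list(mu = a * tau * lambda_bcg, sigma = a * sqrt(lambda_bcg * tau / 2))
}

#' Ratio of mean inhibitory to excitatory background conductance
#'
#' With both background processes sharing the same decay constant, the
#' mean-conductance ratio reduces to
#' `alpha * lambda_bcg_inh / lambda_bcg_exc` (5 with the defaults), the
#' inhibition-dominated background balance observed in vivo.
#'
#' @param config a [network_config()].
#' @return Dimensionless ratio.
#' @export
background_conductance_ratio <- function(config = network_config()) {
  exc <- ou_background_params(config$a_ext, config$tau_exc,
                              config$lambda_bcg_exc)
  inh <- ou_background_params(config$alpha * config$a_ext, config$tau_inh,
                              config$lambda_bcg_inh)
  inh$mu / exc$mu
}

#' Read or write a network configuration as YAML
#'
#' @param path file path.
#' @param config a [network_config()] (for writing).
#' @return `read_network_config()` returns a `network_config`.
#' @export
read_network_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read YAML configurations")
  vals <- yaml::read_yaml(path)
  do.call(network_config, vals)
}

#' @rdname read_network_config
#' @export
write_network_config <- function(config, path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to write YAML configurations")
  vals <- unclass(config)
  yaml::write_yaml(vals, path)
  invisible(path)
}

#' Derive a named-stream seed from one base seed
#'
#' Deterministic seed streams (`connectivity`, `trial`, `probe`,
#' `subsample`) derived from a single base seed, so that any individual
#' trial of an ensemble is reproducible in isolation.  Returned values
#' stay below 2^31 - 1.
#'
#' @param base_seed integer base seed.
#' @param stream one of `"connectivity"`, `"trial"`, `"probe"`,
#'   `"subsample"`.
#' @param index index within the stream (e.g. trial number).
#' @return A numeric seed suitable for [set.seed()].
#' @export
derive_seed <- function(base_seed, stream, index = 0L) {
  streams <- c(connectivity = 1L, trial = 2L, probe = 3L, subsample = 4L)
  sid <- streams[[stream]]
  (as.numeric(base_seed) * 48271 + sid * 1664525 + as.numeric(index) * 69069) %%
    2147483647
}
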