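#' Ion-channel reversal potentials used in the Na+ cost accounting
#'
#' The excitatory synaptic current (reversal 0 mV) is carried jointly by
#' Na+ and K+ channels with reversal potentials 90 mV and -105 mV.
#'
#' @return Named list with `E_Na` and `E_K` (mV).
#' @export
sodium_reversals <- function() list(E_Na = 90, E_K = -105)

#' Action-potential cost model
#'
#' Parameters of the ATP cost of one action potential: depolarizing a
#' membrane of capacitance `C_m` by `Delta_V` requires a minimum charge
#' `Delta_V * C_m`; the implied Na+ influx is quadrupled
#' (`overlap_factor`) to account for simultaneously open K+ channels;
#' pumping costs one ATP per 3 Na+; and the somatic cost is quadrupled
#' again (`axon_factor`) because about 75% of the action-potential cost is
#' incurred in the axon.
#'
#' @param Delta_V depolarization (mV).
#' @param C_m membrane capacitance (pF); the default corresponds to a
#'   69-micron cell at 1 uF/cm^2, see [capacitance_from_geometry()].
#' @param overlap_factor Na+/K+ co-activation multiplier.
#' @param axon_factor total-to-somatic cost multiplier.
#' @param atp_per_na ATP molecules needed per Na+ ion pumped (1/3).
#' @return An object of class `ap_cost_model`.
#' @export
ap_cost_model <- function(Delta_V = 100, C_m = 150, overlap_factor = 4,
                          axon_factor = 4, atp_per_na = 1 / 3) {
  stopifnot(Delta_V > 0, C_m > 0, overlap_factor > 0, axon_factor > 0,
            atp_per_na > 0)
  structure(list(Delta_V = Delta_V, C_m = C_m,
                 overlap_factor = overlap_factor, axon_factor = axon_factor,
                 atp_per_na = atp_per_na),
            class = "ap_cost_model")
}

#' Total membrane capacitance from cell geometry
#'
#' `C_m = pi * D^2 * c_m` for a spherical cell of diameter `D` with
#' specific membrane capacitance `c_m`.
#'
#' @param diameter_um cell diameter (micrometers).
#' @param c_m_uF_cm2 specific capacitance (uF/cm^2).
#' @return Capacitance in pF.
#' @export
capacitance_from_geometry <- function(diameter_um = 69, c_m_uF_cm2 = 1) {
  d_cm <- diameter_um * 1e-4
  pi * d_cm^2 * c_m_uF_cm2 * 1e6   # uF -> pF
}

elementary_charge <- 1.6e-19

#' ATP cost of one action potential
#'
#' @param model an [ap_cost_model()].
#' @return List with the intermediate quantities: `charge` (Coulomb),
#'   `min_na_ions`, `na_influx` (after the K+ overlap factor),
#'   `ionic_cost_atp` (somatic pumping cost) and `total_atp` (including
#'   axonal propagation).
#' @export
action_potential_cost <- function(model = ap_cost_model()) {
  charge <- model$Delta_V * 1e-3 * model$C_m * 1e-12     # V * F = C
  min_ions <- charge / elementary_charge
  influx <- model$overlap_factor * min_ions
  ionic <- influx * model$atp_per_na
  list(charge = charge, min_na_ions = min_ions, na_influx = influx,
       ionic_cost_atp = ionic, total_atp = model$axon_factor * ionic)
}

#' Na+ / K+ split of an excitatory synaptic conductance
#'
#' The excitatory synaptic current `G * (V - E_e)` is carried by Na+ and
#' K+ channels whose conductances sum to `G` and reproduce the total
#' current:
#' `g_Na (V - E_Na) + g_K (V - E_K) = G (V - E_e)`, `g_Na + g_K = G`,
#' giving the voltage-independent split
#' `g_Na = G * (E_K - E_e) / (E_K - E_Na)`.
#'
#' @param V membrane potential (mV).
#' @param G total excitatory synaptic conductance (nS).
#' @param E_e excitatory synaptic reversal potential (mV).
#' @param E_Na,E_K Na+ and K+ reversal potentials (mV).
#' @return List with `g_Na` (nS) and `I_Na` (pA; negative = inward).
#' @export
sodium_current_split <- function(V, G, E_e = 0, E_Na = 90, E_K = -105) {
  if (E_K == E_Na) stop("E_K equal to E_Na makes the split singular")
  if (!(E_K < E_e && E_e < E_Na)) stop("require E_K < E_e < E_Na")
  if (any(G < 0)) stop("conductance must be non-negative")
  g_Na <- G * (E_K - E_e) / (E_K - E_Na)
  list(g_Na = g_Na, I_Na = g_Na * (V - E_Na))
}

#' ATP cost of a sustained synaptic Na+ current
#'
#' Each 3 Na+ ions pumped out cost one ATP, so a mean current `I_Na`
#' flowing for `Delta_T` costs `|I_Na| * Delta_T / (3 e)` ATP.
#'
#' @param mean_I_Na mean Na+ current (pA).
#' @param Delta_T duration (s).
#' @return ATP count.
#' @export
synaptic_current_cost <- function(mean_I_Na, Delta_T) {
  if (Delta_T <= 0) stop("Delta_T must be positive")
  abs(mean_I_Na) * 1e-12 * Delta_T / (3 * elementary_charge)
}

#' Metabolic cost curve of the network activity
#'
#' Converts the interpolated activity of the network into ATP per counting
#' window as a function of the stimulus:
#' an action-potential term covering the excitatory, inhibitory and
#' external populations (the total external population rate is
#' `lambda / P_ext`), plus the pumping cost of the mean excitatory
#' synaptic Na+ currents in the excitatory and inhibitory populations
#' (background-driven, external and recurrent excitatory conductances;
#' inhibitory currents and synaptic currents inside the external
#' population are not metered).
#'
#' @param io an [fit_io_curve()] result carrying per-population rates and
#'   mean Na+ currents.
#' @param config the [network_config()] of the simulated network.
#' @param ap_cost ATP per action potential (default from
#'   [action_potential_cost()]).
#' @return An object of class `cost_curve`: `lambda` (kHz), `w` (ATP per
#'   window), components `ap_evoked`, `ap_external`, `synaptic`, resting
#'   cost `W0` and the AP cost used.
#' @export
activity_cost <- function(io, config = io$config,
                          ap_cost = action_potential_cost()$total_atp) {
  if (is.null(io$I_Na_exc) || is.null(io$I_Na_inh))
    stop("io curve lacks synaptic Na current records")
  lam <- io$lambda
  Delta_T <- io$Delta_T
  # rates in spikes/s; lambda in kHz -> spikes/s via * 1000
  ap_evoked <- (config$n_exc * io$rate_exc + config$n_inh * io$rate_inh) *
    ap_cost * Delta_T
  ap_external <- (lam * 1000 / config$P_ext) * ap_cost * Delta_T
  synaptic <- (config$n_exc * synaptic_current_cost(io$I_Na_exc, Delta_T) +
               config$n_inh * synaptic_current_cost(io$I_Na_inh, Delta_T))
  w <- ap_evoked + ap_external + synaptic
  structure(list(lambda = lam, w = w,
                 ap_evoked = ap_evoked, ap_external = ap_external,
                 synaptic = synaptic, W0 = w[1], ap_cost = ap_cost,
                 Delta_T = Delta_T),
            class = "cost_curve")
}

#' Slope, intercept and per-spike cost of a cost curve
#'
#' `w0` is the finite-difference slope of `w(lambda)`; `W0` the resting
#' cost `w(0)`; `w_AP = w0 / g` the cost of increasing the output by one
#' action potential, with `g` the gain of the paired input-output curve.
#' A least-squares linear summary of `w(lambda)` is returned alongside the
#' per-lambda curves.
#'
#' @param cost a [activity_cost()] result.
#' @param io the matching [fit_io_curve()] (same grid).
#' @return List with per-lambda `w0` and `w_AP` (NA where the gain
#'   vanishes), scalars `W0`, `w0_ls`, `w_AP_ls`.
#' @export
cost_slope <- function(cost, io) {
  if (length(cost$lambda) != length(io$lambda) ||
      max(abs(cost$lambda - io$lambda)) > 1e-9)
    stop("cost and io curves must share the same stimulus grid")
  w0 <- finite_diff(cost$lambda, cost$w)
  g <- gain(io)
  w_AP <- ifelse(g != 0, w0 / g, NA_real_)
  fit_w <- stats::lm(cost$w ~ cost$lambda)
  fit_mu <- stats::lm(io$mu ~ io$lambda)
  w0_ls <- stats::coef(fit_w)[[2]]
  g_ls <- stats::coef(fit_mu)[[2]]
  list(w0 = w0, w_AP = w_AP, W0 = cost$w[1],
       w0_ls = w0_ls, w_AP_ls = if (g_ls != 0) w0_ls / g_ls else NA_real_)
}

#' Write a cost curve to CSV
#'
#' @param cost a `cost_curve`.
#' @param path file path.
#' @export
write_cost_csv <- function(cost, path) {
  utils::write.csv(data.frame(lambda = cost$lambda, w = cost$w,
                              ap_evoked = cost$ap_evoked,
                              ap_external = cost$ap_external,
                              synaptic = cost$synaptic),
                   path, row.names = FALSE)
  invisible(path)
}
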