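#!/usr/bin/env Rscript

# Step 1: fixed quantities of the model that need no simulation.
#
# Computes the ATP budget of a single action potential (charge -> Na+
# ions -> pumping cost -> axonal total), the Na+/K+ decomposition of the
# excitatory synaptic conductance, and the inhibitory/excitatory balance
# of the Ornstein-Uhlenbeck background.  Writes results/cost_constants.csv
# and results/background_balance.csv.

suppressPackageStartupMessages(library(enercode))
dir.create("results", showWarnings = FALSE)

ap <- action_potential_cost()
split <- sodium_current_split(V = -60, G = 1)  # per nS of conductance

constants <- data.frame(
  quantity = c("membrane_capacitance_pF", "ap_charge_C", "ap_min_na_ions",
               "ap_na_influx", "ap_ionic_cost_atp", "ap_total_cost_atp",
               "gNa_fraction_of_G"),
  value = c(capacitance_from_geometry(69, 1), ap$charge, ap$min_na_ions,
            ap$na_influx, ap$ionic_cost_atp, ap$total_atp,
            split$g_Na))
write.csv(constants, "results/cost_constants.csv", row.names = FALSE)

cfg <- network_config()
bal <- data.frame(
  population = c("excitatory", "inhibitory"),
  amplitude_nS = c(cfg$a_ext, cfg$alpha * cfg$a_ext),
  rate_kHz = c(cfg$lambda_bcg_exc, cfg$lambda_bcg_inh),
  mu_nS = c(ou_background_params(cfg$a_ext, cfg$tau_exc,
                                 cfg$lambda_bcg_exc)$mu,
            ou_background_params(cfg$alpha * cfg$a_ext, cfg$tau_inh,
                                 cfg$lambda_bcg_inh)$mu),
  sigma_nS = c(ou_background_params(cfg$a_ext, cfg$tau_exc,
                                    cfg$lambda_bcg_exc)$sigma,
               ou_background_params(cfg$alpha * cfg$a_ext, cfg$tau_inh,
                                    cfg$lambda_bcg_inh)$sigma))
write.csv(bal, "results/background_balance.csv", row.names = FALSE)

cat(sprintf("AP cost: %.3g ATP (ionic %.3g ATP, %.3g Na+ ions)\n",
            ap$total_atp, ap$ionic_cost_atp, ap$na_influx))
cat(sprintf("background conductance ratio (inh/exc): %.2f\n",
            background_conductance_ratio(cfg)))
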