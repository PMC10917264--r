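#' Generate the network connectivity
#'
#' Draws the three synaptic weight matrices (post x pre): external onto the
#' network (`W_ext`), recurrent excitatory (`W_exc`) and recurrent
#' inhibitory (`W_inh`).  In `"random"` mode every (post, pre) pair is
#' connected independently with the corresponding probability, by
#' thresholding a matrix of uniform random numbers at P.  In
#' `"fixed_in_degree"` mode each network neuron receives exactly
#' `k = round(n_ext * P_ext)` external synapses, placed at the k largest
#' entries of that neuron's row of the uniform matrix, which removes the
#' binomial in-degree variability across neurons.
#'
#' Nonzero entries equal the synaptic amplitude of their block: `a_ext` for
#' external, `a_rec` for recurrent excitatory and `alpha * a_rec` for
#' recurrent inhibitory synapses.  All four recurrent blocks (exc-exc,
#' exc-inh, inh-inh, inh-exc) use the same probability `P_rec`.
#'
#' @param config a [network_config()].
#' @param seed integer seed; the same seed reproduces the same wiring.
#' @return An object of class `connectivity_set`: list with dense weight
#'   matrices `W_ext` (n_tot x n_ext), `W_exc` (n_tot x n_exc), `W_inh`
#'   (n_tot x n_inh) and the `seed`.
#' @export
build_connectivity <- function(config, seed) {
  validate_network_config(config)
  n_tot <- config$n_exc + config$n_inh
  set.seed(as.integer(seed %% 2147483647))

  R_ext <- matrix(stats::runif(n_tot * config$n_ext), n_tot, config$n_ext)
  if (config$connection_mode == "fixed_in_degree") {
    k_real <- config$n_ext * config$P_ext
    k <- as.integer(round(k_real))
    if (abs(k_real - k) > 1e-9)
      warning(sprintf("n_ext * P_ext = %.3f is not an integer; using k = %d",
                      k_real, k))
    W_ext <- matrix(0, n_tot, config$n_ext)
    if (k > 0) {
      for (i in seq_len(n_tot)) {
        idx <- order(R_ext[i, ], decreasing = TRUE)[seq_len(k)]
        W_ext[i, idx] <- config$a_ext
      }
    }
  } else {
    W_ext <- matrix(0, n_tot, config$n_ext)
    W_ext[R_ext < config$P_ext] <- config$a_ext
  }

  R_exc <- matrix(stats::runif(n_tot * config$n_exc), n_tot, config$n_exc)
  W_exc <- matrix(0, n_tot, config$n_exc)
  W_exc[R_exc < config$P_rec] <- config$a_rec

  R_inh <- matrix(stats::runif(n_tot * config$n_inh), n_tot, config$n_inh)
  W_inh <- matrix(0, n_tot, config$n_inh)
  W_inh[R_inh < config$P_rec] <- config$alpha * config$a_rec

  structure(list(W_ext = W_ext, W_exc = W_exc, W_inh = W_inh, seed = seed),
            class = "connectivity_set")
}

# Adjacency lists (0-based target indices per presynaptic neuron) for the
# C++ integrator.  Weights within one matrix are constant, so only the
# amplitude and the target lists are passed.
conn_adjacency <- function(W) {
  n_pre <- ncol(W)
  targets <- vector("list", n_pre)
  for (j in seq_len(n_pre)) targets[[j]] <- which(W[, j] != 0) - 1L
  targets
}
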