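#' Full single-point analysis pipeline
#'
#' Runs the complete stimulus-response-cost-information chain for one
#' (`a_rec`, `P_ext`) parameter point: calibrates the stimulus range so
#' the top stimulus drives the network to the target output rate,
#' simulates the trial ensemble on the equidistant stimulus grid, fits
#' the interpolated input-output curve, attaches the ATP cost curve,
#' builds the discretized Gaussian channel, and computes the
#' information-metabolic efficiency (Jimbo-Kunisawa) together with its
#' low-noise (Fisher) approximation and, optionally, the capacity-cost
#' function on a budget grid.
#'
#' @param config a [network_config()]; its `a_rec` and `P_ext` define the
#'   parameter point.
#' @param n_stimuli stimulus grid size.
#' @param n_trials trials per stimulus.
#' @param n_dense dense interpolation grid size.
#' @param base_seed seed for connectivity and trials.
#' @param W_grid optional cost budgets (ATP) for a capacity-cost curve.
#'   With `low_noise = TRUE` the curve evaluates the exact mutual
#'   information of the low-noise input distribution at each budget (fast
#'   lower-bound estimates, the approach used for large parameter
#'   sweeps); otherwise each budget is solved exactly by constrained
#'   Blahut-Arimoto.
#' @param low_noise also compute the low-noise efficiency estimate.
#' @param ba_tol inner Blahut-Arimoto double-bound tolerance (bits).
#' @param ba_value_tol plateau stopping rule on the capacity lower bound
#'   (bits over 50 iterations); trades rigor of the double bound for
#'   runtime on wide network channels.
#' @param ba_max_iter inner iteration cap.
#' @param trials_per_probe probe trials for the stimulus-range search.
#' @return List with the ensemble summary, io/cost curves, channel,
#'   `efficiency` (Jimbo-Kunisawa), `efficiency_low_noise` (or NULL),
#'   `capacity_curve` (or NULL), `lambda_max` and metadata.
#' @export
run_pipeline_point <- function(config, n_stimuli = 11L, n_trials = 24L,
                               n_dense = 301L, base_seed = 1L,
                               W_grid = NULL, low_noise = TRUE,
                               ba_tol = 1e-7, ba_value_tol = 1e-6,
                               ba_max_iter = 5000L,
                               trials_per_probe = 8L) {
  conn <- build_connectivity(config, derive_seed(base_seed, "connectivity"))
  lambda_max <- find_lambda_max(config, conn, base_seed = base_seed,
                                trials_per_probe = trials_per_probe)
  ensemble <- run_ensemble(config, conn, lambda_max, n_stimuli = n_stimuli,
                           n_trials = n_trials, base_seed = base_seed)
  io <- fit_io_curve(ensemble, n_dense = n_dense)
  cost <- activity_cost(io, config)
  channel <- discretized_gaussian_channel(io)
  eff <- info_metabolic_efficiency(channel, cost$w, tol = ba_tol,
                                   value_tol = ba_value_tol,
                                   max_iter = ba_max_iter)

  eff_low <- NULL
  J <- NULL
  if (low_noise) {
    J <- fisher_1d(io)
    eff_low <- tryCatch(efficiency_low_noise(channel, cost$w, J),
                        error = function(e) {
                          warning("low-noise efficiency failed: ",
                                  conditionMessage(e))
                          NULL
                        })
  }
  cap <- NULL
  if (!is.null(W_grid)) {
    if (low_noise && !is.null(J)) {
      rows <- lapply(W_grid, function(W) {
        sol <- tryCatch(solve_low_noise(J, cost$w, W, grid = channel$lambda),
                        error = function(e) NULL)
        if (is.null(sol))
          return(data.frame(W = W, C = NA_real_, W_p = NA_real_, s = NA_real_))
        data.frame(W = W, C = mutual_information(sol$p, channel),
                   W_p = sum(sol$p * cost$w), s = sol$lambda_W)
      })
      cap <- do.call(rbind, rows)
    } else {
      cap <- capacity_cost_curve(channel, cost$w, W_grid, tol = ba_tol,
                                 value_tol = ba_value_tol,
                                 max_iter = ba_max_iter)
    }
  }

  list(a_rec = config$a_rec, P_ext = config$P_ext,
       lambda_max = lambda_max,
       summary = summarize_ensemble(ensemble),
       io = io, cost = cost, channel = channel,
       efficiency = eff, efficiency_low_noise = eff_low,
       capacity_curve = cap, base_seed = base_seed,
       n_stimuli = n_stimuli, n_trials = n_trials)
}

#' Sweep the (a_rec, P_ext) parameter grid
#'
#' Runs [run_pipeline_point()] for every combination of recurrence
#' strength and external connection probability.  Results are keyed by
#' `"a_rec=<x>|P_ext=<y>"`; with a cache directory the sweep is
#' resumable (completed points are loaded, not recomputed).  Everything
#' is deterministic given `base_seed`.
#'
#' @param a_rec_values recurrence strengths (nS).
#' @param P_ext_values external connection probabilities.
#' @param config base [network_config()]; `a_rec` / `P_ext` are
#'   overridden per point.
#' @param cache_dir optional directory for per-point `.rds` caches.
#' @param ... further arguments to [run_pipeline_point()].
#' @return Named list of per-point results (class `sweep_result`).
#' @export
run_sweep <- function(a_rec_values, P_ext_values, config = network_config(),
                      cache_dir = NULL, ...) {
  if (length(a_rec_values) == 0 || length(P_ext_values) == 0)
    stop("parameter grids must be nonempty")
  if (!is.null(cache_dir) && !dir.exists(cache_dir)) {
    ok <- dir.create(cache_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(cache_dir)) stop("cannot create cache_dir")
  }
  store <- list()
  for (P in P_ext_values) for (a in a_rec_values) {
    key <- sprintf("a_rec=%g|P_ext=%g", a, P)
    cache <- if (!is.null(cache_dir))
      file.path(cache_dir, paste0(gsub("[|=]", "_", key), ".rds")) else NULL
    if (!is.null(cache) && file.exists(cache)) {
      store[[key]] <- readRDS(cache)
      next
    }
    cfg <- utils::modifyList(config, list(a_rec = a, P_ext = P))
    class(cfg) <- "network_config"
    res <- tryCatch(run_pipeline_point(cfg, ...),
                    error = function(e) {
                      warning(sprintf("point %s failed: %s", key,
                                      conditionMessage(e)))
                      list(a_rec = a, P_ext = P, error = conditionMessage(e))
                    })
    store[[key]] <- res
    if (!is.null(cache)) saveRDS(res, cache)
  }
  class(store) <- "sweep_result"
  store
}

#' Efficiency summary of a sweep
#'
#' @param store a [run_sweep()] result.
#' @return Data frame with one row per grid point: efficiencies (bits per
#'   1e12 ATP) from the Jimbo-Kunisawa maximizer and, when available, the
#'   low-noise approximation, plus the optimizing cost `W_star`.
#' @export
sweep_efficiency_table <- function(store) {
  rows <- lapply(store, function(res) {
    if (!is.null(res$error))
      return(data.frame(a_rec = res$a_rec, P_ext = res$P_ext,
                        E_jk = NA_real_, E_low = NA_real_,
                        W_star = NA_real_, lambda_max = NA_real_))
    data.frame(a_rec = res$a_rec, P_ext = res$P_ext,
               E_jk = res$efficiency$E_per_1e12,
               E_low = if (!is.null(res$efficiency_low_noise))
                 res$efficiency_low_noise$E_per_1e12 else NA_real_,
               W_star = res$efficiency$W_star,
               lambda_max = res$lambda_max)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Capacity-cost table across the sweep
#'
#' Tabulates, for each requested `P_ext` (rows) and cost budget `W`
#' (columns), the maximum over the swept `a_rec` values of the
#' capacity-cost function `C(W)` -- the highest capacity attainable at
#' that budget when the recurrence strength is free to adapt.
#'
#' @param store a [run_sweep()] result whose points carry
#'   `capacity_curve`s.
#' @param W_values budgets (ATP) to tabulate; must be among those swept.
#' @param P_ext_values rows to include (default: all present).
#' @return Matrix (P_ext x W) of capacities in bits; `NA` where coverage
#'   is missing.
#' @export
tabulate_capacity_cost <- function(store, W_values, P_ext_values = NULL) {
  pts <- Filter(function(r) is.null(r$error) && !is.null(r$capacity_curve),
                store)
  if (length(pts) == 0) stop("no capacity curves in the sweep store")
  P_all <- sort(unique(vapply(pts, `[[`, numeric(1), "P_ext")))
  if (is.null(P_ext_values)) P_ext_values <- P_all
  tab <- matrix(NA_real_, length(P_ext_values), length(W_values),
                dimnames = list(paste0("P_ext=", P_ext_values),
                                paste0("W=", W_values)))
  for (i in seq_along(P_ext_values)) {
    sub <- Filter(function(r) r$P_ext == P_ext_values[i], pts)
    if (length(sub) == 0) next
    for (j in seq_along(W_values)) {
      vals <- vapply(sub, function(r) {
        m <- which(abs(r$capacity_curve$W - W_values[j]) <=
                     1e-9 * W_values[j])
        if (length(m)) r$capacity_curve$C[m[1]] else NA_real_
      }, numeric(1))
      if (all(is.na(vals))) next
      tab[i, j] <- max(vals, na.rm = TRUE)
    }
  }
  tab
}
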