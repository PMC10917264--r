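#' Mean pairwise spike-count correlation
#'
#' Mean Pearson correlation over all unordered neuron pairs of a
#' trials x neurons count matrix.  Neurons with zero count variance carry
#' no correlation information and are excluded pairwise.
#'
#' @param counts integer or numeric matrix, trials in rows.
#' @return Mean pairwise correlation, or `NA` if fewer than two neurons
#'   have positive variance.
#' @export
mean_pairwise_correlation <- function(counts) {
  if (nrow(counts) < 2 || ncol(counts) < 2)
    stop("need at least 2 trials and 2 neurons")
  v <- apply(counts, 2, stats::var)
  keep <- which(v > 0)
  if (length(keep) < 2) return(NA_real_)
  cm <- stats::cor(counts[, keep, drop = FALSE])
  mean(cm[upper.tri(cm)])
}

#' Single-neuron Fano factors
#'
#' Variance-to-mean ratio of each neuron's spike count across trials
#' (unbiased sample variance).  Neurons that never fire have an undefined
#' Fano factor and are excluded from the mean.
#'
#' @param counts trials x neurons count matrix.
#' @return List with `ff` (per-neuron, `NA` where the mean count is 0) and
#'   `mean_ff`.
#' @export
fano_single <- function(counts) {
  if (nrow(counts) < 2) stop("need at least 2 trials")
  m <- colMeans(counts)
  v <- apply(counts, 2, stats::var)
  ff <- ifelse(m > 0, v / m, NA_real_)
  list(ff = ff, mean_ff = mean(ff, na.rm = TRUE))
}

#' Population Fano factor and its covariance decomposition
#'
#' Fano factor of the summed population count,
#' `Var(sum_i N_i) / E(sum_i N_i)`, together with its exact decomposition
#' into the mean single-neuron variance `v` and mean pairwise covariance
#' `c`:
#' `FF_pop = (v / mu) * (1 + (n_tot - 1) * c / v)`,
#' and the correlation-based approximation `FF0 * (1 + (n_tot - 1) * r)`
#' valid for homogeneous populations (with `FF0 = v / mu` and `r` the mean
#' pairwise Pearson correlation).
#'
#' @param counts trials x neurons count matrix.
#' @return List with `fano`, `mean_variance`, `mean_covariance`,
#'   `mean_count`, `decomposition` (the identity-based value) and
#'   `approx_homogeneous`.
#' @export
fano_population <- function(counts) {
  if (nrow(counts) < 2) stop("need at least 2 trials")
  tot <- rowSums(counts)
  mu_tot <- mean(tot)
  if (mu_tot == 0)
    return(list(fano = NA_real_, mean_variance = NA_real_,
                mean_covariance = NA_real_, mean_count = 0,
                decomposition = NA_real_, approx_homogeneous = NA_real_))
  n_tot <- ncol(counts)
  C <- stats::cov(counts)
  v <- mean(diag(C))
  cbar <- if (n_tot > 1) (sum(C) - sum(diag(C))) / (n_tot * (n_tot - 1)) else 0
  mu <- mu_tot / n_tot
  ff <- stats::var(tot) / mu_tot
  decomposition <- v / mu * (1 + (n_tot - 1) * cbar / v)
  r <- mean_pairwise_correlation(counts)
  approx <- if (is.na(r)) NA_real_ else (v / mu) * (1 + (n_tot - 1) * r)
  list(fano = ff, mean_variance = v, mean_covariance = cbar,
       mean_count = mu, decomposition = decomposition,
       approx_homogeneous = approx)
}

#' Interpolated input-output curve of the network
#'
#' Linearly interpolates the per-stimulus empirical mean and variance of
#' the total population spike count (and the per-population mean rates and
#' synaptic Na+ currents) from the sampled stimulus grid onto a dense
#' equidistant grid.  Values at the sampled stimuli are preserved exactly.
#'
#' @param ensemble a [run_ensemble()] result.
#' @param n_dense number of dense grid points.
#' @return An object of class `io_curve`: `lambda` (dense grid, kHz),
#'   `mu` and `var` of the total count per counting window, per-neuron
#'   rates `rate_exc` / `rate_inh` (Hz), `I_Na_exc` / `I_Na_inh` (pA) and
#'   the sampled knots.
#' @export
fit_io_curve <- function(ensemble, n_dense = 1000L) {
  lam <- ensemble$lambda_grid
  if (is.unsorted(lam, strictly = TRUE)) stop("stimulus grid must be increasing")
  cfg <- ensemble$config
  exc_idx <- seq_len(cfg$n_exc)
  inh_idx <- cfg$n_exc + seq_len(cfg$n_inh)

  tot <- lapply(ensemble$counts, rowSums)
  mu_k <- vapply(tot, mean, numeric(1))
  var_k <- vapply(tot, stats::var, numeric(1))
  re_k <- vapply(ensemble$counts, function(cm) mean(cm[, exc_idx]),
                 numeric(1)) / ensemble$Delta_T
  ri_k <- vapply(ensemble$counts, function(cm) mean(cm[, inh_idx]),
                 numeric(1)) / ensemble$Delta_T

  dense <- seq(lam[1], lam[length(lam)], length.out = n_dense)
  li <- function(y) stats::approx(lam, y, xout = dense)$y
  structure(list(lambda = dense,
                 mu = li(mu_k), var = li(var_k),
                 rate_exc = li(re_k), rate_inh = li(ri_k),
                 I_Na_exc = li(ensemble$I_Na_exc),
                 I_Na_inh = li(ensemble$I_Na_inh),
                 knots = list(lambda = lam, mu = mu_k, var = var_k,
                              rate_exc = re_k, rate_inh = ri_k),
                 Delta_T = ensemble$Delta_T, config = cfg),
            class = "io_curve")
}

#' Gain of the input-output curve
#'
#' Derivative of the mean response with respect to the stimulus, by
#' central finite differences on the dense grid (one-sided at the ends).
#'
#' @param io an [fit_io_curve()] result.
#' @param lambda stimulus value(s) inside the grid; `NULL` returns the
#'   gain on the whole dense grid.
#' @return Gain (counts per kHz).
#' @export
gain <- function(io, lambda = NULL) {
  g <- finite_diff(io$lambda, io$mu)
  if (is.null(lambda)) return(g)
  if (any(lambda < min(io$lambda) | lambda > max(io$lambda)))
    stop("lambda outside the interpolation grid")
  stats::approx(io$lambda, g, xout = lambda)$y
}

# central differences, one-sided at the endpoints
finite_diff <- function(x, y) {
  n <- length(x)
  d <- numeric(n)
  d[1] <- (y[2] - y[1]) / (x[2] - x[1])
  d[n] <- (y[n] - y[n - 1]) / (x[n] - x[n - 1])
  if (n > 2) {
    i <- 2:(n - 1)
    d[i] <- (y[i + 1] - y[i - 1]) / (x[i + 1] - x[i - 1])
  }
  d
}

#' Discretized Gaussian channel from an input-output curve
#'
#' Builds the conditional spike-count distribution `f(n | lambda)` as a
#' normal density with the interpolated mean and variance, discretized on
#' the integer counts `0..n_max` and normalized by the explicit sum.
#' `n_max` is the ceiling of `max(mu + 6 * sigma)`, which truncates less
#' than 1e-8 of probability mass.  A zero-variance row degenerates to a
#' point mass at `round(mu)`.
#'
#' @param io an [fit_io_curve()] result, or a list with `lambda`, `mu`,
#'   `var`.
#' @param n_max optional override of the output alphabet size.
#' @return An object of class `channel_model`: `lambda` (input grid),
#'   `outputs` (0..n_max) and the row-stochastic matrix `F` (inputs in
#'   rows).
#' @export
discretized_gaussian_channel <- function(io, n_max = NULL,
                                         n_max_limit = 2e5) {
  mu <- io$mu; v <- io$var; lam <- io$lambda
  if (any(v < 0)) stop("negative variance")
  if (is.null(n_max)) n_max <- ceiling(max(mu + 6 * sqrt(v)))
  if (n_max > n_max_limit)
    stop("output alphabet of ", n_max, " counts exceeds the limit; ",
         "the response is likely outside the stable operating regime")
  n <- 0:n_max
  F <- matrix(0, length(lam), n_max + 1L)
  for (k in seq_along(lam)) {
    if (v[k] > 0) {
      row <- exp(-(n - mu[k])^2 / (2 * v[k]))
      F[k, ] <- row / sum(row)
    } else {
      F[k, min(n_max, max(0, round(mu[k]))) + 1L] <- 1
    }
  }
  structure(list(lambda = lam, outputs = n, F = F),
            class = "channel_model")
}

#' Mean firing rate under an exponential tuning curve with Gaussian input
#'
#' Expected value of `c1 * exp(c2 * x)` when the input `x` across neurons
#' is Normal(`lambda`, `sigma^2`), via the Gaussian moment identity
#' `c1 * exp(c2 * lambda + c2^2 * sigma^2 / 2)`.  Strictly increasing in
#' `sigma` for `c2 != 0`: more dispersed input onto a convex tuning curve
#' raises the mean population rate.
#'
#' @param c1,c2 tuning-curve parameters.
#' @param lambda mean input (kHz).
#' @param sigma input standard deviation across neurons (kHz).
#' @return Mean rate (same units as `c1`).
#' @export
exponential_tuning_mean <- function(c1, c2, lambda, sigma) {
  stopifnot(sigma >= 0)
  c1 * exp(c2 * lambda + c2^2 * sigma^2 / 2)
}

#' Write channel model to CSV / read it back
#'
#' Plain-text round trip for small channels: the first column holds the
#' input grid, remaining columns the conditional probabilities of each
#' output count.
#'
#' @param channel a `channel_model`.
#' @param path file path.
#' @export
write_channel_csv <- function(channel, path) {
  df <- data.frame(lambda = channel$lambda, channel$F)
  names(df) <- c("lambda", paste0("n", channel$outputs))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_channel_csv
#' @export
read_channel_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  F <- as.matrix(df[, -1, drop = FALSE])
  dimnames(F) <- NULL
  structure(list(lambda = df$lambda,
                 outputs = 0:(ncol(F) - 1L), F = F),
            class = "channel_model")
}
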