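#' Project a trial ensemble onto its principal components
#'
#' Fits PCA loadings on the spike-count responses pooled across all
#' stimuli (centered, unscaled) and projects every stimulus's trials with
#' the same loadings, reducing the response dimension before multivariate
#' Fisher-information estimation.
#'
#' @param ensemble a [run_ensemble()] result, or a list of
#'   trials x neurons matrices.
#' @param n_components number of components to keep; reduced with a
#'   warning if the pooled responses have lower rank.
#' @return An object of class `projected_ensemble`: `scores` (list of
#'   trials x components matrices per stimulus), `loadings`, `center`,
#'   `sdev` (explained standard deviations) and `lambda_grid` when
#'   available.
#' @export
pca_project <- function(ensemble, n_components = 50L) {
  counts <- if (inherits(ensemble, "trial_ensemble")) ensemble$counts
            else ensemble
  pooled <- do.call(rbind, counts)
  max_rank <- min(nrow(pooled) - 1L, ncol(pooled))
  if (n_components > max_rank) {
    warning(sprintf("reducing n_components from %d to the available rank %d",
                    n_components, max_rank))
    n_components <- max_rank
  }
  pc <- stats::prcomp(pooled, center = TRUE, scale. = FALSE)
  L <- pc$rotation[, seq_len(n_components), drop = FALSE]
  scores <- lapply(counts, function(cm)
    sweep(cm, 2, pc$center) %*% L)
  structure(list(scores = scores, loadings = L, center = pc$center,
                 sdev = pc$sdev[seq_len(n_components)],
                 n_components = n_components,
                 lambda_grid = if (inherits(ensemble, "trial_ensemble"))
                   ensemble$lambda_grid else NULL),
            class = "projected_ensemble")
}

#' Multivariate Fisher information of the population response
#'
#' Gaussian Fisher information of the (projected) response vector at each
#' sampled stimulus:
#' `J_pop = f'^T S^-1 f' + 1/2 Tr( (S^-1 S')^2 )`,
#' with mean vector `f`, covariance `S`, and derivatives taken by central
#' finite differences across neighboring stimulus levels (one-sided at
#' the grid ends).  Covariances are regularized by diagonal loading
#' `eps * mean(diag(S))` before inversion.  The mean-derivative term and
#' the (typically much smaller) covariance term are reported separately.
#'
#' @param proj a [pca_project()] result (or list of per-stimulus response
#'   matrices plus `lambda_grid`).
#' @param lambda_grid stimulus values; taken from `proj` if present.
#' @param eps diagonal-loading fraction.
#' @return An object of class `population_fisher`: data frame columns
#'   `lambda`, `J_pop`, `term_mean`, `term_cov`.
#' @export
fisher_population <- function(proj, lambda_grid = proj$lambda_grid,
                              eps = 1e-6) {
  scores <- if (inherits(proj, "projected_ensemble")) proj$scores else proj
  S <- length(scores)
  stopifnot(!is.null(lambda_grid), length(lambda_grid) == S, S >= 2)
  means <- lapply(scores, colMeans)
  covs <- lapply(scores, stats::cov)

  deriv_at <- function(vals, i) {
    lo <- max(1L, i - 1L); hi <- min(S, i + 1L)
    (vals[[hi]] - vals[[lo]]) / (lambda_grid[hi] - lambda_grid[lo])
  }

  out <- data.frame(lambda = lambda_grid, J_pop = NA_real_,
                    term_mean = NA_real_, term_cov = NA_real_)
  for (i in seq_len(S)) {
    Sig <- covs[[i]]
    Sig <- Sig + diag(eps * mean(diag(Sig)), nrow(Sig))
    Sinv <- tryCatch(solve(Sig), error = function(e)
      stop("covariance singular after regularization at stimulus ", i))
    fp <- deriv_at(means, i)
    Sp <- deriv_at(covs, i)
    t1 <- as.numeric(t(fp) %*% Sinv %*% fp)
    A <- Sinv %*% Sp
    t2 <- 0.5 * sum(A * t(A))
    out$term_mean[i] <- t1
    out$term_cov[i] <- t2
    out$J_pop[i] <- t1 + t2
  }
  class(out) <- c("population_fisher", class(out))
  out
}

#' Cramer-Rao decoding channel
#'
#' Conditional distribution of an efficient unbiased estimate of the
#' stimulus: Normal with mean `lambda` and variance `1 / J_pop(lambda)`,
#' discretized on the stimulus grid itself and normalized row by row
#' (a noisy identity channel whose noise floor is the Cramer-Rao bound).
#'
#' @param J_curve a [fisher_population()] result (columns `lambda`,
#'   `J_pop`), or a list with those elements.
#' @param n_dense optional size of a dense grid onto which the Fisher
#'   information is linearly interpolated before discretization.  The
#'   grid must resolve the Cramer-Rao noise scale `1/sqrt(J)`; on a
#'   coarse sampled grid the rows degenerate to point masses and the
#'   channel saturates at the grid resolution rather than the decoding
#'   noise floor.
#' @return A `channel_model` whose outputs index the stimulus grid.
#' @export
cramer_rao_channel <- function(J_curve, n_dense = NULL) {
  lam <- J_curve$lambda
  J <- J_curve$J_pop
  keep <- which(is.finite(J) & J > 0)
  if (length(keep) < length(J))
    warning("dropping ", length(J) - length(keep),
            " grid points with non-positive Fisher information")
  lam <- lam[keep]; J <- J[keep]
  if (!is.null(n_dense) && n_dense > length(lam)) {
    dense <- seq(min(lam), max(lam), length.out = n_dense)
    J <- pmax(stats::approx(lam, J, xout = dense)$y, .Machine$double.xmin)
    lam <- dense
  }
  K <- length(lam)
  F <- matrix(0, K, K)
  for (i in seq_len(K)) {
    row <- exp(-J[i] / 2 * (lam - lam[i])^2)
    F[i, ] <- row / sum(row)
  }
  structure(list(lambda = lam, outputs = seq_len(K) - 1L, F = F,
                 J_pop = J),
            class = "channel_model")
}

#' Quadratic sampling-bias extrapolation
#'
#' Information estimates computed from k trials carry an upward sampling
#' bias modeled as `E_k = E_0 + a / k + b / k^2`.  Given estimates at
#' three distinct trial counts, solves the 3x3 linear system for the
#' unbiased value `E_0` and the bias coefficients.
#'
#' @param E estimates at the three trial counts.
#' @param k the three distinct trial counts (e.g. `c(k, k/2, k/4)`).
#' @return List with `E0`, `a`, `b`.
#' @export
bias_correct_quadratic <- function(E, k) {
  stopifnot(length(E) == 3, length(k) == 3)
  if (anyDuplicated(k)) stop("trial counts must be distinct")
  X <- cbind(1, 1 / k, 1 / k^2)
  beta <- solve(X, E)
  list(E0 = beta[[1]], a = beta[[2]], b = beta[[3]])
}

#' Efficiency of the Cramer-Rao channel with trial subsampling
#'
#' Computes the information-metabolic efficiency of the population
#' decoding channel from the full ensemble and from disjoint random
#' halves and quarters of the trials, then extrapolates the sampling bias
#' away with [bias_correct_quadratic()].  Subsample estimates are
#' averaged over the disjoint blocks.
#'
#' @param ensemble a [run_ensemble()] result.
#' @param w_fun function mapping stimulus values to cost (ATP), usually an
#'   interpolant of a [activity_cost()] curve.
#' @param n_components PCA dimension.
#' @param n_dense dense grid size for the Cramer-Rao channel.
#' @param seed seed for the random subsample split.
#' @return List with `E0` (bits/ATP, bias-corrected), `E_k` (the three
#'   raw estimates), `k` (trial counts) and the full-data channel
#'   efficiency object.
#' @export
decoding_efficiency_corrected <- function(ensemble, w_fun,
                                          n_components = 50L,
                                          n_dense = 201L, seed = 1L) {
  n_trials <- nrow(ensemble$counts[[1]])
  if (n_trials < 8) stop("need at least 8 trials for quarter subsampling")

  eff_for <- function(counts_list) {
    proj <- pca_project(counts_list, n_components = n_components)
    J <- fisher_population(proj, lambda_grid = ensemble$lambda_grid)
    ch <- cramer_rao_channel(J, n_dense = n_dense)
    w <- w_fun(ch$lambda)
    info_metabolic_efficiency(ch, w, tol = 1e-7, value_tol = 1e-7,
                              max_iter = 20000)
  }

  full <- suppressWarnings(eff_for(ensemble$counts))
  set.seed(as.integer(derive_seed(seed, "subsample")))
  perm <- sample.int(n_trials)
  halves <- split(perm, rep(1:2, length.out = n_trials))
  quarters <- split(perm, rep(1:4, length.out = n_trials))
  eff_sub <- function(idx_list) {
    vals <- vapply(idx_list, function(idx) {
      cl <- lapply(ensemble$counts, function(cm) cm[idx, , drop = FALSE])
      suppressWarnings(eff_for(cl))$E
    }, numeric(1))
    mean(vals)
  }
  E_k <- c(full$E, eff_sub(halves), eff_sub(quarters))
  k <- c(n_trials, n_trials / 2, n_trials / 4)
  bc <- bias_correct_quadratic(E_k, k)
  list(E0 = bc$E0, a = bc$a, b = bc$b, E_k = E_k, k = k, full = full)
}
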