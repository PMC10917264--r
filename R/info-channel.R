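#' Mutual information of a discrete memoryless channel
#'
#' `I(p) = sum_l p(l) sum_n f(n|l) log2( f(n|l) / q(n) )` with
#' `q = t(F) p`, in bits, with the convention `0 log 0 = 0`.
#'
#' @param p input distribution on the channel's input grid.
#' @param channel a `channel_model` (list with row-stochastic matrix `F`).
#' @return Mutual information in bits.
#' @export
mutual_information <- function(p, channel) {
  F <- channel$F
  if (length(p) != nrow(F)) stop("p must match the channel input grid")
  if (abs(sum(p) - 1) > 1e-9) stop("p is not normalized")
  if (any(p < 0)) stop("p has negative entries")
  q <- as.numeric(crossprod(F, p))
  lq <- ifelse(q > 0, log2(q), 0)
  Hneg <- ia_row_sum_flogf(F)
  D <- Hneg - as.numeric(F %*% lq)
  sum(p * D)
}

# rowSums(F * log2(F)) with 0 log 0 = 0
ia_row_sum_flogf <- function(F) {
  L <- F
  pos <- F > 0
  L[pos] <- F[pos] * log2(F[pos])
  L[!pos] <- 0
  rowSums(L)
}

# Precomputation shared by all Blahut-Arimoto solves on one channel:
# transposed conditional matrix, per-input contiguous support band of the
# outputs, and the row entropies.
ba_prep <- function(F) {
  Ft <- t(F)
  K <- ncol(Ft)
  lo <- integer(K); hi <- integer(K)
  for (k in seq_len(K)) {
    col <- Ft[, k]
    thr <- max(col) * 1e-14
    nz <- which(col > thr)
    lo[k] <- nz[1] - 1L
    hi[k] <- nz[length(nz)] - 1L
  }
  list(Ft = Ft, lo = lo, hi = hi, Hneg = ia_row_sum_flogf(F), K = K)
}

# One cost-tilted Blahut-Arimoto solve: maximizes I(p) - s * sum(p * w)
# in a compiled kernel, with safeguarded over-relaxation (exponent beta,
# reset to 1 if the lower bound ever decreases).  Terminates when the
# Csiszar double-bound gap drops below tol (bits) or, when value_tol > 0,
# when the lower bound has plateaued.
ba_tilted <- function(prep, w, s, p0 = NULL, tol = 1e-9,
                      max_iter = 1e5L, beta = 1.6, value_tol = 0) {
  if (is.matrix(prep)) prep <- ba_prep(prep)
  if (is.null(p0)) {
    p0 <- rep(1 / prep$K, prep$K)
  } else {
    # zero mass is absorbing under multiplicative updates; keep warm
    # starts strictly interior so the support can re-grow
    p0 <- 0.99 * p0 / sum(p0) + 0.01 / prep$K
  }
  ba_iterate_cpp(prep$Ft, prep$lo, prep$hi, prep$Hneg, w, s, p0, tol,
                 as.integer(max_iter), beta, value_tol)
}

#' Cost-constrained channel capacity (Blahut-Arimoto)
#'
#' Computes `C(W) = max_p I(p)` subject to `sum(p * w) <= W` by
#' alternating Blahut-Arimoto updates with an exponential cost tilt
#' `2^(-s w(l))` and an outer bracketed bisection on the Lagrange
#' multiplier `s >= 0` so that the average-cost constraint is met
#' (`s = 0` when the unconstrained optimum is already feasible).
#'
#' @param channel a `channel_model`.
#' @param w cost of each input (ATP), same length as the input grid.
#' @param W cost budget (ATP); must be at least `min(w)`.
#' @param tol convergence tolerance on the capacity double-bound gap
#'   (bits).
#' @param max_iter inner-iteration cap.
#' @return List with `C` (bits), `p` (optimal input distribution), `W_p`
#'   (achieved average cost), multiplier `s` and diagnostics.
#' @export
capacity_cost <- function(channel, w, W, tol = 1e-9, max_iter = 1e5L,
                          value_tol = 0, prep = NULL) {
  F <- channel$F
  if (length(w) != nrow(F)) stop("cost vector must match the input grid")
  if (W < min(w)) stop("W below the minimum achievable average cost")
  if (is.null(prep)) prep <- ba_prep(F)
  ba <- function(s, p0 = NULL) ba_tilted(prep, w, s, p0 = p0, tol = tol,
                                         max_iter = max_iter,
                                         value_tol = value_tol)

  sol0 <- ba(0)
  if (!sol0$converged && sol0$iterations >= max_iter)
    warning(sprintf("Blahut-Arimoto did not reach gap %.1e (gap %.2e after %d iterations)",
                    tol, sol0$gap, sol0$iterations))
  if (sol0$W <= W * (1 + 1e-9))
    return(list(C = sol0$I, p = sol0$p, W_p = sol0$W, s = 0,
                gap = sol0$gap, iterations = sol0$iterations))

  # bracket s so that the achieved cost straddles W
  s_lo <- 0; s_hi <- 1 / max(w)
  sol_hi <- ba(s_hi, p0 = sol0$p)
  while (sol_hi$W > W && s_hi < 1e12 / max(w)) {
    s_lo <- s_hi
    s_hi <- s_hi * 4
    sol_hi <- ba(s_hi, p0 = sol_hi$p)
  }
  if (sol_hi$W > W) stop("failed to bracket the cost constraint in s")

  sol_above <- sol0          # cost above the budget (small s side)
  sol_below <- sol_hi        # cost below the budget (large s side)
  sol <- sol_hi
  for (i in seq_len(200)) {
    s_mid <- (s_lo + s_hi) / 2
    sol <- ba(s_mid, p0 = sol$p)
    if (sol$W > W) { s_lo <- s_mid; sol_above <- sol }
    else           { s_hi <- s_mid; sol_below <- sol }
    if (abs(sol$W - W) <= 1e-7 * W || (s_hi - s_lo) <= 1e-13 * max(s_hi, 1))
      break
  }
  if (abs(sol$W - W) > 1e-7 * W) {
    # C(W) is linear where the optimal cost jumps in s: both endpoint
    # solutions maximize the same tilted functional, so their mixture
    # meeting the budget exactly is optimal on the segment
    th <- (W - sol_below$W) / (sol_above$W - sol_below$W)
    if (is.finite(th) && th >= 0 && th <= 1) {
      p_mix <- th * sol_above$p + (1 - th) * sol_below$p
      p_mix <- p_mix / sum(p_mix)
      sol <- list(p = p_mix, I = mutual_information(p_mix, list(F = F)),
                  W = sum(p_mix * w), gap = max(sol_above$gap, sol_below$gap),
                  iterations = sol$iterations)
    }
  }
  list(C = sol$I, p = sol$p, W_p = sol$W, s = (s_lo + s_hi) / 2,
       gap = sol$gap, iterations = sol$iterations)
}

#' Capacity-cost curve over a budget grid
#'
#' @param channel a `channel_model`.
#' @param w input cost vector (ATP).
#' @param W_grid budgets (ATP).
#' @inheritParams capacity_cost
#' @return Data frame with `W`, `C` (bits), achieved cost and multiplier.
#' @export
capacity_cost_curve <- function(channel, w, W_grid, tol = 1e-9,
                                max_iter = 1e5L, value_tol = 0) {
  prep <- ba_prep(channel$F)
  rows <- lapply(W_grid, function(W) {
    r <- capacity_cost(channel, w, W, tol = tol, max_iter = max_iter,
                       value_tol = value_tol, prep = prep)
    data.frame(W = W, C = r$C, W_p = r$W_p, s = r$s)
  })
  do.call(rbind, rows)
}

#' Information-metabolic efficiency (Jimbo-Kunisawa maximization)
#'
#' Maximizes the ratio of mutual information to average metabolic cost,
#' `E = max_p I(p) / W(p)`, equivalently `max_W C(W)/W`.  Implemented as
#' Dinkelbach fractional programming: each outer step solves the tilted
#' problem `max_p I(p) - E_k W(p)` with the cost-tilted Blahut-Arimoto
#' update and resets `E_{k+1} = I(p_k)/W(p_k)`; at the fixed point the
#' tilted value vanishes and `p` maximizes the ratio.
#'
#' @param channel a `channel_model`.
#' @param w input cost vector (ATP), strictly positive wherever the
#'   channel carries information.
#' @param tol tolerance on the inner double-bound gap (bits).
#' @param ratio_tol relative convergence tolerance on `E`.
#' @return List with `E` (bits per ATP), `E_per_1e12` (bits per 10^12
#'   ATP), `W_star` (average cost of the maximizer, ATP), `C_star`
#'   (bits), `p` and diagnostics.
#' @export
info_metabolic_efficiency <- function(channel, w, tol = 1e-9,
                                      ratio_tol = 1e-8, max_iter = 1e5L,
                                      value_tol = 0) {
  F <- channel$F
  if (length(w) != nrow(F)) stop("cost vector must match the input grid")
  if (any(w < 0)) stop("costs must be non-negative")
  keep <- seq_len(nrow(F))
  if (any(w == 0)) {
    # a free input whose row duplicates a paid one never helps the ratio
    dup <- vapply(which(w == 0), function(i) {
      any(w > 0 & apply(F, 1, function(r) max(abs(r - F[i, ]))) < 1e-12)
    }, logical(1))
    drop <- which(w == 0)[dup]
    if (length(drop)) keep <- setdiff(keep, drop)
    if (any(w[keep] == 0))
      stop("inputs with zero cost and nonzero information make the ratio unbounded")
  }
  Fk <- F[keep, , drop = FALSE]
  wk <- w[keep]
  prep <- ba_prep(Fk)

  K <- nrow(Fk)
  p <- rep(1 / K, K)
  I0 <- mutual_information(p, list(F = Fk))
  if (I0 <= 1e-14) {
    ba <- ba_tilted(prep, wk, 0, tol = tol, max_iter = max_iter,
                    value_tol = value_tol)
    if (ba$I <= 1e-12) {
      warning("channel carries no information; efficiency is 0")
      return(list(E = 0, E_per_1e12 = 0, W_star = NA_real_, C_star = 0,
                  p = rep(0, length(w)), iterations = 0, converged = TRUE))
    }
  }
  E <- max(I0, 1e-12) / sum(p * wk)
  outer <- 0L
  repeat {
    outer <- outer + 1L
    sol <- ba_tilted(prep, wk, E, p0 = p, tol = tol, max_iter = max_iter,
                     value_tol = value_tol)
    p <- sol$p
    E_new <- sol$I / sol$W
    # Dinkelbach fixed point: the tilted value I - E W vanishes at the
    # ratio optimum; accept when it is negligible relative to I
    done <- abs(E_new - E) <= ratio_tol * max(E_new, 1e-300) ||
      abs(sol$value) <= 10 * ratio_tol * max(abs(sol$I), 1e-300)
    E <- E_new
    if (done || outer >= 40L) break
  }
  p_full <- numeric(nrow(F))
  p_full[keep] <- p
  list(E = E, E_per_1e12 = E * 1e12, W_star = sol$W, C_star = sol$I,
       p = p_full, iterations = outer, converged = done,
       inner_gap = sol$gap)
}

#' Merge output symbols of a channel
#'
#' Utility for data-processing checks: collapses output columns by a
#' grouping factor, which can never increase capacity.
#'
#' @param channel a `channel_model`.
#' @param groups integer vector, one group id per output symbol.
#' @return A `channel_model` with merged outputs.
#' @export
merge_outputs <- function(channel, groups) {
  stopifnot(length(groups) == ncol(channel$F))
  g <- as.integer(factor(groups))
  M <- max(g)
  Fm <- matrix(0, nrow(channel$F), M)
  for (j in seq_len(M)) {
    cols <- which(g == j)
    Fm[, j] <- rowSums(channel$F[, cols, drop = FALSE])
  }
  structure(list(lambda = channel$lambda, outputs = seq_len(M) - 1L, F = Fm),
            class = "channel_model")
}
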