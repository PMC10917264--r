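#' Linear-Gaussian surrogate channel
#'
#' The analytically tractable reference system: mean response
#' `g * lambda`, Gaussian output with variance `g * lambda * FF`
#' (constant Fano factor), and affine cost `w0 * lambda + W0`.  It serves
#' as the fast synthetic fixture for every downstream information-theory
#' stage.
#'
#' @param g gain (counts per kHz).
#' @param FF Fano factor.
#' @param w0 cost slope (ATP per kHz).
#' @param W0 resting cost (ATP).
#' @param lambda_range input range (kHz), `lambda_min > 0`.
#' @param n_lambda input grid size.
#' @param n_max optional output alphabet override.
#' @return List with `channel` (a `channel_model`), `w` (cost vector) and
#'   the model parameters.
#' @export
linear_model_channel <- function(g, FF, w0, W0, lambda_range = c(0.05, 5),
                                 n_lambda = 200L, n_max = NULL) {
  stopifnot(g > 0, FF > 0, w0 > 0, lambda_range[1] > 0,
            lambda_range[2] > lambda_range[1])
  lambda <- seq(lambda_range[1], lambda_range[2], length.out = n_lambda)
  io <- list(lambda = lambda, mu = g * lambda, var = g * lambda * FF)
  channel <- discretized_gaussian_channel(io, n_max = n_max)
  list(channel = channel, w = w0 * lambda + W0,
       g = g, FF = FF, w0 = w0, W0 = W0)
}

#' One-dimensional Fisher information of an input-output curve
#'
#' Second-moment (Gaussian) approximation
#' `J(lambda) = mu'(lambda)^2 / sigma^2(lambda)`.
#'
#' @param io an [fit_io_curve()] result (or list with `lambda`, `mu`,
#'   `var`).
#' @param lambda evaluation points; `NULL` for the whole grid.
#' @return Fisher information (kHz^-2).
#' @export
fisher_1d <- function(io, lambda = NULL) {
  if (any(io$var <= 0)) stop("sigma^2 must be positive for Fisher information")
  J <- finite_diff(io$lambda, io$mu)^2 / io$var
  if (is.null(lambda)) return(J)
  stats::approx(io$lambda, J, xout = lambda)$y
}

#' Low-noise optimal input distribution and capacity bound
#'
#' In the low-noise regime the capacity-achieving input density is
#' `p(lambda) = sqrt(J(lambda) / (2 pi e)) * exp(l1 - 1 - lW w(lambda))`,
#' with the multipliers `l1` (normalization) and `lW` (average-cost
#' constraint `int p w = W`).  `l1` is eliminated analytically; `lW` is
#' found by bracketed root finding on the cost constraint, with all
#' integrals evaluated by adaptive quadrature over the support.  The
#' associated capacity estimate `C_low = 1 - l1 + lW W` (nats) is
#' returned in bits.
#'
#' @param J Fisher information: function of lambda, or numeric vector on
#'   `grid`.
#' @param w cost: function of lambda, or numeric vector on `grid`.
#' @param W target average cost (ATP).
#' @param support integration support `c(lambda_min, lambda_max)`;
#'   `lambda_max` may be `Inf` for analytic inputs.
#' @param grid optional lambda grid on which vector inputs live and on
#'   which the returned distribution is evaluated.
#' @return An object of class `low_noise_solution`: `lambda_W`,
#'   `lambda_1`, `C_low` (bits), target `W`, and (when a grid is
#'   available) the discretized distribution `p` (summing to 1) with its
#'   `grid`.
#' @export
solve_low_noise <- function(J, w, W, support = NULL, grid = NULL) {
  if (is.numeric(J)) {
    stopifnot(!is.null(grid), length(J) == length(grid))
    J_fun <- stats::approxfun(grid, J, rule = 2)
  } else J_fun <- J
  if (is.numeric(w)) {
    stopifnot(!is.null(grid), length(w) == length(grid))
    w_fun <- stats::approxfun(grid, w, rule = 2)
  } else w_fun <- w
  if (is.null(support)) {
    if (is.null(grid)) stop("either support or grid must be given")
    support <- range(grid)
  }

  amp <- function(l) sqrt(pmax(J_fun(l), 0) / (2 * pi * exp(1)))
  # Gridded inputs are piecewise linear, whose kinks defeat adaptive
  # quadrature; integrate them with composite Gauss-Legendre (7 nodes per
  # grid interval, exact to machine precision for these smooth-by-pieces
  # integrands).  Analytic inputs use adaptive quadrature, which also
  # handles unbounded supports and endpoint singularities.
  if (!is.null(grid)) {
    gq <- gauss_legendre_composite(grid)
    quad <- function(f) sum(gq$weights * f(gq$nodes))
  } else {
    quad <- function(f)
      stats::integrate(f, support[1], support[2], rel.tol = 1e-10,
                       abs.tol = 0, subdivisions = 1000L)$value
  }

  # The multiplier is searched on the dimensionless scale u = lW * W so
  # that bracketing and the root tolerance are insensitive to the ATP
  # magnitude of the costs.
  stopifnot(W > 0)
  mean_cost <- function(u) {
    Z <- quad(function(l) amp(l) * exp(-u * w_fun(l) / W))
    M <- quad(function(l) w_fun(l) * amp(l) * exp(-u * w_fun(l) / W))
    M / Z
  }

  h <- function(u) mean_cost(u) - W
  # on unbounded support the untilted density need not be normalizable;
  # a divergent integral at u = 0 simply means a positive tilt is needed
  h0 <- tryCatch(h(0), error = function(e) Inf)
  if (h0 > 0) {               # need positive tilt to push cost down to W
    lo <- 0; hi <- 1e-3
    while (h(hi) > 0) {
      lo <- hi; hi <- hi * 8
      if (hi > 1e9) stop("failed to bracket the cost multiplier")
    }
  } else {                    # budget above the untilted mean: negative tilt
    hi <- 0; lo <- -1e-3
    while (h(lo) < 0) {
      hi <- lo; lo <- lo * 8
      if (lo < -1e9) stop("failed to bracket the cost multiplier")
    }
  }
  u <- stats::uniroot(h, c(lo, hi), tol = 1e-12)$root
  lW <- u / W

  Z <- quad(function(l) amp(l) * exp(-lW * w_fun(l)))
  l1 <- 1 - log(Z)
  C_low_nats <- log(Z) + lW * W
  out <- list(lambda_W = lW, lambda_1 = l1,
              C_low = C_low_nats * log2(exp(1)), W = W)
  if (!is.null(grid)) {
    dens <- amp(grid) * exp(l1 - 1 - lW * w_fun(grid))
    p <- dens * trapezoid_weights(grid)
    out$p <- p / sum(p)
    out$grid <- grid
    out$density <- dens
  }
  class(out) <- "low_noise_solution"
  out
}

# composite 7-point Gauss-Legendre rule over the intervals of a grid
gauss_legendre_composite <- function(grid) {
  x <- c(-0.9491079123427585, -0.7415311855993945, -0.4058451513773972, 0,
         0.4058451513773972, 0.7415311855993945, 0.9491079123427585)
  w <- c(0.1294849661688697, 0.2797053914892766, 0.3818300505051189,
         0.4179591836734694, 0.3818300505051189, 0.2797053914892766,
         0.1294849661688697)
  a <- grid[-length(grid)]; b <- grid[-1]
  h2 <- (b - a) / 2; mid <- (a + b) / 2
  nodes <- as.numeric(outer(x, h2) + matrix(mid, length(x), length(a),
                                            byrow = TRUE))
  weights <- as.numeric(outer(w, h2))
  list(nodes = nodes, weights = weights)
}

trapezoid_weights <- function(x) {
  n <- length(x)
  wgt <- numeric(n)
  wgt[1] <- (x[2] - x[1]) / 2
  wgt[n] <- (x[n] - x[n - 1]) / 2
  if (n > 2) wgt[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / 2
  wgt
}

#' Closed-form low-noise capacity of the linear model
#'
#' For the linear-Gaussian surrogate (`J = g / (lambda FF)`, affine cost)
#' the low-noise capacity-cost bound has the closed form
#' `C_low(W) = 1/2 * log2( (W - W0) / (w_AP * FF) )` with
#' `w_AP = w0 / g`.
#'
#' @param spec a [linear_model_channel()] result or list with `g`, `FF`,
#'   `w0`, `W0`.
#' @param W cost budget(s) (ATP), `W > W0`.
#' @return Capacity bound in bits.
#' @export
capacity_low_noise_linear <- function(spec, W) {
  w_AP <- spec$w0 / spec$g
  if (any(W <= spec$W0)) stop("W must exceed the resting cost W0")
  0.5 * log2((W - spec$W0) / (w_AP * spec$FF))
}

#' Information-metabolic efficiency via the low-noise input distribution
#'
#' Evaluates the exact mutual information (and average cost) of the
#' low-noise input distribution on a discretized channel for a sweep of
#' cost budgets, and returns the best information-per-cost ratio found.
#' Because any distribution's ratio lower-bounds the Jimbo-Kunisawa
#' maximum, this estimate is always at or below the exact efficiency.
#'
#' @param channel a `channel_model`.
#' @param w cost vector on the channel grid (ATP).
#' @param J Fisher information on the channel grid.
#' @param n_W number of budgets in the initial sweep between the resting
#'   cost and the maximum cost; the sweep then zooms twice around the
#'   best ratio found.
#' @return List with `E` (bits per ATP), `E_per_1e12`, `W_star`, the
#'   swept table and the best distribution.
#' @export
efficiency_low_noise <- function(channel, w, J, n_W = 40L) {
  grid <- channel$lambda
  eval_W <- function(W) {
    sol <- tryCatch(solve_low_noise(J, w, W, grid = grid),
                    error = function(e) NULL)
    if (is.null(sol)) return(NULL)
    I <- mutual_information(sol$p, channel)
    W_p <- sum(sol$p * w)
    list(W = W, I = I, W_p = W_p, E = I / W_p, p = sol$p)
  }
  W_lo <- min(w) + 1e-6 * diff(range(w))
  W_hi <- max(w) - 1e-6 * diff(range(w))
  W_grid <- seq(W_lo, W_hi, length.out = n_W)
  rows <- list()
  best <- list(E = -Inf)
  for (W in W_grid) {
    r <- eval_W(W)
    if (is.null(r)) next
    rows[[length(rows) + 1L]] <- r
    if (r$E > best$E) best <- r
  }
  if (!is.finite(best$E)) stop("low-noise efficiency sweep failed everywhere")
  # two rounds of local refinement around the running optimum
  h <- diff(W_grid[1:2])
  for (round in 1:2) {
    cand <- seq(max(W_lo, best$W - h), min(W_hi, best$W + h),
                length.out = 9L)
    for (W in cand) {
      r <- eval_W(W)
      if (is.null(r)) next
      rows[[length(rows) + 1L]] <- r
      if (r$E > best$E) best <- r
    }
    h <- h / 4
  }
  tab <- do.call(rbind, lapply(rows, function(r)
    data.frame(W = r$W, I = r$I, W_p = r$W_p, E = r$E)))
  tab <- tab[order(tab$W), ]
  list(E = best$E, W_star = best$W_p, I = best$I, p = best$p,
       W_target = best$W, E_per_1e12 = best$E * 1e12, sweep = tab)
}
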