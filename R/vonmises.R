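#' Von Mises observation model with a normal-gamma prior
#'
#' Circular features (angles in degrees) are modelled per hidden state as
#' Von Mises with unknown mean direction `mu` and concentration `kappa`.
#' The prior couples them as a normal-gamma pair: `kappa ~ Gamma(a0, b0)`
#' (shape/rate) and `mu | kappa ~ Normal(mu0, 1 / (kappa0 * kappa))`
#' wrapped onto the circle. This family has no closed-form marginal, so
#' marginal likelihoods and posterior predictives are computed by
#' trapezoidal quadrature on a `mu x kappa` grid; the prior is
#' renormalized over the grid so that quadrature marginals are proper and
#' agree with the chain of one-step predictives.
#'
#' Defaults: `mu0 = 0` degrees, `kappa0 = 0.001` (so the location prior is
#' nearly flat on the circle), `a0 = 0.01`, `b0 = 0.01`.
#'
#' Multivariate circular observations factor as independent per-dimension
#' Von Mises models. All user-facing angles are degrees; internal
#' computation is in radians. Densities are reported per degree.
#'
#' @param mu0 prior mean direction in degrees.
#' @param kappa0 positive scale coupling the location prior to `kappa`.
#' @param a0,b0 shape and rate of the Gamma prior on `kappa`.
#' @return object of class `"vm_hyper"`.
#' @examples
#' vm_hyper()
#' @export
vm_hyper <- function(mu0 = 0, kappa0 = 0.001, a0 = 0.01, b0 = 0.01) {
  stopifnot(kappa0 > 0, a0 > 0, b0 > 0)
  structure(
    list(mu0 = as.numeric(mu0) %% 360, kappa0 = kappa0, a0 = a0, b0 = b0),
    class = "vm_hyper"
  )
}

#' Quadrature grid for the Von Mises model
#'
#' @param n_mu number of equally spaced mean-direction points on
#'   `[0, 360)` degrees.
#' @param n_kappa number of log-spaced concentration points.
#' @param kappa_range range of `kappa` covered by the grid.
#' @return object of class `"vm_grid"` holding node locations (radians for
#'   `mu`) and trapezoid weights.
#' @examples
#' vm_grid()
#' @export
vm_grid <- function(n_mu = 720, n_kappa = 64, kappa_range = c(1e-3, 1e3)) {
  stopifnot(n_mu >= 8, n_kappa >= 4, kappa_range[1] > 0,
            kappa_range[2] > kappa_range[1])
  mu <- seq(0, 2 * pi, length.out = n_mu + 1L)[-(n_mu + 1L)]
  kappa <- exp(seq(log(kappa_range[1]), log(kappa_range[2]),
    length.out = n_kappa
  ))
  dk <- diff(kappa)
  w_kappa <- c(dk[1] / 2, (dk[-length(dk)] + dk[-1]) / 2, dk[length(dk)] / 2)
  structure(
    list(
      mu = mu, kappa = kappa,
      w_mu = 2 * pi / n_mu, w_kappa = w_kappa,
      log_i0 = log(besselI(kappa, 0, expon.scaled = TRUE)) + kappa
    ),
    class = "vm_grid"
  )
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi
LOG_DEG_PER_RAD <- log(180 / pi)

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) {
    return(m)
  }
  m + log(sum(exp(x - m)))
}

# log wrapped-normal density (per radian) at angles theta (radians) with
# location mu0 and sd sigma; near-uniform regime short-circuits to 1/(2*pi)
log_wrapped_normal <- function(theta, mu0, sigma) {
  if (sigma >= 6) {
    return(rep(-log(2 * pi), length(theta)))
  }
  nwrap <- ceiling((6 * sigma + pi) / (2 * pi))
  dens <- rep(0, length(theta))
  for (j in -nwrap:nwrap) {
    dens <- dens + stats::dnorm(theta + 2 * pi * j, mu0, sigma)
  }
  log(dens)
}

# log prior mass per grid node (mu x kappa matrix), renormalized to sum 1
vm_log_prior_weights <- function(hyper, grid) {
  sigma <- 1 / sqrt(hyper$kappa0 * grid$kappa)
  mu0 <- deg2rad(hyper$mu0)
  lp <- vapply(
    seq_along(grid$kappa),
    function(j) {
      log_wrapped_normal(grid$mu, mu0, sigma[j]) +
        stats::dgamma(grid$kappa[j], hyper$a0, rate = hyper$b0, log = TRUE) +
        log(grid$w_mu) + log(grid$w_kappa[j])
    },
    numeric(length(grid$mu))
  )
  lp - logsumexp(lp)
}

# sum_t log VM(y_t | mu_i, kappa_j) for a single circular dimension
# (y in radians); densities per radian
vm_log_lik_grid <- function(y, grid) {
  m <- length(y)
  if (m == 0L) {
    return(matrix(0, length(grid$mu), length(grid$kappa)))
  }
  a <- sum(cos(y)) * cos(grid$mu) + sum(sin(y)) * sin(grid$mu)
  outer(a, grid$kappa) -
    m * matrix(log(2 * pi) + grid$log_i0, length(grid$mu),
      length(grid$kappa),
      byrow = TRUE
    )
}

# single-dimension state: normalized prior + data likelihood on the grid
vm_dim_state <- function(y_rad, hyper, grid) {
  lp0 <- vm_log_prior_weights(hyper, grid)
  logw <- lp0 + vm_log_lik_grid(y_rad, grid)
  list(logw = logw, log_marginal_rad = logsumexp(logw))
}

# per-degree log predictive density at angles `a_rad` for one dimension
vm_dim_predictive <- function(state, a_rad, grid) {
  mx <- max(state$logw)
  w <- exp(state$logw - mx) # relative posterior weights on the grid
  total <- sum(w)
  cmat <- cos(outer(a_rad, grid$mu, "-")) # n_a x n_mu
  s <- numeric(length(a_rad))
  for (j in seq_along(grid$kappa)) {
    s <- s + exp(grid$kappa[j] * cmat -
      (log(2 * pi) + grid$log_i0[j])) %*% w[, j]
  }
  log(as.numeric(s) / total) - LOG_DEG_PER_RAD
}

# validate/convert circular observations to a radian matrix
circular_matrix <- function(obs) {
  if (inherits(obs, "obs_set") && any(feature_kinds(obs) != "circular")) {
    stop("the Von Mises model requires all-circular features", call. = FALSE)
  }
  deg2rad(obs_matrix(obs) %% 360)
}

#' Log marginal likelihood under the Von Mises model
#'
#' Probability (per-degree density) that all observations came from a
#' single hidden state, with `(mu, kappa)` integrated out numerically per
#' dimension; dimensions multiply. The empty set returns 0.
#'
#' @param hyper a [vm_hyper()] prior.
#' @param obs circular observations in degrees: an [obs_set()], matrix or
#'   vector (rows are observations, columns circular features).
#' @param grid a [vm_grid()].
#' @return scalar log marginal likelihood.
#' @export
vonmises_log_marginal <- function(hyper, obs, grid = vm_grid()) {
  y <- circular_matrix(obs)
  if (nrow(y) == 0L) {
    return(0)
  }
  per_dim <- vapply(
    seq_len(ncol(y)),
    function(d) vm_dim_state(y[, d], hyper, grid)$log_marginal_rad,
    numeric(1)
  )
  sum(per_dim) + nrow(y) * ncol(y) * (-LOG_DEG_PER_RAD)
}

#' Log posterior-predictive density under the Von Mises model
#'
#' Per-degree log density of a new circular observation given the training
#' observations assigned to a state, computed by quadrature:
#' the ratio of the joint (training + probe) grid integral to the training
#' integral, per dimension; dimensions multiply.
#'
#' @inheritParams vonmises_log_marginal
#' @param train training observations (degrees); may be empty, in which
#'   case the prior predictive (nearly uniform, about `1/360` per degree)
#'   is returned.
#' @param y numeric vector of probe angles in degrees, one per feature.
#' @return scalar log density (per degree, summed over dimensions).
#' @export
vonmises_log_predictive <- function(hyper, train, y, grid = vm_grid()) {
  ytr <- circular_matrix(train)
  y <- deg2rad(as.numeric(y) %% 360)
  if (ncol(ytr) == 0L || nrow(ytr) == 0L) {
    ytr <- matrix(numeric(0), 0, length(y))
  }
  if (length(y) != ncol(ytr)) stop("probe dimension mismatch", call. = FALSE)
  total <- 0
  for (d in seq_along(y)) {
    state <- vm_dim_state(ytr[, d], hyper, grid)
    total <- total + vm_dim_predictive(state, y[d], grid)
  }
  total
}
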