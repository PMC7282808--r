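#' Normal-Wishart Gaussian observation model
#'
#' Real-valued features are modelled per hidden state as multivariate
#' normal with unknown mean and covariance, under a conjugate
#' normal-(inverse-)Wishart prior. State parameters are never materialized:
#' everything is expressed through the closed-form posterior predictive,
#' a generalized Student-t distribution.
#'
#' Default hyperparameters: `mu0 = 0`, `kappa0 = 0.001` (prior observation
#' count for the mean), `nu0 = 0.02` (degrees of freedom) and scale matrix
#' `T0 = 0.02 * I`. With `d > 1` a prior with `nu0 = 0.02` makes the
#' empty-state predictive improper (degrees of freedom `nu0 - d + 1 <= 0`),
#' so the effective prior degrees of freedom are floored at
#' `nu0 + d - 1` — identical to the stated value in one dimension and the
#' minimal proper correction above it.
#'
#' @param dim feature dimension `d >= 1`.
#' @param mu0 prior mean vector (recycled to length `dim`).
#' @param kappa0 prior scale (pseudo-count) on the mean, `> 0`.
#' @param nu0 prior degrees of freedom before the propriety floor.
#' @param t0 prior scale matrix, or a scalar `s` meaning `s * I`.
#' @return object of class `"niw_hyper"` with fields `mu0`, `kappa0`,
#'   `nu0` (floored), `t0`, `dim`, `m = 0`.
#' @examples
#' niw_hyper(dim = 4)
#' @export
niw_hyper <- function(dim = 1L, mu0 = 0, kappa0 = 0.001, nu0 = 0.02,
                      t0 = 0.02) {
  stopifnot(dim >= 1, kappa0 > 0, nu0 > 0)
  mu0 <- rep_len(as.numeric(mu0), dim)
  if (length(t0) == 1L) t0 <- diag(as.numeric(t0), dim)
  t0 <- as.matrix(t0)
  if (!isTRUE(all.equal(t0, t(t0))) || any(eigen(t0, symmetric = TRUE, only.values = TRUE)$values <= 0)) {
    stop("`t0` must be symmetric positive-definite", call. = FALSE)
  }
  if (nrow(t0) != dim) stop("`t0` dimension mismatch", call. = FALSE)
  structure(
    list(
      mu0 = mu0, kappa0 = kappa0,
      nu0 = nu0 + dim - 1, # propriety floor; identity for dim = 1
      t0 = t0, dim = dim, m = 0L
    ),
    class = "niw_hyper"
  )
}

#' Posterior update of normal-Wishart hyperparameters
#'
#' Conjugate update for `m` observations: `kappa_m = kappa0 + m`,
#' `nu_m = nu0 + m`, `mu_m = (kappa0 mu0 + m ybar) / (kappa0 + m)`,
#' `T_m = T0 + S + kappa0 m / (kappa0 + m) (mu0 - ybar)(mu0 - ybar)'`,
#' where `S` is the centered scatter matrix `sum_t (y_t - ybar)(y_t - ybar)'`.
#' An empty observation set returns the prior unchanged.
#'
#' @param hyper a [niw_hyper()] prior (or an already-updated posterior).
#' @param obs observations: an [obs_set()], matrix or vector with `d`
#'   linear features per row.
#' @return object of class `"niw_posterior"` with fields `mu`, `kappa`,
#'   `nu`, `t_mat`, `dim`, `m`.
#' @examples
#' niw_update(niw_hyper(1), c(1.0))
#' @export
niw_update <- function(hyper, obs) {
  stopifnot(inherits(hyper, "niw_hyper") || inherits(hyper, "niw_posterior"))
  y <- obs_matrix(obs)
  if (inherits(obs, "obs_set") && any(feature_kinds(obs) != "linear")) {
    stop("the Gaussian model requires all-linear features", call. = FALSE)
  }
  m <- nrow(y)
  post <- structure(
    list(
      mu = hyper$mu0 %||% hyper$mu, kappa = hyper$kappa0 %||% hyper$kappa,
      nu = hyper$nu0 %||% hyper$nu, t_mat = hyper$t0 %||% hyper$t_mat,
      dim = hyper$dim, m = hyper$m
    ),
    class = "niw_posterior"
  )
  if (m == 0L) {
    return(post)
  }
  if (ncol(y) != hyper$dim) {
    stop("observation dimension does not match the prior", call. = FALSE)
  }
  ybar <- colMeans(y)
  centred <- sweep(y, 2L, ybar)
  scatter <- crossprod(centred)
  k0 <- post$kappa
  dev <- post$mu - ybar
  post$t_mat <- post$t_mat + scatter + (k0 * m / (k0 + m)) * tcrossprod(dev)
  post$mu <- (k0 * post$mu + m * ybar) / (k0 + m)
  post$kappa <- k0 + m
  post$nu <- post$nu + m
  post$m <- post$m + m
  post
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.niw_posterior <- function(x, ...) {
  cat(
    "<niw_posterior> d=", x$dim, " m=", x$m, " kappa=", x$kappa,
    " nu=", format(x$nu), "\n mu = [", paste(signif(x$mu, 6), collapse = ", "),
    "]\n",
    sep = ""
  )
  invisible(x)
}

#' Log posterior-predictive density under the Gaussian model
#'
#' The posterior predictive of a new observation is a generalized
#' (multivariate) Student-t with `nu_m - d + 1` degrees of freedom,
#' location `mu_m` and scale matrix `T_m (kappa_m + 1) / (kappa_m
#' (nu_m - d + 1))`.
#'
#' @param post a [niw_posterior()] (a bare [niw_hyper()] is accepted and
#'   treated as the zero-observation posterior).
#' @param y numeric vector of length `d`, or a matrix of rows to evaluate.
#' @return log density (vector if `y` is a matrix).
#' @export
gaussian_log_predictive <- function(post, y) {
  if (inherits(post, "niw_hyper")) post <- niw_update(post, matrix(numeric(0), 0, post$dim))
  d <- post$dim
  y <- if (is.null(dim(y))) matrix(y, ncol = d) else as.matrix(y)
  if (ncol(y) != d) stop("probe dimension mismatch", call. = FALSE)
  df <- post$nu - d + 1
  stopifnot(df > 0)
  scale <- post$t_mat * (post$kappa + 1) / (post$kappa * df)
  dmvt_log(y, post$mu, scale, df)
}

# log density of the multivariate Student-t, parameterized by scale matrix
dmvt_log <- function(y, mu, scale, df) {
  d <- length(mu)
  ch <- chol(scale)
  z <- forwardsolve(t(ch), t(sweep(y, 2L, mu)))
  quad <- colSums(z^2)
  logdet <- 2 * sum(log(diag(ch)))
  lgamma((df + d) / 2) - lgamma(df / 2) - (d / 2) * log(df * pi) -
    logdet / 2 - ((df + d) / 2) * log1p(quad / df)
}

#' Log marginal likelihood of an observation set under one hidden state
#'
#' Probability that all observations in `obs` were generated by a single
#' state, with state parameters integrated out. Computed as the chain of
#' one-step posterior predictives `log P(y_1) + log P(y_2 | y_1) + ...`,
#' which equals the marginalized likelihood integral for this conjugate
#' family; the value is order-invariant. The empty set returns 0.
#'
#' @inheritParams niw_update
#' @return scalar log marginal likelihood.
#' @export
gaussian_log_marginal <- function(hyper, obs) {
  y <- obs_matrix(obs)
  if (nrow(y) == 0L) {
    return(0)
  }
  post <- niw_update(hyper, matrix(numeric(0), 0, hyper$dim))
  total <- 0
  for (t in seq_len(nrow(y))) {
    total <- total + gaussian_log_predictive(post, y[t, , drop = FALSE])
    post <- niw_update(post, y[t, , drop = FALSE])
  }
  total
}
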