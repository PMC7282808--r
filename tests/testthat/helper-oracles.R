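# Independent oracles used across test files.

# Sequential CRP probability of an assignment vector: product of the
# next-state probabilities, evaluated step by step.
sequential_crp_log_prob <- function(assignments, alpha) {
  total <- 0
  for (t in seq_along(assignments)) {
    probs <- crp_next_state_probs(partition(assignments[seq_len(t - 1L)]), alpha)
    total <- total + log(probs[assignments[t]])
  }
  total
}

# Brute-force 2-D quadrature for the 1-D Gaussian marginal likelihood:
# lambda ~ Gamma(nu0/2, rate t0/2), mu | lambda ~ N(mu0, 1/(kappa0*lambda)),
# y_t | mu, lambda ~ N(mu, 1/lambda). Log-spaced lambda grid; per-lambda
# Gaussian-adapted mu grid (the mu-integrand is an exact Gaussian).
brute_force_gaussian_log_marginal <- function(y, mu0 = 0, kappa0 = 0.001,
                                              nu0 = 0.02, t0 = 0.02,
                                              n_lambda = 4000, n_mu = 400) {
  m <- length(y)
  lam <- exp(seq(log(1e-9), log(1e5), length.out = n_lambda))
  dl <- diff(lam)
  wl <- c(dl[1] / 2, (dl[-length(dl)] + dl[-1]) / 2, dl[length(dl)] / 2)
  log_terms <- vapply(seq_along(lam), function(i) {
    l <- lam[i]
    prec <- l * (kappa0 + m)
    centre <- (kappa0 * mu0 + sum(y)) * l / prec
    sd_mu <- 1 / sqrt(prec)
    mus <- seq(centre - 10 * sd_mu, centre + 10 * sd_mu, length.out = n_mu)
    dmu <- mus[2] - mus[1]
    lg <- vapply(mus, function(mu) {
      sum(stats::dnorm(y, mu, 1 / sqrt(l), log = TRUE)) +
        stats::dnorm(mu, mu0, 1 / sqrt(kappa0 * l), log = TRUE)
    }, numeric(1))
    mx <- max(lg)
    mx + log(sum(exp(lg - mx)) * dmu) +
      stats::dgamma(l, nu0 / 2, rate = t0 / 2, log = TRUE) + log(wl[i])
  }, numeric(1))
  mx <- max(log_terms)
  mx + log(sum(exp(log_terms - mx)))
}

circular_mean_deg <- function(x) {
  (atan2(mean(sin(x * pi / 180)), mean(cos(x * pi / 180))) * 180 / pi)
}
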