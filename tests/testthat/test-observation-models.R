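test_that("normal-Wishart update matches the conjugate formulas", {
  h <- niw_hyper(1)
  p <- niw_update(h, 1.0)
  expect_equal(p$mu, 0.001 * 0 / 1.001 + 1 / 1.001, tolerance = 1e-12)
  expect_equal(p$kappa, 1.001)
  expect_equal(p$nu, 1.02)
  expect_equal(as.numeric(p$t_mat), 0.02 + (0.001 * 1 / 1.001) * 1,
    tolerance = 1e-12
  )
  # no-data update is the identity
  p0 <- niw_update(h, numeric(0))
  expect_equal(p0$mu, h$mu0)
  expect_equal(p0$kappa, h$kappa0)
  expect_equal(as.numeric(p0$t_mat), as.numeric(h$t0))
  # two equal points contribute no scatter
  for (c0 in c(0.7, -2.2)) {
    p2 <- niw_update(h, c(c0, c0))
    expect_equal(as.numeric(p2$t_mat), 0.02 + (0.001 * 2 / 2.001) * c0^2,
      tolerance = 1e-12
    )
  }
  expect_error(niw_update(niw_hyper(2), c(1, 2, 3)), "dimension")
})

test_that("degrees-of-freedom floor keeps multivariate predictives proper", {
  # d = 1 is untouched; d > 1 floors nu0 so the prior predictive df is
  # positive
  expect_equal(niw_hyper(1)$nu0, 0.02)
  expect_equal(niw_hyper(4)$nu0, 3.02)
  prior4 <- niw_update(niw_hyper(4), matrix(numeric(0), 0, 4))
  expect_true(is.finite(gaussian_log_predictive(prior4, rep(5, 4))))
})

test_that("Gaussian posterior predictive is a proper, unimodal density", {
  post <- niw_update(niw_hyper(1), 0)
  # quadrature normalization oracle
  dens <- function(y) exp(gaussian_log_predictive(post, matrix(y, ncol = 1)))
  total <- stats::integrate(Vectorize(dens), -Inf, Inf, rel.tol = 1e-8)$value
  expect_equal(total, 1, tolerance = 1e-3)
  # maximal at the posterior mean, monotone tail decay
  at_mu <- gaussian_log_predictive(post, post$mu)
  expect_gt(at_mu, gaussian_log_predictive(post, post$mu + 0.5))
  expect_gt(
    gaussian_log_predictive(post, 0),
    gaussian_log_predictive(post, 5)
  )
  # 2-D: density maximal at the posterior mean
  post2 <- niw_update(niw_hyper(2), rbind(c(1, -1), c(1.2, -0.8)))
  expect_gt(
    gaussian_log_predictive(post2, post2$mu),
    gaussian_log_predictive(post2, post2$mu + c(0.3, 0))
  )
})

test_that("Gaussian marginal equals brute-force quadrature and chains exactly", {
  h <- niw_hyper(1)
  for (y in list(c(0, 0, 0), c(0.4, -0.1, 0.2, 0.05))) {
    chain <- gaussian_log_marginal(h, y)
    brute <- brute_force_gaussian_log_marginal(y)
    expect_equal(chain, brute, tolerance = 1e-3)
  }
  # empty set has probability one
  expect_identical(gaussian_log_marginal(h, numeric(0)), 0)
  # exchangeability
  expect_equal(
    gaussian_log_marginal(h, c(0.3, -0.3)),
    gaussian_log_marginal(h, c(-0.3, 0.3)),
    tolerance = 1e-10
  )
  set.seed(5)
  y <- rnorm(6)
  expect_equal(
    gaussian_log_marginal(h, y),
    gaussian_log_marginal(h, rev(y)),
    tolerance = 1e-10
  )
})

test_that("duplicating the sample mean never lowers per-obs predictive density", {
  h <- niw_hyper(1)
  set.seed(8)
  y <- rnorm(5, 2, 0.5)
  post <- niw_update(h, y)
  lp_before <- gaussian_log_predictive(post, mean(y))
  post2 <- niw_update(h, c(y, mean(y)))
  lp_after <- gaussian_log_predictive(post2, mean(y))
  expect_gte(lp_after, lp_before)
})

test_that("Von Mises prior predictive is near-uniform", {
  h <- vm_hyper()
  g <- vm_grid()
  empty <- matrix(numeric(0), 0, 1)
  for (y in c(0, 10, 90, 180, 271, 355.5)) {
    dens <- exp(vonmises_log_predictive(h, empty, y, g)) * 360
    expect_equal(dens, 1, tolerance = 0.05)
  }
})

test_that("Von Mises predictive concentrates at the training mode and is proper", {
  h <- vm_hyper()
  g <- vm_grid()
  train <- rep(30, 20)
  expect_gt(
    vonmises_log_predictive(h, train, 30, g),
    vonmises_log_predictive(h, train, 210, g)
  )
  # normalization over a 1-degree grid
  dens <- vapply(
    seq(0.5, 359.5, by = 1),
    function(a) exp(vonmises_log_predictive(h, train, a, g)),
    numeric(1)
  )
  expect_equal(sum(dens), 1, tolerance = 1e-3)
})

test_that("Von Mises model is approximately rotation-equivariant", {
  h <- vm_hyper()
  g <- vm_grid()
  set.seed(21)
  for (i in 1:5) {
    train <- (rnorm(10, runif(1, 0, 360), 18)) %% 360
    probe <- runif(1, 0, 360)
    shift <- runif(1, 0, 360)
    d1 <- vonmises_log_predictive(h, train, probe, g)
    d2 <- vonmises_log_predictive(h, (train + shift) %% 360,
      (probe + shift) %% 360, g
    )
    expect_lt(abs(d1 - d2), 1e-3)
  }
})

test_that("Von Mises marginal chains, is exchangeable, and converges in grid size", {
  h <- vm_hyper()
  g <- vm_grid()
  y <- c(10, 30, 355, 200)
  marg <- vonmises_log_marginal(h, y, g)
  chain <- sum(vapply(seq_along(y), function(t) {
    vonmises_log_predictive(h, y[seq_len(t - 1)], y[t], g)
  }, numeric(1)))
  expect_equal(marg, chain, tolerance = 1e-3)
  expect_equal(marg, vonmises_log_marginal(h, rev(y), g), tolerance = 1e-10)
  expect_identical(vonmises_log_marginal(h, numeric(0), g), 0)
  # doubling both grid resolutions moves the result by less than 1e-3
  g2 <- vm_grid(n_mu = 1440, n_kappa = 128)
  set.seed(31)
  ytrain <- rnorm(10, 0, 18) %% 360
  expect_lt(
    abs(
      vonmises_log_marginal(h, ytrain, g) -
        vonmises_log_marginal(h, ytrain, g2)
    ),
    1e-3
  )
})

test_that("antipodal clusters favor two Von Mises states over one", {
  h <- vm_hyper()
  g <- vm_grid()
  a <- c(358, 2, 5, 355, 1)
  b <- c(178, 183, 176, 181, 185)
  one <- vonmises_log_marginal(h, c(a, b), g)
  two <- vonmises_log_marginal(h, a, g) + vonmises_log_marginal(h, b, g)
  expect_gt(two, one)
})

test_that("observation kinds are validated per family", {
  circ <- obs_set(c(10, 20), kinds = "circular")
  lin <- obs_set(c(0.1, 0.2), kinds = "linear")
  expect_error(niw_update(niw_hyper(1), circ), "linear")
  expect_error(vonmises_log_marginal(vm_hyper(), lin), "circular")
  expect_equal(feature_kinds(circ), "circular")
  # circular storage wraps into [0, 360)
  expect_equal(obs_set(-10, kinds = "circular")$y1, 350)
})
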