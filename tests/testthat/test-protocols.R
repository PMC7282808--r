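test_that("synthetic generators reproduce their distribution parameters", {
  # degenerate Gaussian: five identical zero vectors
  z <- generate_observations(dist_spec("gaussian", mean = 0, sd = 0), 5,
    seed = 1
  )
  expect_true(all(obs_matrix(z) == 0))
  expect_equal(nrow(z), 5L)
  # uniform circular: resultant length near zero
  u <- obs_matrix(generate_observations(dist_spec("uniform_circular"), 1e4,
    seed = 2
  ))
  rad <- u * pi / 180
  resultant <- sqrt(mean(cos(rad))^2 + mean(sin(rad))^2)
  expect_lt(resultant, 0.03) # E[R] ~ 1/sqrt(n) under uniformity
  # wrapped normal moment recovery
  w <- obs_matrix(generate_observations(
    dist_spec("wrapped_normal", mean = 0, sd = 18), 1e4,
    seed = 3
  ))
  wr <- w * pi / 180
  r <- sqrt(mean(cos(wr))^2 + mean(sin(wr))^2)
  circ_sd_deg <- sqrt(-2 * log(r)) * 180 / pi
  expect_lt(abs(circular_mean_deg(w)), 1)
  expect_equal(circ_sd_deg, 18, tolerance = 0.03)
  # von mises draws concentrate at the stated mean
  v <- obs_matrix(generate_observations(
    dist_spec("vonmises", mean = 90, kappa = 10), 2000,
    seed = 4
  ))
  expect_lt(abs(circular_mean_deg(v) - 90), 3)
  expect_error(dist_spec("gaussian", sd = -1), "non-negative")
})

test_that("alternating schedules cycle through the spec list", {
  specs <- list(
    dist_spec("gaussian", mean = -1, sd = 0),
    dist_spec("gaussian", mean = 1, sd = 0)
  )
  y <- obs_matrix(generate_observations(specs, 6, seed = 1))
  expect_equal(as.numeric(y), rep(c(-1, 1), 3))
  expect_error(
    generate_observations(
      list(dist_spec("gaussian"), dist_spec("uniform_circular")), 4,
      seed = 1
    ),
    "share kind"
  )
})

test_that("max-margin split finds the emptiest diameter", {
  s <- max_margin_split(c(0, 180))
  expect_equal(s$theta, 90)
  expect_equal(s$margin, 90)
  expect_equal(sort(unique(s$groups)), c(1L, 2L))
  # two Von Mises clusters at 0/180 put the boundary near 90 or 270
  y <- obs_matrix(generate_observations(
    list(
      dist_spec("vonmises", mean = 0, kappa = 10),
      dist_spec("vonmises", mean = 180, kappa = 10)
    ),
    30,
    seed = 5
  ))
  s2 <- max_margin_split(y)
  expect_lt(abs(s2$theta - 90), 12)
  expect_true(all(s2$groups[y < 90 | y > 270] == s2$groups[1]))
  # perfect four-point tie returns the smallest qualifying angle
  s3 <- max_margin_split(c(0, 90, 180, 270))
  expect_equal(s3$theta, 45)
  expect_error(max_margin_split(10), "at least two")
})

test_that("protocols are deterministic functions of config and seed", {
  for (p in c(
    "cue_constellation", "alternation_learning", "direction_foraging",
    "morph_test", "schedule_hypotheses", "cue_variability"
  )) {
    a <- run_protocol(p, seed = 7)
    b <- run_protocol(p, seed = 7)
    expect_identical(as.data.frame(a), as.data.frame(b))
  }
})

test_that("unknown config fields are rejected by name", {
  expect_error(run_cue_constellation(list(bogus = 1)), "bogus")
  expect_error(run_schedule_hypotheses(list(schedule = character(0))),
    "non-empty"
  )
  expect_error(
    run_schedule_hypotheses(list(schedule = c("white_circle", "moon"))),
    "known environments"
  )
})

test_that("alternation learning supports a vector of concentration values", {
  r <- run_alternation_learning(list(alpha = c(0.05, 0.5), n_pairs = 6),
    seed = 3
  )
  expect_setequal(unique(r$condition), c("alpha=0.05", "alpha=0.5"))
  expect_equal(nrow(r), 12L)
  # same draws, so the alpha difference is purely the prior term
  wide <- tidyr::pivot_wider(r,
    id_cols = "step", names_from = "condition",
    values_from = "value"
  )
  prior_gap <- (crp_log_prior(partition(c(1, 1)), 0.05) -
    crp_log_prior(partition(c(1, 2)), 0.05)) -
    (crp_log_prior(partition(c(1, 1)), 0.5) -
      crp_log_prior(partition(c(1, 2)), 0.5))
  expect_equal(
    wide$`alpha=0.05`[1] - wide$`alpha=0.5`[1],
    prior_gap,
    tolerance = 1e-10
  )
})

test_that("cue-variability inference is symmetric under feature transposition", {
  fam <- gaussian_family(dim = 2)
  part <- partition(rep(1, 20))
  train <- obs_matrix(generate_observations(
    dist_spec("gaussian", mean = c(-5, 0), sd = c(2, 0.1)), 20,
    seed = 11
  ))
  probe <- c(-1, 0)
  er <- state_evidence_ratio(probe, train, part, 0.1, fam)$log_odds
  er_t <- state_evidence_ratio(rev(probe), train[, 2:1], part, 0.1,
    fam
  )$log_odds
  expect_equal(er, er_t, tolerance = 1e-10)
  # and the protocol realizes the intended qualitative contrast
  r <- run_cue_variability(seed = 11)
  vals <- setNames(r$value, r$condition)
  expect_gt(vals[["cyan"]], 0)
  expect_lt(vals[["magenta"]], 0)
})

test_that("schedule posteriors are normalized and respond to alpha", {
  r <- run_schedule_hypotheses(seed = 13)
  sums <- r |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(total = sum(.data$value))
  expect_true(all(abs(sums$total - 1) < 1e-10))
  wide <- tidyr::pivot_wider(r,
    id_cols = "condition", names_from = "quantity",
    values_from = "value"
  )
  # the separate-states hypothesis gains and the single-state hypothesis
  # loses as alpha grows
  alphas <- as.numeric(sub("alpha=", "", wide$condition))
  ord <- order(alphas)
  expect_true(all(diff(wide$p_all_separate[ord]) > 0))
  expect_true(all(diff(wide$p_all_together[ord]) < 0))
})
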