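#' Distribution specifications for synthetic observations
#'
#' @param family one of `"gaussian"`, `"vonmises"`, `"wrapped_normal"`,
#'   `"uniform_circular"`.
#' @param mean mean vector (linear units, or degrees for circular
#'   families).
#' @param sd standard deviation vector (linear units or degrees); used by
#'   `"gaussian"` and `"wrapped_normal"`.
#' @param kappa Von Mises concentration (per dimension).
#' @param dims number of feature dimensions (inferred from the parameter
#'   vectors when omitted).
#' @return object of class `"dist_spec"`.
#' @examples
#' dist_spec("gaussian", mean = c(0, 0), sd = 0.2)
#' dist_spec("wrapped_normal", mean = 0, sd = 18)
#' @export
dist_spec <- function(family = c(
                        "gaussian", "vonmises", "wrapped_normal",
                        "uniform_circular"
                      ),
                      mean = 0, sd = 1, kappa = 1, dims = NULL) {
  family <- match.arg(family)
  dims <- dims %||% max(length(mean), length(sd), length(kappa), 1L)
  mean <- rep_len(as.numeric(mean), dims)
  sd <- rep_len(as.numeric(sd), dims)
  kappa <- rep_len(as.numeric(kappa), dims)
  if (family %in% c("gaussian", "wrapped_normal") && any(sd < 0)) {
    stop("`sd` must be non-negative", call. = FALSE)
  }
  if (family == "vonmises" && any(kappa < 0)) {
    stop("`kappa` must be non-negative", call. = FALSE)
  }
  structure(
    list(family = family, mean = mean, sd = sd, kappa = kappa, dims = dims),
    class = "dist_spec"
  )
}

spec_kind <- function(spec) {
  if (spec$family == "gaussian") "linear" else "circular"
}

draw_from_spec <- function(spec, n) {
  d <- spec$dims
  out <- matrix(0, n, d)
  for (j in seq_len(d)) {
    out[, j] <- switch(spec$family,
      gaussian = stats::rnorm(n, spec$mean[j], spec$sd[j]),
      wrapped_normal = stats::rnorm(n, spec$mean[j], spec$sd[j]) %% 360,
      uniform_circular = stats::runif(n, 0, 360),
      vonmises = rad2deg(rvonmises(
        n, deg2rad(spec$mean[j]),
        spec$kappa[j]
      )) %% 360
    )
  }
  out
}

# Best-Fisher (1979) rejection sampler for the Von Mises distribution
rvonmises <- function(n, mu, kappa) {
  if (kappa == 0) {
    return(stats::runif(n, 0, 2 * pi))
  }
  tau <- 1 + sqrt(1 + 4 * kappa^2)
  rho <- (tau - sqrt(2 * tau)) / (2 * kappa)
  r <- (1 + rho^2) / (2 * rho)
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      u <- stats::runif(3)
      z <- cos(pi * u[1])
      f <- (1 + r * z) / (r + z)
      c0 <- kappa * (r - f)
      if (c0 * (2 - c0) - u[2] > 0 || log(c0 / u[2]) + 1 - c0 >= 0) {
        out[i] <- (mu + sign(u[3] - 0.5) * acos(f)) %% (2 * pi)
        break
      }
    }
  }
  out
}

#' Generate synthetic observations
#'
#' Draws `n` observations from a distribution specification, or from a
#' repeating sequence of specifications (alternating schedules): with a
#' list of specs, observation `t` is drawn from spec `((t - 1) mod L) + 1`.
#'
#' @param spec a [dist_spec()] or list of them (all the same kind and
#'   dimension).
#' @param n number of observations.
#' @param seed optional integer for a reproducible draw (RNG state is
#'   restored afterwards).
#' @return an [obs_set()].
#' @examples
#' generate_observations(dist_spec("gaussian", mean = 0, sd = 0.2), 5, seed = 1)
#' @export
generate_observations <- function(spec, n, seed = NULL) {
  if (!is.null(seed)) {
    return(with_preserved_seed(seed, generate_observations(spec, n)))
  }
  specs <- if (inherits(spec, "dist_spec")) list(spec) else spec
  stopifnot(n >= 1, length(specs) >= 1)
  kinds <- vapply(specs, spec_kind, character(1))
  dims <- vapply(specs, function(s) s$dims, numeric(1))
  if (length(unique(kinds)) > 1L || length(unique(dims)) > 1L) {
    stop("alternating specs must share kind and dimension", call. = FALSE)
  }
  out <- matrix(0, n, dims[1])
  for (t in seq_len(n)) {
    s <- specs[[(t - 1L) %% length(specs) + 1L]]
    out[t, ] <- draw_from_spec(s, 1L)
  }
  obs_set(out, kinds = kinds[1])
}

#' Maximum-margin split of circular observations
#'
#' Finds the diameter of the circle that is farthest from all
#' observations: the boundary angle `theta` (with antipode `theta + 180`)
#' maximizing the minimum angular distance from any observation to the
#' boundary. Used to split running directions into two candidate states.
#' Ties return the smallest qualifying angle.
#'
#' @param obs at least two circular observations (degrees, single
#'   feature).
#' @param resolution search grid spacing in degrees.
#' @return list with `theta` (boundary angle in `[0, 180)`), `margin`
#'   (degrees) and `groups` (1/2 assignment of each observation to a
#'   half-circle).
#' @examples
#' max_margin_split(c(0, 180))
#' @export
max_margin_split <- function(obs, resolution = 1) {
  ang <- as.numeric(obs_matrix(obs)) %% 360
  if (length(ang) < 2L) {
    stop("at least two observations are required", call. = FALSE)
  }
  thetas <- seq(0, 180 - resolution, by = resolution)
  margin <- vapply(thetas, function(th) {
    d1 <- abs(wrap_angle(ang - th))
    d2 <- abs(wrap_angle(ang - th - 180))
    min(pmin(d1, d2))
  }, numeric(1))
  i <- which.max(margin)
  theta <- thetas[i]
  groups <- ifelse(((ang - theta) %% 360) < 180, 1L, 2L)
  list(theta = theta, margin = margin[i], groups = groups)
}

result_row <- function(protocol, condition, step, quantity, value, seed) {
  tibble::tibble(
    protocol = protocol, condition = as.character(condition),
    step = as.numeric(step), quantity = quantity,
    value = as.numeric(value), seed = as.integer(seed)
  )
}

as_result <- function(rows, protocol, config) {
  out <- dplyr::bind_rows(rows)
  attr(out, "protocol") <- protocol
  attr(out, "config") <- config
  class(out) <- c("statemap_result", class(out))
  out
}

merge_config <- function(defaults, overrides) {
  overrides <- overrides %||% list()
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
      call. = FALSE
    )
  }
  utils::modifyList(defaults, overrides)
}

#' Cue-constellation protocol
#'
#' Trains on 20 observations of a four-feature Gaussian environment
#' (mean 0, SD 0.2 per feature) and probes with observations in which 0,
#' 1, 2 or all 4 cues are displaced to 1. Reports the same-state versus
#' novel-state evidence ratio for each probe: positive for the unchanged
#' probe (no remapping), near zero for partly changed constellations
#' (partial remapping), strongly negative when every cue changes (global
#' remapping).
#'
#' @param config named list of overrides of the protocol defaults
#'   (`n_features`, `train_mean`, `train_sd`, `n_train`, `probes`,
#'   `alpha`).
#' @param seed integer seed; every protocol is a deterministic function
#'   of (config, seed).
#' @return a tidy result tibble (protocol, condition, step, quantity,
#'   value, seed).
#' @export
run_cue_constellation <- function(config = list(), seed = 1) {
  defaults <- list(
    n_features = 4, train_mean = 0, train_sd = 0.2, n_train = 20,
    probes = list(c(0, 0, 0, 0), c(1, 0, 0, 0), c(1, 0, 0, 1), c(1, 1, 1, 1)),
    alpha = 0.1
  )
  cfg <- merge_config(defaults, config)
  train <- generate_observations(
    dist_spec("gaussian",
      mean = cfg$train_mean, sd = cfg$train_sd,
      dims = cfg$n_features
    ),
    cfg$n_train,
    seed = seed
  )
  fam <- gaussian_family(dim = cfg$n_features)
  part <- partition(rep(1L, cfg$n_train))
  rows <- purrr::imap(cfg$probes, function(probe, i) {
    er <- state_evidence_ratio(probe, train, part, cfg$alpha, fam,
      option_a = 1L, option_b = "novel"
    )
    result_row(
      "cue_constellation", paste(probe, collapse = ","), i,
      "state_evidence_ratio", er$log_odds, seed
    )
  })
  as_result(rows, "cue_constellation", cfg)
}

#' Alternation-learning protocol
#'
#' Observations alternate between two 1-D Gaussian generators. After each
#' pair, the partition evidence ratio compares the single-state hypothesis
#' against the alternating two-state hypothesis. With separated means
#' (defaults -1 and +1, SD 0.3) the trajectory crosses to a two-state
#' preference with experience; with identical means it accumulates
#' evidence for one state (map stabilization). A vector of `alpha` values
#' reproduces concentration-dependent transition speeds.
#'
#' @inheritParams run_cue_constellation
#' @export
run_alternation_learning <- function(config = list(), seed = 1) {
  defaults <- list(
    means = c(-1, 1), sd = 0.3, n_pairs = 20, alpha = 0.1
  )
  cfg <- merge_config(defaults, config)
  n_obs <- 2L * cfg$n_pairs
  obs <- generate_observations(
    list(
      dist_spec("gaussian", mean = cfg$means[1], sd = cfg$sd),
      dist_spec("gaussian", mean = cfg$means[2], sd = cfg$sd)
    ),
    n_obs,
    seed = seed
  )
  y <- obs_matrix(obs)
  fam <- gaussian_family(dim = 1L)
  rows <- list()
  for (alpha in cfg$alpha) {
    for (p in seq_len(cfg$n_pairs)) {
      t <- 2L * p
      er <- partition_evidence_ratio(
        y[seq_len(t), , drop = FALSE],
        hypothesis("one state", rep(1L, t)),
        hypothesis("two states", rep(c(1L, 2L), p)),
        alpha, fam
      )
      rows[[length(rows) + 1L]] <- result_row(
        "alternation_learning", paste0("alpha=", alpha), p,
        "partition_evidence_ratio", er$log_odds, seed
      )
    }
  }
  as_result(rows, "alternation_learning", cfg)
}

#' Direction-foraging protocol
#'
#' Circular running-direction observations under two conditions: random
#' foraging (uniform directions) and directed running (alternating Von
#' Mises at 0 and 180 degrees, kappa = 10). Each sample is split by the
#' maximum-margin diameter and the partition evidence ratio compares the
#' split two-state partition against the single-state partition
#' (positive favors two states).
#'
#' @inheritParams run_cue_constellation
#' @export
run_direction_foraging <- function(config = list(), seed = 1) {
  defaults <- list(
    n_obs = 10, kappa = 10, means = c(0, 180), alpha = 0.1
  )
  cfg <- merge_config(defaults, config)
  uniform <- generate_observations(
    dist_spec("uniform_circular"), cfg$n_obs,
    seed = seed
  )
  directional <- generate_observations(
    list(
      dist_spec("vonmises", mean = cfg$means[1], kappa = cfg$kappa),
      dist_spec("vonmises", mean = cfg$means[2], kappa = cfg$kappa)
    ),
    cfg$n_obs,
    seed = seed + 1L
  )
  fam <- vonmises_family()
  rows <- purrr::imap(
    list(uniform = uniform, directional = directional),
    function(obs, cond) {
      split <- max_margin_split(obs)
      er <- partition_evidence_ratio(
        obs,
        hypothesis("two states (split)", split$groups),
        hypothesis("one state", rep(1L, cfg$n_obs)),
        cfg$alpha, fam
      )
      dplyr::bind_rows(
        result_row(
          "direction_foraging", cond, NA,
          "partition_evidence_ratio", er$log_odds, seed
        ),
        result_row(
          "direction_foraging", cond, NA, "split_angle",
          split$theta, seed
        )
      )
    }
  )
  as_result(rows, "direction_foraging", cfg)
}

#' Cue-rotation protocol
#'
#' Three cue-card rotation manipulations. "180, clean": a single circular
#' feature (the cue card, wrapped normal mean 0, SD 18 degrees; 10
#' training observations) probed at 180 degrees. "180, dirty" and "45,
#' dirty": six circular features — the cue card plus five lower-fidelity
#' cues (uniformly distributed means, SD 54 degrees) left intact — probed
#' with the cue card rotated and the other cues at their means. Reports
#' each manipulation's best rotational offset and the same-state versus
#' novel-state evidence ratio at the best offset.
#'
#' @inheritParams run_cue_constellation
#' @export
run_cue_rotation <- function(config = list(), seed = 1) {
  defaults <- list(
    n_train = 10, card_sd = 18, n_extra = 5, extra_sd = 54,
    rotations = c(180, 180, 45), dirty = c(FALSE, TRUE, TRUE),
    alpha = 0.1, resolution = 1, n_mu = 720, n_kappa = 64
  )
  cfg <- merge_config(defaults, config)
  hyper <- vm_hyper()
  grid <- vm_grid(n_mu = cfg$n_mu, n_kappa = cfg$n_kappa)
  # low-fidelity cue means are drawn once per run and held fixed
  extra_means <- with_preserved_seed(
    seed,
    stats::runif(cfg$n_extra, 0, 360)
  )
  rows <- list()
  for (i in seq_along(cfg$rotations)) {
    dirty <- cfg$dirty[i]
    rot <- cfg$rotations[i]
    label <- paste0(rot, ", ", if (dirty) "dirty" else "clean")
    specs <- dist_spec("wrapped_normal", mean = 0, sd = cfg$card_sd)
    if (dirty) {
      specs <- dist_spec("wrapped_normal",
        mean = c(0, extra_means),
        sd = c(cfg$card_sd, rep(cfg$extra_sd, cfg$n_extra))
      )
    }
    train <- generate_observations(specs, cfg$n_train, seed = seed + i)
    probe <- if (dirty) c(rot, extra_means) else rot
    res <- rotation_assignment(
      probe, train, partition(rep(1L, cfg$n_train)),
      cfg$alpha, hyper, grid, cfg$resolution
    )
    rows[[length(rows) + 1L]] <- dplyr::bind_rows(
      result_row(
        "cue_rotation", label, i, "best_offset",
        res$per_state_offset[1], seed
      ),
      result_row(
        "cue_rotation", label, i, "state_evidence_ratio",
        res$evidence$log_odds, seed
      )
    )
  }
  as_result(rows, "cue_rotation", cfg)
}

#' Morph-environment protocol
#'
#' Trains on observations alternating between two 1-D Gaussian extremes
#' ("square" at -1, "circle" at +1, SD 0.3) and probes with intermediate
#' morph values after 5 and after 25 training observations. For each
#' probe, the log odds between the hypothesis set S (probe shares a state
#' with the square) and D (probe does not) is computed over the five
#' named hypotheses: S1 (one training state, probe same), S2 (two states,
#' probe with square), D1 (one state, probe novel), D2 (two states, probe
#' with circle), D3 (two states, probe novel).
#'
#' @inheritParams run_cue_constellation
#' @export
run_morph_test <- function(config = list(), seed = 1) {
  defaults <- list(
    means = c(-1, 1), sd = 0.3, n_train = c(5, 25),
    probes = seq(-1, 1, length.out = 9), alpha = 0.1
  )
  cfg <- merge_config(defaults, config)
  n_max <- max(cfg$n_train)
  obs_all <- generate_observations(
    list(
      dist_spec("gaussian", mean = cfg$means[1], sd = cfg$sd),
      dist_spec("gaussian", mean = cfg$means[2], sd = cfg$sd)
    ),
    n_max,
    seed = seed
  )
  y_all <- obs_matrix(obs_all)
  fam <- gaussian_family(dim = 1L)
  rows <- list()
  for (n in cfg$n_train) {
    y <- y_all[seq_len(n), , drop = FALSE]
    one <- rep(1L, n)
    two <- rep(c(1L, 2L), length.out = n) # state 1 = square generator
    set_s <- list(
      hypothesis("S1", one, probe_assignment = 1L),
      hypothesis("S2", two, probe_assignment = 1L)
    )
    set_d <- list(
      hypothesis("D1", one, probe_assignment = "novel"),
      hypothesis("D2", two, probe_assignment = 2L),
      hypothesis("D3", two, probe_assignment = "novel")
    )
    for (probe in cfg$probes) {
      er <- hypothesis_set_log_odds(
        y, probe, set_s, set_d, cfg$alpha, fam,
        name_s = "same state as square", name_d = "different state"
      )
      rows[[length(rows) + 1L]] <- result_row(
        "morph_test", paste0("n_train=", n), probe,
        "s_vs_d_log_odds", er$log_odds, seed
      )
    }
  }
  as_result(rows, "morph_test", cfg)
}

#' Training-schedule hypothesis protocol
#'
#' Two-feature (shape, color) sessions drawn from three environment
#' generators — white circle [1, 1], morph circle [1, -1], morph square
#' [-1, -1], all SDs 0.1 — presented according to a configurable session
#' schedule. For each concentration value, reports the normalized
#' posterior over three named partitions: every environment separate,
#' the two circles together with the square separate, and all sessions
#' together.
#'
#' @inheritParams run_cue_constellation
#' @export
run_schedule_hypotheses <- function(config = list(), seed = 1) {
  defaults <- list(
    means = list(
      white_circle = c(1, 1), morph_circle = c(1, -1),
      morph_square = c(-1, -1)
    ),
    sd = 0.1,
    schedule = c(
      rep(c("white_circle", "morph_circle"), 4),
      rep("morph_square", 4)
    ),
    alphas = c(0.001, 0.01, 0.1, 1, 10)
  )
  cfg <- merge_config(defaults, config)
  if (!length(cfg$schedule)) stop("schedule must be non-empty", call. = FALSE)
  if (!all(cfg$schedule %in% names(cfg$means))) {
    stop("schedule entries must name known environments", call. = FALSE)
  }
  y <- with_preserved_seed(seed, {
    t(vapply(
      cfg$schedule,
      function(env) stats::rnorm(2, cfg$means[[env]], cfg$sd),
      numeric(2)
    ))
  })
  env_id <- match(cfg$schedule, names(cfg$means))
  parts <- list(
    all_separate = partition(env_id),
    circles_together = partition(ifelse(
      cfg$schedule == "morph_square", 2L, 1L
    )),
    all_together = partition(rep(1L, length(cfg$schedule)))
  )
  fam <- gaussian_family(dim = 2L)
  rows <- list()
  for (alpha in cfg$alphas) {
    scores <- vapply(
      parts, function(p) partition_log_posterior(y, p, alpha, fam),
      numeric(1)
    )
    probs <- exp(scores - logsumexp(scores))
    for (h in names(parts)) {
      rows[[length(rows) + 1L]] <- result_row(
        "schedule_hypotheses", paste0("alpha=", alpha), NA,
        paste0("p_", h), probs[[h]], seed
      )
    }
  }
  as_result(rows, "schedule_hypotheses", cfg)
}

#' Cue-variability protocol
#'
#' Two training conditions with opposite anisotropy: "cyan" draws 20
#' observations from a 2-D Gaussian with mean [-5, 0] and SDs [2, 0.1];
#' "magenta" from mean [0, 0] with SDs [0.1, 2]. Both are probed with the
#' same observation (default [-1, 0], novel along feature 1) and the
#' same-state versus novel-state evidence ratio is reported: training
#' variability along the displaced feature makes the same-state
#' assignment more likely.
#'
#' @inheritParams run_cue_constellation
#' @export
run_cue_variability <- function(config = list(), seed = 1) {
  defaults <- list(
    cyan_mean = c(-5, 0), cyan_sd = c(2, 0.1),
    magenta_mean = c(0, 0), magenta_sd = c(0.1, 2),
    n_train = 20, probe = c(-1, 0), alpha = 0.1
  )
  cfg <- merge_config(defaults, config)
  fam <- gaussian_family(dim = 2L)
  part <- partition(rep(1L, cfg$n_train))
  conds <- list(
    cyan = dist_spec("gaussian", mean = cfg$cyan_mean, sd = cfg$cyan_sd),
    magenta = dist_spec("gaussian",
      mean = cfg$magenta_mean,
      sd = cfg$magenta_sd
    )
  )
  rows <- purrr::imap(conds, function(spec, cond) {
    train <- generate_observations(spec, cfg$n_train,
      seed = seed + match(cond, names(conds))
    )
    er <- state_evidence_ratio(cfg$probe, train, part, cfg$alpha, fam,
      option_a = 1L, option_b = "novel"
    )
    result_row(
      "cue_variability", cond, NA, "state_evidence_ratio",
      er$log_odds, seed
    )
  })
  as_result(rows, "cue_variability", cfg)
}
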