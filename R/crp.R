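#' The Chinese Restaurant Process prior over hidden-state partitions
#'
#' The model assumes observations are generated by an unbounded set of
#' hidden states drawn sequentially: observation `t` joins existing state
#' `k` with probability `m_k / (t - 1 + alpha)` (where `m_k` counts earlier
#' observations in state `k`) and opens a new state with probability
#' `alpha / (t - 1 + alpha)`. The concentration parameter `alpha` controls
#' the propensity to create new states; small values encode a simplicity
#' bias toward few states. The default used throughout the simulation
#' protocols is `alpha = 0.1`.
#'
#' @name crp
NULL

check_alpha <- function(alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) || alpha < 0) {
    stop("`alpha` must be a single non-negative number", call. = FALSE)
  }
  invisible(alpha)
}

#' Sequential CRP assignment probabilities
#'
#' Probability that the next observation joins each existing state or opens
#' a new one, given the current partition.
#'
#' @param part a [partition()] (possibly empty) of the observations so far.
#' @param alpha CRP concentration parameter, `alpha >= 0`.
#' @return numeric vector of length `n_states + 1`; entry `k <= n_states`
#'   is the probability of joining state `k`, the last entry is the
#'   probability of a new state. Sums to 1. For the empty partition the
#'   new state is certain, so the result is `1`.
#' @examples
#' crp_next_state_probs(partition(c(1, 1, 2)), alpha = 0.1)
#' @export
crp_next_state_probs <- function(part, alpha = 0.1) {
  check_alpha(alpha)
  part <- as_partition(part)
  if (part$n_obs == 0L) {
    return(1)
  }
  w <- c(part$counts, alpha)
  w / (part$n_obs + alpha)
}

#' Log prior probability of a partition under the CRP
#'
#' Closed form for the probability of a full assignment sequence:
#' `K log(alpha) + sum_k log Gamma(m_k) + log Gamma(alpha) -
#' log Gamma(T + alpha)`. Evaluated entirely in log space via `lgamma`.
#' This equals the product of the sequential assignment probabilities, and
#' sums to one over all partitions of `T` observations.
#'
#' @inheritParams crp_next_state_probs
#' @return log probability (scalar). `alpha = 0` yields 0 for a single-state
#'   partition and `-Inf` for any multi-state partition, so evidence ratios
#'   against degenerate priors remain well-defined.
#' @examples
#' crp_log_prior(partition(c(1, 2, 1)), alpha = 0.1)
#' @export
crp_log_prior <- function(part, alpha = 0.1) {
  check_alpha(alpha)
  part <- as_partition(part)
  if (part$n_obs == 0L) {
    return(0)
  }
  if (alpha == 0) {
    return(if (part$n_states > 1L) -Inf else 0)
  }
  part$n_states * log(alpha) + sum(lgamma(part$counts)) +
    lgamma(alpha) - lgamma(part$n_obs + alpha)
}

#' Sample a partition from the CRP prior
#'
#' Draws a partition of `n_obs` observations by sequentially applying the
#' CRP assignment probabilities.
#'
#' @param n_obs number of observations, `>= 1`.
#' @inheritParams crp_next_state_probs
#' @param seed optional integer; when supplied the draw is reproducible
#'   (the RNG state is restored afterwards).
#' @return a [partition()].
#' @examples
#' crp_sample_partition(20, alpha = 0.5, seed = 1)
#' @export
crp_sample_partition <- function(n_obs, alpha = 0.1, seed = NULL) {
  check_alpha(alpha)
  stopifnot(n_obs >= 1)
  if (!is.null(seed)) {
    return(with_preserved_seed(seed, crp_sample_partition(n_obs, alpha)))
  }
  assign <- integer(n_obs)
  counts <- numeric(0)
  for (t in seq_len(n_obs)) {
    w <- c(counts, alpha)
    if (sum(w) == 0) {
      k <- length(counts) + 1L # alpha = 0: first state persists
      if (t > 1L) k <- 1L
    } else {
      k <- sample.int(length(w), 1L, prob = w)
    }
    if (k > length(counts)) counts <- c(counts, 0)
    counts[k] <- counts[k] + 1
    assign[t] <- k
  }
  partition(assign)
}

#' Expected number of CRP states
#'
#' Exact expectation `alpha * (digamma(n + alpha) - digamma(alpha))` of the
#' number of occupied states after `n` observations, together with the
#' asymptotic approximation `alpha * log(n)` quoted in discussions of the
#' prior's growth rate.
#'
#' @param n number of observations.
#' @inheritParams crp_next_state_probs
#' @return tibble with columns `n`, `alpha`, `expected_states` (exact) and
#'   `asymptotic` (`alpha * log(n)`).
#' @export
crp_expected_states <- function(n, alpha = 0.1) {
  check_alpha(alpha)
  exact <- if (alpha == 0) {
    ifelse(n >= 1, 1, 0)
  } else {
    alpha * (digamma(n + alpha) - digamma(alpha))
  }
  tibble::tibble(
    n = n,
    alpha = alpha,
    expected_states = exact,
    asymptotic = alpha * log(n)
  )
}

# Run expr with a temporary seed, restoring the caller's RNG state.
with_preserved_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
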