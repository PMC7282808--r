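#' Evidence results
#'
#' Every model comparison returns its log odds together with the names of
#' the hypotheses in the numerator and denominator, so the sign convention
#' is always explicit. Swapping numerator and denominator flips the sign.
#'
#' @param log_odds scalar log posterior odds.
#' @param numerator,denominator hypothesis names.
#' @return object of class `"evidence_result"`.
#' @export
evidence_result <- function(log_odds, numerator, denominator) {
  structure(
    list(
      log_odds = as.numeric(log_odds),
      numerator = numerator,
      denominator = denominator
    ),
    class = "evidence_result"
  )
}

#' @export
print.evidence_result <- function(x, ...) {
  cat(
    "<evidence_result> log P(", x$numerator, ") - log P(", x$denominator,
    ") = ", format(x$log_odds, digits = 6), "\n",
    sep = ""
  )
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.evidence_result <- function(x, ...) {
  tibble::tibble(
    numerator = x$numerator,
    denominator = x$denominator,
    log_odds = x$log_odds
  )
}

#' Unnormalized log posterior of a partition
#'
#' Scores a hypothetical assignment of observations to hidden states:
#' the sum of per-state log marginal likelihoods plus the CRP log prior of
#' the partition.
#'
#' @param obs observations (an [obs_set()], matrix or vector).
#' @param part a [partition()] covering exactly the rows of `obs`.
#' @param alpha CRP concentration parameter.
#' @param model a likelihood family ([gaussian_family()] or
#'   [vonmises_family()]).
#' @return scalar unnormalized log posterior.
#' @export
partition_log_posterior <- function(obs, part, alpha = 0.1, model) {
  part <- as_partition(part)
  y <- obs_matrix(obs)
  if (part$n_obs != nrow(y)) {
    stop("partition must cover exactly the observation set", call. = FALSE)
  }
  lik <- sum(vapply(
    seq_len(part$n_states),
    function(k) model$log_marginal(y[part$assignments == k, , drop = FALSE]),
    numeric(1)
  ))
  lik + crp_log_prior(part, alpha)
}

#' Partition evidence ratio
#'
#' Log odds between the posterior probabilities of two partitions of the
#' same observations (the normalizing constant over partitions cancels).
#'
#' @inheritParams partition_log_posterior
#' @param hyp_num,hyp_den the two competing partitions; either bare
#'   partitions/assignment vectors or [hypothesis()] objects.
#' @return an [evidence_result()].
#' @export
partition_evidence_ratio <- function(obs, hyp_num, hyp_den, alpha = 0.1,
                                     model) {
  hn <- as_hypothesis(hyp_num)
  hd <- as_hypothesis(hyp_den)
  lo <- partition_log_posterior(obs, hn$partition, alpha, model) -
    partition_log_posterior(obs, hd$partition, alpha, model)
  evidence_result(lo, hn$name, hd$name)
}

#' Posterior over state assignments of a new observation
#'
#' Given past observations and their (hypothetical) partition, the
#' probability that a new observation belongs to each existing state or to
#' a novel state: posterior predictive density times the sequential CRP
#' probability, normalized over the `K + 1` options.
#'
#' @inheritParams partition_log_posterior
#' @param y_new feature vector of the new observation.
#' @return numeric vector of length `n_states + 1` summing to 1; the last
#'   entry is the novel-state probability.
#' @export
assignment_posterior <- function(y_new, obs, part, alpha = 0.1, model) {
  scores <- assignment_log_scores(y_new, obs, part, alpha, model)
  w <- exp(scores - max(scores))
  w / sum(w)
}

# unnormalized log scores for assigning y_new to each state / novel state
assignment_log_scores <- function(y_new, obs, part, alpha, model) {
  part <- as_partition(part)
  y <- obs_matrix(obs)
  if (part$n_obs != nrow(y)) {
    stop("partition must cover exactly the observation set", call. = FALSE)
  }
  crp <- log(crp_next_state_probs(part, alpha))
  empty <- y[0, , drop = FALSE]
  pred <- c(
    vapply(
      seq_len(part$n_states),
      function(k) {
        model$log_predictive(y_new, y[part$assignments == k, , drop = FALSE])
      },
      numeric(1)
    ),
    model$log_predictive(y_new, empty)
  )
  pred + crp
}

#' State evidence ratio
#'
#' Log odds between two candidate assignments of a single new observation
#' (an existing state index, or `"novel"`), given past observations and
#' their partition. This is the quantity mapped onto degree of remapping:
#' strongly positive for same-state (no remapping), near zero for partial
#' remapping, strongly negative for a new state (global remapping) when
#' the numerator option is the familiar state.
#'
#' @inheritParams assignment_posterior
#' @param option_a,option_b the two assignments to compare: a state index
#'   in `1..n_states` or `"novel"`. Must be distinct.
#' @return an [evidence_result()] with `option_a` in the numerator.
#' @export
state_evidence_ratio <- function(y_new, obs, part, alpha = 0.1, model,
                                 option_a = 1L, option_b = "novel") {
  part <- as_partition(part)
  idx <- function(opt) {
    if (identical(opt, "novel")) {
      return(part$n_states + 1L)
    }
    opt <- as.integer(opt)
    if (opt < 1L || opt > part$n_states) {
      stop("state option out of range", call. = FALSE)
    }
    opt
  }
  ia <- idx(option_a)
  ib <- idx(option_b)
  if (ia == ib) stop("the two options must be distinct", call. = FALSE)
  scores <- assignment_log_scores(y_new, obs, part, alpha, model)
  lab <- function(i) {
    if (i > part$n_states) "novel state" else paste0("state ", i)
  }
  evidence_result(scores[ia] - scores[ib], lab(ia), lab(ib))
}

#' Named hypotheses over partitions and probe assignments
#'
#' A hypothesis is a partition of the training observations, optionally
#' extended by an assignment of a probe observation to one of the
#' partition's states or to a novel state.
#'
#' @param name label used in reported evidence results.
#' @param part partition (or assignment vector) over the training set.
#' @param probe_assignment optional: a state index or `"novel"`.
#' @return object of class `"sm_hypothesis"`.
#' @export
hypothesis <- function(name, part, probe_assignment = NULL) {
  part <- as_partition(part)
  if (!is.null(probe_assignment) && !identical(probe_assignment, "novel")) {
    probe_assignment <- as.integer(probe_assignment)
    if (probe_assignment < 1L || probe_assignment > part$n_states) {
      stop("probe assignment out of range", call. = FALSE)
    }
  }
  structure(
    list(name = name, partition = part, probe_assignment = probe_assignment),
    class = "sm_hypothesis"
  )
}

as_hypothesis <- function(x) {
  if (inherits(x, "sm_hypothesis")) {
    return(x)
  }
  p <- as_partition(x)
  hypothesis(format(p), p)
}

# joint score of training partition + probe assignment: the partition
# posterior of the extended (training + probe) data set
hypothesis_log_score <- function(obs, y_probe, hyp, alpha, model) {
  if (is.null(hyp$probe_assignment)) {
    return(partition_log_posterior(obs, hyp$partition, alpha, model))
  }
  y <- obs_matrix(obs)
  probe_label <- if (identical(hyp$probe_assignment, "novel")) {
    hyp$partition$n_states + 1L
  } else {
    hyp$probe_assignment
  }
  extended <- partition(c(hyp$partition$assignments, probe_label))
  partition_log_posterior(rbind(y, as.numeric(y_probe)), extended, alpha,
    model
  )
}

#' Log odds between two sets of hypotheses
#'
#' Scores every hypothesis jointly over the training partition and the
#' probe assignment, then reports
#' `log sum_S exp(score) - log sum_D exp(score)` computed with
#' log-sum-exp. Used for the morph-environment comparison between the
#' "same state as one extreme" hypotheses and the "different state"
#' hypotheses.
#'
#' @inheritParams partition_log_posterior
#' @param y_probe probe feature vector.
#' @param set_s,set_d non-empty lists of [hypothesis()] objects.
#' @param name_s,name_d labels for the reported evidence result.
#' @return an [evidence_result()].
#' @export
hypothesis_set_log_odds <- function(obs, y_probe, set_s, set_d, alpha = 0.1,
                                    model, name_s = "S", name_d = "D") {
  if (!length(set_s) || !length(set_d)) {
    stop("hypothesis sets must be non-empty", call. = FALSE)
  }
  score <- function(h) hypothesis_log_score(obs, y_probe, h, alpha, model)
  ls <- logsumexp(vapply(set_s, score, numeric(1)))
  ld <- logsumexp(vapply(set_d, score, numeric(1)))
  evidence_result(ls - ld, name_s, name_d)
}
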