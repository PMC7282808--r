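#' Partition of observations into hidden states
#'
#' A partition assigns each of `T` ordered observations to a hidden-state
#' label. Labels are canonicalized to contiguous positive integers in order
#' of first appearance, so two assignment vectors describing the same
#' grouping compare equal regardless of the label strings used.
#'
#' @param assignments vector of state labels (integers, characters or
#'   factors), one per observation, in presentation order. May be empty.
#'
#' @return An object of class `"crp_partition"`: a list with elements
#'   `assignments` (canonical integer labels), `counts` (observations per
#'   state, indexed by label), `n_states` and `n_obs`.
#'
#' @examples
#' partition(c("a", "a", "b", "a"))
#' partition(integer(0))  # the empty partition
#' @export
partition <- function(assignments = integer(0)) {
  if (anyNA(assignments)) {
    stop("partition assignments must not contain NA", call. = FALSE)
  }
  canon <- match(assignments, unique(assignments))
  counts <- if (length(canon)) tabulate(canon) else integer(0)
  structure(
    list(
      assignments = as.integer(canon),
      counts = as.integer(counts),
      n_states = length(counts),
      n_obs = length(canon)
    ),
    class = "crp_partition"
  )
}

#' @export
print.crp_partition <- function(x, ...) {
  cat(
    "<crp_partition> ", x$n_obs, " observations in ", x$n_states,
    " state(s): [", paste(x$assignments, collapse = " "), "]\n",
    sep = ""
  )
  invisible(x)
}

#' @rdname partition
#' @param x object to coerce or test.
#' @export
as_partition <- function(x) {
  if (inherits(x, "crp_partition")) x else partition(x)
}

#' @rdname partition
#' @export
is_partition <- function(x) inherits(x, "crp_partition")

#' @export
format.crp_partition <- function(x, ...) {
  paste0("{", paste(x$assignments, collapse = ","), "}")
}

#' Enumerate all partitions of n observations
#'
#' Generates every set partition of `1..n` as canonical restricted-growth
#' assignment vectors. The number of partitions is the Bell number, so this
#' is only practical for small `n`; it exists to support exhaustive
#' posterior normalization checks and brute-force searches.
#'
#' @param n number of observations (capped at 10).
#' @return list of `crp_partition` objects.
#' @examples
#' length(enumerate_partitions(4))  # Bell(4) = 15
#' @export
enumerate_partitions <- function(n) {
  stopifnot(n >= 1)
  if (n > 10) {
    stop("exhaustive enumeration is restricted to n <= 10", call. = FALSE)
  }
  out <- list()
  recurse <- function(assign, k) {
    t <- length(assign)
    if (t == n) {
      out[[length(out) + 1L]] <<- partition(assign)
      return(invisible(NULL))
    }
    for (lab in seq_len(k + 1L)) {
      recurse(c(assign, lab), max(k, lab))
    }
  }
  recurse(integer(0), 0L)
  out
}

#' @exportS3Method generics::tidy
tidy.crp_partition <- function(x, ...) {
  tibble::tibble(
    state = seq_len(x$n_states),
    count = x$counts
  )
}
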