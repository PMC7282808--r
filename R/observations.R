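#' Observation sets
#'
#' An observation set is an ordered collection of D-dimensional feature
#' vectors, stored as a tibble with one row per observation (presentation
#' order) and one column per feature. Each feature is either `"linear"`
#' (real-valued) or `"circular"` (an angle in degrees, stored in
#' `[0, 360)`); the kinds are carried in the `"feature_kinds"` attribute.
#'
#' @param data matrix or data frame of feature values, rows in
#'   presentation order; a bare vector is treated as a single feature.
#' @param kinds character vector of feature kinds (`"linear"` or
#'   `"circular"`), recycled across features.
#' @return tibble of class `"obs_set"` with a `feature_kinds` attribute.
#' @examples
#' obs_set(c(0.1, -0.2, 0.05))
#' obs_set(cbind(a = c(10, 350), b = c(90, 100)), kinds = "circular")
#' @export
obs_set <- function(data, kinds = "linear") {
  if (is.null(dim(data))) data <- matrix(as.numeric(data), ncol = 1L)
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("observations must be numeric", call. = FALSE)
  d <- ncol(data)
  kinds <- rep_len(match.arg(kinds, c("linear", "circular"), several.ok = TRUE),
    length.out = d
  )
  data[, kinds == "circular"] <- data[, kinds == "circular"] %% 360
  if (is.null(colnames(data))) colnames(data) <- paste0("y", seq_len(d))
  out <- tibble::as_tibble(data)
  attr(out, "feature_kinds") <- kinds
  class(out) <- c("obs_set", class(out))
  out
}

#' @rdname obs_set
#' @param x object to query.
#' @export
feature_kinds <- function(x) {
  k <- attr(x, "feature_kinds")
  if (is.null(k)) rep("linear", ncol(as.matrix(x))) else k
}

#' @export
print.obs_set <- function(x, ...) {
  cat(
    "<obs_set> ", nrow(x), " observations x ", ncol(x), " features (",
    paste(feature_kinds(x), collapse = ", "), ")\n",
    sep = ""
  )
  print(tibble::as_tibble(unclass_obs(x)))
  invisible(x)
}

# strip the obs_set class/attrs, returning a plain numeric matrix
obs_matrix <- function(x) {
  if (is.null(dim(x))) {
    matrix(as.numeric(x), ncol = 1L)
  } else {
    m <- as.matrix(as.data.frame(x))
    storage.mode(m) <- "double"
    m
  }
}

unclass_obs <- function(x) {
  class(x) <- setdiff(class(x), "obs_set")
  attr(x, "feature_kinds") <- NULL
  x
}

# subset rows of an observation container, preserving kinds
obs_rows <- function(x, idx) {
  m <- obs_matrix(x)
  obs_set(m[idx, , drop = FALSE], kinds = feature_kinds(x))
}
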