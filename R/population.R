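#' Map an evidence ratio to Beta population parameters
#'
#' The extent of per-cell rate modulation, `1 - (lower rate)/(higher
#' rate)` in `[0, 1]`, is modelled across the place-field population as a
#' Beta distribution. The shape parameter on the side of the preferred
#' hypothesis equals the magnitude of the evidence ratio plus one and the
#' other parameter is one, so that `ratio = b - a`: a positive ratio
#' (no-remapping preferred) piles mass toward 0, a negative ratio toward 1.
#'
#' @param ratio finite evidence ratio (log odds, no-remap over remap).
#' @return named numeric vector `c(a = , b = )`.
#' @examples
#' evidence_to_beta(6) # c(a = 1, b = 7)
#' evidence_to_beta(-0.5) # c(a = 1.5, b = 1)
#' @export
evidence_to_beta <- function(ratio) {
  stopifnot(is.finite(ratio))
  if (ratio >= 0) c(a = 1, b = ratio + 1) else c(a = abs(ratio) + 1, b = 1)
}

#' Remapping-category fractions under a Beta population profile
#'
#' Splits the Beta distribution of rate-modulation extents at two
#' thresholds: cells below `t_low` are classified as not remapping, cells
#' above `t_high` as completely remapping, and the remainder as rate
#' remapping. Fractions are closed-form regularized incomplete beta
#' values and sum to one.
#'
#' @param a,b Beta shape parameters, `> 0`.
#' @param t_low,t_high classification thresholds, `0 < t_low < t_high < 1`
#'   (defaults 0.15 and 0.85).
#' @return named numeric vector `(no_remap, rate_remap, complete_remap)`.
#' @examples
#' remap_fractions(1.5, 1) # ~ 6% / 72% / 22%
#' @export
remap_fractions <- function(a, b, t_low = 0.15, t_high = 0.85) {
  stopifnot(a > 0, b > 0)
  if (!(t_low > 0 && t_low < t_high && t_high < 1)) {
    stop("thresholds must satisfy 0 < t_low < t_high < 1", call. = FALSE)
  }
  no_remap <- stats::pbeta(t_low, a, b)
  complete <- 1 - stats::pbeta(t_high, a, b)
  c(
    no_remap = no_remap,
    rate_remap = 1 - no_remap - complete,
    complete_remap = complete
  )
}

#' Population remapping profile for an evidence ratio
#'
#' Bundles the Beta mapping, category fractions and population summaries
#' for one evidence ratio: mean rate-modulation extent `a / (a + b)`,
#' heterogeneity (the Beta standard deviation) and uncertainty
#' `exp(-|ratio|)`.
#'
#' @inheritParams evidence_to_beta
#' @inheritParams remap_fractions
#' @return object of class `"remap_profile"`.
#' @examples
#' remap_profile(-0.5)
#' @export
remap_profile <- function(ratio, t_low = 0.15, t_high = 0.85) {
  ab <- evidence_to_beta(ratio)
  a <- ab[["a"]]
  b <- ab[["b"]]
  fr <- remap_fractions(a, b, t_low, t_high)
  structure(
    list(
      ratio = ratio, a = a, b = b, t_low = t_low, t_high = t_high,
      fractions = fr,
      mean_extent = a / (a + b),
      heterogeneity = sqrt(a * b / ((a + b)^2 * (a + b + 1))),
      uncertainty = exp(-abs(ratio))
    ),
    class = "remap_profile"
  )
}

#' @export
print.remap_profile <- function(x, ...) {
  cat(
    "<remap_profile> evidence ratio ", x$ratio, " -> Beta(", x$a, ", ", x$b,
    ")\n", sep = ""
  )
  fr <- round(100 * x$fractions)
  cat(
    " no remap ", fr[1], "% | rate remap ", fr[2], "% | complete remap ",
    fr[3], "%\n",
    sep = ""
  )
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.remap_profile <- function(x, ...) {
  tibble::tibble(
    category = names(x$fractions),
    fraction = unname(x$fractions)
  )
}

#' @exportS3Method generics::glance
glance.remap_profile <- function(x, ...) {
  tibble::tibble(
    ratio = x$ratio, a = x$a, b = x$b,
    mean_extent = x$mean_extent,
    heterogeneity = x$heterogeneity,
    uncertainty = x$uncertainty
  )
}

#' Population summaries across a grid of evidence ratios
#'
#' Evaluates the Beta population profile over a grid of evidence ratios,
#' returning the mean rate-modulation extent, the complete-remap
#' (partial-remapping) fraction, the population heterogeneity (Beta
#' standard deviation) and the uncertainty `exp(-|ratio|)` for each.
#'
#' @param ratio_grid numeric vector of evidence ratios (the default spans
#'   Beta(10, 1) to Beta(1, 10), i.e. ratios -9 to 9).
#' @inheritParams remap_fractions
#' @return tibble with one row per ratio.
#' @examples
#' heterogeneity_curve(seq(-9, 9, by = 3))
#' @export
heterogeneity_curve <- function(ratio_grid = seq(-9, 9, by = 0.5),
                                t_low = 0.15, t_high = 0.85) {
  purrr::map_dfr(ratio_grid, function(r) {
    p <- remap_profile(r, t_low, t_high)
    tibble::tibble(
      ratio = r, a = p$a, b = p$b,
      mean_extent = p$mean_extent,
      no_remap = p$fractions[["no_remap"]],
      rate_remap = p$fractions[["rate_remap"]],
      complete_remap = p$fractions[["complete_remap"]],
      heterogeneity = p$heterogeneity,
      uncertainty = p$uncertainty
    )
  })
}
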