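#' Likelihood families
#'
#' Inference functions are generic over the observation model through a
#' small family object exposing the two quantities hidden-state inference
#' needs: the log marginal likelihood of a set of observations under one
#' state, and the log posterior-predictive density of a new observation
#' given a state's training observations.
#'
#' @param dim feature dimension for the Gaussian family.
#' @param ... hyperparameters forwarded to [niw_hyper()].
#' @return object of class `"obs_model"` with elements `label`, `kind`,
#'   `log_marginal(obs)` and `log_predictive(y, train)`.
#' @examples
#' fam <- gaussian_family(dim = 2)
#' fam$log_marginal(rbind(c(0, 0), c(0.1, -0.1)))
#' @export
gaussian_family <- function(dim = 1L, ...) {
  hyper <- niw_hyper(dim = dim, ...)
  structure(
    list(
      label = "gaussian",
      kind = "linear",
      dim = dim,
      hyper = hyper,
      log_marginal = function(obs) gaussian_log_marginal(hyper, obs),
      log_predictive = function(y, train) {
        gaussian_log_predictive(niw_update(hyper, train), y)
      }
    ),
    class = "obs_model"
  )
}

#' @rdname gaussian_family
#' @param hyper a [vm_hyper()] prior for the Von Mises family.
#' @param grid a [vm_grid()] quadrature grid.
#' @export
vonmises_family <- function(hyper = vm_hyper(), grid = vm_grid()) {
  structure(
    list(
      label = "vonmises",
      kind = "circular",
      hyper = hyper,
      grid = grid,
      log_marginal = function(obs) vonmises_log_marginal(hyper, obs, grid),
      log_predictive = function(y, train) {
        vonmises_log_predictive(hyper, train, y, grid)
      }
    ),
    class = "obs_model"
  )
}

#' @export
print.obs_model <- function(x, ...) {
  cat("<obs_model> ", x$label, " likelihood family\n", sep = "")
  invisible(x)
}
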