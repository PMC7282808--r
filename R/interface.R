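protocol_registry <- function() {
  list(
    cue_constellation = run_cue_constellation,
    alternation_learning = run_alternation_learning,
    direction_foraging = run_direction_foraging,
    cue_rotation = run_cue_rotation,
    morph_test = run_morph_test,
    schedule_hypotheses = run_schedule_hypotheses,
    cue_variability = run_cue_variability
  )
}

protocol_defaults <- function(protocol) {
  fn <- protocol_registry()[[protocol]]
  # defaults are the first `merge_config` argument inside each runner;
  # evaluate the runner's `defaults` expression in the package namespace
  body_ <- body(fn)
  env <- new.env(parent = environment(fn))
  eval(body_[[2]], env) # `defaults <- list(...)`
  get("defaults", envir = env)
}

#' List the registered simulation protocols
#'
#' @return tibble with one row per protocol and its default parameters
#'   (deparsed).
#' @examples
#' list_protocols()
#' @export
list_protocols <- function() {
  names_ <- names(protocol_registry())
  purrr::map_dfr(names_, function(p) {
    defs <- protocol_defaults(p)
    tibble::tibble(
      protocol = p,
      parameter = names(defs),
      default = vapply(
        defs,
        function(v) paste(deparse(v, width.cutoff = 500), collapse = ""),
        character(1)
      )
    )
  })
}

#' Run a simulation protocol by name
#'
#' Dispatches to the registered protocol runner and optionally writes the
#' result table (CSV and JSON) plus a run manifest to `out_dir`. Every
#' protocol is a deterministic function of its configuration and seed.
#'
#' @param protocol protocol name; see [list_protocols()].
#' @param config named list of overrides of the protocol defaults.
#' @param seed integer seed.
#' @param out_dir optional output directory; created if missing.
#' @return the result tibble, invisibly carrying `protocol` and `config`
#'   attributes.
#' @examples
#' run_protocol("cue_constellation", seed = 1)
#' @export
run_protocol <- function(protocol, config = list(), seed = 1,
                         out_dir = NULL) {
  reg <- protocol_registry()
  if (!protocol %in% names(reg)) {
    stop(
      "unknown protocol '", protocol, "'; valid protocols: ",
      paste(names(reg), collapse = ", "),
      call. = FALSE
    )
  }
  result <- reg[[protocol]](config = config, seed = seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_results(result, file.path(out_dir, paste0(protocol, ".csv")))
    write_results(result, file.path(out_dir, paste0(protocol, ".json")),
      format = "json"
    )
    manifest <- list(
      protocol = protocol,
      config = attr(result, "config"),
      seed = seed,
      package_version = as.character(utils::packageVersion("statemap")),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    )
    jsonlite::write_json(
      manifest, file.path(out_dir, paste0(protocol, "_manifest.json")),
      auto_unbox = TRUE, pretty = TRUE, digits = NA
    )
  }
  result
}

#' Write a result table
#'
#' Serializes a protocol result table with a stable column order and
#' floats at 10 significant digits. JSON output mirrors the CSV rows.
#'
#' @param table a result tibble (columns protocol, condition, step,
#'   quantity, value, seed).
#' @param path output file path.
#' @param format `"csv"` or `"json"`.
#' @return the path, invisibly.
#' @export
write_results <- function(table, path, format = c("csv", "json")) {
  format <- match.arg(format)
  cols <- c("protocol", "condition", "step", "quantity", "value", "seed")
  if (!all(cols %in% names(table))) {
    stop("result table is missing required columns", call. = FALSE)
  }
  out <- as.data.frame(table)[, cols, drop = FALSE]
  out$value <- signif(out$value, 10)
  out$step <- ifelse(is.na(out$step), NA, signif(out$step, 10))
  if (format == "csv") {
    utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  } else {
    jsonlite::write_json(out, path, dataframe = "rows", na = "null",
      digits = NA
    )
  }
  invisible(path)
}

#' Read back a result table written by [write_results()]
#'
#' @param path CSV or JSON file produced by [write_results()].
#' @return tibble with the stable result schema.
#' @export
read_results <- function(path) {
  raw <- if (grepl("\\.json$", path)) {
    jsonlite::fromJSON(path)
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  tibble::as_tibble(raw) |>
    dplyr::mutate(
      protocol = as.character(.data$protocol),
      condition = as.character(.data$condition),
      step = as.numeric(.data$step),
      quantity = as.character(.data$quantity),
      value = as.numeric(.data$value),
      seed = as.integer(.data$seed)
    )
}
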