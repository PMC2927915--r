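## Single CSV dialect throughout: comma-separated, '.' decimal, UTF-8,
## header row, units embedded in column names.

OEC_COLUMNS <- c("label", "temperature_C", "pH", "chloride_M", "dpg_ratio",
                 "pco2_mmHg", "po2_mmHg", "saturation")

#' Read and write equilibration tables
#'
#' The on-disk form of a simulated or measured equilibration dataset: one
#' row per step, condition columns repeated, columns `label`,
#' `temperature_C`, `pH`, `chloride_M`, `dpg_ratio`, `pco2_mmHg`,
#' `po2_mmHg`, `saturation`. Round-trips without loss.
#'
#' @param data A tibble in the layout produced by [oec_simulate()].
#' @param path File path.
#' @return `read_oec_csv()` returns the tibble; `write_oec_csv()` returns
#'   `path` invisibly.
#' @export
write_oec_csv <- function(data, path) {
  stopifnot(is.data.frame(data), all(OEC_COLUMNS %in% names(data)))
  readr::write_csv(data[OEC_COLUMNS], path)
  invisible(path)
}

#' @rdname write_oec_csv
#' @export
read_oec_csv <- function(path) {
  readr::read_csv(
    path,
    col_types = readr::cols(
      label = readr::col_character(),
      .default = readr::col_double()
    ),
    progress = FALSE
  )
}

#' Write a Hill fit as JSON
#'
#' Serialises the quantities a report needs (`p50_mmHg`, `n50`, `r2`,
#' `n_points_used`, `window`) at full precision.
#'
#' @param fit A `"hill_fit"` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hill_json <- function(fit, path) {
  stopifnot(inherits(fit, "hill_fit"))
  jsonlite::write_json(
    list(p50_mmHg = fit$p50, n50 = fit$n50, r2 = fit$r2,
         n_points_used = fit$n_points_used, window = fit$window),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a run configuration
#'
#' Configurations are YAML (or JSON, which YAML subsumes) mappings of
#' subcommand parameters. Stochastic subcommands require a `seed` key.
#'
#' @param path Path to a YAML/JSON config file.
#' @return A named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("config file not found: %s", path), class = "oxy_invalid")
  }
  yaml::read_yaml(path)
}
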