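#' Fractional saturation of the Hill binding model
#'
#' `Y = PO2^n / (PO2^n + P50^n)`, the two-parameter sigmoid underlying the
#' Hill plot. Exactly 0.5 at `po2 == p50`.
#'
#' @param po2 Oxygen tension(s) in mmHg, >= 0. Vectorised.
#' @param p50 Half-saturation pressure in mmHg, > 0.
#' @param n Hill cooperativity coefficient, > 0.
#' @return Fractional saturation(s) in \[0, 1\].
#' @examples
#' saturation_at(20, p50 = 10, n = 2) # 0.8
#' @export
saturation_at <- function(po2, p50, n) {
  stopifnot(all(po2 >= 0), p50 > 0, n > 0)
  ## computed on the log scale to stay finite for large po2^n
  r <- (po2 / p50)^n
  r / (1 + r)
}

#' P50 predicted by the log-linear linkage + van't Hoff forward model
#'
#' Composes the heterotropic and thermal responses into a single prediction:
#' \deqn{\log_{10} P_{50} = \log_{10} P_{50}^{ref}
#'   + \phi\,\Delta pH + k_{Cl}\,\Delta\log_{10}[Cl^-]
#'   + \Delta_{DPG} + \frac{\Delta H_{app}}{\ln 10\, R}
#'     \left(\frac1T - \frac1{T_{ref}}\right)}
#' with temperatures in kelvin, `R = 8.314` J/mol/K, and the apparent enthalpy
#' `dH_app = dH_corr + dH_solution`. The DPG term scales linearly with the
#' DPG:Hb4 ratio up to the saturating ratio of 50 and is flat beyond it,
#' measured relative to the reference ratio so that the identity
#' `p50_at_conditions(params, ref) == 10^logp50_ref` always holds.
#'
#' The chloride term is a log-log slope, so it is only defined when chloride
#' is present on both sides (or absent on both, in which case it vanishes);
#' a stripped sample on exactly one side is a contradiction and errors.
#'
#' @param params An [allosteric_params()] object.
#' @param c An [conditions()] object to predict at.
#' @return P50 in mmHg (scalar).
#' @examples
#' ref <- conditions(36, 7.36, chloride = 0.1)
#' p <- allosteric_params(log10(28.8), 2.76, bohr_phi = -0.78, k_cl = 0.23,
#'                        dH_corr = -8.3, ref_conditions = ref)
#' p50_at_conditions(p, ref) # 28.8
#' @export
p50_at_conditions <- function(params, c) {
  stopifnot(inherits(params, "allosteric_params"),
            inherits(c, "oxy_conditions"))
  ref <- params$ref_conditions

  cl_q <- is_stripped_chloride(c$chloride)
  cl_r <- is_stripped_chloride(ref$chloride)
  cl_term <- if (cl_q && cl_r) {
    0
  } else if (cl_q != cl_r) {
    abort("chloride reference mismatch")
  } else {
    params$k_cl * (log10(c$chloride) - log10(ref$chloride))
  }

  dpg_frac <- function(ratio) min(1, ratio / DPG_SATURATING_RATIO)
  dpg_term <- params$dpg_shift *
    (dpg_frac(c$dpg_ratio) - dpg_frac(ref$dpg_ratio))

  dh_app <- (params$dH_corr + params$dH_solution) * 1000 # J/mol
  t_term <- dh_app / (log(10) * GAS_CONSTANT) *
    (1 / (c$temperature + 273.15) - 1 / (ref$temperature + 273.15))

  logp50 <- params$logp50_ref +
    params$bohr_phi * (c$pH - ref$pH) + cl_term + dpg_term + t_term
  10^logp50
}

#' Simulate a noisy oxygen-equilibration dataset
#'
#' Forward-simulates the stepwise tonometry record a diffusion-chamber or
#' Hem-O-Scan run would produce: the Hill model is evaluated at each PO2 of
#' `po2_grid` with the condition-dependent P50 from [p50_at_conditions()],
#' then additive Gaussian noise (absorbance-derived, so on saturation, not on
#' PO2) is applied and clipped to \[0, 1\]. PO2 steps are treated as exact.
#'
#' A single RNG stream is seeded explicitly per call; identical seeds give
#' bit-identical datasets and the caller's RNG state is left untouched.
#'
#' @param params An [allosteric_params()] object (ground truth).
#' @param c An [conditions()] object for this run.
#' @param po2_grid Strictly increasing PO2 values in mmHg (at least 2).
#' @param noise_sd Absolute SD of the saturation noise, in \[0, 0.05\].
#' @param seed Integer seed; required whenever `noise_sd > 0`.
#' @param label Sample label carried into the output.
#' @return A tibble with columns `label`, `temperature_C`, `pH`, `chloride_M`,
#'   `dpg_ratio`, `pco2_mmHg`, `po2_mmHg`, `saturation` (one row per step).
#' @examples
#' ref <- conditions(36, 7.4, chloride = 0.1)
#' p <- allosteric_params(log10(25), 2.8, ref_conditions = ref)
#' oec_simulate(p, ref, po2_grid = seq(5, 60, by = 5), noise_sd = 0.01,
#'              seed = 1)
#' @export
oec_simulate <- function(params, c, po2_grid, noise_sd = 0, seed = NULL,
                         label = "sim") {
  stopifnot(inherits(params, "allosteric_params"),
            inherits(c, "oxy_conditions"))
  if (length(po2_grid) == 0) abort("`po2_grid` must be non-empty.")
  if (length(po2_grid) < 2 || any(diff(po2_grid) <= 0)) {
    abort("`po2_grid` must be strictly increasing with >= 2 steps.")
  }
  if (noise_sd < 0 || noise_sd > 0.05) {
    abort("`noise_sd` must be in [0, 0.05].")
  }
  if (noise_sd > 0 && is.null(seed)) {
    abort("`seed` is required when `noise_sd` > 0.")
  }

  p50 <- p50_at_conditions(params, c)
  y <- saturation_at(po2_grid, p50, params$hill_n)
  if (noise_sd > 0) {
    y <- withr::with_seed(as.integer(seed),
                          y + rnorm(length(y), sd = noise_sd))
    y <- pmin(pmax(y, 0), 1) # clipped steps are kept; the fit window
                             # excludes the extremes anyway
  }
  tibble::tibble(
    label = label,
    temperature_C = c$temperature,
    pH = c$pH,
    chloride_M = c$chloride,
    dpg_ratio = c$dpg_ratio,
    pco2_mmHg = c$pco2,
    po2_mmHg = as.numeric(po2_grid),
    saturation = y
  )
}

#' PO2 grid spanning a saturation window
#'
#' Returns `n_steps` PO2 values whose noise-free saturations are equally
#' spaced across `span` for a Hill curve with the given `p50` and `n` —
#' convenient for placing the required number of equilibration steps inside
#' the 30-70% fitting window.
#'
#' @param p50,n Hill parameters of the target curve.
#' @param n_steps Number of steps (>= 2).
#' @param span Saturation range to cover, default `c(0.25, 0.75)`.
#' @return Strictly increasing numeric vector of PO2 values (mmHg).
#' @export
po2_grid_window <- function(p50, n, n_steps = 10, span = c(0.25, 0.75)) {
  stopifnot(n_steps >= 2, span[1] > 0, span[2] < 1, span[1] < span[2])
  y <- seq(span[1], span[2], length.out = n_steps)
  p50 * (y / (1 - y))^(1 / n)
}

#' Simulate a hematology panel from per-group summaries
#'
#' Draws normal per-animal values for each group of a blood panel and returns
#' both the draws and the recomputed group summaries (mean, SE, n) — the
#' fixture shape needed to exercise Welch comparisons end to end.
#'
#' @param group_specs A data frame with columns `label`, `mean`, `sd`, `n`
#'   (one row per group; `sd >= 0`, `n >= 1`).
#' @param seed Integer seed (mandatory; one RNG stream per call).
#' @return A list with `draws` (tibble: `label`, `value`) and `summary`
#'   (tibble: `label`, `mean`, `se`, `n`).
#' @examples
#' specs <- data.frame(label = c("a", "b"), mean = c(0.45, 7.09),
#'                     sd = c(0.12, 0.35), n = c(4, 3))
#' blood_panel_simulate(specs, seed = 42)
#' @export
blood_panel_simulate <- function(group_specs, seed) {
  stopifnot(is.data.frame(group_specs),
            all(c("label", "mean", "sd", "n") %in% names(group_specs)))
  if (any(group_specs$sd < 0) || any(group_specs$n < 1)) {
    abort("`group_specs` needs sd >= 0 and n >= 1.")
  }
  if (missing(seed) || is.null(seed)) abort("`seed` is mandatory.")

  draws <- withr::with_seed(as.integer(seed), {
    purrr::pmap_dfr(group_specs[c("label", "mean", "sd", "n")],
                    function(label, mean, sd, n) {
                      tibble::tibble(label = label,
                                     value = rnorm(n, mean, sd))
                    })
  })
  summary <- draws |>
    dplyr::group_by(.data$label) |>
    dplyr::summarise(
      mean = mean(.data$value),
      se = if (dplyr::n() > 1) stats::sd(.data$value) / sqrt(dplyr::n()) else 0,
      n = dplyr::n(),
      .groups = "drop"
    )
  list(draws = draws, summary = summary)
}
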