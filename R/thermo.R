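#' Oxygenation enthalpy from the integrated van't Hoff equation
#'
#' The apparent heat of the Hb + O2 reaction is obtained from the temperature
#' dependence of P50: `dH_apparent = R * slope of ln(P50) vs 1/T` (T in
#' kelvin; two-point quotient when only two temperatures are available, OLS
#' otherwise). Because the measured shift includes the heat of dissolving O2
#' in the aqueous phase, the conventional correction
#' `dH_corrected = dH_apparent - dH_solution` (with `dH_solution = -12.5`
#' kJ/mol, i.e. apparent + 12.5) isolates the oxygenation reaction proper.
#'
#' @param data A data frame holding the temperature and P50 columns.
#' @param temperature,p50 Column names for temperature (degrees C) and P50
#'   (mmHg, > 0). At least two distinct temperatures are required.
#' @param dH_solution Solubilization heat in kJ/mol, default -12.5; kept as
#'   an argument for sensitivity analyses.
#' @return A `"thermo_result"` object with fields `dH_apparent`,
#'   `dH_corrected` (kJ per mol O2), `dH_solution`, `temp_coefficient`
#'   (Delta log10 P50 per degree C), `inputs`, and `gas_constant`.
#' @examples
#' vant_hoff_enthalpy(data.frame(temperature_C = c(32, 40),
#'                               p50_mmHg = c(17.3, 26.6)))
#' @export
vant_hoff_enthalpy <- function(data, temperature = "temperature_C",
                               p50 = "p50_mmHg",
                               dH_solution = DH_SOLUTION) {
  t_v <- data[[temperature]]
  p50_v <- data[[p50]]
  stopifnot(length(t_v) >= 2, all(p50_v > 0))
  if (diff(range(t_v)) == 0) abort("degenerate temperature range")
  inv_T <- 1 / (t_v + 273.15)
  slope <- unname(coef(lm(log(p50_v) ~ inv_T))[2])
  dh_app <- GAS_CONSTANT * slope / 1000 # kJ/mol
  structure(
    list(dH_apparent = dh_app,
         dH_corrected = dh_app - dH_solution,
         dH_solution = dH_solution,
         temp_coefficient = temperature_coefficient(data,
                                                    temperature = temperature,
                                                    p50 = p50),
         inputs = tibble::tibble(temperature_C = t_v, p50_mmHg = p50_v),
         gas_constant = GAS_CONSTANT),
    class = "thermo_result"
  )
}

#' @export
print.thermo_result <- function(x, ...) {
  cat(sprintf(
    paste0("<thermo_result> dH apparent = %.3g, corrected = %.3g kJ/mol O2 ",
           "(solution heat %.3g); dlog10 P50/dT = %.3g per degC\n"),
    x$dH_apparent, x$dH_corrected, x$dH_solution, x$temp_coefficient))
  invisible(x)
}

#' Tidy / summarise a van't Hoff result
#'
#' @param x A `"thermo_result"` object.
#' @param ... Unused.
#' @return `tidy()`: one-row tibble with both enthalpies (kJ per mol O2) and
#'   the temperature coefficient; `glance()`: the constants and input size.
#' @method tidy thermo_result
#' @export
tidy.thermo_result <- function(x, ...) {
  tibble::tibble(dH_apparent = x$dH_apparent,
                 dH_corrected = x$dH_corrected,
                 temp_coefficient = x$temp_coefficient)
}

#' @rdname tidy.thermo_result
#' @method glance thermo_result
#' @export
glance.thermo_result <- function(x, ...) {
  tibble::tibble(dH_solution = x$dH_solution,
                 gas_constant = x$gas_constant,
                 n_points = nrow(x$inputs))
}

#' Empirical temperature coefficient of log P50
#'
#' OLS slope of log10 P50 against temperature in degrees Celsius (two-point
#' quotient when n = 2) — the table-style summary of thermal sensitivity
#' reported alongside the van't Hoff enthalpy.
#'
#' @inheritParams vant_hoff_enthalpy
#' @return Delta log10 P50 per degree C (scalar).
#' @examples
#' temperature_coefficient(data.frame(temperature_C = c(32, 40),
#'                                    p50_mmHg = c(25.3, 31.0))) # 0.011
#' @export
temperature_coefficient <- function(data, temperature = "temperature_C",
                                    p50 = "p50_mmHg") {
  t_v <- data[[temperature]]
  p50_v <- data[[p50]]
  stopifnot(length(t_v) >= 2, all(p50_v > 0))
  if (diff(range(t_v)) == 0) abort("degenerate temperature range")
  unname(coef(lm(log10(p50_v) ~ t_v))[2])
}
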