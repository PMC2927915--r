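#' Experimental conditions for an oxygen-equilibration run
#'
#' Bundles the covariates that shift hemoglobin-oxygen affinity: temperature,
#' pH, chloride concentration, the DPG:Hb4 molar ratio, and (optionally) the
#' CO2 tension used to set the pH. A chloride of `NA` (or 0) denotes a
#' "stripped" preparation with no added anion; a `dpg_ratio` of 0 denotes a
#' phosphate-free sample.
#'
#' @param temperature Temperature in degrees Celsius, in (0, 45].
#' @param pH pH of the (oxygenated) sample, in [5.5, 9.5].
#' @param chloride Chloride concentration in mol/L, or `NA` for stripped.
#' @param dpg_ratio DPG:Hb4 molar ratio (0 = stripped; ratios above 50 are
#'   treated as saturating).
#' @param pco2 Optional CO2 tension in mmHg, recorded as an annotation only.
#'
#' @return An object of class `"oxy_conditions"`: a named list of the five
#'   fields above.
#' @examples
#' conditions(temperature = 36, pH = 7.36, chloride = 0.1, dpg_ratio = 0)
#' @export
conditions <- function(temperature, pH, chloride = NA_real_, dpg_ratio = 0,
                       pco2 = NA_real_) {
  stopifnot(is.numeric(temperature), length(temperature) == 1L,
            is.numeric(pH), length(pH) == 1L)
  if (!(temperature > 0 && temperature <= 45)) {
    abort("`temperature` must be in (0, 45] degrees C.")
  }
  if (!(pH >= 5.5 && pH <= 9.5)) {
    abort("`pH` must be in [5.5, 9.5].")
  }
  if (!is.na(chloride) && chloride < 0) {
    abort("`chloride` must be >= 0 mol/L (or NA for stripped).")
  }
  if (is.na(dpg_ratio) || dpg_ratio < 0) {
    abort("`dpg_ratio` must be >= 0.")
  }
  structure(
    list(temperature = as.numeric(temperature), pH = as.numeric(pH),
         chloride = as.numeric(chloride), dpg_ratio = as.numeric(dpg_ratio),
         pco2 = as.numeric(pco2)),
    class = "oxy_conditions"
  )
}

#' @export
print.oxy_conditions <- function(x, ...) {
  cl <- if (is_stripped_chloride(x$chloride)) "stripped" else
    sprintf("%g M", x$chloride)
  cat(sprintf("<oxy_conditions> %g degC, pH %g, Cl- %s, DPG:Hb4 %g%s\n",
              x$temperature, x$pH, cl, x$dpg_ratio,
              if (is.na(x$pco2)) "" else sprintf(", PCO2 %g mmHg", x$pco2)))
  invisible(x)
}

is_stripped_chloride <- function(chloride) {
  is.na(chloride) || chloride == 0
}

#' Ground-truth allosteric parameters for the forward P50 model
#'
#' Describes how the half-saturation pressure of a hemoglobin (or whole-blood)
#' sample responds to pH, chloride, 2,3-DPG and temperature, anchored at a
#' reference condition. The temperature response is parameterised by the
#' *corrected* oxygenation enthalpy (the physically meaningful heat of the
#' Hb + O2 reaction); internally the apparent enthalpy
#' `dH_corr + dH_solution` drives the measurable temperature shift, so the
#' simulator and the van't Hoff estimator are exact inverses.
#'
#' @param logp50_ref log10 of P50 (mmHg) at `ref_conditions`.
#' @param hill_n Hill cooperativity coefficient, in (0.5, 4].
#' @param bohr_phi Bohr factor, Delta log10 P50 / Delta pH (typically negative).
#' @param k_cl Chloride sensitivity, Delta log10 P50 / Delta log10 \[Cl-\].
#' @param dpg_shift Delta log10 P50 between a stripped sample and one at a
#'   saturating DPG:Hb4 ratio (>= 50).
#' @param dH_corr Corrected oxygenation enthalpy in kJ per mol O2 (<= 0 for
#'   normally exothermic oxygenation).
#' @param ref_conditions An [conditions()] object giving the anchor state.
#' @param dH_solution Heat of O2 solubilization in kJ/mol, subtracted from the
#'   apparent enthalpy by convention; default -12.5.
#'
#' @return An object of class `"allosteric_params"`.
#' @examples
#' allosteric_params(
#'   logp50_ref = log10(28.8), hill_n = 2.76, bohr_phi = -0.78,
#'   k_cl = 0.23, dpg_shift = 0.02, dH_corr = -8.3,
#'   ref_conditions = conditions(36, 7.36, chloride = 0.1, dpg_ratio = 0)
#' )
#' @export
allosteric_params <- function(logp50_ref, hill_n, bohr_phi = 0, k_cl = 0,
                              dpg_shift = 0, dH_corr = 0, ref_conditions,
                              dH_solution = DH_SOLUTION) {
  if (!is.finite(logp50_ref)) abort("`logp50_ref` must be finite.")
  if (!(hill_n > 0.5 && hill_n <= 4)) abort("`hill_n` must be in (0.5, 4].")
  if (!inherits(ref_conditions, "oxy_conditions")) {
    abort("`ref_conditions` must be created with conditions().")
  }
  structure(
    list(logp50_ref = logp50_ref, hill_n = hill_n, bohr_phi = bohr_phi,
         k_cl = k_cl, dpg_shift = dpg_shift, dH_corr = dH_corr,
         ref_conditions = ref_conditions, dH_solution = dH_solution),
    class = "allosteric_params"
  )
}

#' @export
print.allosteric_params <- function(x, ...) {
  cat(sprintf(
    paste0("<allosteric_params> P50_ref %.3g mmHg, n %.3g, Bohr %.3g, ",
           "k_Cl %.3g, DPG shift %.3g, dH_corr %.3g kJ/mol\n"),
    10^x$logp50_ref, x$hill_n, x$bohr_phi, x$k_cl, x$dpg_shift, x$dH_corr))
  print(x$ref_conditions)
  invisible(x)
}
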