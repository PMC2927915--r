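new_linkage_coef <- function(kind, value, inputs, driver) {
  structure(
    list(kind = kind, value = value, inputs = inputs,
         n_points = nrow(inputs), driver = driver),
    class = "linkage_coef"
  )
}

#' @export
print.linkage_coef <- function(x, ...) {
  cat(sprintf("<linkage_coef> %s: %.3g (Delta log10 P50 per %s, %d points)\n",
              x$kind, x$value, x$driver, x$n_points))
  invisible(x)
}

#' Tidy a linkage coefficient
#'
#' @param x A `"linkage_coef"` object.
#' @param ... Unused.
#' @return A one-row tibble: `kind`, `value`, `n_points`.
#' @method tidy linkage_coef
#' @export
tidy.linkage_coef <- function(x, ...) {
  tibble::tibble(kind = x$kind, value = x$value, n_points = x$n_points)
}

#' Bohr coefficient from paired (pH, P50) measurements
#'
#' The Bohr factor is the slope of log10 P50 against pH — the canonical
#' measure of oxygen-linked proton binding. With exactly two pairs this is
#' the two-point quotient; with more, ordinary least squares. The CO2 Bohr
#' coefficient — the same slope measured between a high-PCO2 state and a
#' CO2-free state, using the pH of deoxygenated sub-samples — is tagged
#' `kind = "co2_bohr"` but computed identically.
#'
#' @param data A data frame holding the pH and P50 columns.
#' @param ph,p50 Column names (strings) for pH and P50 (mmHg, > 0).
#' @param kind `"bohr"` (default) or `"co2_bohr"`.
#' @return A `"linkage_coef"` object with `value` = Delta log10 P50 / Delta
#'   pH.
#' @examples
#' bohr_coefficient(data.frame(pH = c(7.36, 7.76), p50 = c(28.8, 14.1)),
#'                  ph = "pH", p50 = "p50", kind = "co2_bohr")
#' @export
bohr_coefficient <- function(data, ph = "pH", p50 = "p50_mmHg",
                             kind = c("bohr", "co2_bohr")) {
  kind <- match.arg(kind)
  ph_v <- data[[ph]]
  p50_v <- data[[p50]]
  stopifnot(length(ph_v) >= 2, all(p50_v > 0))
  if (diff(range(ph_v)) == 0) abort("degenerate pH range")
  slope <- unname(coef(lm(log10(p50_v) ~ ph_v))[2])
  new_linkage_coef(kind, slope,
                   tibble::tibble(driver = ph_v, p50_mmHg = p50_v),
                   driver = "pH unit")
}

#' Chloride sensitivity from paired ([Cl-], P50) measurements
#'
#' Slope of log10 P50 against log10 chloride concentration (mol/L), the
#' Wyman linkage coefficient for oxygen-linked chloride binding. Stripped
#' (zero-chloride) baselines cannot enter a log-log slope and error. If the
#' measurements were taken at unequal pH, supply the per-pair pH values and
#' a Bohr factor: each P50 is first adjusted to the mean pH with
#' [ph_correct_p50()].
#'
#' @param data A data frame holding the chloride and P50 columns.
#' @param chloride,p50 Column names for chloride (mol/L, > 0) and P50 (mmHg).
#' @param ph Optional column name of per-pair pH values.
#' @param bohr Optional Bohr factor (a `"linkage_coef"` or a bare slope) used
#'   with `ph` to equalise pH before the slope is taken.
#' @return A `"linkage_coef"` with `kind = "chloride"`.
#' @examples
#' chloride_coefficient(
#'   data.frame(cl = c(0.01, 0.1), p50 = c(10, 10^1.25)),
#'   chloride = "cl", p50 = "p50") # slope 0.25
#' @export
chloride_coefficient <- function(data, chloride = "chloride_M",
                                 p50 = "p50_mmHg", ph = NULL, bohr = NULL) {
  cl_v <- data[[chloride]]
  p50_v <- data[[p50]]
  stopifnot(length(cl_v) >= 2, all(p50_v > 0))
  if (any(is.na(cl_v)) || any(cl_v <= 0)) {
    abort("stripped samples cannot enter a log-log chloride slope: need chloride > 0")
  }
  if (!is.null(ph) && !is.null(bohr)) {
    ph_v <- data[[ph]]
    slope_b <- if (inherits(bohr, "linkage_coef")) bohr$value else bohr
    p50_v <- ph_correct_p50(p50_v, ph_obs = ph_v, ph_target = mean(ph_v),
                            bohr = slope_b)
  }
  slope <- unname(coef(lm(log10(p50_v) ~ log10(cl_v)))[2])
  new_linkage_coef("chloride", slope,
                   tibble::tibble(driver = cl_v, p50_mmHg = p50_v),
                   driver = "log10 [Cl-]")
}

#' DPG effect as a paired log10 P50 difference
#'
#' The organophosphate effect is reported as the shift
#' `log10(P50 with DPG) - log10(P50 without)`, measured at matched pH,
#' temperature and chloride (the caller's responsibility). A value near zero
#' is the DPG-insensitive phenotype.
#'
#' @param p50_without,p50_with P50 (mmHg, > 0) without and with DPG.
#' @return A `"linkage_coef"` with `kind = "dpg"`.
#' @examples
#' dpg_effect(10.05, 18.3) # 0.260
#' @export
dpg_effect <- function(p50_without, p50_with) {
  stopifnot(p50_without > 0, p50_with > 0)
  new_linkage_coef(
    "dpg", log10(p50_with) - log10(p50_without),
    tibble::tibble(driver = c(0, 1), p50_mmHg = c(p50_without, p50_with)),
    driver = "saturating DPG")
}

#' Adjust a P50 to a target pH via the Bohr factor
#'
#' `P50' = 10^(log10 P50 + phi * (pH_target - pH_obs))`, the standard
#' correction used to compare whole-blood affinities measured at unequal in
#' vivo pH. Exactly invertible: correcting back to the observed pH restores
#' the input.
#'
#' @param p50 P50 in mmHg (> 0). Vectorised.
#' @param ph_obs Observed pH.
#' @param ph_target Target pH.
#' @param bohr Bohr factor (a `"linkage_coef"` or a bare slope).
#' @return Corrected P50 in mmHg.
#' @examples
#' ph_correct_p50(17.7, ph_obs = 7.58, ph_target = 7.4, bohr = -0.514) # 21.9
#' @export
ph_correct_p50 <- function(p50, ph_obs, ph_target, bohr) {
  stopifnot(all(p50 > 0))
  slope <- if (inherits(bohr, "linkage_coef")) bohr$value else bohr
  stopifnot(is.finite(slope))
  10^(log10(p50) + slope * (ph_target - ph_obs))
}
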