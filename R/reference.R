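#' Reference whole-blood respiratory measurements for three mole species
#'
#' Published-table-style measurements on freshly drawn whole blood of the
#' eastern mole (*Scalopus aquaticus*), coast mole (*Scapanus orarius*) and
#' star-nosed mole (*Condylura cristata*): pH and P50 at PCO2 = 38 mmHg and
#' in CO2-free gas at 36 degrees C, P50 at 32 and 40 degrees C, and the
#' reported derived quantities (CO2 Bohr coefficient, oxygenation enthalpy,
#' temperature coefficient). The `*_reported` columns are the printed
#' derived values; [reproduce_blood_table()] recomputes them from the
#' measurement columns.
#'
#' @return A tibble, one row per species.
#' @export
mole_blood_reference <- function() {
  tibble::tribble(
    ~species, ~pH_co2, ~p50_co2, ~n50_co2, ~pH_free, ~p50_free, ~n50_free,
    ~p50_32C, ~p50_40C,
    ~co2_bohr_reported, ~dH_reported, ~temp_coeff_reported,
    "eastern",    7.36, 28.8, 2.76, 7.76, 14.1, 2.54, 25.3, 31.0, -0.78,  -8.3, 0.011,
    "coast",      7.58, 17.7, 2.84, 8.48,  6.1, 2.44, 16.9, 19.3, -0.52,  -1.0, 0.008,
    "star-nosed", 7.56, 22.5, 2.76, 8.61,  8.0, 2.86, 17.3, 26.6, -0.40, -29.9, 0.023
  )
}

#' Reference heterotropic-effect coefficients for purified mole hemoglobins
#'
#' Published-table-style summaries for the two major isohemoglobin
#' components of eastern and coast moles at pH 7.2: stripped P50 at 37
#' degrees C, chloride sensitivity (Delta log10 P50 / Delta log10 \[Cl-\]),
#' the DPG shift (Delta log10 P50 on adding 2.5 mM DPG), Bohr factors under
#' several media, and the corrected oxygenation enthalpy in 0.1 M Cl-.
#'
#' @return A tibble, one row per (species, component).
#' @export
mole_hb_reference <- function() {
  tibble::tribble(
    ~species, ~component, ~p50_stripped_37C, ~k_cl, ~dpg_shift,
    ~bohr_25C_cl, ~bohr_37C_stripped, ~bohr_37C_cl, ~bohr_37C_cl_dpg, ~dH,
    "eastern", "Hb I",  13.8, 0.21, 0.02, -0.57, -0.40, -0.51, -0.63, -13.7,
    "eastern", "Hb II", 14.8, 0.25, 0.02, -0.61, -0.41, -0.52, -0.73, -10.3,
    "coast",   "Hb I",   5.3, 0.31, 0.26, -0.55, -0.32, -0.54, -0.86,  -9.7,
    "coast",   "Hb II",  5.1, 0.33, 0.23, -0.62, -0.44, -0.59, -0.78,  -7.6
  )
}

#' Reference hematology panel for eastern and coast moles
#'
#' Published-table-style group summaries (mean, 1 SE, n) of hematological
#' parameters, tissue myoglobin concentrations and muscle buffering
#' capacities. Single-animal entries have `se = NA`. Units follow the
#' conventional panel: hematocrit %, hemoglobin g/dL, RBC 10^6/mm^3, MCV fL,
#' MCH pg, MCHC g/L, 2,3-DPG mM/L RBC, myoglobin mg/g wet tissue, buffering
#' capacity in Slykes.
#'
#' @return A tibble with columns `variable`, `group`, `mean`, `se`, `n`.
#' @export
mole_hematology_reference <- function() {
  tibble::tribble(
    ~variable, ~group, ~mean, ~se, ~n,
    "hematocrit_pct",      "eastern", 56.4,  1.3,  7,
    "hematocrit_pct",      "coast",   46.8,  2.0, 11,
    "hemoglobin_g_dL",     "eastern", 19.2,  0.7,  7,
    "hemoglobin_g_dL",     "coast",   17.4,  0.8, 11,
    "rbc_1e6_mm3",         "eastern", 12.58, 0.32, 3,
    "rbc_1e6_mm3",         "coast",   10.48, NA,   1,
    "mcv_fL",              "eastern", 46.0,  1.3,  3,
    "mcv_fL",              "coast",   42.6,  NA,   1,
    "mch_pg",              "eastern", 15.3,  0.6,  3,
    "mch_pg",              "coast",   13.5,  NA,   1,
    "mchc_gL",             "eastern", 333,   7,    3,
    "mchc_gL",             "coast",   318,   NA,   1,
    "dpg_mM_L_rbc",        "eastern", 0.45,  0.06, 4,
    "dpg_mM_L_rbc",        "coast",   7.09,  0.20, 3,
    "myoglobin_heart",     "eastern", 8.34,  0.38, 6,
    "myoglobin_heart",     "coast",   9.24,  0.28, 7,
    "myoglobin_forelimb",  "eastern", 10.98, 0.64, 6,
    "myoglobin_forelimb",  "coast",   12.10, 0.25, 10,
    "myoglobin_hindlimb",  "eastern", 8.56,  0.21, 6,
    "myoglobin_hindlimb",  "coast",   10.61, 0.56, 10,
    "buffering_forelimb",  "eastern", 43.86, 3.29, 6,
    "buffering_forelimb",  "coast",   37.33, 2.10, 10,
    "buffering_hindlimb",  "eastern", 44.99, 5.54, 6,
    "buffering_hindlimb",  "coast",   38.94, 1.77, 10,
    "plasma_pH",           "eastern", 7.42,  0.01, 6,
    "intraerythrocytic_pH","eastern", 7.21,  0.00, 6,
    "osmolarity_mOsm",     "eastern", 333,   2,    6
  )
}

#' Demo allosteric parameter sets mimicking mole whole blood
#'
#' Forward-model parameter sets anchored at the reference whole-blood
#' measurements of [mole_blood_reference()]: P50 and pH at 36 degrees C and
#' PCO2 = 38 mmHg as the reference state, the CO2 Bohr coefficient as the pH
#' slope, the corrected oxygenation enthalpy driving the temperature
#' response. Chloride and DPG terms are zero: whole blood is measured with
#' its endogenous effectors in place.
#'
#' @return A named list of [allosteric_params()] objects
#'   (`eastern`, `coast`, `star-nosed`).
#' @export
mole_demo_params <- function() {
  ref <- mole_blood_reference()
  out <- purrr::pmap(ref, function(species, pH_co2, p50_co2, n50_co2,
                                   co2_bohr_reported, dH_reported, ...) {
    allosteric_params(
      logp50_ref = log10(p50_co2), hill_n = n50_co2,
      bohr_phi = co2_bohr_reported, dH_corr = dH_reported,
      ref_conditions = conditions(36, pH_co2, pco2 = 38)
    )
  })
  setNames(out, ref$species)
}

#' Recompute the derived whole-blood columns from printed measurements
#'
#' For each species in [mole_blood_reference()] (or a table of the same
#' shape), recomputes from the measurement columns: the CO2 Bohr coefficient
#' (two-point slope between the PCO2 = 38 mmHg and CO2-free states), the
#' temperature coefficient and van't Hoff oxygenation enthalpy from the
#' 32/40 degree C P50s, and the P50 corrected to pH 7.4 with the species'
#' own CO2 Bohr slope.
#'
#' @param blood A table shaped like [mole_blood_reference()]; defaults to it.
#' @return A tibble, one row per species: `species`, `co2_bohr`,
#'   `temp_coefficient`, `dH_corrected`, `p50_pH74`, plus the `*_reported`
#'   columns for side-by-side comparison.
#' @examples
#' reproduce_blood_table()
#' @export
reproduce_blood_table <- function(blood = mole_blood_reference()) {
  blood |>
    dplyr::rowwise() |>
    dplyr::mutate(
      co2_bohr = bohr_coefficient(
        data.frame(pH = c(.data$pH_co2, .data$pH_free),
                   p50_mmHg = c(.data$p50_co2, .data$p50_free)),
        kind = "co2_bohr")$value,
      temp_coefficient = temperature_coefficient(
        data.frame(temperature_C = c(32, 40),
                   p50_mmHg = c(.data$p50_32C, .data$p50_40C))),
      dH_corrected = vant_hoff_enthalpy(
        data.frame(temperature_C = c(32, 40),
                   p50_mmHg = c(.data$p50_32C, .data$p50_40C)))$dH_corrected,
      p50_pH74 = ph_correct_p50(.data$p50_co2, ph_obs = .data$pH_co2,
                                ph_target = 7.4, bohr = .data$co2_bohr)
    ) |>
    dplyr::ungroup() |>
    dplyr::select("species", "co2_bohr", "temp_coefficient", "dH_corrected",
                  "p50_pH74", dplyr::ends_with("_reported"))
}

#' Recompute the derived hematology contrasts
#'
#' Runs [panel_compare()] (eastern vs coast) on a hematology panel and
#' appends the derived red-cell indices computed from the group means.
#'
#' @param panel A panel shaped like [mole_hematology_reference()]; defaults
#'   to it.
#' @return A list with `comparisons` (Welch tests + fold/percent contrasts)
#'   and `indices` (per-group MCV/MCH/MCHC recomputed from mean Hct, Hb,
#'   RBC).
#' @export
reproduce_hematology_table <- function(panel = mole_hematology_reference()) {
  wide <- panel |>
    dplyr::filter(.data$variable %in%
                    c("hematocrit_pct", "hemoglobin_g_dL", "rbc_1e6_mm3")) |>
    tidyr::pivot_wider(id_cols = "group", names_from = "variable",
                       values_from = "mean")
  list(
    comparisons = panel_compare(panel, group1 = "eastern", group2 = "coast"),
    indices = dplyr::bind_cols(
      wide["group"],
      red_cell_indices(wide$hematocrit_pct, wide$hemoglobin_g_dL,
                       wide$rbc_1e6_mm3))
  )
}
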