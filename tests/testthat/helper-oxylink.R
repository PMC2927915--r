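# Shared fixture builders. Parameter sets mirror the reference whole-blood
# measurements (mole_blood_reference()); noise-free datasets are generated
# on window-spanning grids so the 30-70% fit always has enough steps.

eastern_blood_params <- function() {
  allosteric_params(
    logp50_ref = log10(28.8), hill_n = 2.76, bohr_phi = -0.78,
    dH_corr = -8.3,
    ref_conditions = conditions(36, 7.36, pco2 = 38)
  )
}

coast_blood_params <- function() {
  allosteric_params(
    logp50_ref = log10(17.7), hill_n = 2.84, bohr_phi = -0.52,
    dH_corr = -1.0,
    ref_conditions = conditions(36, 7.58, pco2 = 38)
  )
}

# a purified-Hb-like parameter set with all effector terms active
hb_params <- function(k_cl = 0.25, dpg_shift = 0.26) {
  allosteric_params(
    logp50_ref = log10(10), hill_n = 2.8, bohr_phi = -0.55,
    k_cl = k_cl, dpg_shift = dpg_shift, dH_corr = -9.7,
    ref_conditions = conditions(37, 7.2, chloride = 0.1, dpg_ratio = 0)
  )
}

# noise-free dataset at given conditions with n_steps across the window
noise_free_oec <- function(params, c, n_steps = 8, span = c(0.25, 0.75)) {
  p50 <- p50_at_conditions(params, c)
  oec_simulate(params, c, po2_grid_window(p50, params$hill_n, n_steps, span))
}

# P50 estimated through the full pipeline (simulate -> Hill fit)
fit_p50_at <- function(params, c, ...) {
  hill_fit(noise_free_oec(params, c, ...))$p50
}

globin_fixture <- function() {
  system.file("extdata", "synthetic_globins.fasta", package = "oxylink")
}
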