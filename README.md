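# oxylink

Tools for hemoglobin–oxygen equilibrium analysis in comparative blood-gas
physiology: Hill-plot estimation of P50 and cooperativity, heterotropic
linkage coefficients (Bohr, CO2 Bohr, chloride, 2,3-DPG), van't Hoff
oxygenation enthalpies with solubilization correction, pH-corrected
whole-blood affinities, derived red-cell indices with Welch group
comparisons, and a sequence-level audit of beta-type globin chains. It is
aimed at physiologists working with tonometric oxygen-equilibration data —
the running example throughout is the striking affinity divergence between
eastern, coast and star-nosed mole blood.

## The model

A stepwise equilibration run is summarised by the Hill model
`Y = PO2^n / (PO2^n + P50^n)`; in Hill coordinates
(`log10(Y/(1−Y))` vs `log10 PO2`) the slope is the cooperativity
coefficient `n50` and the zero crossing is `log10 P50`. `hill_fit()`
performs the classical interpolation: OLS through at least four steps with
saturations between 30 and 70%.

Effector responses are quantified as log-linear linkage slopes:

| quantity | definition | function |
|---|---|---|
| Bohr factor | Δlog10 P50 / ΔpH | `bohr_coefficient()` |
| chloride sensitivity | Δlog10 P50 / Δlog10 [Cl−] | `chloride_coefficient()` |
| DPG effect | log10 P50(+DPG) − log10 P50(−DPG) | `dpg_effect()` |
| oxygenation enthalpy | R·dln P50/d(1/T), corrected by +12.5 kJ/mol | `vant_hoff_enthalpy()` |
| temperature coefficient | Δlog10 P50 / ΔT (°C) | `temperature_coefficient()` |

A forward allosteric simulator (`p50_at_conditions()`, `oec_simulate()`)
composes these same responses, so every estimator is testable by parameter
recovery; `blood_panel_simulate()` does the same for hematology panels.
See the methods vignette (`vignettes/oxygen-equilibrium-analysis.Rmd`) for
the model, its assumptions and the design decisions.

## Worked example

Recompute the derived whole-blood respiratory quantities from the shipped
reference measurements:

```r
library(oxylink)
reproduce_blood_table()
#> # A tibble: 3 × 8
#>   species    co2_bohr temp_coefficient dH_corrected p50_pH74 co2_bohr_reported dH_reported temp_coeff_reported
#> 1 eastern      -0.775          0.0110        -7.68      26.8             -0.78        -8.3               0.011
#> 2 coast        -0.514          0.00721       -0.687     21.9             -0.52        -1                 0.008
#> 3 star-nosed   -0.428          0.0234       -30.2       26.3             -0.4        -29.9               0.023
```

Each row recomputes, from the printed pH/P50 measurements alone: the CO2
Bohr coefficient (two-point slope between the PCO2 = 38 mmHg and CO2-free
states), the temperature coefficient and van't Hoff enthalpy from the
32/40 °C P50s, and the P50 corrected to pH 7.4. Eastern-mole blood stays
far to the right (low affinity, strong Bohr effect, P50 ≈ 26.8 mmHg at pH
7.4) of coast-mole blood (21.9 mmHg) even after pH correction, while
star-nosed blood is by far the most temperature-sensitive
(ΔH ≈ −30 kJ mol⁻¹ O2).

Simulate a noisy equilibration run and refit it:

```r
p <- allosteric_params(
  logp50_ref = log10(28.8), hill_n = 2.76, bohr_phi = -0.78,
  dH_corr = -8.3, ref_conditions = conditions(36, 7.36, pco2 = 38))
d <- oec_simulate(p, p$ref_conditions, po2_grid_window(28.8, 2.76, 12),
                  noise_sd = 0.01, seed = 1)
tidy(hill_fit(d))
#> # A tibble: 1 × 4
#>   p50_mmHg   n50 intercept slope
#> 1     28.7  2.77     -4.04  2.77
```

The fit recovers the generating P50 (28.8 mmHg) and n50 (2.76) to well
within the noise. `autoplot()` on the fit draws the Hill plot;
`construct_oec()` + `plot_oec()` draw full equilibration curves.

A thin command-line wrapper ships in `inst/cli/oxylink.R` with
subcommands `simulate | fit | linkage | thermo | hematology | seqsites |
reproduce-tables`, each driven by a YAML config and an explicit seed.

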