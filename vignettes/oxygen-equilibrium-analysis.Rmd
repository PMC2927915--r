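---
title: "Hemoglobin-oxygen equilibria and heterotropic linkage with oxylink"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hemoglobin-oxygen equilibria and heterotropic linkage with oxylink}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oxylink)
```

## The measurement and the model

A tonometric oxygen-equilibration experiment exposes a thin layer of
hemoglobin solution (or whole blood) to a stepwise series of oxygen
tensions and records fractional saturation at each step. The classical
summary of such a run is the Hill model,

$$Y = \frac{P O_2^{\,n}}{P O_2^{\,n} + P_{50}^{\,n}},$$

whose two parameters are the half-saturation pressure $P_{50}$ (mmHg; lower
means higher affinity) and the cooperativity coefficient $n_{50}$
(dimensionless, around 2.5-3 for a cooperative tetramer). In Hill
coordinates $\log_{10}(Y/(1-Y))$ versus $\log_{10} PO_2$ the model is a
straight line: the slope is $n_{50}$ and the abscissa of the zero crossing
is $\log_{10} P_{50}$. `hill_fit()` estimates both by ordinary least
squares through the transformed steps, restricted to the saturation window
0.30-0.70 (inclusive bounds), requiring at least four in-window steps — the
standard interpolation protocol for this kind of data. We deliberately use
plain OLS rather than an errors-in-variables scheme: gas-mixing pumps set
$PO_2$ with high precision, so the measurement error lives almost entirely
in the absorbance-derived saturations, and OLS in the transformed space is
deterministic and reproducible. The fit records its diagnostics ($r^2$,
points used, window) so a pathological run is visible.

Affinity is modulated by heterotropic effectors. The package quantifies
each of them exactly as comparative blood-gas studies tabulate them:

* **Bohr factor** $\varphi = \Delta\log_{10} P_{50}/\Delta \mathrm{pH}$
  (`bohr_coefficient()`); a CO2 Bohr factor is the same slope measured
  between a hypercapnic and a CO2-free state, using the pH of deoxygenated
  sub-samples, and is tagged `co2_bohr`.
* **Chloride sensitivity** $\Delta\log_{10} P_{50}/\Delta\log_{10}[Cl^-]$
  (`chloride_coefficient()`), a Wyman linkage slope. A stripped
  (zero-chloride) sample has no finite $\log[Cl^-]$, so such baselines are
  rejected rather than approximated with a pseudo-count. If the paired
  measurements sit at unequal pH, the caller may supply per-pair pH values
  and a Bohr factor; each $P_{50}$ is then adjusted to the mean pH first.
* **DPG effect** (`dpg_effect()`), the paired difference
  $\log_{10} P_{50}^{+DPG} - \log_{10} P_{50}^{-DPG}$ at matched pH,
  temperature and chloride — a difference, not a regression, because the
  assay design is paired.
* **Temperature**: the apparent oxygenation enthalpy comes from the
  integrated van't Hoff relation, $\Delta H_{app} = R\,\mathrm{d}\ln
  P_{50}/\mathrm{d}(1/T)$ (`vant_hoff_enthalpy()`), and is corrected for
  the heat of O2 solubilization, $\Delta H = \Delta H_{app} + 12.5$ kJ
  mol$^{-1}$ O2 (the solution heat is $-12.5$; the constant lives in one
  argument, `dH_solution`, so its influence can be probed). The empirical
  companion $\Delta\log_{10} P_{50}/\Delta T$ in $^\circ$C
  (`temperature_coefficient()`) is reported side by side, as the field's
  tables do.

`ph_correct_p50()` moves a whole-blood $P_{50}$ from its in vivo pH to a
common target (typically 7.4) with a species' own Bohr slope; the
correction is exactly invertible.

## The forward simulator

Because raw tonometry traces for the mole study system are not published,
every estimator in the package is validated against a forward allosteric
model (`p50_at_conditions()`):

$$\log_{10} P_{50} = \log_{10} P_{50}^{ref}
 + \varphi\,\Delta\mathrm{pH}
 + k_{Cl}\,\Delta\log_{10}[Cl^-]
 + \delta_{DPG}
 + \frac{\Delta H_{app}}{\ln 10\,R}\Big(\frac{1}{T}-\frac{1}{T_{ref}}\Big)$$

with $T$ in kelvin and $R = 8.314$ J mol$^{-1}$ K$^{-1}$. Design choices
worth stating:

* **DPG dose-response.** The studies this package serves report only a
  "saturating" DPG condition (DPG:Hb4 ratio above ~50). We model the shift
  as linear in the ratio up to 50 and flat beyond — the simplest monotone
  form consistent with that usage. The term is computed relative to the
  reference ratio, so the model is the identity at its own reference state
  even when that reference is DPG-loaded.
* **Temperature scaling uses the apparent enthalpy** ($\Delta H_{corr} -
  12.5$), so the simulator and `vant_hoff_enthalpy()` are exact inverses
  by construction: a noise-free round trip recovers `dH_corr` to machine
  precision. This is a deliberate self-consistency, not an independent
  validation of the enthalpy itself; the independent check is the
  closed-form hand evaluation frozen in the tests.
* **Noise model.** Additive Gaussian noise on saturation (absorbance is
  the noisy channel), none on $PO_2$ (precision gas mixing), clipped to
  $[0,1]$ afterwards; clipped steps are kept because the fitting window
  excludes the extremes anyway. One RNG stream per call, seeded
  explicitly; the caller's RNG state is untouched.
* **Chloride bookkeeping.** `NA` or 0 chloride means "stripped". A
  stripped state on exactly one side of a prediction is a contradiction
  (the log-log term is undefined) and errors; stripped on both sides makes
  the term vanish.

What the generator emulates is the *shape* of an equilibration series and
the log-linear response of $P_{50}$ to effectors; what it does not emulate
includes methemoglobin formation, time-dependent drift, pH change during a
run, Adair-level curve asymmetry, and correlated residuals. Passing
recovery tests therefore demonstrates that the estimators are correct
inverses of the stated model at realistic noise, not that real tonometry
data are this well behaved.

## Numerical and protocol choices

* Temperatures convert as $T_K = T_{^\circ C} + 273.15$ throughout.
* With more than two temperatures, the enthalpy is OLS on $\ln P_{50}$
  versus $1/T$; with exactly two it reduces to the two-point quotient.
  Recomputing a published enthalpy from table values rounded to 0.1 mmHg
  can differ from the printed number by a few tenths of a kJ (for one
  whole-blood case, about 0.6 kJ on $-8.3$); the tests treat a $\pm 0.7$
  kJ band as the reconciliation tolerance for rounded-input recomputation,
  while simulator round trips are exact.
* Curve construction (`construct_oec()`) through measured points uses a
  monotone piecewise-linear interpolant in Hill coordinates with linear
  extrapolation of the terminal segments. The classical reference for
  curve construction is cited in the literature by name only, without a
  reproducible recipe, so this interpolant is a documented stand-in chosen
  for monotonicity, boundedness in $(0,1)$, and exact interpolation — not
  a claim about the original procedure.
* Hill-plot precision depends strongly on how many steps fall inside the
  30-70% window. At saturation noise SD 0.01, a 12-step protocol spanning
  saturations 0.25-0.75 (8-10 in-window steps) recovers $P_{50}$ within
  3% essentially always, but recovers $n_{50}$ within 5% in only ~86-91%
  of runs; a 16-step protocol concentrated inside the window reaches ~95%
  for both. The recovery studies in the tests and the acceptance script
  use the 12-step design for $P_{50}$ and the 16-step window-dense design
  for $n_{50}$, and this sensitivity is a property of the slope estimator
  worth knowing when planning real experiments: the slope needs leverage
  *within* the window, which extreme steps do not provide.
* Simulation sizes: 500 seeds for recovery studies, 2000 for the Welch
  type-I calibration — enough for the binomial SE on a 5% rate to be
  about 0.5%.

## Hematology and sequence audit

`welch_t()` implements the unequal-variance t comparison directly from
summary statistics (mean, SE, n) — the only form possible when the input
is a published table; it is cross-checked in the tests against
`stats::t.test()` on reconstructed samples. Standard errors are the
primary inputs; SDs are derived as $se\sqrt{n}$ only when draws must be
simulated. Two-sided p-values, no multiple-testing correction (matching
the practice of the tables this mirrors). `red_cell_indices()` computes
MCV $= 10\,Hct/RBC$, MCH $= 10\,Hb/RBC$ and MCHC $= 1000\,Hb/Hct$ in the
conventional units (fL, pg, g/L). Note that indices computed from *group
mean* inputs need not equal a table's per-animal-averaged indices.

The sequence module audits beta-type (delta) globin chains in mature-chain
numbering (initiator Met removed, position 1 = N-terminal Val):
`list_substitutions()` reports differing aligned columns with a charge
classification at pH 7 ({D,E} negative, {K,R} positive, His counted
neutral — its context-dependent pKa is noted, not modelled), and
`dpg_site_audit()` checks the canonical cationic DPG pocket (1 Val, 2 His,
82 Lys, 143 His). The shipped fixture is synthetic: a canonical human
beta chain and a variant carrying L3M and the charge-introducing G136E —
enough to exercise the audit logic that matters scientifically: a chain
can conserve every known phosphate-binding site yet carry a central-cavity
acid substitution that abolishes DPG sensitivity by another route.

## A worked whole-blood example

```{r example}
blood <- reproduce_blood_table()
blood
```

The recomputed CO2 Bohr coefficients, temperature coefficients and
enthalpies sit next to their reported counterparts; discrepancies at the
last digit trace to the inputs being rounded to 0.1 mmHg. The eastern-mole
blood corrected to pH 7.4 remains markedly lower-affinity than coast-mole
blood — the central physiological contrast this toolchain is built to
quantify.

```{r recovery}
p <- allosteric_params(
  logp50_ref = log10(28.8), hill_n = 2.76, bohr_phi = -0.78,
  dH_corr = -8.3, ref_conditions = conditions(36, 7.36, pco2 = 38))
d <- oec_simulate(p, p$ref_conditions, po2_grid_window(28.8, 2.76, 12),
                  noise_sd = 0.01, seed = 1)
tidy(hill_fit(d))
```

## Limitations

No MWC two-state or Adair four-constant analysis (the package targets
Hill-level summaries), no binding kinetics, no methemoglobin correction,
no proton-release stoichiometry or carbamate chemistry, and no sequence
alignment (inputs must be pre-aligned or equal length). Buffering-capacity
and myoglobin assay values pass through as data; their assay math is out
of scope.
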