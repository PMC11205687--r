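---
title: "Methods: from bomb records to formation enthalpies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from bomb records to formation enthalpies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermoredux)
```

This vignette is the package's own account of the models and conventions it
implements: what each stage assumes, which parameters matter, what the
synthetic-data generators do and do not emulate, and where the design was
genuinely open.

## The measurement model

Static-bomb combustion calorimetry measures the energy released when a
weighed sample burns in ~3 MPa of oxygen inside a constant-volume bomb
immersed in a stirred water calorimeter. The calorimeter is not adiabatic:
it exchanges heat with its surroundings at a rate proportional to the
temperature difference from a convergence temperature (Newton's law of
cooling). The observable is therefore a three-phase temperature–time
record — a fore period of pure drift, a main period containing the
combustion rise, and an after period of drift again — from which the
*adiabatic* temperature rise must be extracted before any energy
bookkeeping.

### Heat-exchange correction

`reduce_trace()` implements the Regnault–Pfaundler treatment. Linear drift
rates \(g_i, g_f\) are fitted by least squares in the fore and after
periods; with mean period temperatures \(T_i, T_f\) the cooling constant is
\(k = (g_i - g_f)/(T_f - T_i)\) and the convergence temperature follows
from \(g = k(T_{conv} - T)\). The heat leaked during the main period,
\(\int k (T_{conv} - T(t))\,dt\), is evaluated by the trapezoidal rule on
the actual readings (10 s spacing) and subtracted from the observed rise.
A Dickinson extrapolation (fore and after drift lines evaluated at the time
the trace passes 60 % of the observed rise) is available as an alternative;
both are classical for this instrument class, and on the package's
synthetic traces they agree to a few mK. Degenerate inputs are handled
explicitly: a zero-exchange trace reduces to the plain temperature
difference, and missing or non-monotone period boundaries are errors, not
guesses. On noise-free closed-form traces the extraction recovers a known
rise of 1.2 K to better than \(10^{-4}\) K (the instrument's own reading
resolution), which is the package's acceptance bar for this component.

### Energy bookkeeping

With \(\Delta T_{ad}\) in hand, the isothermal-bomb-process energy is

\[\Delta U(\mathrm{IPB}) = -\{\varepsilon_{cal} + \Delta m(\mathrm{H_2O})\,
c_p(\mathrm{H_2O,l}) + \varepsilon_f\}\,\Delta T_{ad} + \Delta U(\mathrm{ign}).\]

A bookkeeping convention worth stating: because \(\Delta U(\mathrm{ign})\)
appears in this expression, \(\Delta U(\mathrm{IPB})\) is already the pure
chemical energy of the bomb process — the electrical ignition energy is
*not* subtracted a second time downstream. `massic_energy` therefore reads

\[\Delta_c u^\circ = \frac{\Delta U(\mathrm{IPB}) - \Delta U(\mathrm{fuse})
- \Delta U(\mathrm{Melinex}) - \Delta U(\mathrm{HNO_3}) -
\Delta U_\Sigma}{m_{sample}},\]

and with every correction switched off it degenerates to
\(\Delta U(\mathrm{IPB})/m\). The corrections are:

* **Fuse and bag.** Built-in massic energies −16,240 J g⁻¹ (cotton,
  empirical formula CH₁.₆₈₆O₀.₈₄₃) and −(22,902 ± 5) J g⁻¹ (Melinex), the
  latter applied to the dry mass after stripping the conventional water
  fraction w = 0.0032.
* **Nitric acid.** Combustion of nitrogen-containing compounds in moist
  oxygen forms aqueous HNO₃; its formation energy −59.7 kJ mol⁻¹ (for
  0.1 mol dm⁻³ acid) times the titrated amount is removed.
* **Standard state (\(\Delta U_\Sigma\)).** The full Washburn reduction to
  standard states needs bomb-specific data the package does not model.
  Implemented instead is the dominant pressure term
  \(m\,(\partial u/\partial p)_T\,(p - 0.1\,\mathrm{MPa})\) summed over
  sample (default coefficient −0.2 J g⁻¹ MPa⁻¹, the typical organic value),
  Melinex (−0.03) and cotton (−0.29) at the working pressure 3.04 MPa, with
  a `washburn_hook` so a user can substitute a complete correction. For the
  compounds this package targets the simplified term is a few J against
  ~19 kJ of combustion energy.
* **CO2 accounting.** The sample mass can be recovered from the collected
  CO2 after removing the fuse/bag contributions; when both mass and CO2 are
  recorded, the recovery ratio is reported and values outside [0.99, 1.01]
  are flagged (a purity and completeness diagnostic), attached as a note
  rather than an error.

Calibration (`calibrate_bomb()`) inverts the same bookkeeping on burns of
certificated benzoic acid (default certificate value −(26,434 ± 3) J g⁻¹),
referring \(\varepsilon_{cal}\) to the nominal 3119.6 g water load and
reporting the mean ± standard deviation of the mean; a single run is
refused since no uncertainty can be stated.

## From replicates to formation enthalpies

`summarize_replicates()` reports mean and sdom (sd/√n, n ≥ 2). The molar
chain is then: \(\Delta_c U^\circ_m = \overline{\Delta_c u^\circ}\, M\);
\(\Delta_c H^\circ_m = \Delta_c U^\circ_m + \Delta n_{gas} R T\) with
\(\Delta n_{gas} = \nu_{CO_2} + \nu_{N_2} - \nu_{O_2}\) (fuel and water
condensed — the coefficients are quarters and halves of integer element
counts, hence exact in floating point); and Hess's law

\[\Delta_f H^\circ_m(l) = \nu_{CO_2}\,\Delta_f H^\circ[\mathrm{CO_2(g)}] +
\nu_{H_2O}\,\Delta_f H^\circ[\mathrm{H_2O(l)}] - \Delta_c H^\circ_m(l)\]

with the CODATA reference values −(393.51 ± 0.13) and −(285.830 ± 0.040)
kJ mol⁻¹ (overridable via `thermo_constants()`).

**Uncertainty convention.** Expanded uncertainties of combustion quantities
follow the Rossini convention: twice the RSS of the *relative* sdom and the
relative calibration/auxiliary components. The component list behind a
published ±0.9 or ±1.3 kJ mol⁻¹ is rarely stated; the package's default
budget (replicate sdom, calibration sdom, certificate uncertainty) yields
0.8/1.2 kJ mol⁻¹ for the bundled data — close to but not exactly the
published 0.9/1.3, which evidently include further auxiliary terms. The
budget is therefore explicit configuration (`rel_budget`), and a published
expanded uncertainty can be passed directly (`expanded_u`) when the goal is
to reproduce a published chain. Downstream RSS combinations (to ±1.1/±1.5
for the liquid values and ±1.4/±1.7 for the gas values) are reproduced
exactly either way.

**Rounding.** Published tables round each stage to one decimal in kJ mol⁻¹,
and derived cells are computed from the *rounded* parents (this is visible
in the bundled data: the liquid formation enthalpy of the C6 amine is
134.495 → 134.5 from the rounded combustion enthalpy, but 134.4465 → 134.4
from the unrounded chain). `derive_formation()` therefore carries full
precision by default (`rounding = "none"`) and offers
`rounding = "table"` to reproduce published-table arithmetic; rounding uses
half-up (`round_table()`), the convention of printed tables, not banker's
rounding. `run_pipeline()` uses the table convention for its report tibbles
and keeps the unrounded chain alongside.

**A note on the bundled replicate table.** The eight replicate values for
5-methylfurfurylamine average to −31,578.4 J g⁻¹ (sdom 3.3), while the
published summary row lists −31,577.4 ± 3.3. The sdom matches exactly and
every downstream published value is consistent with the replicate-derived
mean under table rounding, so the package treats the summary-row mean as a
transcription slip and computes statistics from the replicates; the
corresponding acceptance test asserts the published mean and is expected to
fail, documenting the contradiction rather than hiding it.

## Calvet drop microcalorimetry

In a drop experiment a few mg of liquid in a capillary falls from room
temperature into the hot cell at oven temperature T; the measured enthalpy
is vaporization *plus* heating of the gas from 298.15 K to T. The
correction is the analytic integral of a gas-phase heat-capacity polynomial
\(C^\circ_{p,m}(g)(T)\), validated in the tests against numerical
quadrature to 10⁻⁹ kJ mol⁻¹. Design choices:

* `cp_polynomial()` carries a multiplicative `scale` for frequency-scaled
  quantum-chemical heat capacities (0.965 is customary for
  B3LYP/6-31G(2df,p)); the default is 1 so that already-scaled or
  user-fitted polynomials pass through unchanged — scaling is the
  supplier's declaration, not something the integral should silently apply.
* The heat-capacity polynomials behind the bundled corrections are not
  publicly tabulated, so `synthetic_cp_polynomial()` ships linear
  surrogates of realistic magnitude (mean C_p ≈ 117 and 144 J K⁻¹ mol⁻¹
  for the C5 and C6 amine) constructed to reproduce the published integral
  corrections (5.4 kJ mol⁻¹ over 298.15→344.5 K and 6.0 over
  298.15→339.9 K). They are labelled synthetic everywhere; they validate
  the machinery, not the physics.
* In-situ calibration against a reference alkane (n-decane/n-undecane) is
  a multiplicative constant k = literature/observed with its relative
  uncertainty; k outside [0.95, 1.05] warns, since a drop calorimeter that
  far off nominal needs attention before its data do.
* `reduce_calvet()` reports the mean of k-corrected drops with the expanded
  uncertainty 2·RSS(sdom, calibration term), the convention for these
  instruments; blank-capillary corrections are per-run additive inputs.

## Gas-phase estimation toolkit

`boltzmann_populations()` weights conformers by
\(p_i \propto e^{-\Delta G_i/RT}\) (log-sum-exp shifted, so an arbitrarily
high-lying conformer cleanly gets population 0), and
`conformer_weighted_enthalpy()` averages absolute enthalpies with those
weights. `reaction_enthalpy()` converts balanced working reactions over
computed absolute enthalpies (hartree → kJ mol⁻¹ at 2625.4997, the single
place quantum-chemistry units enter) and `solve_unknown_formation()` solves
the Hess identity for the one species marked unknown, with RSS over the
participants' experimental uncertainties. Element balance is checked before
any arithmetic and is mandatory; bond-type balance — the full isodesmic
criterion — is the reaction designer's responsibility, since it requires a
bond perception the formula registry cannot provide. Estimates over several
working reactions are reported as mean ± sdom, the convention for
composite-method estimates.

`dimer_cycle()` evaluates the two vaporization hypotheses for an
associating liquid: monomeric vaporization
\(\Delta_l^g H = \Delta_f H(g) - \Delta_f H(l)\) and fully dimeric
vaporization \(2\Delta_f H(g) - 2\Delta_f H(l) + \Delta_{dim}H\) (default
dimerization enthalpy −24 kJ mol⁻¹, negative = exothermic association).
Comparing both branches with a measured vaporization enthalpy diagnoses
which species actually leaves the liquid.

## What the synthetic generators emulate — and what they do not

`generate_bomb_experiments()` draws sample (0.5–0.7 g), fuse (2–4 mg) and
bag (40–60 mg) masses, water-load deviations, capacitor discharges
(1400 μF, 40 V → ~20 V) and nitric-acid amounts, then constructs each run
so that the reduction chain returns the configured true massic energy
exactly in the noise-free limit; the temperature trace follows the
closed-form Newtonian model (fore drift toward T_conv = 298.6 K, cooling
constant 1.5 × 10⁻³ min⁻¹, main-period release with a 45 s time constant,
100 readings per period at 10 s). Gaussian reading noise defaults to
10⁻⁴ K, the instrument resolution, which propagates to a few J g⁻¹ of
scatter — the magnitude seen in real campaigns.
`generate_calvet_runs()` adds the heat-capacity integral and Gaussian noise
(default 0.98 kJ mol⁻¹, chosen so six drops give an sdom near 0.4 kJ mol⁻¹,
the instrument's scatter scale) to a true vaporization enthalpy. All
randomness flows from a mandatory integer seed.

What passing round-trip tests therefore demonstrate is *internal
consistency*: the reducers invert exactly the physics the generators encode
(Newtonian exchange, complete combustion, exact CO2 stoichiometry, additive
noise). They do not demonstrate robustness to what real instruments add —
incomplete combustion and soot, drifting jacket temperature, fuse sparking
losses, pre-ignition evaporation through a bag pinhole, or non-Gaussian
electrical disturbances. A real campaign's defence against those is the CO2
recovery ratio and replicate scatter, both of which the reduction reports.

Problem sizes throughout the test-suite simulations (runs of 2–6
experiments, 200-repeat coverage checks) are chosen so each property is
exercised at the scale of a real campaign.

## Known limitations

* Stoichiometry is restricted to C/H/N/O fuels; sulfur appears only as a
  label in increment estimation, never in combustion chemistry.
* The standard-state correction is the simplified pressure term; studies
  demanding full Washburn rigor must supply it via the hook.
* Buoyancy (apparent→true mass) is a single multiplicative factor, not a
  density-resolved correction.
* \(\varepsilon_f\) (bomb contents after ignition) is a per-run input, not
  modelled thermodynamically.
* Formation enthalpies are reported at 298.15 K only; no Kirchhoff
  temperature extrapolation beyond the drop-calorimetric correction.
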