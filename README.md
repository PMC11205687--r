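# thermoredux

Data reduction for classical combustion and drop-calorimetric
thermochemistry: from raw static-bomb combustion records and Calvet
high-temperature drop runs to standard (p° = 0.1 MPa) molar enthalpies of
formation in the liquid and gas phases at T = 298.15 K.

The package is written for experimental thermochemists and for anyone who
needs to audit or reproduce a combustion-calorimetry study: every stage of
the chain is an exported, tested function with its uncertainty budget
visible, and synthetic-data generators emulate both instruments so the whole
chain can be validated end to end without access to a calorimeter.

## The reduction chain

A static-bomb combustion experiment on a liquid CaHbNcOd compound realises
the idealized reaction

    CaHbNcOd (l) + (a + b/4 − d/2) O2 (g) → a CO2 (g) + (b/2) H2O (l) + (c/2) N2 (g)

The chain implemented here is:

1. **Adiabatic temperature rise.** The fore/main/after temperature–time
   record is reduced by the Regnault–Pfaundler heat-exchange correction
   (Dickinson extrapolation available): ΔT_ad = ΔT_obs − ∫ k (T_conv − T) dt.
2. **Isothermal bomb process energy.**
   ΔU(IPB) = −{ε_cal + Δm(H2O)·c_p(H2O,l) + ε_f}·ΔT_ad + ΔU(ign),
   with the ignition energy ΔU(ign) = ½C(V₁² − V₂²) from the capacitor
   discharge and ε_cal from benzoic-acid calibration (`calibrate_bomb()`).
3. **Standard massic energy of combustion.** Fuse, Melinex-bag, nitric-acid
   (−59.7 kJ·mol⁻¹) and simplified standard-state (pressure-coefficient)
   corrections are removed and the residual energy divided by the sample
   mass, itself optionally recovered from the collected CO2.
4. **Molar quantities.** Δ_c U°_m = mean massic energy × M;
   Δ_c H°_m = Δ_c U°_m + Δn(gas)·R·T; Hess's law with the CODATA values
   Δ_f H°[CO2(g)] = −(393.51 ± 0.13) and Δ_f H°[H2O(l)] =
   −(285.830 ± 0.040) kJ·mol⁻¹ gives Δ_f H°_m(l). Uncertainties follow the
   thermochemical convention: twice the overall standard deviation of the
   mean including calibration and auxiliary contributions, combined
   root-sum-square (RSS).
5. **Vaporization.** Calvet drop measurements at oven temperature T are
   referred to 298.15 K by Δ_l^g H°_m(298.15 K) = Δ H_obs − ∫ C°_p,m(g) dT,
   with the heat-capacity integral evaluated analytically from a
   polynomial C_p(T).
6. **Gas phase.** Δ_f H°_m(g) = Δ_f H°_m(l) + Δ_l^g H°_m (RSS), plus an
   estimation toolkit: Boltzmann conformer weighting, isodesmic-reaction
   solving from computed absolute enthalpies, substitution increments, and
   a monomer/dimer vaporization thermochemical cycle.

## Worked example

The package ships the replicate massic combustion energies of
furfurylamine (C5H7NO, six burns). The full chain, using the published
expanded uncertainty of 0.9 kJ·mol⁻¹ for the molar combustion energy and a
drop-calorimetric vaporization enthalpy of (49.1 ± 0.8) kJ·mol⁻¹:

```r
library(thermoredux)
ch <- derive_formation(combustion_replicates("furfurylamine"),
                       fuel = "C5H7NO", expanded_u = 0.9,
                       vaporization = qty(49.1, 0.8, "kJ/mol"))
ch
#> <thermo_chain> C5H7NO
#>   massic energy       -29588.1 ± 2.0 J/g (n = 6)
#>   dcU(l)               -2873.5 ± 0.9 kJ/mol
#>   dcH(l)               -2875.4 ± 0.9 kJ/mol
#>   dfH(l)                 -92.6 ± 1.1 kJ/mol
#>   dvapH                   49.1 ± 0.8 kJ/mol
#>   dfH(g)                 -43.5 ± 1.4 kJ/mol
```

Reading the chain: the six burns average −29,588.1 J·g⁻¹ with a standard
deviation of the mean of 2.0; multiplied by the molar mass (97.117 g·mol⁻¹)
this is the molar combustion energy −2873.5 kJ·mol⁻¹; the gas-mole work term
Δn·R·T with Δn = −0.75 gives the combustion enthalpy −2875.4; Hess's law
with the CO2/H2O reference values gives the liquid formation enthalpy
−(92.6 ± 1.1); adding the vaporization enthalpy gives the gas-phase value
−(43.5 ± 1.4) kJ·mol⁻¹. `tidy(ch)` returns the same chain as a tibble with
full-precision and table-rounded columns, and `autoplot(ch)` draws the
enthalpy ladder. `run_pipeline()` produces the complete set of report
tables for both bundled compounds.

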