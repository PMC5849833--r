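# neutronvault

Neutron shielding assessment for single-room (in-room cyclotron) proton
therapy vaults.

In passive-scattering proton therapy, contamination neutrons from the
accelerator, the field-shaping nozzle and the patient dominate the
radiation-protection problem. A compact unit mounts the cyclotron on the
gantry inside the treatment room, so all three neutron sources sit in the
vault itself and the shielding must be assessed against all of them at
every gantry angle. `neutronvault` is aimed at medical physicists and
shielding designers who need that assessment as reproducible code rather
than a spreadsheet.

## What it computes

The core is the three-source line-of-sight barrier model for the weekly
ambient dose equivalent at a point of interest:

```
H = W · T · Σ_x  N_x · H*(θ_x) · (1/r_x²) · exp(−d / λ_x(θ_x))
```

with workload `W` (Gy/wk), occupancy `T`, per-source protons-per-Gray
`N_x` (beam-loss adjusted: 10% cyclotron, 10% nozzle, 100% phantom),
angular source terms `H*(θ)` (Sv·m²/proton at 1 m, 10° bins; a
Monte-Carlo-derived table for the three sources is packaged), slant
barrier thickness `d` and source/angle-specific attenuation lengths `λ`.
Around it sit:

* **spherical tally scoring** — 18 angle × 250 energy bins, zone-area
  normalization, conversion to `H*(θ)` via ICRP-74-style
  fluence-to-H\*(10) coefficients (`score_fluence()`,
  `spectrum_to_source_term()`);
* **the classical Moyer point-loss model**
  `H = (H₀/r²)(E_p/E₀)^0.8 exp(−d/λ)`, `H₀ = 2.6e-14 Sv·m²`
  (`moyer_dose()`);
* **compliance reporting** — worst-case gantry-angle search and NCRP
  design-goal verdicts per point (`compliance_report()`,
  `run_assessment()`);
* **in-room H\*/D prediction** around the phantom versus distance, angle
  and field size, plus conversion of measured rates via
  `H/D = H_r/(MU_r·c)` (`predict_h_over_d()`,
  `h_over_d_from_measurement()`);
* **seeded synthetic data** — Monte-Carlo-like crossing records from a
  two-component (evaporation + cascade) forward-peaked spectrum, and
  randomized valid vault geometries (`generate_crossings()`,
  `generate_vault()`).

## Worked example

Assess a synthetic four-point vault (thick concrete walls, survey points
30 cm outside them, occupancies and goals from the standard NCRP sets):

```r
library(neutronvault)

vault <- generate_vault(seed = 42, n_pois = 4)
res <- run_assessment(vault)
res$report[, c("poi_id", "gantry_angle_deg", "occupancy", "annual_mSv",
               "design_goal_mSv_per_yr", "verdict")]
#>   poi_id gantry_angle_deg occupancy annual_mSv design_goal_mSv_per_yr verdict
#> 1 poi_01              180      1.00     0.0135                      1    pass
#> 2 poi_02                0      1.00     0.1810                      1    pass
#> 3 poi_03                0      1.00     0.2896                      5    pass
#> 4 poi_04                0      0.25     0.0040                      1    pass
res$all_pass
#> [1] TRUE
```

Each row is the worst gantry angle found for that point: `annual_mSv` is
the weekly three-source dose behind the wall times 50 operating weeks, and
the verdict compares it to the point's annual design goal. (The synthetic
vault carries a placeholder beam normalization of 1e11 protons/Gy; real
assessments must supply their machine's calibration, which scales every
dose linearly.)

A quick bulk estimate with the Moyer model — 250 MeV beam, 3 m away,
1.5 m of concrete with λ = 0.45 m:

```r
moyer_dose(r_m = 3, d_m = 1.5, lambda_m = 0.45, Ep_MeV = 250)
#> [1] 3.4e-17   # Sv per the H0 normalization
```

In-room neutron dose per therapeutic Gy at 100 cm from isocenter, 135°
toward the gantry side:

```r
predict_h_over_d(100, 135, beam_configuration("large"),
                 default_sources(), beam_normalization(1e11),
                 read_source_terms())
#> <h_over_d> large, 100 cm @ 135 deg, field 26.5 cm: 0.0948 mSv/Gy
```

The per-source breakdown (`$per_source_mSv_per_Gy`) shows what the number
is made of; the predictor is a trend and breakdown tool, not a calibrated
absolute (see the vignette).

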