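---
title: "Neutron shielding assessment for a single-room proton therapy vault"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neutron shielding assessment for a single-room proton therapy vault}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neutronvault)
```

## The problem

Passive-scattering proton therapy produces contamination neutrons wherever
the beam strikes matter: in the accelerator, in the field-shaping nozzle,
and in the patient. In a compact single-room unit the cyclotron itself is
mounted on the gantry inside the treatment vault, so all three neutron
sources sit in the room with the patient and the shielding problem cannot
be delegated to an accelerator bunker. This package implements the
standard analytical machinery for assessing such a vault: angular source
terms obtained from spherical fluence scoring, a three-source line-of-sight
barrier model, the classical Moyer point-loss formula as a bulk
cross-check, and an additive in-room predictor of neutron ambient dose
equivalent per therapeutic dose (H\*/D).

## Scoring: from tally records to angular source terms

Neutron crossings of a scoring sphere centred on a source are binned into
18 polar-angle bins of 10° (measured from the incident proton beam
direction; azimuthal symmetry is assumed) and 250 energy bins of 1 MeV.
Bins are half-open `[lo, hi)` with the single closed endpoint θ = 180°
folded into the last bin, so every valid record has exactly one home. Each
angle bin is normalized by its spherical-zone area
`2πr²(cos θ_lo − cos θ_hi)` — not by solid angle — so fluence carries units
of m⁻² per incident proton at the scoring radius, and the tally is exactly
conservative: summing `value × area × n_protons` recovers the input weight
to floating precision.

The angular source term is then

H\*(θ) = Σ_E Φ(θ, E) · f(E_mid) · 10⁻¹⁶  [Sv·m²/proton at 1 m],

where `f` is the fluence-to-H\*(10) conversion coefficient (pSv·cm²) and
10⁻¹⁶ converts pSv·cm² to Sv·m². The energy-bin representative is the bin
midpoint; with 1 MeV bins the choice is second order. Coefficients are
interpolated log-log, the standard rule for the sparse log-spaced grids on
which such coefficients are published, with flat extrapolation beyond both
ends of the grid. The packaged coefficient file is the ICRP Publication 74
neutron H\*(10)/fluence grid with the commonly used high-energy extension
to 201 MeV; results above 201 MeV therefore inherit the flat-extrapolation
policy, and any H\* value produced by `spectrum_to_source_term()` is
coefficient-table-dependent — swapping in a different grid is a one-line
change via `read_conversion_table()`.

## The three-source barrier model

The weekly ambient dose equivalent at a point of interest behind the vault
barriers is

H = W · T · Σ_x N_x · H\*(θ_x) · (1/r_x²) · exp(−d/λ_x(θ_x)),

summing over the three sources x ∈ {cyclotron target, nozzle, phantom}.

* **W** — workload, Gy/wk. The default clinical schedule is 20 patients/day
  × 2 Gy, doubled for machine QA, over a 5-day week: 400 Gy/wk
  (`weekly_workload()`).
* **T** — occupancy factor of the most-exposed individual, 0–1.
* **N_x** — protons interacting in source x per Gy at isocenter. The
  required input is the machine's protons-per-Gray calibration P; with 10%
  beam loss at the cyclotron, 10% at the nozzle and 100% in the phantom,
  back-propagating P through the survival chain gives N_phantom = P,
  N_nozzle = 0.1·P/0.9 and N_cyclotron = 0.1·P/0.81. A simpler reading —
  losses as plain fractions of P — is available via
  `protons_per_gray(..., method = "fraction_of_isocenter")`; the
  back-propagated form is the default because it preserves the meaning
  "protons transported through the source". P itself is never defaulted in
  the assessment API: it scales every dose linearly, and the synthetic
  vault generator carries an explicitly documented placeholder (10¹¹ p/Gy,
  a round order-of-magnitude value, not a machine calibration).
* **H\*(θ_x)** — the angular source term, looked up piecewise-constant in
  the 10° bin containing θ_x (bin averages are not interpolated). θ_x is
  the angle between the beam direction at source x and the ray from x to
  the point; because the cyclotron rides the gantry, both θ_x and r_x
  change with gantry angle.
* **d, λ** — each barrier slab crossed by the ray contributes its slant
  thickness `t/cos φ`, capped at φ = 70°: line-of-sight exponential
  attenuation degrades badly at high obliquity, so path lengths beyond
  `t/cos 70°` are not credible and are clamped. λ is material-, source- and
  angle-specific; by default it is looked up at the source-term angle θ_x
  (the attenuation length follows the emitted spectrum, which varies with
  emission angle), switchable to the slab incidence angle via
  `lambda_angle = "incidence"`. Published attenuation-length
  compilations are not redistributed here; the packaged concrete table is
  a synthetic smooth profile (≈0.50 m forward to ≈0.28 m backward for the
  hardest source) for examples and tests, and real assessments must supply
  their own table.

The gantry angle is searched over a candidate grid (default 0°, 90°, 180°,
270°) and the maximizing angle reported per point, ties resolved to the
smallest angle — a deterministic, conservative convention. Weekly doses are
annualized with 50 operating weeks per year (configurable; annual design
goals are stated per year while the workload is weekly, and 50 wk/yr is the
conventional bridge). Annual values below 0.001 mSv are flagged *minimal*:
below that level a survey instrument cannot resolve the dose and reporting
a number would overstate the model's precision.

The classical Moyer model, H = (H₀/r²)(E_p/E₀)^α·exp(−d/λ) with
H₀ = 2.6 × 10⁻¹⁴ Sv·m², E₀ = 1 GeV and α = 0.8, is included as
`moyer_dose()` for bulk estimates and as an independent cross-check of the
inverse-square/attenuation machinery. Energies are accepted in MeV and
compared to E₀ = 1000 MeV internally, keeping the API single-unit.

## In-room H*/D prediction

`predict_h_over_d()` reuses the barrier kernel with no barriers and W·T
replaced by one Gy: survey points lie in the horizontal plane through
isocenter at polar coordinates (distance, angle), angle 0° pointing
downstream along the gantry-0 beam axis and increasing toward the upstream
(gantry) side. An optional brass-aperture term, co-located with the nozzle,
is scaled by the blocked-area fraction `1 − (field/max_field)²`: smaller
fields intercept more beam on the aperture and produce more neutrons; the
magnitude per blocked proton is a configuration scalar with no packaged
default, because no measured value is available.

Two cautions govern interpretation. First, an additive point-source model
inside a concrete room ignores room-return (scattered) neutrons and
in-phantom moderation, and full transport simulations of comparable setups
are known to overpredict in-room measurements by about an order of
magnitude; the predictor is therefore a trend and breakdown tool, not a
calibrated absolute. Second, with the packaged source-term table and the
stated loss fractions, the phantom (100% loss, forward-peaked term)
dominates the total near isocenter, so the *total* H\*/D falls with angle
even though measurements rise. The measured rise is driven by proximity to
the upstream components — and exactly that is what the model reproduces:
the cyclotron contribution is non-decreasing from 0° to 135° at every
survey distance, and the summed upstream (cyclotron + nozzle) contribution
is larger at 135° than at 0°. The tests assert the angle trend on those
per-source breakdowns, where it is literally true, rather than on the
total; the distance falloff (phantom-only, exact inverse square) and the
field-size decrease are asserted on the totals.

## Synthetic data

`generate_crossings()` emulates a Monte Carlo tally export with a
two-component spectrum: an evaporation Maxwellian p(E) ∝ E·exp(−E/T)
(default T = 2 MeV, a typical evaporation temperature) plus an
intranuclear-cascade component modeled as a truncated normal (default mean
100 MeV, sd 40 MeV, weight 0.3 — a broad high-energy shoulder below the
250 MeV beam energy), both truncated to [0, 250) MeV, with a forward-peaked
angular density ∝ exp(κ·cos θ) (default κ = 2). These defaults are
statistical fixtures chosen once to exercise the pipeline with a
realistic shape — a soft evaporation peak under a hard forward cascade —
not nuclear-physics claims. The record count is Poisson, energies and
angles are i.i.d., and every draw flows through one explicit seed with the
session RNG restored afterwards. Because the mixture CDF is closed-form
(`energy_bin_probabilities()`), the expected Σ Φ·f and its compound-Poisson
standard error are available analytically, which is what the recovery tests
check the full crossings → fluence → H\* pipeline against (10⁵ protons,
yield 0.05, ten fixed seeds, 3-standard-error bands with one allowed
failure).

What the generator does *not* emulate: energy-angle correlation (real
cascade neutrons are both harder and more forward than evaporation
neutrons; here the angular law is shared), source self-shielding, room
scatter, and variance-reduction weights. Passing recovery tests therefore
demonstrate correctness of the scoring and conversion arithmetic, not
fidelity of any physics.

`generate_vault()` builds a valid rectangular concrete vault (half-widths
4–7 m, wall thicknesses 1–3 m) with points of interest 30 cm outside the
outer wall faces — the conventional survey offset — occupancies drawn from
the standard set {0.025, 0.0625, 0.25, 1} and design goals from
{1, 5} mSv/yr (uncontrolled/controlled). It stands in for real
architectural blueprints, which are site-specific and not distributable.

## Numerical choices and degenerate inputs

* Records with energy ≥ 250 MeV or angle outside [0, 180] are rejected by
  name, not silently dropped; a tally export containing them is a
  configuration error.
* A ray parallel to a slab, or missing its bounded extent, contributes no
  attenuation; a zero-length ray is an error.
* A point of interest coinciding with a source position at some gantry
  angle is an error (the 1/r² kernel has no sensible value there).
* Exact ties in the gantry search go to the smallest angle; grid-point
  energies return their tabulated coefficient exactly.
* Report CSVs round to 3 significant digits in scientific notation (the
  precision at which source-term tables are published); JSON reports keep
  full precision. Reruns on identical inputs are byte-identical.

## Problem sizes

The test suite tallies up to 10⁴ crossings against a brute-force
double-loop histogram (exact equality on all 4 500 bins), runs the
ten-seed recovery study at 10⁵ protons per seed, and assesses synthetic
vaults of up to eight points over the four-angle gantry grid; the whole
suite completes in a few seconds on one core.

## Known limitations

No skyshine, mazes/ducts, groundshine, activation or photon dose; no
detector-response folding (a rem-meter's energy response is not the
H\*(10) ideal); the cyclotron is a point source, which overstates its
contribution by ignoring self-shielding; and the packaged attenuation
table is synthetic. The barrier model's absolute accuracy is bounded by
the user-supplied attenuation lengths and protons-per-Gray calibration —
both enter the exponent or scale linearly, and both must come from the
facility being assessed.
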