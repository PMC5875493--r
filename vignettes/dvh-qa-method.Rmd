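---
title: "Validating brachytherapy DVHs against TG-43 hand calculations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating brachytherapy DVHs against TG-43 hand calculations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brachyqa)
```

## Why this test exists

A cumulative dose-volume histogram answers "what fraction of this structure
receives at least this dose"; clinicians accept or reject brachytherapy
plans on DVH metrics. Planning systems compute those metrics through a
chain of discretizations — dose grid, region-of-interest voxelization,
histogram binning, contour handling — any of which can bias the reported
volumes, and professional guidance asks that DVH output be validated at
commissioning and at least annually without saying how. `brachyqa`
implements a closed-form check: a geometry so simple that every DVH point
can be predicted by hand, plus a pass/fail rule for the differences.

## The QA geometry

The test structure is a narrow rectangular cuboid, by default
0.5 × 0.5 × 5.0 cm (1.25 cm³), with the sealed source placed at the center
of one 0.5 × 0.5 cm end face and (for line sources) the source axis
perpendicular to the cuboid's long axis. Two properties make this geometry
self-calibrating:

* **Constant cross-section.** The volume between depths r and r + dr is
  proportional to dr, so a flat isodose cut at depth r covers exactly
  `100 · min(r, L)/L` percent of the structure — 20 % per centimetre for the
  5-cm default (`ideal_volume_fraction()`).
* **Radial symmetry of the dose.** With anisotropy set to unity the isodose
  surface at distance r is (to the accuracy of the line-source geometry
  factor) a sphere, so the covered fraction is a known function of r alone.

The sphere's curvature means the covered volume is slightly *less* than the
flat cut. Two corrections are available through `correction_factors()`:

* `"published"` (default): the factors in routine hand-calculation use,
  derived from a perfect circle via its sagitta and apothem — 1.045, 1.021,
  1.014, 1.010, 1.008 at r = 1…5 cm, giving reference volumes 19.1, 39.2,
  59.2, 79.2, 99.2 %. These are shipped verbatim as the de facto standard
  the reference tables are expected to print.
* `"exact"`: equivalent factors computed from the true sphere–cuboid
  intersection volume (`exact_partial_volume()`), about 1.022, 1.005,
  1.002, 1.001, 1.001 for the default structure.

The two disagree: the circle-based construction overstates the curvature
loss relative to the 3-D integral (19.1 % versus 19.58 % at r = 1 cm). We
could not reproduce the sagitta/apothem derivation from the stated geometry
(a 2-D chord over the 0.25-cm half-width gives ≈ 1.011, the 3-D integral
≈ 1.022 at r = 1 cm), so the package does not guess at it: the published
values are the default so that standard tables reproduce cell for cell, the
exact integrator is exposed as a clearly separate mode, and the 0.47-point
gap at r = 1 cm is well inside the 5-point gate either way.

`exact_partial_volume()` integrates
`min(sqrt(r² − y² − z²), length)` over the cross-section with adaptive 2-D
quadrature (`pracma::integral2`, relative tolerance 1e-9), switching to the
closed half-ball form `2πr³/3` when the sphere fits inside the
cross-section; an independent dense voxel-counting mode cross-checks it
(they agree within 0.1 % relative at 0.01-cm pitch in the test suite).

## The dose engine

Doses follow the TG-43 factorization. Point source (permanent implant):
`D(r) = S_K Λ (r₀/r)² g_p(r) φ_an(r) τ` with mean lifetime
`τ = 1.44 t_½`; line source (temporary implant):
`D(r) = S_K Λ [G_L(r,θ)/G_L(r₀,θ₀)] g_L(r) F(r,θ) t`. Choices that matter:

* **Units.** S_K in U (1 U = 1 cGy·cm²·h⁻¹), Λ in cGy·h⁻¹·U⁻¹, times in
  hours. Arithmetic is done in cGy and converted to Gy only at the
  reporting boundary.
* **Anisotropy is exactly 1.** Many systems restrict anisotropy data entry,
  so commissioning for this test sets φ_an and F to unity; a per-source
  functional override exists but no preset ships data.
* **Radial dose function.** Tabulated at 1-cm nodes per preset, linearly
  interpolated in r, with *no extrapolation* in the hand-calculation path —
  any monotone interpolant agrees at the nodes, which is all the reference
  table uses. (The synthetic TPS clamps g at the table endpoints; see
  below.)
* **Dwell time.** The HDR presets store the 20-min dwell exactly as 1/3 h;
  storing the display value 0.33 would shift the reference dose by 0.1 %.
* **Geometry ratio.** On the transverse plane the reduced form
  `[r₀ arctan(L/2r)]/[r arctan(L/2r₀)]` is used; off the bisector the
  general `β/(L r sinθ)` form, normalized to the reference position, with
  the on-axis limit `1/(r² − L²/4)`. As L → 0 the ratio collapses to
  inverse square (asserted to 1e-6 at L = 1e-4 cm).
* **Display rounding.** Dosimetry tables round ties away from zero: doses
  to 2 decimals, dimensionless ratios to 3, percentages to 1
  (`round_half_away()`). Relative dose is computed from unrounded doses and
  rounded once for display; all CSV output is full precision so nothing is
  quantized twice.

The mHDR-v2 preset carries a wrinkle: the transverse geometry ratios
tabulated in common commissioning practice for this source (0.256 at
r = 2 cm) do not match the analytic line-source expression for its 0.36-cm
active length (0.252), and its nominal `S_K Λ t` product differs slightly
from the reference dose quoted alongside those ratios. The preset therefore
ships both modes — `brachy_source("mHDRv2")` uses the tabulated ratios
verbatim, `brachy_source("mHDRv2", geometry = "eq")` the analytic form —
and no constant was adjusted to hide the inconsistency. The DVH
comparison keys on radius, not on the printed dose label, so it is
unaffected by which mode generated the reference.

## The comparison and its gates

`build_reference_table()` assembles per-radius rows (geometry term, g,
dose, %Dose = 100·D(r)/D(r₀), corrected %Vol); `compare_dvh()` queries the
TPS curve at each reference %Dose (linear interpolation between the
export's points — TPS exports step in volume, nominally ~2 %, and no
smoothing is applied) and forms the signed difference in percentage points
of structure volume. The verdict is **pass** iff every per-radius
|difference| ≤ 5 points *and* the |signed mean| ≤ 2 points. Signed
averaging is deliberate: opposite-sign local errors may cancel in the mean,
which is exactly why the individual gate exists, and the two gates fail
independently (both branches are exercised in the tests). The tolerances
are absolute %Vol differences, not relative, and are overridable per run.

A bundled survey dataset (`tps_survey()`) of per-radius differences
observed when commissioning five commercial systems against these presets
demonstrates the metrics: all surveyed columns pass both gates, with
recomputed signed averages between −0.1 and 0.7 points.

## The synthetic planning system

`simulate_dvh()` stands in for a commercial TPS so the pipeline can be
exercised end to end at desk scale. It voxelizes the cuboid on a regular
grid anchored at the cuboid corner (half-open cells, membership by voxel
center, so grids whose pitch divides the dimensions reproduce the 1.25 cm³
volume exactly), evaluates the TG-43 dose at each voxel center — point
form, or line form at the voxel's true polar angle with the source axis
along z — normalizes to the reference-position dose, and samples the
empirical cumulative curve at dose-bin edges.

Parameter defaults, chosen once as representative of a careful TPS setup:

| parameter | default | rationale |
|---|---|---|
| `voxel_pitch` | 0.05 cm | fine dose grid; divides all default dimensions |
| `dvh_bin_width` | 0.5 % | finer than the ~2 % steps of typical exports, coarse enough to mimic binning |
| `max_pct_dose` | 150 % | queries never exceed 100 %; near-source voxels pool in the top bin |
| `contour_perturbation` | 0 cm | optional uniform shrink mimicking contouring loss |

Numerical notes: voxel radii span from about half a pitch (where relative
dose is enormous — those voxels are counted at every queried level, so the
cap is harmless) to slightly past the 5-cm table end at the far corners,
where g(r) is endpoint-clamped; the clamp perturbs g by under 0.7 % over a
sliver of volume and no queried level crosses it. Dose is sampled at voxel
centers without sub-voxel averaging, matching typical TPS dose-grid
behavior and keeping the oracle comparison clean.

Convergence is verified against the exact sphere–cuboid integral rather
than against the published corrected volumes: at 0.025-cm pitch and 0.1 %
bins the simulated %Vol at every reference dose is within 0.5 percentage
points of the oracle for the analytically consistent presets (for mHDR-v2
this means the `"eq"` geometry mode; the tabulated-ratio mode shifts the
reference dose levels by construction and is compared only through the
gates, which it passes). Problem sizes were chosen so the whole suite runs
in seconds: 10⁴ voxels at the default pitch, 8 × 10⁴ in the convergence
checks.

**What the simulator does not emulate:** vendor contouring artifacts beyond
a uniform shrink, dose-grid/ROI-grid misalignment, absolute-volume DVH
dialects, scatter and heterogeneity corrections, 2-D anisotropy. A pass of
the synthetic self-check therefore validates the comparison pipeline and
the geometry model, not any commercial system; real commissioning still
requires the TPS's own export through `read_dvh_csv()`.

## Degenerate inputs and errors

Zero dwell time yields zero dose (a valid degenerate prescription);
negative times, non-positive strengths, radii outside tabulated ranges, a
voxel pitch exceeding a cuboid dimension, and a disc radius clipping the
thin-slab square all raise classed errors (`brachyqa_invalid_parameter`,
`brachyqa_out_of_range`, …). Single-row tables are legal and produce a
one-point DVH curve. DVH curves must be strictly decreasing in dose and
non-decreasing in volume; violating exports are rejected rather than
silently reordered.

## Known limitations

* The published curvature factors are constants for the default structure;
  for a different cuboid use `correction_factors("exact", structure = …)`.
* Only single-source implants are modeled; no TG-186 model-based dose.
* Factor interpolation between tabulated radii is linear, and comparisons
  default to the tabulated radii.
* The thin-square-slab alternative geometry is modeled only while the
  isodose disc lies fully inside the square (r ≤ side/2).
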