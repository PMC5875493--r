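# brachyqa

Independent quality assurance of the dose-volume histograms (DVH) that
brachytherapy treatment planning systems (TPS) report.

Clinical decisions on brachytherapy plans lean on cumulative DVH metrics,
yet planning systems offer no built-in way to verify that the volumetric
statistics they print are right. `brachyqa` implements the desk-top check a
medical physicist can run at commissioning, after upgrades, and annually: a
narrow rectangular cuboid (0.5 × 0.5 × 5.0 cm, 1.25 cm³) is contoured with a
single sealed source at the center of one end face, the TG-43 formalism
gives the dose at each centimetre along the cuboid by hand, and the constant
cross-section makes the covered volume fraction proportional to distance —
so every (relative dose, relative volume) point of the TPS DVH can be
predicted independently and gated.

## The model

For a permanent LDR implant (point-source approximation):

    D(r) = S_K · Λ · (r₀/r)² · g_p(r) · φ_an(r) · τ,   τ = 1.44 · t_½

and for a temporary HDR implant (line-source approximation):

    D(r) = S_K · Λ · [G_L(r,θ) / G_L(r₀,θ₀)] · g_L(r) · F(r,θ) · t

with `S_K` the air-kerma strength (U), `Λ` the dose-rate constant
(cGy·h⁻¹·U⁻¹), `g(r)` the radial dose function, anisotropy set to unity,
and the reference position at r₀ = 1 cm, θ₀ = 90°. On the transverse plane
the geometry-function ratio reduces to

    G_L(r,90°)/G_L(r₀,90°) = [r₀ · arctan(L/2r)] / [r · arctan(L/2r₀)].

A flat cut at depth r would cover `100·r/length` percent of the cuboid; the
real isodose surface is curved, so the ideal 20, 40, 60, 80, 100 % fractions
are divided by curvature correction factors (1.045, 1.021, 1.014, 1.010,
1.008 at r = 1…5 cm), giving the reference %Vol of 19.1, 39.2, 59.2, 79.2,
99.2 %. The TPS curve is then queried at each reference relative dose and
the signed %Vol differences are gated: investigate if any single radius
differs by more than 5 percentage points, or the average by more than 2.

Three commissioning presets ship with the package: the I-125 Model 6711
seed, and the Ir-192 VS2000 and mHDR-v2 HDR sources. A synthetic planning
system (voxelized TG-43 dose grid + cumulative DVH binning) lets the whole
pipeline run without any commercial TPS.

## Worked example

```r
library(brachyqa)

tb <- build_reference_table(brachy_source("6711"))
tb
#> Hand-calculation reference table: source 6711 (point mode)
#>  r_cm geometry_term     g dose_Gy pct_vol pct_dose
#>     1         1.000 1.000   20.01    19.1    100.0
#>     2         0.250 0.819    4.10    39.2     20.5
#>     3         0.111 0.636    1.41    59.2      7.1
#>     4         0.063 0.499    0.62    79.2      3.1
#>     5         0.040 0.367    0.29    99.2      1.5
```

Row by row: at r = 1 cm the 1.01 U seed delivers 20.01 Gy over the implant
(100 % of prescription) and the 100 % isodose sphere covers 19.1 % of the
cuboid; at 5 cm the dose has fallen to 0.29 Gy (1.5 %) while 99.2 % of the
structure receives at least that dose. Comparing a (here simulated) TPS DVH
against this reference:

```r
end_to_end_selfcheck(brachy_source("6711"))
#> DVH comparison report: synthetic TPS / 6711
#>  r pct_dose pct_vol_ref pct_vol_tps actual_variance
#>  1    100.0        19.1        19.6             0.5
#>  2     20.5        39.2        40.0             0.8
#>  3      7.1        59.2        59.9             0.7
#>  4      3.1        79.2        80.1             0.8
#>  5      1.5        99.2        99.1            -0.1
#> average variance: 0.5 pp (tolerance 2); individual tolerance 5
#> verdict: PASS
```

Every per-radius difference is within 5 points and the signed average
within 2, so the simulated system passes. Real TPS exports go through the
same path: `read_dvh_csv()` (a `pct_dose,pct_vol` CSV, or `dose_Gy` with a
prescription for normalization) then `compare_dvh()`.

For scripted annual QA there is a shell entry point
(`exec/brachyqa.R`) with `table`, `simulate` and `compare` subcommands;
`compare` exits 0 on pass, 1 on fail:

```sh
Rscript exec/brachyqa.R table --source 6711 --out ref.csv
Rscript exec/brachyqa.R compare --reference ref.csv --tps export.csv
```

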