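# dqihld

Oral drug suitability parameters from a minimal three-compartment
pharmacokinetic model.

## What this package is for

Early in drug discovery a chemist must judge, from a handful of
measured or QSAR-predicted properties, whether a candidate can ever work
as an oral drug. `dqihld` answers that with a mechanistic simulation
rather than property heuristics. It simulates repeat oral dosing with a
deliberately minimal PK model — a saturable, time-limited intestinal
absorption compartment feeding a classic two-compartment disposition
model with hepatic first-pass loss — and reduces each simulated
log10(dose) vs log10(exposure) curve to two numbers:

- **DQI** (dose–quantity intercept), the intercept of the slope-1
  regression through the linear-PK region:
  `log10(quantity) = 1·log10(dose) + DQI`. Exposure obtained per mg of
  dose; a measure of elimination.
- **HLD** (highest linear dose), the log10(dose) at which that line
  reaches the curve's maximum quantity: `HLD = log10(max_quantity) − DQI`.
  The approximate upper dose limit of linear PK; a measure of
  absorbability.

`HLD + DQI = log10(max_quantity)` is the exposure ceiling reachable by
raising the dose. Because distribution kinetics are unknown at the design
stage, every compound is simulated under five (V_central, V_terminal)
hypotheses, optionally crossed with 50 Gaussian input-error scenarios on
Vss and Cl (SD 0.3 on the log10 scale), and the resulting 255 (HLD, DQI)
pairs are summarised as a polygon in the DQI–HLD plane (area, centroid,
second moments of area).

Inputs per compound: charge type, pKa, aqueous solubility at pH 7.4 (M),
apparent Caco-2 permeability A→B at pH 6.5 (cm/s), human Vss (L/kg),
human plasma clearance (mL/min/kg), molecular weight (g/mol) and,
optionally, plasma protein binding (% bound). A reference table of 15
marketed oral drugs ships with the package
(`example_compounds()`).

## Worked example

```r
library(dqihld)
drugs    <- example_compounds()
settings <- model_settings()        # the standard protocol
dz <- drugs[["diazepam"]]

# distribution scenario (i): Vc = 3 L (plasma volume), Vt = 1.1 Vss
sc <- make_scenarios(dz, settings)$i
sc
#> <distribution_scenario i> Vc 3 | Vss 70 | Vt 77 L; k2 0.08156, k3 0.003652,
#>   k4 0.008867 /min (alpha 0.09373, beta 0.0003455)

curves <- run_dose_sweep(dz, sc, settings, quantities = "css_central_max")
estimate_dqi_hld(curves$css_central_max, settings)
#> $dqi                -0.821
#> $hld                 1.46
#> $log10_max_quantity  0.642
#> $n_linear_points     9
#> $slope               1
#> $plateau_reached     TRUE
```

Read: in this scenario diazepam delivers `10^-0.821 ≈ 0.15` mg/L of
steady-state total C(ss,central,max) per mg of twice-daily dose, stays
(near-)linear up to `10^1.46 ≈ 29` mg, and cannot exceed
`10^0.642 ≈ 4.4` mg/L however large the dose — the intestinal segment
saturates. `quantity_at_dose(-0.821, 1.46, 10)` gives the capped
prediction at a 10 mg dose, `1.51` mg/L.

All five scenarios at once, as a DQI–HLD polygon:

```r
p <- build_polygon(dqi_hld_vertices(dz, settings, errors = FALSE))
p
#> <dqi_hld_polygon> 5 vertices (hull order): area 0.04113,
#>   centroid (HLD 1.600, DQI -0.904)
#>   second moments of area: HLD 0.03429, DQI 0.1057
```

With `errors = TRUE` (the default) the polygon is built from 255
vertices and reflects input uncertainty as well; `suitability_summary()`
tabulates every compound, and `plot_dqi_hld()` draws the polygons.

A thin command-line interface wraps the same functions:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","oraldose-dqi",package="dqihld"))')" \
  summary --compounds inst/extdata/oral_drugs_15.csv --seed 17 --out results/ --plot
```

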