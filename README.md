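# ritkit

Biodistribution processing, internal dosimetry and therapy-outcome
analysis for preclinical antibody radioimmunotherapy (RIT).

## The problem

A common theranostic design in mouse xenograft studies labels a
tumor-targeting antibody with a gamma-emitting imaging surrogate
(e.g. ¹¹¹In, t½ = 67.4 h), measures its biodistribution as the percentage
of injected dose per gram of tissue (%ID/g) over about a week, and uses
those kinetics to predict the absorbed dose that the chemically matched
beta-emitting therapy conjugate (e.g. ⁹⁰Y, t½ = 64.1 h) would deliver.
Therapy arms are then followed by caliper until tumors reach a humane
endpoint. `ritkit` implements that whole computational chain for
analysts who have the tabular measurements (or want a faithful synthetic
stand-in) and need reproducible dose tables and outcome summaries.

## The model

For each organ, the group-mean %ID/g curve f(t) is interpolated
piecewise-linearly and the **time-integrated activity** per unit tissue
mass is

    Ã = A₀ · 10 · ∫₀^∞ f(t) · e^(−λt) dt      [Bq·s·kg⁻¹]

with A₀ the injected activity (Bq), λ the *therapy* nuclide's physical
decay constant (the %ID/g data are assumed decay-corrected), and the
factor 10 converting %ID/g to fraction of injected dose per kg. Each
linear segment times the exponential is integrated in closed form; the
unmeasured head and tail of the curve follow explicit, configurable
rules. The self-absorbed dose for a pure beta emitter is

    D = Δ · Ã      with Δ(⁹⁰Y) = 1.495 × 10⁻¹³ Gy·kg·(Bq·s)⁻¹.

Tumor volumes use the ellipsoid approximation V = length × width² / 2;
time-to-endpoint (12 mm diameter, 56-day observation) is summarized with
a product-limit (Kaplan–Meier) curve.

## Worked example

```r
library(ritkit)
y90 <- builtin_nuclide("Y-90")

# synthetic two-arm cohort: 5 animals/arm at 1, 6, 24, 48, 96, 168 h,
# 30% inter-animal CV, 1.4-fold early tumor enhancement in the SQAP arm
cfg    <- synthetic_config(seed = 7)
curves <- summarize_curves(simulate_biodistribution(cfg))
get_curve(curves, "saline", "tumor")
#>    group organ time_h mean_pidg sd_pidg n
#> 1 saline tumor      1      2.52   0.602 5
#> 2 saline tumor      6     12.92   3.090 5
#> 3 saline tumor     24     31.14   7.448 5
#> 4 saline tumor     48     35.67   8.530 5
#> 5 saline tumor     96     31.44   7.519 5
#> 6 saline tumor    168     23.68   5.663 5
```

The curve shows the expected antibody kinetics: slow accumulation to a
peak near 48 h (the noiseless model peaks at 37.8 %ID/g; this 5-animal
draw at 30% CV gives 35.7 ± 8.5) followed by slow clearance.

```r
dose_table(curves, c(0.925e6, 1.85e6, 3.7e6), y90) |>
  format_dose_table_wide()
#>        organ saline_0.925MBq saline_1.85MBq saline_3.7MBq ... SQAP_3.7MBq
#> 1      blood             4.5            9.0          17.9 ...        20.7
#> 5      liver             3.3            6.6          13.2 ...        15.2
#> 10     tumor            12.5           25.1          50.2 ...        61.3
```

Doses are exactly linear in injected activity; tumor receives an order
of magnitude more than normal organs, and the SQAP arm's tumor dose
exceeds saline's (differences in normal organs here are 5-animal
sampling noise, not a modelled effect). Therapy outcomes:

```r
tc   <- therapy_sim_config(seed = 7)
meas <- rbind(simulate_therapy(tc, 0,    group = "control"),
              simulate_therapy(tc, 47.9, group = "3.7MBq_SQAP"))
recs <- survival_records(meas)
surv_at(survival_curve(recs[recs$group == "3.7MBq_SQAP", ]), c(33, 48, 56))
#> [1] 1 1 0
```

Controls reach the 12-mm endpoint around day 20–26, while a 47.9 Gy
tumor dose (0.6 d/Gy growth arrest) keeps all animals below the
endpoint past day 48.

## Command line

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","ritkit.R",package="ritkit"))')" \
    full-run --config config.json --out results/run1 --seed 7
```

Subcommands: `simulate-biodist`, `simulate-therapy`, `dose-table`,
`therapy-analyze`, `full-run`. Each run writes delimited-text artifacts
plus `manifest.json`; identical config and seed give byte-identical
outputs.

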