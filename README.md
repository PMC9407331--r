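# citrusnmr

Quantitative ¹H NMR scoring of sweetness, acidity and consumer acceptability
in mandarin extracts — on high-field (400 MHz) and benchtop (60 MHz)
spectrometers.

## The problem

Consumer acceptability of mandarins tracks the balance between sugars and
citric acid. Both are easy to read off a ¹H NMR spectrum of the aqueous fruit
extract in D₂O: the anomeric protons of sucrose (5.40 ppm), α-glucose
(5.22 ppm) and β-glucose (4.63 ppm), the H-3/H-4 multiplet of the β-furanose
form of fructose (4.09 ppm) and the citrate methylene AB system near 2.8 ppm
all sit in relatively uncluttered regions. Integrating fixed windows around
these markers, anchoring everything to the sucrose signal (set to 1.00), and
weighting each sugar by its relative sweetness (1.0 sucrose, 1.3 fructose,
0.6 glucose) gives the **sweetening-power/citric-acid ratio**

```
ratio = ( Σ_n sweetness_n × sugar_content_n ) / citric_acid_content
```

A per-variety linear model then predicts panel acceptability from the ratio:

```
acceptability = β₀ + β₁ × ratio
```

The scientific point is instrument equivalence: the same extracts measured at
400.13 MHz and at 62.32 MHz give ratios that correlate almost perfectly, so a
low-cost benchtop magnet supports the same assay as a high-field instrument.
This package implements the whole workflow and, because raw instrument data
for such assays are rarely deposited, ships a physics-based synthetic FID
generator (first-order multiplets for the sugars, the exact two-spin AB
solution for citrate, field-scaled chemical shifts, replicate variability,
noise) so every stage is testable end to end.

It is intended for analytical chemists and fruit-quality researchers who want
a reproducible, scriptable version of the assay — and a simulation workbench
for studying how field strength, linewidth and integration windows interact.

## What is in the box

| Stage | Functions |
|---|---|
| Synthetic spectra | `default_line_list()`, `synthesize_fid()`, `simulate_cohort()` |
| Processing | `processing_params()`, `process_fid()`, `phase_correct()`, `baseline_correct()`, `reference_spectrum()`, `align_spectra()` |
| Quantification | `default_windows()`, `integrate_window()`, `relative_areas()` |
| Scoring & model | `sweetness_acid_ratio()`, `fit_acceptability_model()` (+ `predict`, `plot`, `summary` methods), `compare_instruments()` |
| Pipeline & IO | `run_pipeline()`, `read_spectrum()`/`write_spectrum()` (JCAMP-DX and columnar text), `repro_table1()`, `repro_figures()`, a CLI at `inst/cli/citrusnmr` |

Processing follows the assay protocol: exponential apodization (0.3 Hz), zero
filling to 64 K, Fourier transformation, phase correction (automated or
fixed), optional baseline correction, referencing to the α-glucose anomeric
proton at 5.22 ppm, and derivative-based alignment against the average
spectrum.

## Worked example

```r
library(citrusnmr)

t1 <- mandarin_table1()          # bundled five-variety reference table
fit <- fit_acceptability_model(t1$ratio_400, t1$acceptability)
fit
#> Linear acceptability model (OLS on variety mean ratios)
#>   acceptability = 0.912 + 0.628 * ratio   (n = 5)
#>   R-squared = 0.935, RMSE = 0.353 (divisor n)

predict(fit, ratio = 8.0)
#> [1] 5.937773
```

The fitted line says each unit of sweetness/acid ratio buys ~0.63 points of
panel acceptability, and the five varieties' scores are reproduced with an
RMSE of 0.35 points. Comparing both instruments:

```r
va <- data.frame(variety_id = t1$variety_id,
                 acceptability = t1$acceptability, mean_ratio = t1$ratio_400)
vb <- data.frame(variety_id = t1$variety_id,
                 acceptability = t1$acceptability, mean_ratio = t1$ratio_60)
compare_instruments(va, vb)
#> Cross-instrument equivalence
#>   ratio R-squared:      0.9980
#>   prediction R-squared: 0.9980
#>   model A: slope 0.628, intercept 0.912, R2 0.935, RMSE 0.353
#>   model B: slope 0.485, intercept 1.620, R2 0.955, RMSE 0.294
```

Both ratio columns and both models' predictions agree with R² ≈ 0.998: the
60 MHz assay is as informative as the 400 MHz one. A fully synthetic version
of the study (simulate → process → quantify → score) runs in a few seconds:

```r
cohort_ratio_rsd(seed = 7)
#>   variety_id mean_ratio rsd_percent n_rep
#> 1      B475A   6.967773    7.421016     5
#> 2      B475B   9.208892    9.094611     5
#> ...
```

Replicate precision of the simulated assay (RSD 7–10% here) sits comfortably
inside the < 20% tolerance the wet-lab assay reports.

The declarative pipeline does the same from a single YAML file (see
`inst/extdata/config-synthetic-demo.yaml`), and the CLI wraps every stage:

```sh
Rscript inst/cli/citrusnmr fit --table table1 --out results/
Rscript inst/cli/citrusnmr repro figures --out figures/
```

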