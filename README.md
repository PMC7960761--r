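# osmoscan

Analysis and simulation tools for **osmotic-gradient ektacytometry**
("osmoscan") — the laser-diffraction assay that measures red-blood-cell
deformability while sweeping extracellular osmolality from 0 to 500 mOsm/kg
at constant shear stress (30 Pa). The assay is used in the diagnostic
work-up of hereditary hemolytic anemias, but its healthy reference ranges
are wide; both donor age and red-cell age (density) shift the curve, which
motivates age-stratified reference intervals. This package is aimed at
hemorheology and clinical-laboratory researchers who need a tested,
reproducible implementation of the curve analysis and of the cohort-level
statistics around it.

## What it computes

From an elongation-index curve EI(O) the package extracts the seven Lorrca
indices:

* **O_min, EI_min** — position and depth of the hypoosmotic valley
  (physiologically tied to 50% osmotic lysis);
* **O_EI_max, EI_max** — osmolality and value of maximal deformability;
* **O_hyper, EI_hyper** — the hyperosmotic half-maximum point,
  EI(O_hyper) = EI_max / 2, a marker of cell hydration;
* **Area** — the trapezoidal area under the curve on [O_min, O_hyper].

Degenerate curves are reported through QC flags (`NO_VALLEY`,
`HYPER_NOT_REACHED`, `LOW_SIGNAL`, ...), never as crashes.

Around that core the package provides:

* a **synthetic curve generator** (monotone piecewise-cubic through named
  control features) whose ground-truth indices are exact inputs, with
  presets for whole blood (WB), mock-Percoll-treated blood (WBP) and
  low/medium/high-density red-cell fractions (L/M/H);
* a **cohort simulator** calibrated to a 45-donor healthy reference table
  (28 women 18–61 y, 17 men 23–51 y), with an age effect on O_hyper and
  its couplings to RDW and cell water content, plus per-donor fraction
  samples and a 10-marker panel (band 4.1a:b, reticulocytes, CD71, EMA,
  FS/SS, thiols, DHR, DAF) with the expected L/M/H orderings;
* the **statistical pipeline**: Shapiro–Wilk-gated paired t / Wilcoxon
  tests, OLS models `index ~ age + gender`, hypochromic-RBC QC filtering,
  and age-stratified percentile reference intervals;
* **morphometry** of integer-labeled segmentation masks (projected area,
  moment-ellipse axes, sphericity = minor/major) with a synthetic
  ellipse-mask oracle;
* **marker computations**: gravimetric water fraction, SDS-PAGE band
  4.1a:b densitometric ratio, geometric-mean fluorescence.

See `vignettes/osmoscan-methods.Rmd` for the model, the numerical choices
and their rationale.

## Worked example

```r
library(osmoscan)

# simulate a whole-blood scan with realistic noise, then extract
p <- fraction_presets(noise_sd = 0.005, seed = 42)$WB
s <- synth_curve(p, sample_id = "demo", fraction = "WB")
extract_indices(s$curve)
#> <lorrca_indices> O_min 139.5 EI_min 0.177 | O_EI_max 304.1 EI_max 0.602 |
#>                  O_hyper 459.1 EI_hyper 0.301 | Area 140.0
s$truth
#> <lorrca_indices> O_min 140.0 EI_min 0.180 | O_EI_max 300.0 EI_max 0.600 |
#>                  O_hyper 460.0 EI_hyper 0.300 | Area 140.2
```

The extracted indices sit on the generator's ground truth to within the
documented tolerances (osmolality indices within ~1 mOsm/kg noiseless,
O_hyper within 5 mOsm/kg at this noise level).

The end-to-end pipeline simulates a 45-donor replica cohort, synthesizes
the five scans per donor, extracts all indices, and runs the study-level
statistics:

```r
m <- run_pipeline(run_config(seed = 7, out_dir = "demo_run"))
read.csv("demo_run/index_models.csv") |>
  subset(index == "o_hyper", c(term, estimate, ci_lo, ci_hi, p_value))
#>       term estimate   ci_lo ci_hi p_value
#>        age    0.294  0.0644 0.524  0.0133
#>    genderM   -2.400 -7.3586 2.559  0.3344
```

At this seed the recovered age slope on O_hyper is 0.29 mOsm/kg per year
(generating value 0.3) and significant at the 5% level, while gender is
not — the structure the generator encodes. The paired fraction comparisons
show O_hyper falling with cell density and the Percoll handling artifact:

```r
read.csv("demo_run/fraction_tests.csv") |>
  subset(index == "o_hyper", c(pair, test_name, estimate, p_value))
#>      pair test_name estimate  p_value
#>       L:M  paired_t    10.07 5.66e-30
#>       M:H  paired_t    19.73 1.14e-42
#>       L:H  paired_t    29.80 2.63e-51
#>    WB:WBP  paired_t    -9.94 1.22e-33   # WB - WBP: treatment raises O_hyper
```

A thin command-line front end over the same functions is installed at
`inst/cli/osmoscan.R` (`extract`, `simulate-curve`, `simulate-cohort`,
`analyze-cohort`, `compare-fractions`, `morph`, `run-all`).

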