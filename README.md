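# psrquant

Digital quantification of fibrosis on picrosirius red (PSR) stained
brightfield sections, designed to transpose across organs (liver, lung,
kidney) with one shared set of detection conventions. Intended users are
histopathology and preclinical-model labs quantifying collagen deposition
from whole-section scans.

## What it computes

PSR stains fibrillar collagen red on a picric-yellow counterstain. From a
calibrated RGB section image, `psrquant`:

1. **Detects stain** two ways: a simple RGB filter (`PSR_RGB`, thresholded
   green suppression `255 − G`) and an optimized detector (`PSR_OPT`) that
   thresholds `clip((R − G) − noise, 0, 255)` where
   `noise = max(w_g·G, w_h·AEC)` combines a counterstain cue with an
   AEC-like optical-density channel, then completes faint fiber margins by
   red chromaticity `255·R/(R+G+B)` within a 1-px collar of the core mask.
2. **Builds regions**: automatic tissue and lumen detection, exclusion
   handling from label maps, and organ rule sets — liver
   perivascular/bridges/parenchyma from the closed stain mask, lung 25 µm
   distance bands around ducts and vessels, kidney compartments with large
   cortical vessels (lumens + 10 µm rim) split out of the cortex.
3. **Types fibers** (`PSR_MORF`): seeded-watershed separation of the
   detected stain and a two-class call per segment — *compact* (mean
   signal ≥ 96 and closure density ≥ 0.6) versus *scattered*.
4. **Quantifies**, per sample × ROI × fiber class, with `A` areas in µm²:
   - relative ROI area = 100·A_ROI / A_tissue
   - in toto CPA = 100·S_total / A_tissue
   - collagen proportion CP = 100·S_ROI / S_total (sums to 100 over a ROI
     partition)
   - ROI CPA = 100·S_ROI / A_tissue (sums to the in toto CPA)

A deterministic phantom generator (`generate_phantom()`) renders PSR-like
synthetic sections with exact ground truth — graded fibers, lumens,
erythrocyte-like artifacts — and backs the entire test suite.

## Worked example

```r
library(psrquant)

ph  <- generate_phantom(organ_preset("liver", seed = 42))
run <- run_sample(ph, run_config(profile = organ_profile("liver")))
print(run)
#> psr_run 'phantom_liver_seed42' (liver): tissue 0.0152 mm^2
#>   PSR_RGB in toto CPA: 4.63%
#>   PSR_OPT in toto CPA: 4.44%

rec <- run$records
rec[rec$method == "PSR_OPT" & rec$fiber_class == "all",
    c("roi_name", "stained_area_um2", "relative_roi_area_pct", "cp_pct", "roi_cpa_pct")]
#>      roi_name stained_area_um2 relative_roi_area_pct  cp_pct roi_cpa_pct
#>       in_toto           676.25               100.000 100.000      4.4413
#>  perivascular           189.00                 1.254  27.948      1.2413
#>       bridges           449.00                 3.052  66.396      2.9489
#>    parenchyma            38.25                95.693   5.656      0.2512
```

Reading the table: the three ROIs partition the 0.0152 mm² of tissue
(relative areas sum to 100%), 4.44% of tissue is PSR-positive by the
optimized detector, two thirds of all detected collagen sits in bridges
(CP 66.4%), and the per-ROI CPAs (1.24 + 2.95 + 0.25) sum back to the in
toto 4.44%. `write_run(run, "out/")` exports the records as CSV plus mask
PNGs and a JSON manifest of every parameter; `run_manifest()` aggregates
several samples into group mean ± SD tables.

A thin CLI wraps the same functions
(`inst/cli/psrquant generate-phantom | calibrate | run | batch`).

## Design notes

The methods vignette (`vignettes/psr-quantification.Rmd`) documents the
model and its assumptions: the evidence images and why the AEC noise
weight is small, the reference threshold calibration (midpoint rule on the
canonical palette), region rule conventions, the watershed and the
two-class cutoffs, what the phantom does and does not emulate, and the
package's numerical conventions.
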