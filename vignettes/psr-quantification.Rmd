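---
title: "Quantifying PSR-stained collagen: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying PSR-stained collagen: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psrquant)
```

## The problem

Picrosirius red (PSR) stains fibrillar collagen red against a picric-acid
yellow counterstain. Digital quantification of fibrosis on such sections has
three steps: detect the stain reliably, identify the histological
compartments it falls into, and express the result as interpretable
percentages. `psrquant` implements all three with one set of conventions
that transposes across liver, lung and kidney sections, plus a
deterministic phantom generator that provides exact ground truth for
validation in the absence of shared slide material.

## Stain evidence and the two detectors

All evidence images are oriented *higher = more stain*, so a single
`>= threshold` convention serves every detector, and thresholds are shared
across organs (per-organ tuning would defeat multi-organ comparison).

**PSR_RGB** thresholds green suppression, `255 - G`. Red stain absorbs
green light, so this is a cheap stain proxy — but *anything* non-green
(erythrocytes, debris, dark nuclei) also responds, and faint anti-aliased
fiber margins fall below practical thresholds. Those two failure modes are
what the optimized detector addresses.

**PSR_OPT** thresholds a noise-subtracted signal
`clip(max(R - G, 0) - noise, 0, 255)` where

```
noise = median_smooth( max(w_g * G, w_h * AEC) )
```

combines two non-collagen cues by pixel-wise maximum, so either cue alone
vetoes a pixel: the raw green channel (bright on counterstain and pale
cytoplasm) and an AEC-like channel from two-stain optical-density
separation (bright on diffuse reddish-brown chromogen). The core mask is
then *completed* by the red-chromaticity filter `255 * R / (R+G+B)`,
restricted to a 1-px dilation collar of the core: chromaticity is
brightness-invariant and recovers faint fiber margins, while the collar
constraint prevents it from ever seeding isolated noise. An unconstrained
union is available (`chrom_collar = FALSE`) for sensitivity analysis only.

### Optical-density separation

Per pixel, `OD_c = log10(255 / max(I_c, floor))` for each channel; the OD
vector is decomposed by least squares onto two unit stain directions
(standard published hematoxylin and AEC vectors by default), negative
coefficients clamped to zero, and each coefficient mapped to `[0, 255]`
with an OD ceiling of 2.5. The floor (`od_intensity_floor = 1`) guards the
logarithm at zero transmission; both are configurable.

### Why the AEC weight is small

The AEC-like channel cross-reacts with the primary stain — both are red
chromogens. On the canonical palette (below), saturated PSR red projects
*more* strongly onto the AEC direction (rescaled response 142) than the
erythrocyte colour does (110). A weight near 1 would therefore veto
collagen itself. The default `w_h = 0.3` keeps the AEC veto strictly below
the red-green contrast of genuine stain at any dilution (`0.3 * 142c < 10 +
140c` for all coverage `c`), while still penalising pixels whose AEC
evidence overwhelms their red evidence. The green weight stays at 1.0: it
is the cue that actually rejects both the counterstain (G = 220) and
erythrocytes (G = 80 versus collagen's 30).

### Reference threshold calibration

Thresholds are deployment parameters; `calibrate_global_threshold()`
implements the documented convention — the midpoint between the mean
evidence of stained and unstained patch populations. The package defaults
are this rule applied once to the canonical phantom palette:

| colour | role | green-supp. | R−G contrast | OPT signal | chromaticity |
|---|---|---|---|---|---|
| (230,220,60) | counterstain | 35 | 10 | 0 | 115.0 |
| (180,30,40)  | saturated stain | 225 | 150 | 107.3 | 183.6 |
| (210,140,110)| faint stain | 115 | 70 | 0 | 116.4 |
| (220,80,60)  | erythrocyte | 175 | 140 | 60.0 | 155.8 |

* `t_opt = 84`: midpoint of saturated stain (107.3) and the hardest
  confounder, the erythrocyte (60.0).
* `t_chrom = 149`: midpoint of saturated stain (183.6) and the counterstain
  (115.0) — the element completion must reject at fiber margins. Note that
  the counterstain's chromaticity is as high as 115; any completion
  threshold below it would leak background collars around every fiber.
* `t_rgb = 165`: midpoint of saturated stain (225) and the mean non-stain
  response ((35 + 175) / 2). Deliberately, no green-suppression threshold
  can reject erythrocytes (175) without also losing faint stain (115) —
  that limitation is intrinsic to the simple detector and is what the
  phantom-based sensitivity comparison exhibits.

Thresholds use `>=` (ties included). Masks drop connected components below
`min_object_px = 3` (single-pixel speckle at a 20x scale; 0 disables).

## Regions: tissue, exclusions, ROIs

**Tissue** is non-white pixels (minimum channel below 240), with holes
below `fill_holes_max_um2` filled back (pale intratissue gaps) and larger
holes kept open so lumens remain detectable; components below 1000 µm² are
dropped. An all-white frame is a hard error. **Lumens** are enclosed
background holes of at least `lumen_min_area_um2` (200 µm² default);
border-touching holes never qualify. **Exclusions** come from an ingested
label map: role `roe` is removed from the total-tissue denominator; role
`roe_keep_in_tissue` stays in the denominator but is never a ROI (used for
dense peri-air-duct connective tissue).

Organ rule sets:

* **Liver** — connective tissue is the morphologically closed detected
  stain (closing radius 2 px, components ≥ 50 µm²); a component touching a
  lumen within 1 px is *perivascular*, otherwise a *bridge*; the rest of
  tissue is *parenchyma*. Deriving connective tissue from the stain mask is
  a declared convention: nothing else in a brightfield PSR image delineates
  it. Sub-threshold connective specks count as parenchyma, so faint
  parenchymal stain still contributes there.
* **Lung** — Euclidean distance bands of `band_um = 25` µm around air-duct
  and vessel structure masks (from an annotation label map), measured from
  the structure wall with pixel-centre distances; overlaps resolve to the
  nearer structure, exact ties to the peri-air-duct ROI; the rest is
  parenchyma.
* **Kidney** — inner medulla, outer medulla and cortex are ingested from a
  manual label map (the package validates rather than draws); within the
  cortex, qualifying lumens plus a `vessel_rim_um = 10` µm rim form the
  *large cortical vessels* ROI, the remainder is *vessel-free cortex*, and
  the two sub-ROIs record `parent = "cortex"` so hierarchical additivity
  can be reported. For the kidney the quantified domain is the labelled
  compartment map (which includes enclosed vessel lumens), mirroring manual
  morphological delineation.

After exclusion handling, ROI labels partition the quantified domain
exactly — this is what makes the percentage identities below hold to
machine precision. All areas are `pixel count * px_size_um^2`.

## Fiber morphometry (PSR_MORF)

Detected stain is split into fragments by seeded watershed: seeds are
local maxima of the optimized signal separated by at least
`seed_min_distance_px = 5`, and flooding proceeds by descending quantized
intensity (quarter-levels, FIFO within a level; a popped pixel takes the
label of its highest-signal labelled neighbour, lowest index on ties).
Connectivity is 4-connected throughout the package. Fragments below
`min_segment_px = 4` merge into their largest touching neighbour or are
dropped when isolated. The segmentation is deterministic and its pixels
partition the mask minus dropped specks.

Each segment gets a mean optimized signal and a *closure density* — its
pixel count over that of its footprint closed with radius 2 px, a fill
ratio in `[0, 1]` that operationalises "loose". A segment is **compact**
iff `mean_signal >= 96` *and* `density >= 0.6`, else **scattered**; ties
classify compact. The intensity cutoff is again the midpoint rule: midway
between the saturated-stain signal (107.3) and the minimum signal a
detected core can carry (the detection threshold, 84). A cutoff at or
below the detection threshold would sit inside the weak-segment
distribution and make that classification arbitrary.

A known limitation: because watershed pieces are locally solid, the density
criterion is rarely decisive at defaults — the class split is carried
mainly by mean signal. Density matters for large unfragmented loose
structures and for user-lowered `seed_min_distance_px`.

## Metrics

With `A_roi` a ROI's area, `A_tt` total tissue area, `S_roi` stained area
in the ROI and `S_tot` total stained area:

* relative ROI area `= 100 * A_roi / A_tt` — sums to 100 over a partition;
* in toto CPA `= 100 * S_tot / A_tt`;
* collagen proportion (CP) `= 100 * S_roi / S_tot` — sums to 100 over a
  partition whenever `S_tot > 0`; undefined (NA with a warning, never 0)
  when nothing was detected;
* ROI CPA `= 100 * S_roi / A_tt` — shares its denominator with in toto
  CPA, so ROI CPA values sum exactly to it.

The same four metrics are emitted per fiber class; compact + scattered
equal the all-fibers values by construction, and within each ROI the two
class shares of stained area are complementary. Percentages are stored at
full precision and rounded to two decimals only at CSV export. Doubling
`px_size_um` scales every area by 4 and leaves every percentage unchanged.

## The phantom generator

`generate_phantom()` renders a deterministic synthetic section: a
picric-yellow tissue ellipse on a white canvas, red collagen strokes of two
classes (compact: thick, saturated, gently curved; scattered: thin,
moderately coloured, drawn as tight zigzag meanders whose concavities are
at the closing-radius scale), carved lumens, erythrocyte-like red-orange
blobs and off-white gaps as artifact traps, with per-fiber colour jitter.
Strokes are anti-aliased by analytic coverage; an edge pixel belongs to
ground truth iff its coverage is at least 0.5. A fixed seed gives
bit-identical output and the caller's RNG state is restored. Organ presets
lay out the matching ROI vocabulary (liver rings around every lumen plus
parenchymal bridges; lung ducts/vessels with 25 µm bands; nested kidney
compartments with cortical vessels), and a `target_cpa_pct` mode adds
compact strokes until a requested ground-truth CPA is reached (overshoot
at most one stroke). A `class_layout = "split"` mode confines the two
fiber classes to disjoint tissue halves, emulating the regional
organization of dense septa versus loose interstitial collagen; it is the
appropriate layout for class-recovery checks, since fibers of different
classes crossing each other produce mixed watershed segments that no
segment-level classifier can split.

What the phantom does *not* emulate: scanner noise and shading, stain
batch variation, real tissue texture, nuclei, or compression artifacts.
Passing phantom tests therefore demonstrates the geometry and arithmetic
of the method — detection margins, region rules, metric identities,
class separation — not robustness to acquisition variation, which requires
per-deployment threshold calibration on real patches.

The default faint-fiber colour (210,140,110) is deliberately below any
admissible optimized-detection threshold (its green level exceeds its
red-green contrast, so the counterstain veto excludes it). Such wisps are
the hard sensitivity case: the simple detector can only reach them by
accepting every erythrocyte first, which is exactly the trade-off the
sensitivity comparison measures. Class-recovery phantoms instead use a
moderately stained scattered colour (interior signal ~90, inside the
detectable window), since the two-class morphology operates on detected
stain.

## Numerical conventions and degenerate inputs

* Rasters are row-major, origin top-left, pixel-centre distances.
* 4-connectivity everywhere (components, holes, flooding, collars).
* Filters return real-valued images; rounding half-up happens only at
  8-bit export.
* Additivity identities are asserted to 1e-9 relative tolerance; analytic
  disc/annulus areas to 2–3% (discretization).
* Degenerate inputs have defined behaviour: empty tissue and zero-area
  denominators are hard errors; zero detected stain makes CP undefined
  (NA); `brightness_cutoff > 255` warns and takes the whole frame;
  identical calibration populations warn and return their common mean;
  zero noise weights reduce PSR_OPT to thresholded red-green contrast.

## Validation problem sizes

The test suite runs entirely on generated data: 320–448 px phantoms
(0.16–0.22 mm at 0.5 µm/px) for end-to-end runs, 20 seeds for the
additivity property, 10 seeds for the sensitivity-ordering comparison, and
≤ 128 px instances for the brute-force oracle equivalences (per-pixel
distance bands, level-sweep flood assignment). These sizes were chosen so
every geometric feature (band widths, fiber widths, lumen rims) spans
many pixels while the whole suite stays fast enough to run on every
change.
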