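---
title: "Methods: dNBR burn-severity mapping and RSEI ecological assessment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dNBR burn-severity mapping and RSEI ecological assessment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(burnsev)
```

## The mapping model

Burning removes photosynthetic canopy: near-infrared reflectance falls and
shortwave-infrared reflectance rises over char, ash and exposed soil. The
Normalized Burn Ratio,

$$NBR = \frac{\rho_{nir} - \rho_{swir1}}{\rho_{nir} + \rho_{swir1}},$$

is therefore high over healthy forest and low over burns, and the
pre-/post-fire difference $dNBR = NBR_{pre} - NBR_{post}$ is close to zero
over unchanged land and increasingly positive with burn severity. Working
on the difference rather than a single date suppresses permanently dark
surfaces (water, terrain shadow) whose single-date NBR mimics burns. The
assumptions are the usual ones for bitemporal index differencing: the two
scenes are co-registered surface-reflectance products on the same grid, and
phenology between the two acquisitions is comparable (the package expects
inputs composited accordingly and performs no temporal processing itself).

### Two-stage Otsu decision tree

Severity is classed by thresholding dNBR twice with Otsu's criterion.
For a histogram with bin probabilities $P_i$ ($\sum_i P_i = 1$), a split at
bin $t$ divides mass into $C_0$ (bins $\le t$, probability $\omega_0$, mean
$\mu_0$) and $C_1$ (probability $\omega_1 = 1-\omega_0$, mean $\mu_1$), and
the chosen split maximizes the between-class variance

$$\sigma_b^2(t) = \omega_0(\mu_0-\mu_T)^2 + \omega_1(\mu_1-\mu_T)^2
               = \omega_0\,\omega_1\,(\mu_0-\mu_1)^2 .$$

The decision tree applies this twice: stage 1 on all valid (optionally
water-masked) pixels yields `threshold1`, and pixels with
$dNBR \ge$ `threshold1` become *heavily burned* (forest loss); stage 2
repeats the scan on the remaining pixels only, and $dNBR \ge$ `threshold2`
marks *mildly burned* (fire-traced) land, the rest unburned. Because stage
2 sees only values strictly below `threshold1`, the ordering
`threshold1 > threshold2` is structural. Both thresholds are data-adaptive;
nothing is hand-tuned per scene.

Numerical conventions, chosen once and asserted in the test suite:

* **Bins.** 256 equal-width gray levels over the valid-data min–max range —
  the method's native 8-bit formulation. Class means use bin midpoints, so
  the selected split is invariant under positive affine rescaling of the
  data.
* **Edges.** A value exactly on the histogram's top edge joins the last
  bin; a value exactly equal to a threshold joins the more-burned class.
  The reported `threshold_value` is the upper edge of the selected bin.
* **Ties.** When several splits attain the same $\sigma_b^2$ — which
  happens systematically when the histogram has an empty valley, since
  $\sigma_b^2$ is exactly constant across empty bins — the smallest split
  is taken, for reproducibility. A consequence worth knowing: for strongly
  separated modes the threshold sits at the *lower edge* of the valley, not
  its centre. Any valley split yields the same classification.
* **Degenerate inputs.** Constant rasters, single-occupied-bin histograms,
  or a stage-2 domain with no remaining variation raise errors naming the
  failing stage rather than returning arbitrary thresholds.

### Areas, accuracy, kappa

Pixel counts convert to areas via the pixel footprint
(`pixel_m`² / 10 000 hm²; a 10 m pixel is 0.01 hm²). Agreement with a
reference survey is summarized two ways: the area/count accuracy
$P = (1 - |a-b|/b)\times 100$, a dimensionless comparison of extracted
amount $a$ to reference amount $b$ (negative when $a > 2b$; returned
unclamped), and Cohen's kappa on the pixel confusion matrix,
$\kappa = (P_o - P_e)/(1 - P_e)$. For comparing maps at different
resolutions, `resample_categorical()` aggregates by majority vote with
ties broken toward the higher severity code, so coarsening never silently
erases burn signal; blocks more than half nodata become nodata. Majority
aggregation is this package's choice of rule for the 10 m → 30 m
comparison step.

## The ecological index

RSEI summarizes ecological condition from four indicators computed on a
Landsat-8-style scene: **greenness** (NDVI), **wetness** (the tasseled-cap
moisture component, $0.1511 b_2 + 0.1973 b_3 + 0.3283 b_4 + 0.3407 b_5 -
0.7117 b_6 - 0.4559 b_7$ on OLI bands 2–7), **heat** (land surface
temperature from the statistical mono-window model
$LST = A\,T_b/\varepsilon + B/\varepsilon + C$) and **dryness** (the
bare-soil index SI; the building component of the usual dryness composite
is omitted because burned forest is far from built-up areas). Open water
distorts wetness, so pixels with MNDWI above a configurable threshold
(default 0) are masked before any statistic.

Each indicator is min-max normalized to $[0,1]$ over the shared valid
domain — this equalizes the indicators' leverage without hand-set weights —
then the four-column pixel matrix is centered (no variance scaling beyond
the min-max step) and decomposed by PCA. PC1, which in practice
concentrates the bulk of the joint variance, is the index. Two further
conventions:

* **Orientation.** A principal axis has arbitrary sign, so PC1 is flipped,
  when necessary, to make the NDVI loading positive. For data with the
  expected one-factor structure this forces the full sign pattern
  (wet +, NDVI +, LST −, SI −). NDVI anchors the orientation because
  greenness is the least ambiguous "better ecology" direction.
* **Rescaling.** The oriented PC1 score is min-max normalized again, giving
  RSEI in $[0,1]$ with no percentile clipping. Together with the indicator
  normalization this makes RSEI invariant to any positive affine rescaling
  of the raw indicators (asserted to 1e-9 in the tests). The flip side is
  that RSEI is *relative to the scene*: means from different scenes are
  comparable only to the extent the scenes share their indicator extremes.

Levels are cut on 0.2 intervals (poor, fair, moderate, good, excellent),
half-open on the left and closed at 1; the boundary memberships (0.2 →
fair, 0.6 → good) are computed with exact break comparisons rather than
division, to avoid floating-point misclassing. Pre/post change
$d = RSEI_{pre} - RSEI_{post}$ (positive = decline) is binned at ±0.05 and
±0.2; a fifth class, *significant increase* ($d < -0.2$), completes the
partition that the usual four-bin description leaves open. Transfer
matrices cross-tabulate pre-fire (columns) against post-fire (rows) levels
over a zone — typically one severity class — in hm², with row/column totals
and a per-column "change" margin (column total minus diagonal, the area
that left that level). Conservation (grand total = zone area, margins =
zonal level areas) is asserted property-style in the tests.

## What the synthetic scenes emulate

`make_burn_pair()` plants contiguous blob-shaped burn patches (heavy cores
grown from random seeds, mild rings grown outward from them) in an
otherwise uniform vegetated landscape, then assigns per-class band means
and adds independent Gaussian band noise. The defaults are the package's
fixed study conditions, chosen once:

* class fractions 0.70 / 0.20 / 0.10 (unburned / mild / heavy) — a
  substantial but minority burn, with mild exceeding heavy as is typical;
* noiseless class dNBR values 0 / 0.2 / 0.55, straddling the magnitude of
  adaptive dNBR thresholds reported for real fires (mild cuts in the
  0.07–0.15 range, heavy cuts near 0.3–0.4);
* per-band noise σ = 0.005 reflectance, which propagates to a dNBR class
  separation of roughly ten dNBR-noise standard deviations — separable, but
  honestly noisy.

`make_rsei_scene()` draws a smooth latent condition field $e \in [0,1]$
(rank-uniformized smoothed noise) and constructs bands so that, at zero
noise, all four indicators are *exactly* affine in $e$: the indicator stack
is then rank one, PC1 carries 100% of the variance, and RSEI equals $e$ up
to min-max scaling — a sharp correctness oracle. Band noise (σ = 0.01 in
the recovery tests; thermal noise scaled ×20 to kelvin) perturbs this
structure while leaving the latent field recoverable at $r \ge 0.99$.

What the generator does **not** emulate: topographic and illumination
effects, phenology differences between dates, clouds and shadows, mixed
pixels at burn edges, spatially correlated sensor noise, and any real
radiative transfer. Passing the recovery tests therefore demonstrates the
*algorithmic* correctness of the chain (index → histogram → threshold →
class → area/transfer bookkeeping), not field-accuracy on real imagery,
where scene quality and compositing dominate.

Problem sizes in the shipped tests were picked to exercise the code at
meaningful scale while keeping the suite quick: the end-to-end recovery
runs on 512×512 scenes (≈ 0.26 M pixels), supporting property checks on
64–160 px grids, and the Otsu oracle equivalence on 1 000 random
histograms of up to 64 bins.

## Raster storage

No geospatial raster binding is assumed: grids travel as plain TIFF plus a
JSON sidecar (pixel size, origin, CRS tag, kind, scaling). Categorical
rasters are 8-bit with code 255 reserved for nodata (bit-exact round
trip); continuous rasters store min-max-scaled 32-bit values plus a
validity channel (round trip well inside 1e-7 of the data range). The
package never reprojects; all inputs must arrive co-registered, and
misalignment raises an error naming the offending band.

## Known limitations

* Two severity classes only (plus unburned); no sub-pixel burn fraction.
* The SMW land-surface-temperature coefficients are runtime inputs; the
  identity default (A = 1, B = 0, C = 0) reduces LST to brightness
  temperature over emissivity, which is adequate for relative RSEI work
  but is not a calibrated temperature retrieval.
* Scene-relative RSEI normalization (see above) — cross-scene mean
  comparisons inherit that caveat.
* Water masking uses a single MNDWI threshold; turbid or shadowed water
  may leak through.
* The accuracy statistic $P$ compares aggregate amounts, not locations;
  kappa on the confusion matrix is the locational check.
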