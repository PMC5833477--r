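---
title: "High-content Aldefluor screening: models, parameters and validation"
author: "AldhScreen authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{High-content Aldefluor screening: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(AldhScreen)
```

## The assay and its statistic

Cancer stem cells (CSCs) form a small subpopulation of a tumor cell line
and are commonly marked by elevated aldehyde dehydrogenase (ALDH)
activity, read out with a fluorogenic substrate (Aldefluor) that is
retained in ALDH-active cells. In the high-content version of the assay,
cells in a 384-well plate are co-stained with a nuclear dye, imaged at
10x, and every single cell's reporter intensity is measured. The readout
per well is the *ALDH-high fraction*: the proportion of cells whose
intensity exceeds a cutoff anchored on an enzyme-inhibitor control.

The cutoff is the core statistic of the package. Wells treated with the
ALDH inhibitor DEAB define the staining background; pooling their
single-cell intensities per plate gives

$$T = \bar{x}_{\mathrm{DEAB}} + k \cdot s_{\mathrm{DEAB}}, \qquad k = 6
\text{ by default},$$

with the sample SD ($n - 1$ denominator). A cell is ALDH-high when its
background-corrected intensity is *strictly* above $T$; ties count as low
(the conservative direction: a tie never inflates the CSC estimate).
Several choices here were genuinely open and are worth recording:

* **Pooled cell-level control statistics.** The DEAB mean and SD could be
  computed per control well and averaged, or from the pooled cells of all
  control wells. We pool cells: the gate is a per-plate property, every
  plate carries its own controls, and pooling uses all control cells with
  their natural weights. Per-well gating is available via the
  configuration (`summarizePlate()`), but is not the default.
* **QC floor.** A gate from too few control cells is noise; below
  `minCells = 200` pooled control cells the plate fails QC with an error
  rather than returning a threshold.
* **Zero variance** (degenerate synthetic input) gives $T = \bar{x}$ with
  a warning rather than an error, so that constructed fixtures behave
  predictably.

`gateFraction()` reports the fraction above $T$; an *empty* well is an
explicit error, because "no cells" (a staining or toxicity artifact) must
never be confused with "0 % ALDH-high". `inSilicoSort()` partitions a
cell table at the same cutoff, mirroring a FACS sort, and reports sorted
purity when ground-truth labels are available.

## Image analysis

The imaging module reproduces a standard high-content single-cell
measurement stack. Segmentation of the nuclear channel:
Gaussian smoothing ($\sigma = 2$ px), Otsu threshold, hole filling, then
a distance-transform watershed whose tolerance is 10 % of the maximum
distance value (an h-maxima-style seed suppression) to split touching
nuclei, followed by an area gate (defaults 30-3000 px$^2$ at
0.65 um/px). Otsu always produces a split, even on a noise-only field,
so a contrast guard rejects segmentations whose foreground-background
separation is below 5 background SDs of the smoothed image.

The reporter is cytoplasmic, so "cellular" intensity is measured on the
nucleus dilated by a ring (default 3 um); collisions between
neighbouring rings are resolved by nearest-label assignment. Each cell's
intensity is the mean reporter value over that region minus a single
per-field background scalar (the median over non-cell pixels), floored
at 0. Background is deliberately a scalar: the synthetic fields are
flat, and illumination-field or shading correction for real microscopes
is out of scope. Whether the original instrument software subtracted
background or measured nucleus versus cytoplasm is not documented
anywhere we could rely on; the choices above are explicit parameters
(`ringRadius`, `minContrast`), not hidden constants.

## Tumorsphere detection and TFC

Tumorsphere-formation capacity (TFC) assays seed a limiting single-cell
suspension (100 or 200 cells/well) and count the spheres formed after
7 days. A detected object counts as a tumorsphere when its equivalent
circular diameter $2\sqrt{A/\pi}$ lies in 50-250 um *inclusive* and its
shape factor (circularity) $4\pi A / P^2$ is at least 0.5. Two
interpretation decisions: "size" is read as a length (equivalent
diameter), and "shape factor of 0.5" as a *minimum* circularity --
both the standard usages in high-content morphometry.

Perimeters use the 4-direction Crofton approximation computed from the
histogram of 2x2 pixel configurations. Boundary-pixel counting
systematically distorts circularity (a rasterized circle can score above
1.2); with the Crofton estimate a rasterized ideal circle scores within
about 0.01 of 1 and a filled square within about 0.1 of its true value
$\pi/4 \approx 0.785$. The documented discretization epsilon on the
shape factor is therefore 0.1. Border-touching objects are excluded
because their area and perimeter are truncated. TFC is the passing-count
divided by the seeded count, with an optional percent-of-reference
(DMSO or lipid-only) rescaling.

## Screen statistics

Plate-level analytics follow screening practice:

* **Toxicity masking.** Wells whose cell count is reduced by strictly
  more than 50 % relative to the neutral (DMSO) control aggregate are
  masked; a reduction of exactly 50 % is not masked. Masked wells can
  never be hits.
* **Normalization.** The ALDH-high fraction is rescaled so the neutral
  control is 0 % effect and the full-effect control (DEAB, or the
  ALDH1A3-siRNA control in knockdown screens -- the roles are
  configuration, `screenConfig()`) is 100 %. Values outside [0, 100]
  are legitimate over-normalization and only flagged beyond +/-150.
* **Hit calling** operates on the neutral-relative scale, not the
  normalized scale: a hit needs a strict > 25 % reduction of the
  ALDH-high fraction versus the neutral control. The rule is stated
  before normalization in screening workflows and the two scales differ
  whenever the full-effect anchor is nonzero; both numbers are reported
  per well.
* **Control aggregation** defaults to the per-plate median (robust to a
  single bad control well); mean is available by configuration.
* **Fast-acting triage.** A compound that abolishes the reporter signal
  within 2 h and whose effect reverses after wash-off behaves like a
  direct enzyme inhibitor, not a CSC-maintenance inhibitor, and is
  flagged as a likely false positive. The thresholds (2 h effect >= 75 %,
  post-wash-off effect < 25 %) are explicit configuration defaults
  patterned on the DEAB exemplar (~94 % reduction within 2 h, full
  rebound); they are not constants of nature.
* **Quality control.** The robust Z' factor is
  $1 - 3(1.4826\,\mathrm{MAD}_{pos} + 1.4826\,\mathrm{MAD}_{neg}) /
  |\tilde{x}_{pos} - \tilde{x}_{neg}|$ -- the median/scaled-MAD analogue
  of Z'; MAD was chosen over IQR as the spread estimator, the standard
  construction. Equal control medians are a QC failure reported as
  $-\infty$. Signal-to-background is the ratio of the neutral to the
  full-effect aggregate fraction, with a $+\infty$ sentinel when the
  background is exactly zero.

## Dose-response fitting

IC50s come from the four-parameter logistic
$y = b + (t - b)/(1 + (x/\mathrm{IC50})^{h})$, fitted by bounded
Levenberg-Marquardt least squares with the IC50 optimised on the log10
scale. Initialization is multistart (IC50 at the dose quartiles, Hill
slope at +1 and -1) and the lowest-RSS converged start wins. Bounds keep
the asymptotes on the percent scale (bottom in [-20, 50], top in
[50, 150]) and the IC50 within two decades of the tested dose range. A
flat response, or a fitted |Hill| below 0.05, is reported as
non-identifiable (`converged = FALSE`) instead of a forced fit -- a
screening pipeline must distinguish "no dose dependence" from "IC50 =
something". Fits are refused below 4 distinct doses.

## The synthetic-data generator

Every stage is validated against synthetic data with exact ground truth,
generated by the package itself and serialized next to the data (tests
never re-derive truth from images).

* **Intensity mixtures.** A population is a two-component Gaussian
  mixture: background (ALDH-low) cells at `bgMean = 500` a.u. with
  `bgSd = 50` (a 10 % CV typical of a well-stained field), and ALDH-high
  cells shifted `highShift = 8` background SDs above the background
  mean. Intensities are truncated at zero by *resampling* rather than
  clipping, so the realized moments stay close to nominal. The high
  population's absolute spread defaults to `highSd = bgSd / 2`: the
  generator is designed so that at the reference shift of 8 the $k = 6$
  gate sits four high-population SDs below the high mode, which makes
  fraction recovery binomial-limited (misclassification
  $\Phi(-4) \approx 3\times10^{-5}$) and the two populations' ranges
  essentially disjoint. With an equal spread the gate would clip 2.3 %
  of genuinely high cells and the recovery error would no longer be
  dominated by sampling -- a different, and for validation less useful,
  regime.
* **Fields.** Nuclei (6 um radius at 0.65 um/px, a 10x confocal
  geometry) are placed by rejection sampling with a hard minimum
  separation (default 24 um) and a cap of $10^4$ attempts per nucleus;
  failure to place is an error, never silent under-placement. The
  reporter value of each cell is painted over its nucleus dilated by the
  measurement ring plus a 3-px guard, so that on noise-free fields the
  measurement path recovers painted values exactly; blur and
  non-negative additive noise are applied on top. The painted-footprint
  construction is also why the default separation is 24 um: footprints
  must be disjoint for the exactness property to be testable.
* **Spheres** are filled axis-aligned ellipses parameterized by
  equivalent diameter and elongation (area-preserving), with true shape
  factors computed from the numeric ellipse perimeter; debris is drawn
  below the 50 um filter. Sphere overlap is rejected at specification
  time.
* **Plates.** A plate spec maps wells to roles, compounds and doses,
  with per-well mixture overrides and a toxicity map of cell-count
  multipliers. DEAB wells are always generated with a zero high
  fraction -- enzyme inhibition abolishes reporter retention regardless
  of the biology. Each well draws from its own substream seeded as
  *plate seed + row-major well index*, so any well is reproducible in
  isolation and removing a well never changes the others.
* **Dose-response curves** are the 4PL closed form plus Gaussian noise.

What the generator deliberately does *not* emulate: heavy-tailed
intensity distributions (real Aldefluor backgrounds have them -- which is
why real screens report finite signal-to-background ratios while the
Gaussian model drives the DEAB-well gated fraction to essentially zero
and S/B to the infinite sentinel), illumination gradients and vignetting,
out-of-focus debris, cell clumping beyond the separation limit, mitotic
and dead cells, and 3D spheroid structure. Passing the validation suite
therefore demonstrates the correctness of the *computational* pipeline
under its stated model, not robustness to every real-microscope
artifact.

## The reference screen scenario

`screenScenario()` builds the package's end-to-end validation plate: 16
DMSO and 16 DEAB control wells, 352 single-compound sample wells at
5000 cells/well (roughly four imaged fields at 10x), a 5 % baseline
ALDH-high fraction, and planted ground truth -- 10 true suppressors at
half the baseline fraction (a 50 % reduction), 5 fast-acting enzyme
mimics at a DEAB-like 94 % apparent reduction, and 20 toxic wells at a
0.4 cell-count multiplier. `followUpEffects()` generates the matching
2 h and wash-off experiments through the same gating path. The
acceptance suite asserts that masking, hit calling and fast-acting
triage recover exactly the planted classification; at 5000 cells/well
the 25 % hit boundary lies about four binomial SDs away from a neutral
well's sampling noise, which is what makes an exact-recovery assertion
meaningful.

## Numerical conventions and problem sizes

Strict inequalities are used exactly where stated (gate: intensity
$> T$; masking: count $< 0.5 \times$ reference; hits: reduction
$> 25\,\%$), with inclusive sphere-filter boundaries. Well coordinates
are letter row A-P plus two-digit column 01-24; indices are row-major
A01 = 1 .. P24 = 384. CSVs are UTF-8, comma-separated, '.' decimal;
every output table carries `#`-prefixed header lines echoing the tool
version, a configuration fingerprint and the gate parameters. All
randomness flows from a single configured seed.

The validation suite runs at deliberately chosen sizes: $10^4$-cell
wells for recovery properties (100 replicates per planted fraction),
$10^5$ background cells per seed for the null-gate calibration (100
seeds), seven 640-px fields for the image-vs-table equivalence check,
and the full 384-well scenario above for the end-to-end screen. These
sizes put the binomial error bars well inside the decision boundaries
being tested while keeping the whole suite runnable on a laptop in
about a minute.

## Known limitations

Single-plate analytics only: no multi-plate batch correction, B-score or
spatial detrending, and no FDR control across compounds -- the screen is
a single-plate rule-based design. The 4PL fit reports per-fit RSS but no
confidence intervals. Sphere elongation is axis-aligned in the
generator (detection itself is orientation-agnostic). The imaging module
assumes flat illumination and well-separated or moderately touching
nuclei; heavily confluent cultures would need a more elaborate
segmentation than the distance-transform watershed used here.
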