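---
title: "Models and methods behind spheroidq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind spheroidq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spheroidq)
library(dplyr)
```

spheroidq quantifies collective behavior in tumor spheroid co-cultures of
drug-sensitive and drug-resistant cancer cells: radial cell-sorting of the
resistant population to the spheroid shell, population-level
chemoprotection, junction-marker redistribution, and collective invasion
into collagen, together with the plate-level (dose-response, growth) and
molecular (qPCR, densitometry) measurements that characterize the
subclones. This vignette explains the models, the tunable parameters, the
synthetic benchmark, and the numerical conventions — including where a
design question was genuinely open and what we chose.

## Dose-response and fold-resistance

Viability from an MTT plate is `A560 − A690` per well, minus the mean
blank net absorbance, divided by the mean untreated net absorbance within
each experimental replicate; technical replicates are averaged before any
fitting. The dose-response model is the conventional three-parameter
inhibition curve with unit Hill slope,

$$V(c) = \mathrm{bottom} + \frac{\mathrm{top} - \mathrm{bottom}}{1 + c/\mathrm{IC}_{50}},$$

fitted by Levenberg–Marquardt least squares to each experimental replicate
independently, in log-dose space with the IC50 parameterized as
$\log \mathrm{IC}_{50}$ for conditioning. Initialization is top = maximum
response, bottom = minimum response, IC50 = the dose nearest the
half-range; the optimizer runs to minpack's relative-change tolerance
(≈1.5e−8) with a 500-iteration cap, and a failed or flat fit is flagged
non-convergent rather than reported. An IC50 outside the tested dose
range is flagged `extrapolated`. Replicate IC50s are summarized as
mean ± SEM; `fold_resistance()` is the plain ratio of two IC50s.

A note on precision: with ~5% well noise on an 11-point 3-fold dilution,
the sampling SD of a single experiment's recovered IC50 is about 7% even
with six technical replicates — the bottom parameter trades off against
the IC50. The recovery tests therefore average over several simulated
experiments, and the long-run bias check uses the geometric mean, since
the fit estimates $\log \mathrm{IC}_{50}$.

Doubling times come from the logistic growth model
$K/(1+e^{-r(t-t_0)})$ fitted to confluency (%) time courses; the reported
doubling time is the exponential-phase value $\ln 2 / r$. Constant or
decreasing series are flagged non-convergent. `K` is bounded by 100%
confluency.

## Chemoprotection

For a co-culture seeded at ratio $w$ (e.g. 3:1), the expected viability at
each dose is the ratio-weighted linear combination of the mono-culture
mean viabilities, $E = \sum_i w_i V_i / \sum_i w_i$, and the
chemoprotection coefficient is $C_{O/E} = O/E$ with $O$ the observed
co-culture viability. $C_{O/E} = 1$ is exactly the independent-action
null; values above 1 mean the mixture survives better than its parts.

Design choices the source material leaves open:

* Expected viability uses mono-culture *means* per dose, not per-replicate
  pairing — there is one expected curve per condition.
* The SEM of $C_{O/E}$ is propagated from the observed and expected SEMs
  by the first-order delta method.
* Doses where the expected viability is below 2% of control, *or*
  statistically indistinguishable from zero (within 3 SEM), are flagged
  `unstable`: the ratio is ill-conditioned there and its delta-method SEM
  unreliable. Flagged doses are reported, not dropped.

## Radial profiling and the cell-sorting statistic

For each spheroid image the mask is detected on the brightfield channel
(Gaussian smoothing, global Otsu threshold, largest connected component,
hole fill), background is estimated as the median intensity outside 1.5x
the mask's equivalent radius and subtracted *without clipping* (so
background noise cancels in annulus means instead of accumulating with
annulus area), and the tracker-dye channel is averaged in concentric 1-px
half-open annuli $[r, r+1)$ about the intensity-weighted centroid, out to
the nearest image border. The profile conserves total intensity exactly:
$\sum(\text{annulus mean} \times \text{annulus pixel count})$ equals the
image sum over covered pixels.

The spheroid radius is the distance enclosing 95% of the total profile
intensity (linear interpolation within the crossing annulus); for a
uniform disk this is $\sqrt{0.95}\,R$. The per-type radius is the mean
enclosure radius over spheroids (a per-spheroid option exists). Profiles
are normalized in distance by that radius and in intensity by the center
estimate, then resampled to 100 uniform bins on [0, 1.2]. The sorting
readout is the normalized intensity at normalized distance 0.77 — the
edge/center ratio, since the center is 1 by construction.

Two numerical choices matter here:

* **Center region.** The center intensity is the pixel-weighted mean of
  the annuli within the innermost 20% of the spheroid radius. A
  single-pixel center is noise-dominated; more importantly, for a
  sparse-label disk (a few hundred labeled cells), even a few-percent
  region contains roughly one labeled cell, making the normalization
  denominator a near-Poisson(1) variable and biasing the ratio upward by
  tens of percent. The 20% region keeps the readout position (0.77) far
  outside the center region while giving the denominator enough cells.
* **Order of averaging.** Per-type mean profiles are formed by pooling the
  raw profiles annulus-by-annulus across spheroids *first* and
  center-normalizing the pooled profile (the default); the headline
  edge/center ratio is read from this pooled profile, which removes the
  small-denominator bias of per-spheroid normalization. Per-spheroid
  normalized profiles are still computed and supply the SEM (and a
  `normalize_first` averaging option is exposed).

## PI death score

Spheroid death is the integrated propidium-iodide intensity over the
detected spheroid area, divided by the mean of the same quantity over
untreated control wells. Empty masks and non-positive control integrals
are errors, not silent zeros.

## Junction enrichment

Nuclei are segmented from DAPI (smoothing, Otsu, watershed on the distance
transform, minimum-area filter); cell outlines grow from the nuclei over
the marker foreground with the CellProfiler propagation algorithm. The
foreground threshold is a *three-class* Otsu on log intensity, keeping the
middle and upper classes: once junctions are bright, within-cell intensity
is bimodal and a two-class split would cut through the cells instead of
separating them from background.

Per cell, the edge band is the outline expanded by 2 px minus the outline
shrunk by 7 px; the shrunken cytoplasm is the remainder. Expansion and
shrinkage are per-cell Euclidean distance-transform thresholds (erode:
interior distance > 7; dilate: exterior distance ≤ 2.5 — the half pixel
corrects pixel-center vs region-edge distance, calibrated against the
analytic annulus area of a disk cell, residual error < 0.1% at R = 30 px).
Background pixels reachable by several dilated outlines go to the strictly
nearest cell (first label on exact ties). Excluded from statistics, with
warnings so exclusions are auditable: cells emptied by the shrinkage,
cells touching the image border, cells whose edge band borders empty
substrate (colony rim — their junction readout is diluted by background),
and cells with zero cytoplasmic signal. The enrichment result is the
per-cell edge/cytoplasm mean-intensity ratio and its field mean; a
configurable warning fires below 160 analyzed cells per field.

## Collagen invasion

A "continuous invasive sheet" is operationalized as an above-threshold
connected component of the tracked-population channel that touches the
(slightly dilated) boundary of the initial, pre-embedding spheroid mask
and exceeds 50 px in area. Per sheet, the end distance is the maximum
Euclidean distance from the spheroid center over the sheet's pixels. The
statistic averages the three largest end distances (ties broken by
component area, then label — deterministic) and divides by the starting
diameter, defined as twice the equivalent radius of the t = 0 mask. With
fewer than three sheets the available ones are averaged and flagged; a
spheroid with no sheets scores the center-to-boundary floor 0.5 and is
flagged `no invasion`, keeping the statistic defined for every spheroid.

## Molecular quantification

Technical replicates are combined by the arithmetic mean of Ct (not of
$2^{-Ct}$), per analysis repeat. Copy number follows
$\Delta C_t = C_{t,\text{target}} - C_{t,\text{reference gene}}$,
$n_{rel} = 2^{-\Delta C_t}$, and
$n_{abs} = n_{rel}/n_{rel,\text{diploid reference}} \times 2$; the diploid
reference sample evaluates to exactly 2 in every analysis, and spread over
analysis repeats is reported as SEM. Amplification efficiency is fixed at
2 (exponential amplification assumed); no efficiency correction in this
version. Expression uses the standard $\Delta\Delta C_t$ fold change
against a calibrator sample, and densitometry normalizes band intensity to
protein loaded per lane and then to the control sample.

## The synthetic benchmark: what it emulates, and what it does not

Every stage has a paired generator whose randomness flows from one
explicit seed per call (the global RNG state is saved and restored), so
identical spec + seed gives bit-identical output.

* **Spheroids** are 2D disks of `n_cells` (default 2000, 25% labeled)
  placed area-uniformly; sorting is implemented by rejection-sampling
  labeled-cell radii with weight $e^{s\,\mathbf{1}[r \in \text{band}]}$
  (default band [0.7, 1]), so the in-band/out-of-band placement density
  ratio is $e^s$ — monotone in `s`, with $s=0$ the exact well-mixed case.
  Cells render as isotropic Gaussians ($\sigma$ = cell radius / 2),
  matching blurred cytoplasmic fluorescence; additive Gaussian noise is
  clipped at zero for images.
* **Protection tables** evaluate the three-parameter curves in closed
  form; in shielding mode the sensitive co-culture component sees
  dose / attenuation (attenuation 1 reduces to independence). Replicate
  noise is *not* clipped at zero — background-subtracted viabilities can
  dip below zero, and clipping would bias near-zero means upward and
  thereby deflate both $C_{O/E}$ and fitted IC50s.
* **Monolayers** are colony patches: seeds dart-thrown with a minimum
  spacing inside a centered disk, cells the nearest-seed regions within
  reach, a marker band elevated by $(1+e)$ within 2 px of any outline,
  and nuclei disks at the seeds. The background margin around the colony
  is what foreground detection segments against; requests too dense to
  tessellate are rejected.
* **Invasion fields** are a central disk plus radial rectangular sheets at
  evenly spaced angles ending at prescribed distances.
* **Ct tables** place the target Ct at
  $C_{t,\text{ref}} - \log_2(\text{copy number}/2)$ plus noise, so the
  ΔCt chain recovers the truth against a diploid reference.

The attenuation factor is a test construct, not a mechanistic claim about
drug transport: it produces the qualitative signature (protection
appearing only in the shielded geometry, growing with dose) without
modeling diffusion or consumption. Likewise the generators omit optics
(PSF, photobleaching, vignetting), 3D structure and projection (a real
spheroid image integrates signal through its depth, so real center
intensities are far less sparse than the 2D-disk benchmark), cell shape
and contact mechanics, and Poisson photon noise. Passing the recovery
suite therefore demonstrates that the *estimators* are correct and
well-calibrated on data satisfying their assumptions — not that those
assumptions hold for any particular microscope.

## Problem sizes and conventions

Tests run the sorting recovery at 20 spheroids (ratio 3) and 50 spheroids
(well-mixed null) of 2000 cells at radius 100 px in 256² images; the
uniformity χ² property uses 800 cells over 50 seeds; junction fields use
40 cells in 320² images; recovery invariants use 100 seeds. These sizes
were chosen to estimate each property's sampling error well below its
tolerance. Coordinates are pixel-space, origin at the top-left pixel
center, x right and y down; annuli are half-open $[r, r+1)$; all tabular
interchange is long-format CSV (`well`, `condition`, `dose_M`,
`replicate`, `value`), with a converter from wide 8x12 layouts; images
are multi-page TIFF with channels mapped by page order; every
`run_pipeline()` stage writes a JSON provenance record (config hash, seed,
package version, timestamp) and a log that records excluded
wells/cells/spheroids with reasons.

## Known limitations

* The three-parameter fit fixes the Hill slope at 1; steep or shallow
  response data will show lack of fit rather than a slope estimate.
* $C_{O/E}$ is a ratio of means: at doses where the expected viability
  approaches assay noise it is ill-conditioned; such doses are flagged,
  and its SEM is a first-order approximation.
* The sorting statistic assumes an approximately radially symmetric,
  roughly circular spheroid; fragmented or strongly elliptical aggregates
  violate the annulus model.
* ΔCt arithmetic assumes perfect doubling per cycle; no amplification
  efficiency correction is provided.
* The edge/cytoplasm morphology operates at fixed pixel offsets (2/7 px),
  so results depend on magnification; there is no physical-unit
  conversion unless a pixel size is supplied.
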