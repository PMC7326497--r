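---
title: "Quantifying lipid-kinase activity on giant unilamellar vesicles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying lipid-kinase activity on giant unilamellar vesicles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(guvkin)
```

## The measurement

Giant unilamellar vesicles (GUVs, radii of roughly 1--30 µm) incubated with a
PI 3-kinase and a fluorescent PI(3)P-binding reporter domain are imaged on a
confocal microscope in two channels: a membrane dye that delineates each
vesicle as a bright ring in the equatorial cross-section, and the reporter,
whose accumulation on the ring tracks PI(3)P production. Frames are acquired
every 2--3 min for an hour or more. The quantity of interest is the *initial
rate*: the slope (AU/min) of the reporter's membrane intensity during the
linear phase of its progress curve, one rate per vesicle, with vesicles as
replicates. Conditions (enzyme variants, lipid compositions) are compared by
the ratio of their mean rates and Welch's t-test.

Two complications shape the whole pipeline. First, unbound reporter and small
lipid particles create a diffuse haze in the reporter channel that rises
*before* enzymatic activity does; it is estimated from GUV-free regions and
subtracted per time point, so corrected traces are legitimately negative
during the lag phase. Second, the membrane is thinner than a pixel: what is
imaged is a diffraction-broadened ring, so the membrane mask must be a band of
calibrated thickness around each vesicle's contour rather than a literal
bilayer.

## Segmentation model

Each frame of each channel is band-pass filtered with a difference of
Gaussians (DoG), which responds strongly to ring-like structures at the
membrane scale and cancels constant backgrounds exactly. The response is
thresholded; the masks of the two channels are OR-ed so a vesicle visible in
either channel contributes; ring interiors are filled; an *internal
morphological gradient* (the filled region minus its erosion by a disc of
`k = round(thickness / pixel size)` pixels) produces a contour band of
calibrated thickness; and the band is intersected with the original
segmentation so spurious signal inside the vesicle is discarded. Connected
components of the filled mask (8-connectivity) become vesicle regions;
components smaller than `min_radius_um` or with circularity
$4\pi A / P^2 < 0.7$ (typically touching vesicles merged into one blob) are
discarded, mirroring manual curation. Segmentation contains no randomness.

Numerical choices worth stating:

* **Threshold.** Otsu's method on the DoG response histogram, *guarded by a
  robust noise floor* of median + 6 scaled MADs of the response. Otsu always
  splits a histogram, so on a frame with no true signal (the reporter channel
  during the lag phase) it would return a dense mask of noise pixels; the
  floor keeps such frames empty while leaving genuine rings (whose response
  sits far above 6 MADs) untouched. A fixed numeric threshold can be
  configured instead.
* **DoG scales.** Defaults are tied to the geometry:
  $\sigma_s = 0.5\,\cdot$ thickness/pixel size and $\sigma_l = 3 \sigma_s$.
  Filtering uses mirrored boundary handling.
* **Smoothing.** The classical "open before filling" step defaults to *off*
  (`smooth_radius_px = 0`). At Nyquist-limited sampling (0.25 µm/px, 0.5 µm
  membrane band) the detected ring is only about two pixels wide, and opening
  with even the smallest 3 x 3 structuring element erases such a ring
  completely, destroying the vesicle. The noise-floor guard already performs
  the despeckling that opening was meant for; opening remains available for
  oversampled data.
* **Radius.** The filled section's equivalent radius $\sqrt{A/\pi}$ tracks
  the *outer* edge of the band and so overestimates the vesicle radius by
  about half the band width -- material for small vesicles. The reported
  radius is therefore the algebraic (Kåsa) least-squares circle fit through
  the membrane-band pixels, i.e. the band midline; the equivalent radius is
  kept alongside. Curvature is `1 / radius_um` of the fitted circle, the 2-D
  section quantity, not a 3-D mean curvature.
* **Per-frame masks, frame-fixed regions.** Every frame is re-segmented, but
  vesicles are identified once on a reference frame (the first, where the
  membrane dye is already at full brightness) and each vesicle's measurements
  are taken inside a fixed disc of 1.5 x its radius -- tracking-free, since
  the assay's vesicles are immobilized. A configuration switch reuses the
  reference band for all frames instead.

## Quantification and kinetics

The trace value is the plain mean over the membrane-band pixels in the
region's disc, per channel and frame; an empty intersection yields a flagged
`NA`, never a silent zero. The haze baseline is the unweighted average of the
temporal profiles of ten GUV-free discs (each region contributes one profile
regardless of area) and is subtracted from the reporter traces only; the
membrane-dye channel is never baseline-corrected. `corrected + baseline ==
raw` is asserted on every run.

The linear phase is located automatically: among all contiguous windows of at
least `min_points = 4` samples whose ordinary-least-squares fit reaches
$R^2 \ge 0.95$ *and* whose values are not constant, the window with the
maximal slope is chosen, ties broken towards longer windows and then earlier
starts. If no window qualifies (flat or hopelessly noisy traces), the
best-slope minimal window is returned flagged `low_confidence`. A manual
window can be passed instead, which reproduces hand-selected regions exactly.
This estimator has a known, deliberate property: picking the maximum slope
over many short windows is upward-biased by noise, by roughly the slope
standard error of a minimal window. The synthetic study conditions (below)
are scaled so this bias stays small relative to the slowest condition.

Fold changes are ratios of group means over per-vesicle rates; group
comparisons use Welch's two-sided t-test with no multiple-testing correction,
matching the pairwise reporting style of GUV assays. Both SD and SE summaries
are available from `compare_rates()` output.

## The forward model

The simulator exists so that every downstream stage is testable with exact
ground truth. Per vesicle it renders an annulus of width
`membrane_thickness_um` (default 0.5 µm): constant brightness in the dye
channel, and in the reporter channel the piecewise progress curve

$$ s(t) = \min\!\big(\max(t - t_{lag}, 0)\, r_{\mathrm{eff}},\; s_{max}\big),
   \qquad r_{\mathrm{eff}} = r + b / R, $$

plus a spatially uniform haze $B(t) = B_{max}(1 - e^{-t/\tau})$ with
$\tau < t_{lag}$ so the haze leads the activity. The curvature coupling $b$
(AU·µm/min) makes smaller vesicles accumulate faster, the mechanism probed by
the curvature analysis. Frames are optionally blurred with a Gaussian PSF and
degraded with scaled-Poisson shot noise (`Poisson(gain * x) / gain`) plus
Gaussian read noise, negatives clipped. Identical seeds give bit-identical
stacks.

What the generator deliberately does **not** emulate: photobleaching,
reporter-binding equilibria, vesicle drift or fusion, 3-D geometry (the assay
analyses equatorial sections and maximum projections), and non-uniform haze.
Passing tests therefore demonstrate correctness of the *measurement
machinery* under the stated forward model, not robustness to every artefact
of real microscope data.

### Fixture scenes and their scales

The registry `guv_fixture()` encodes one scene per condition of the assay's
headline comparisons, with ground-truth rate *ratios* fixed to the reported
fold changes (7; 7 and 11; 1.8 and 1.2; 1.7 and 1.0; plus the curvature sign
pattern and the PS-charge series). Two deliberate choices:

* **Absolute rates are scaled for measurability.** Arbitrary-unit scales
  carry no information, only ratios do. The slowest condition is set to
  1 AU/min and everything else follows from the ratios. A power argument
  fixes the noise model: with photon gain 50 counts/AU, read noise 1 AU and a
  haze plateau of 100 AU, a membrane band of a few hundred pixels gives a
  per-frame trace error of a few tenths of an AU, hence a minimal-window
  slope error well under 0.1 AU/min -- small against the 1 AU/min floor, so
  the max-slope selection bias perturbs recovered ratios by only a few
  percent.
* **Fixture scenes render crisp annuli (`psf_sigma_um = 0`).** The 0.5 µm
  annulus *is* the PSF-broadened image of a 5 nm bilayer; blurring it again
  would double-count the optics. With a binary annulus, any subset of annulus
  pixels the segmenter selects gives an unbiased band mean, so recovered
  rates are attenuation-free. Generic scenes default to a 0.2 µm PSF and the
  blur path is exercised by the rendering tests.

Problem sizes: fixture movies are 256 x 256 px at 0.25 µm/px (384 px for the
30-vesicle curvature and low-noise profiles), 15 vesicles of radius 2--5 µm
per condition, 25 frames every 2.5 min for 60 min, three simulated wells per
comparison -- comfortably the scale at which the per-well statistics (>= 15
vesicles) match assay practice while keeping a full fold-change study in the
minutes range on one core.

## Input/output conventions

Pixel indices are 1-based `(row, col)`, the R convention, stated once and
used everywhere; lengths are µm, time is minutes, intensities AU. Movies are
stored as plain multi-page TIFF (frame-major, channel-minor) with a JSON
sidecar carrying channel names, time stamps, pixel size and the intensity
scale -- integer data round trip bit-exactly, float data to float32
precision. ROIs use a small text dialect (`id kind shape geometry`).
Acquisition metadata missing from a file must be supplied explicitly and is
logged, never silently defaulted.

## HDX utility

The companion utility implements the standard peptide inclusion criteria
(minimum intensity 5000, length >= 5 residues, >= 0.1 fragmentation products
per residue, |MH+ error| <= 5 ppm, identified in >= 2 of 3 undeuterated
runs), with all boundaries read inclusively; sequence coverage as the merged
interval union over kept peptides; and per-peptide deuterium-uptake
differences between states. The protection/deprotection call uses a
configurable threshold (default 0.5 Da at >= 1 exposure) and is an explicit
stand-in: community guidelines do not fix a single numeric criterion, and no
back-exchange correction or spectral processing is attempted.

## Known limitations

* The max-slope window selection is upward-biased for near-zero rates; truly
  inactive conditions are best summarized as "rate indistinguishable from
  zero relative to an active control" rather than by their tiny positive
  estimates.
* Touching vesicles are discarded (circularity filter), not split; there is
  no watershed step.
* The band mean under a nonzero PSF underestimates the true amplitude by a
  geometry-dependent factor; ratios between conditions are unaffected, but
  absolute AU rates from blurred data should not be compared across optical
  configurations.
* Baseline regions are chosen per field of view; fields dominated by
  vesicles may fail to place ten background discs and will say so.
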