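---
title: "Unfolding and averaging STED images of hair bundles: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unfolding and averaging STED images of hair bundles: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hairbundle)
```

## The problem

Cochlear hair cells carry a bundle of actin-filled stereocilia arranged in
two or three rows of graded height. During development, fibrous "ankle
links" containing the adhesion GPCR ADGRV1 and the scaffold protein PDZD7
connect neighbouring stereocilia, both within a row and between rows.
Two-colour STED microscopy (actin in one channel, an immunolabelled
protein in the other, 40–60 nm planar resolution, 10–25 nm pixels) resolves
where such a protein sits relative to the stereocilia — but hair bundles
are curved, so raw images cannot simply be projected onto an axis.

`hairbundle` implements the semi-automated analysis this problem calls
for:

1. **Detection.** Inside a user-supplied mask of the outer stereocilia
   row, the actin channel is Gaussian-smoothed (σ = 2 px) and all local
   maxima whose topographic prominence exceeds a threshold become
   stereocilium centres. Centres are curated (flagged, never deleted) and
   reordered so consecutive entries are nearest neighbours, starting from
   a bundle extremity.
2. **Unfolding.** An interpolating natural cubic spline through the
   ordered centres is resampled to uniform arc length; both channels are
   resampled along the spline's normals. Transverse distances are
   preserved; distances along the row are distorted (which is why the
   along-row axis of an unfolded image carries no scale). The mean over
   the along-bundle axis, normalized per channel to its maximum, is the
   transverse profile with origin at the outer row.
3. **Averaging.** Each stereocilium's orientation is the outward normal of
   the circumcircle through it and its two closest neighbours. Square
   ROIs (side = 2× the inter-cilium distance) are rotated to a common
   vertical normal, stacked, averaged per channel, and background-
   subtracted by one of three modes. Horizontal and vertical profiles
   through the average read the intra- and inter-row distributions.
4. **Readout.** Actin maxima in the transverse profile give row positions
   and inter-row spacing; protein maxima are expressed as a fraction of
   the inter-row space measured from the outer row. Shoulders (bumps
   without a local maximum) are reported separately and never counted as
   peaks.

Because no raw image data are deposited alongside the reported
measurements, quantitative validation is by parameter recovery: a seeded
synthetic generator renders bundles with exactly known geometry and
labeling, and the pipeline must recover what was put in.

## The synthetic generator and its presets

`make_geometry()` lays out 2–3 rows of stereocilia: OHC bundles on
concentric arcs (the U-shaped bundle, staircase register), IHC bundles on
straight lines. The defaults — cilium radius 150 nm, intra-row spacing
450 nm, row spacing 500 nm, arc radius 2 µm (OHC), 9 cilia per row, 15 nm
pixels, 50 nm PSF FWHM, 200 photons at the brightest actin pixel, read
noise SD 2 — are plausible values for P5 mouse cochlea chosen once for
this package; none is a measurement of the original samples, and every one
can be overridden. Recovery holds across a swept range of band fractions
(0.2–0.8) and a 1.3× global scale change, not only at the defaults.

`render()` draws the actin channel as filled discs and the protein channel
from a preset: rings (circular arcs around stereocilia), inter-row bands
at a stated fraction *f* of the inter-row space, intra-row bridges between
same-row neighbours, each with a Gaussian cross-section of stated FWHM.
A structure's amplitude is normalized to be its expected profile peak
density, so amplitudes of structures with different widths are directly
comparable. Everything is convolved with the Gaussian PSF, scaled to the
photon budget, Poisson-sampled, read-noise-degraded and quantized to
integer counts (so TIFF round trips are bit-exact). Finite `granularity`
replaces continuous structures by a Poisson point process of puncta along
them. The generator emits the mask a user's brush would produce (discs
over the outer row) and the exact ground truth.

Preset constants encode the reported labeling patterns: band fractions
0.36 (IHC extracellular ADGRV1), 0.24 with a weak far-side component
around 0.62 (IHC intracellular), 0.35 (IHC PDZD7), symmetric mid-space
bands in both OHC inter-row spaces (extracellular), and bands flanking
space 1–2 plus one near row 2 in space 2–3 (intracellular; PDZD7 is the
same pattern at a quarter of the intensity). Realization choices worth
stating explicitly:

* **Rings are interior-facing arcs** (240° for the ADGRV1 "rings"/
  "crowns", 180° for the PDZD7 "half-circles"). A full circle would
  project a limb maximum *outside* the outer row, which the reported
  profiles do not show; links physically attach toward neighbours.
* **Bridge amplitudes (2–2.8) exceed band amplitudes (≈1).** Bridges only
  span the gaps between same-row cilia, so along-bundle averaging dilutes
  them by roughly the gap fraction; the chosen amplitudes make the
  intra-row component a clear profile maximum, as observed.
* **The 62 % "shoulder" is a graded ladder** of weak bands (amplitudes
  0.26/0.20/0.14 at f = 0.42/0.58/0.70). A single narrow band 190 nm from
  the main peak would always form its own maximum; a graded decay of
  labeling density toward row 2 reproduces a monotone flank whose
  curvature maximum — the shoulder — sits near 62 % of the space.
* **The kinked central segment** of real bundles is emulated by an
  optional flag displacing the two central outer-row stereocilia outward;
  it exists to test that excluding non-representative cilia improves the
  aligned average.

What the generator deliberately does **not** emulate: 3-D structure and
defocus, depletion-beam physics, chromatic offsets between channels
(channels are perfectly co-registered, as line-interleaved acquisition
approximates), antibody linkage error as a separate term (it is folded
into band width), and tissue background structure. Passing recovery tests
therefore demonstrates correctness of the *analysis geometry and
statistics*, not robustness to every artefact of real tissue.

## Numerical choices

* **Prominence-based detection.** Maxima are ranked by topographic
  prominence (height above the highest connecting saddle), computed by a
  union–find pass over pixels in decreasing intensity order. The default
  threshold is 3× the robust noise SD (scaled MAD) of the masked smoothed
  image; it is scale-free and user-overridable.
* **Plateau maxima.** A blurred uniform disc has a flat top, on which both
  the integer argmax and a 3×3 quadratic vertex are noise-dominated (±3 px
  in practice). Maxima whose near-top region (≥ 90 % of peak) spans more
  than a 3×3 window are therefore placed at that region's
  intensity-weighted centroid — the behaviour of the interactive maxima
  finder this workflow descends from — reducing centre error to ≈ 0.1 px.
  The same logic applies to 1-D profile maxima (≥ 97 % of peak, capped at
  the minimum peak separation): sharp maxima keep the 3-point parabolic
  vertex, broad domes (the projection of a disc row) use the top
  centroid. Without this, row positions carry tens of nanometres of noise.
* **Interior side of the bundle.** Transverse offsets are positive toward
  the bundle interior. For curved bundles the side is taken from the
  global bend of the centre chain, estimated by a quadratic fit in the
  principal-axis frame — pointwise spline curvature is useless here
  because an interpolating spline through noisy centres wiggles locally.
  Below 0.3 rad of net turning the bundle counts as straight and an
  explicit hint (`interior_hint`, default "down") decides. Real curved
  bundles turn by well over 1 rad; noisy straight chains measure < 0.1.
* **Spline and resampling.** Interpolating natural cubic spline
  (smoothing splines would bias offsets), chord-length parameterized,
  inverted to uniform arc length (consecutive sample spacing uniform to
  1 %). Curvature from natural end conditions is unreliable within a few
  knot spacings of the ends. Unfolding and ROI rotation use bilinear
  interpolation about exact sub-pixel positions (non-ringing on noisy
  counts); out-of-image samples are flagged invalid and excluded from
  averages.
* **Default transverse half-width** is 2.5× the mean inter-cilium
  spacing, which covers both 2- and 3-row bundles with margin (1.5× the
  row spacing, an earlier working value, fails to reach the third row of
  an OHC bundle).
* **Peak calling.** Default minimum prominence 0.1 on max-normalized
  profiles; default minimum separation 50 nm (the PSF FWHM). Endpoint
  maxima are never peaks. Shoulders are local maxima of the negative
  second derivative (Savitzky–Golay, window ≈ 2× the minimum separation)
  at least the minimum separation away from any called peak, within the
  0.1–0.95 intensity band, and within a factor 2 of the strongest such
  feature; they are reported with their own positions and never counted
  as peaks.
* **Fractions.** A protein peak at *p* between rows *r_i* < *r_{i+1}*
  reports (p − r_i)/(r_{i+1} − r_i), measured from the outer member of
  the pair. Peaks within 50 nm of a row are intra-row (fraction 0 at that
  row); peaks beyond the outermost rows by more than half a spacing are
  flagged out of range. Fractions are rounded only at reporting.
* **Backgrounds.** Mode 1 measures the upper quarter of the averaged ROI
  (outside the bundle, since interior rows point down), eroded 2 px from
  the borders; mode 2 takes a user region (warning if it overlaps the
  central disc); mode 3 recalls exported values, bit-exactly (the JSON
  sidecar stores 17 significant digits), which is how control conditions
  are normalized against their antibody-free counterparts.
* **Mean, not sum.** Stack projection uses the per-pixel mean over valid
  samples (robust to varying stack depth); a display scaling reproduces
  the sum view, which differs only by a constant.

## Problem sizes

The bundled tests render full default bundles (9 cilia per row; rasters
around 400 × 230 px) and run the complete pipeline 20 times per preset for
the recovery checks, plus a 100-run sweep over band fractions at 5 cilia
per row; the whole suite takes on the order of two minutes on one core.
`scripts/acceptance.R` reruns the three IHC presets at 20 seeds each.

## Known limitations

* Detection assumes one manually masked row; there is no automatic row
  segmentation or multi-row detection, by design.
* The unfolded along-row axis is distorted and deliberately uncorrected.
* Sub-resolution band separations (≲ the PSF FWHM) merge into single
  maxima; the shoulder detector flags, but cannot localize, features much
  closer than the Savitzky–Golay window.
* The analysis is strictly 2-D single-plane; lateral views and z-stacks
  are out of scope.
* With fewer than three included stereocilia the spline, the circumcircle
  frames, and everything downstream refuse to run.

## A worked run

```{r example, eval = FALSE}
sim <- render(make_geometry("IHC"), preset_library("IHC_ADGRV1_extra"),
              render_settings(seed = 1))
fit <- analyze_bundle(sim$image, sim$mask)
glance(fit)           # centre counts, spacing, peak counts
tidy(fit)             # per-peak positions and inter-row fractions
autoplot(fit$profile) # the two-colour transverse overlay
```
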