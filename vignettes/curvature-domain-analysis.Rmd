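---
title: "Mapping curvature-selective domains in intrinsic-signal imaging data"
author: "curvmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping curvature-selective domains in intrinsic-signal imaging data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(curvmap)
```

## The analysis problem

Intrinsic-signal optical imaging measures stimulus-evoked changes in the
reflectance of cortex under red illumination.  The evoked signal is tiny —
peak fractional changes of 0.01–0.03 % that develop over 2–3 s — and
activation *darkens* the image, so "preferred" always means a reflectance
decrease.  In extrastriate area V4, imaging with curved versus straight
gratings reveals sub-millimetre *curvature domains*: patches of 200–500 µm
equivalent diameter that respond much more to curved than to straight
contours, sit inside the orientation (achromatic) bands of V4, avoid
orientation pinwheel centres, and are organised systematically — maps of
similar curvature degree resemble each other more than maps of dissimilar
degree, opposing curve orientations occupy roughly complementary
subregions, and sequences of domains progress spatially from a straight
orientation domain towards higher preferred curvature.

curvmap implements the full analysis chain for such experiments, together
with a stimulus generator and a synthetic-cortex imaging simulator.  Since
raw imaging stacks for this kind of study are typically not deposited, the
simulator is first-class, tested code: every downstream stage is exercised
end-to-end against planted ground truth, and the test suite consists
largely of parameter-recovery checks.

## Stimuli

Curved gratings derive from the ellipse $X^2/a^2 + Y^2/b^2 = 1$; the
*curvature index* is the axis ratio $a/b$ (1 = circle, larger = sharper
apex, 0 = the straight limit).  The package renders the grating through
the displacement-field form
$$u(x, y) = y + \Delta(x), \qquad
  \Delta(x) = a\left(1 - \sqrt{1 - x^2/b^2}\right),$$
with $b$ equal to half the stimulus width and $a = (a/b)\,b$, and
luminance $0.5 + 0.5\sin\!\big(2\pi f (u - vt) + \phi\big)$.  The
construction conventionally described for such stimuli — elliptical
contours cropped and tiled into a grating template — has no closed form;
the displacement field is one consistent reading and reproduces the two
properties that matter for the science: the central-axis profile is a
sinusoid of the nominal spatial frequency *independent of the curvature
ratio*, and the local spatial frequency on the flanks grows with the
ratio (apex curvature is $a/b^2$, monotone in the ratio).  Straight
gratings are the exact $a/b \to 0$ limit; other apex directions are exact
reflections/rotations; flashed single lines use the same geometry with
the vertex fixed at the stimulus centre; scrambled controls permute an
8×8 block grid bit-exactly (frames are centre-cropped to the largest
divisible size so the permutation is exact).  Rendering defaults:
0.01 °/pixel, 4° stimulus size, line width 0.05° (unspecified by
convention; configurable).

## The synthetic cortex and forward model

`make_cortical_model()` plants, per pixel:

* an orientation preference map — band-pass filtered complex Gaussian
  noise (annular ring around a 0.7 mm map wavelength), preferred angle =
  half the complex argument.  Zeros of the field are orientation
  pinwheels and are recorded as ground truth by the same plaquette
  winding rule the detector uses (tests verify both against an
  independent brute-force loop);
* colour/orientation bands as oblique stripes (1.7 mm period, 60 %
  orientation by default);
* curvature domains: compact super-Gaussian blobs
  $\exp(-\ln 2\,(r/r_0)^8)$ — mask = profile ≥ 0.5, so the planted mask
  is a sharp-edged disk of equivalent diameter $2 r_0$ with a narrow soft
  rim — placed inside orientation bands with a 0.1 mm separation margin,
  with preferred curvature ratio and apex orientation; optionally in
  linear centroid progressions of increasing ratio;
* a peak-amplitude map within 1–3 × 10⁻⁴ (i.e. 0.01–0.03 %).

The tuning model is multiplicative and encodes the reported
phenomenology rather than a biophysical mechanism:

* colour-band pixels respond only to chromatic stimuli (untuned);
  orientation-band pixels only to achromatic ones;
* straight gratings drive orientation-band pixels through a 180°-periodic
  von Mises term (κ = 2) scaled by local orientation selectivity;
  curvature-domain pixels respond to straight contours at
  `straight_gain = 0.1` — an order of magnitude below their curved
  optimum, and without orientation preference;
* curved stimuli drive curvature-domain pixels through a Gaussian on the
  $\log(1 + a/b)$ degree axis (σ = 0.8 by default) times a 360°-periodic
  von Mises term on apex orientation (κ = 1 by default, i.e. graded);
  *outside* the domains a drifting curved grating sweeps the local
  orientations of its flanks and drives orientation columns at their
  orientation-averaged level, so curved-minus-straight contrasts cancel
  there.  This last choice is what makes curvature-vs-straight maps show
  curvature domains and not orientation bands, as observed;
* scrambled gratings drive an untuned response at 30 % gain; blanks drive
  nothing.

`simulate_session()` turns tuning into reflectance:
$R = B\,(1 + v)\big(1 - A\,k(t) + d(t) + \varepsilon\big)$ with $A$ the
peak tuning response, $k$ a gamma hemodynamic kernel (shape 5, unit peak
at 2.5 s — within the 2–3 s range typical of intrinsic signals; no kernel
form is prescribed by convention), $v$ a static vascular pattern
(cancels exactly in dR/R), $d$ a slow global drift (amplitude 2 × 10⁻⁴,
60 s timescale — minutes-scale drift largely cancels under the
pre-stimulus baseline normalisation and is removed spatially by the
high-pass filter), and $\varepsilon$ white noise with SD
10⁻³ = 5 × the default signal amplitude, chosen so that the field's
standard ≥ 30 trials/condition yield clear maps.  Acquisition follows the
field's conventions: 4 Hz frames, 2 pre-stimulus frames, 4.5 s stimuli
(20 frames) for curvature batteries.  Sessions are bit-reproducible given
a seed, and the generating model travels with the session as ground
truth.

Grids default to 256 × 256 px at 0.01 mm/px (a 2.56 mm field).  The
0.01 mm pitch matters: the analysis filters are specified in *pixels*
(10 px Gaussian, 100–150 px low-frequency diameter), and at ~10 µm/px
those pixel sizes correspond to the same physical scales as in the
imaging systems this analysis is used with.  Heavier simulations in the
tests use 128–192 px grids to keep the default test run inside a few
minutes of CPU; those sizes are stated in the tests themselves.

## From frames to maps

Frame labels are 1-based throughout, matching the field's convention.
`frame_drr()` computes $dR/R = (F_x - F_0)/F_0$ against the mean of the
first two (pre-stimulus) frames; `trial_response()` is the per-trial
scalar response (mean frames 8–16 minus mean frames 1–3, over mean
frames 1–3).  `difference_statistic_map()` computes the per-pixel paired
t statistic $\bar d \sqrt{N} / S$ with $S$ the SD of per-trial
differences — conditions recorded in block fashion are paired by trial
index — with a Welch option, and a display-only flag for the literal
$\times N$ scaling that sometimes appears in print (a monotone
transform; p-values always come from the standard statistic).

`filter_map()` implements the field's two-scale filtering: Gaussian
smoothing at "10 pixel diameter", read as FWHM (σ = 10/2.355 ≈ 4.25 px;
the alternative σ = diameter/4 reading is configurable), minus a circular
mean at 120 px diameter (the middle of the 100–150 px convention),
replicate boundary.

One ordering decision is worth spelling out.  The convention "maps were
high-pass filtered" does not say whether filtering happens before or
after the statistic.  `contrast_map()` filters the **per-trial** response
maps and then computes the paired t.  Because the filters are linear the
mean difference map is identical either way, but the statistic differs:
filtering trials first keeps the per-pixel null distribution exactly
Student-t (the suite verifies a significant-pixel fraction ≈ α on
noise-only sessions), and raises the domain-scale signal-to-noise so
that planted domains at realistic amplitude are detectable at all.
Filtering the finished t-map instead (available as
`filter_trials = FALSE`) both mis-calibrates the null and buries the
signal; neither property test can pass in that ordering.

## Domains and morphometrics

`detect_domains()` keeps pixels with $p < 0.01$ (uncorrected, the field
convention; Benjamini–Hochberg available) and the activation sign, then
labels 8-connected components (4-connectivity available; labelling is
done in-package because the installed image library is 4-connected
only).  An optional second gate reproduces the convention of further
assessing curvature pixels by one-way ANOVA across conditions (p < 0.05)
with Tukey–Kramer-corrected curved-vs-straight pairwise comparisons; it
is vectorised over pixels and cross-checked against `aov()` +
`TukeyHSD()` in the tests.  Patch size follows the convention
size $= \pi R^2$ with $R$ the mean of the patch's second-moment
(inertia) ellipse semi-axes — well-defined for arbitrary shapes — the
equivalent diameter is $2R$, and patches under 0.2 mm are excluded as
unreliable.  The activation centre is the unweighted pixel centroid, in
mm from the top-left pixel centre.  Overlap between two pixel sets is
reported as intersection-over-union percent ("overlapped pixels vs. all
coloured pixels" is read as IoU; an intersection-over-smaller-mask mode
is also provided since the phrasing admits both readings).

## Feature maps, similarity, progressions, timecourses

`orientation_angle_map()` vector-averages rectified single-condition
responses on the doubled angle; `detect_pinwheels()` finds singularities
by the winding number of the doubled angle around each 2×2 plaquette
(±180° total = a pinwheel, sign = chirality), with optional
complex-domain smoothing (σ = 2 px) for noisy maps — use σ = 0 on clean
synthetic maps, where detection is exact and net topological charge on
periodic fixtures is zero.

`map_correlation()` is Pearson correlation over an ROI; the default ROI
concept is "the region activatable by curvature stimuli" (union of
significant-vs-blank or significant-vs-straight pixels across curvature
conditions).  Correlations are computed on filtered maps — the maps one
displays — since the convention does not state raw vs filtered.
`degree_difference_regression()` regresses correlation against the
absolute difference of ordinal degree ranks per reference condition and
pools a common slope; a negative slope is the signature of a spatially
progressing degree representation.

`nearest_curvature_domains()` links a straight orientation domain to the
nearest (Euclidean, cortical mm — flat-chamber imaging justifies
Euclidean over geodesic) curvature domain per ratio, ties broken to the
lower label id; orientation congruence is enforced by passing domain
sets restricted to the congruent class.  `progression_distances()` adds
a Spearman monotonicity statistic with a "shifting" flag at ρ > 0.5 — a
reporting convenience, not an inferential threshold; under null
(independent) layouts the flag fires ~13 % of the time for six ratios,
and the suite checks ≤ 20 %.

`extract_domain_timecourse()` averages per-frame dR/R over mask pixels
and then trials (the two orders agree exactly; tested), with SEM over
trials and an optional significant-vs-blank pixel gate.  When comparing
conditions, gate the mask once and reuse it, so every condition averages
the same pixels.  `compare_timecourses()` applies the Wilcoxon rank-sum
test to the per-frame values within frames 9–18 (clipped with a warning
for short sessions).  This is the field's procedure and is reproduced as
such; frames within the window are autocorrelated, so the p-value is
descriptive rather than strictly calibrated.

## What the simulations do and do not show

The generator reproduces the *statistical structure the analysis
assumes*: amplitudes, kernel timing, trial counts, domain sizes, band
parcellation, degree and orientation tuning, planted progressions, and
white pixel noise at 5× signal amplitude.  It does not model
biophysical hemodynamics, vessel artifacts beyond a static pattern, eye
movements, anesthesia state, inter-trial adaptation, or acquisition
hardware.  Passing recovery tests therefore demonstrates that the
pipeline is correct and calibrated under its own assumptions — not that
those assumptions exhaust real imaging data.

Two deliberate idealisations in the heavier simulations: the degree-
battery model uses broad degree tuning (σ = 1.5) with orientation-flat
curvature domains, isolating the degree-progression structure (graded
correlation decay, straight maps least similar) from the orientation
complementarity that a separate simulation plants and recovers
explicitly; and progression recovery is exercised at the geometry level
(planted centroids + 0.05 mm noise → domain sets → linking), which is
the quantity the distance analysis actually consumes.

## Reproducing the numbers

`scripts/acceptance.R --seed <int> --out <path>` regenerates every
headline quantity from scratch — null calibration, domain recovery
(Dice, diameters), degree-structure statistics, orientation-pair
overlap, pinwheel exactness, progression spacing — using only the
installed package, and writes them as JSON.  The test suite asserts the
same properties at fixed seeds with explicit tolerances.
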