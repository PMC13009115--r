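---
title: "Electromechanical wave imaging and ECGI: models, phantoms and comparison statistics"
author: "ewimap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Electromechanical wave imaging and ECGI: models, phantoms and comparison statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ewimap)
```

## The two mapping modalities

Electromechanical wave imaging (EWI) maps cardiac activation from
high-frame-rate transthoracic ultrasound (2000 frames per second, a
128-line / 90° sector). At each myocardial site the incremental (frame to
frame) axial strain trace is positive during diastolic lengthening and
turns negative when the tissue starts to shorten; the first *downward zero
crossing* of that trace marks the local electromechanical activation. The
crossing lags local electrical depolarization by the electromechanical
delay (EMD), tens of milliseconds. Because the strain field is imaged
through the wall, EWI can assign a source to the endocardial, mid-wall or
epicardial layer — the *axial* site of origin — which no surface mapping
method offers.

Electrocardiographic imaging (ECGI) reconstructs unipolar electrograms on
the epicardial surface from body-surface potentials (here emulated, not
inversely reconstructed), samples them at 1000 Hz, low-passes them at
100 Hz, and annotates the local activation time (LAT) at the maximum
negative dV/dt. ECGI sees only the epicardium: septal segments carry no
nodes, and only surrogates — QS versus rS electrogram morphology and the
slew rate at the earliest site — hint at the transmural depth of a source.

The package implements both measurement chains and a comparison framework
(24-segment bullseyes, per-segment activation-time differences, subgroup
statistics, localization scoring), driven by a synthetic phantom generator
so that every stage runs against known ground truth.

## Phantom model

**Geometry and masks.** A view is a polar sector (`viewGeometry`);
`buildMask` rasterizes a concentric half-annular wall at 0.5–1 mm pixel
pitch, assigns each pixel a normalized transmural coordinate (0 at the
endocardial contour, 1 at the epicardial) and divides the angular span
among segment labels. Transmural terciles define the layers
(endo [0, 1/3), mid [1/3, 2/3), epi [2/3, 1]); the tercile rule is a
package choice — layer boundaries are not standardized quantitatively.

**Wavefront.** `simulateActivation` propagates a focal source as an
isotropic geodesic wavefront: activation time = onset time + shortest-path
distance on the 8-connected pixel graph with metric edge lengths, travelled
at the local conduction velocity (default 0.8 mm/ms; scar polygons scale
velocity by a multiplier in (0, 1]). Isotropic geodesics are the simplest
model honoring "site of earliest activation" semantics; fiber anisotropy is
deliberately out of scope. The implementation delegates the shortest-path
solve to igraph's Dijkstra; the tests check it against an independent
O(V²) Dijkstra oracle with identical edge weights.

**Strain traces.** `synthesizeStrain` uses a smooth template
$s(t) = A\,\tanh\!\big((t_m - t)/w\big)$ — positive plateau, downward
crossing at exactly $t_m = \mathrm{AT} + \mathrm{EMD}$, negative systolic
plateau (150 ms), linear recovery — with configurable amplitude
($A = 0.02$), transition width ($w = 4$ ms), additive Gaussian noise and
optional baseline drift. No published trace shape exists to copy; the
template is the minimal shape with the right sign structure. Sampling at
2000 fps bounds the crossing quantization at half a frame period
(0.25 ms).

**Electromechanical delay.** `emdModel` realizes EMD as a Gaussian draw
plus deterministic layer and basal/mid/apical offsets. The subgroup
presets are the reference cohort's global statistics: all patients
45 ± 28 ms, LGE-positive 50 ± 29 ms, impaired LV function without scar
39 ± 25 ms, structurally normal 33 ± 21 ms. Draws default to the *segment*
level (independent per segment), which matches how the per-segment
difference tables are parameterized; a *subject*-level mode (one draw
shared across a subject's segments) is available where between-subject
variation should dominate.

**Electrograms.** `synthesizeECGI` builds each node's unipolar electrogram
as a sigmoidal fall whose steepest descent sits at the node's electrical
activation time, with slew rate $A/2w$ set by configuration (transition
width 8 ms: narrower transitions lose >10% of their slew through the
100 Hz low-pass, 8 ms loses ~1%). Non-epicardial sources add an initial r
bump 20 ms before the intrinsic deflection, small and early enough never
to displace the maximum negative dV/dt. Septal segments cannot be
requested; that restriction is structural to ECGI.

**Cohorts.** `generateCohort` works at segment-surface scale: electrical
activation spreads over the 24-segment adjacency graph (20 ms per hop),
each segment gets 8 epicardial strain sites and 4 ECGI nodes with
within-segment jitter, and the measurement chain
(`annotateZeroCrossings`, `computeLAT`, `extractBullseye`, `computeEMD`)
runs on the generated signals, not on the ground truth. Full pixel-raster
views with isochrone interpolation and SoO localization are exercised by
the single-view pipeline; generating six full views per subject for 33
subjects would multiply runtime without adding information to statistics
that only consume per-segment epicardial means. Generation is
reproducible bit-for-bit under the cohort seed (one derived seed per
subject).

## Measurement chain choices

**Zero-crossing rule.** Clinical practice reviews candidate crossings
manually; a tested artifact needs a deterministic rule. `detectZeroCrossing`
smooths with a centered moving average (default 5 ms), then accepts the
first downward sign change inside the analysis window (default reference
to reference + 350 ms) after which the smoothed trace does not rise above
zero for at least 20 ms (and does go strictly negative) — single-frame
negative blips are rejected. The crossing time interpolates linearly
between the bracketing frames. Traces without a qualifying crossing are
flagged `no_crossing`, never silently zero; multiple qualifying crossings
flag `ambiguous` while reporting the first. A manual-override table
(pixel → forced time) emulates reviewer intervention. The tests hold the
detector against a brute-force oracle on 10⁴ random traces.

**Isochrone interpolation.** Scattered crossing times (150–300 stratified
points per view, exact largest-remainder allocation over segment areas)
are interpolated by Delaunay-based cubic interpolation: deldir provides
the (deterministic) triangulation; each triangle carries a cubic Bézier
patch whose edge control points follow least-squares nodal gradients, with
the interior control point fixed for quadratic precision. The interpolant
is exact at sample points and reproduces linear fields to rounding error.
The Bézier form was chosen over C1 spline schemes for a numerical reason:
focal activation fields are cones, and global/C1 splines overshoot badly
around the conical minimum (observed range [0.6, 72] ms from data in
[11, 53] ms), which corrupts minimum-based localization; Bézier patch
values stay inside their control-point hull, bounding undershoot by
one-third of a gradient–edge product. Pixels outside the convex hull take
the nearest sample's value and are flagged extrapolated.

**Co-registration and SoO.** Views are aligned by subtracting each view's
surface-ECG reference (QRS onset, or pacing spike for paced beats). The
site of origin is read from the earliest region — pixels within 5 ms of
the global minimum across views: its AT-weighted centroid picks the
segment (robust to single-pixel noise, unlike a raw argmin) and the
centroid's wall-depth tercile the layer. A map is *diffuse* when the early
region spans more than 2 segments or more than 25% of any view's mask
while the near-minimum set (within 1 ms) is not confined to one segment of
one view; diffuse maps carry layer `"diffuse"` and score as axially
incorrect. The thresholds are package-defined quantifications of a
qualitative clinical judgement.

**RF path.** Where strain is not supplied directly, `synthesizeRF` builds
Gaussian-pulse scatterer lines (2.5 MHz center, 20 MHz sampling, c = 1540
m/s, hence 0.0385 mm axial sample spacing) and `estimateDisplacement`
tracks interframe motion by 1-D normalized cross-correlation with
parabolic sub-sample refinement — the standard RF speckle-tracking
estimator; phase-based estimators were considered and rejected to keep a
single well-understood bias model (measured |bias| < 0.05 samples on
sub-sample shifts; refinement is skipped when the integer-lag correlation
is already exactly 1, which otherwise perturbs exact shifts).
`estimateIncrementalStrain` is the least-squares gradient of displacement
versus depth over a 5 mm kernel, exact for linear profiles. Incremental
strain only: the zero-crossing definition operates frame to frame, so
cumulative strain is out of scope. At 20 dB SNR the per-depth profile
(averaged over lines and frame pairs) recovers a scheduled strain with
under 10% RMS error; individual estimates are noisier, which is inherent
to correlation-based tracking at this window length.

**Electrogram measurements.** LAT is the sample time of the minimum
central first difference (ties to the earliest sample; a monotone
non-decreasing signal has no LAT and is flagged). Slew rate is the
magnitude of that minimum, in mV/ms, measured on the averaged beat when
beat averaging is used. Beat averaging aligns candidate beats to a
template at the maximum-correlation lag and accepts those with Pearson
r ≥ 0.93. Morphology is rS when an initial positivity exceeds 0.1 of the
dominant negative amplitude (measured against a 10 ms baseline), QS when
it does not, "other" without a dominant negative deflection; the 0.1
threshold quantifies a criterion that is usually read by eye.

## Comparison framework

The 24-segment biventricular model (16 LV segments in the AHA style plus
8 RV segments; 6 septal segments, flagged not-ECGI-covered) is encoded as
data with an explicit adjacency graph and a view→segment allocation that
partitions the 24 segments over six standard views — both are package
definitions, swappable by configuration, since no standard enumeration of
the RV extension exists. Bullseye values are per-segment means of
epicardial samples (EWI restricted to wall depth ≥ 2/3; ECGI uses its
nodes). The per-segment delta is EWI_AT − ECGI_AT, positive when ECGI
precedes EWI — electrical activation precedes mechanical onset, so deltas
concentrate near the EMD mean. Subgroup tables pool segment-level deltas
across subjects within each cell (pooling at the segment level is a
documented choice; subject-first averaging is the alternative), with
one-way ANOVA across subgroups per row, Bonferroni-corrected pairwise
t-tests, and level/chamber comparisons within columns. ANOVA is applied
unconditionally, mirroring the reference analysis; Kruskal–Wallis can be
run by the user on the same table if normality is a concern. Localization
scoring reduces to per-map booleans (exact segment match per modality;
axial match for EWI with diffuse counted incorrect) aggregated with exact
binomial confidence intervals.

## Problem sizes and numerical conventions

Times are ms relative to the view's ECG reference (negative values are
legal for pre-QRS intramural sources), lengths mm, strain dimensionless.
Grids are stored as R matrices (row = y, column = x) with pixel-center
coordinates. All randomness flows through explicit seeds; cohort subjects
draw from seeds derived deterministically from the master seed. The test
suite runs 50 single-view phantoms for the noiseless localization
property, 10⁴ random traces for the detector oracle, 500 replicates for
ANOVA calibration and 20-seed × 33-subject cohorts in the acceptance
script — sizes chosen so the full suite completes in a few minutes on one
core while keeping Monte-Carlo error well inside the asserted tolerances.

## What the phantoms do not show

The generator emulates the *timing structure* of the two modalities, not
their physics: ECGI maps are synthesized forward (no inverse problem, no
torso geometry, hence none of the spatial smoothing and breakthrough-site
displacement real ECGI shows); echo views are ideal sectors without
signal dropout, clutter, through-plane motion or misaligned imaging
planes; the EMD model is Gaussian with deterministic offsets, not
physiology. Passing tests therefore demonstrate that the measurement and
comparison chains are correct and calibrated — not that the modalities
would achieve the same accuracy on patients. Lateral beam resolution is
carried as metadata only; no lateral point-spread function is simulated.

## A short tour

```{r tour, eval = FALSE}
library(ewimap)

# one noiseless view: phantom -> strain -> isochrones -> SoO
m <- buildMask(viewGeometry(depthMax = 60), rEndo = 30, rEpi = 40,
  spacing = 0.8)
f <- simulateActivation(m, sourceSpec("S2", "mid", originTime = 10,
  cv = 0.8))
mov <- synthesizeStrain(f, delay = 0, durationMs = 300)
mv <- mapView(mov, n = 300, seed = 1)
localizeSoO(registerViews(list(list(map = mv$map, ecg = mv$ecg))))

# a paired cohort and its delay table
cohort <- generateCohort(cohortSpec(33, seed = 1), emd = emdModel("all"))
emd <- cohortEMDTable(cohort)
mean(emd$delta); mean(emd$delta > 0)
subgroupAnalysis(cohortEMDTable(generateCohort(cohortSpec(33, seed = 1))))
```
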