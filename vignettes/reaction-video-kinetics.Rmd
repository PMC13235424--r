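---
title: "Video colorimetry as a kinetic instrument: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Video colorimetry as a kinetic instrument: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromatrace)
```

## The measurement model

A camera pointed at a reacting vessel is a cheap, non-invasive,
massively parallel colorimeter. chromatrace treats a video as a sequence
of still frames at a known rate, averages the color of each frame over
user-defined regions of interest (ROIs), and converts the resulting
per-ROI color time series into kinetic quantities.

Color is carried through three representations:

* **RGB** — the native camera encoding, device-dependent and
  perceptually non-uniform; kept because thresholds and simple derived
  scalars are naturally expressed in it.
* **HSV** — separates chromatic identity (hue) from brightness, useful
  under varying illumination. We report hue in degrees on [0, 360) and
  scale saturation and value to [0, 255] so they are directly comparable
  with 8-bit channel intensities.
* **CIE-L\*a\*b\*** — approximately perceptually uniform; the space in
  which color *differences* are meaningful numbers.

The workhorse scalar is the CIE76 color difference against a reference
frame,

$$\Delta E = \sqrt{(L_2-L_1)^2 + (a_2-a_1)^2 + (b_2-b_1)^2},$$

computed per sample between the ROI-mean color and the reference
sample's color. As a rule of thumb, ΔE below ~1 is imperceptible and
within instrumental noise, 1–2 is the threshold of perception, 2–10 a
minor shift, 10–25 a moderate change, 25–50 a distinct transition,
50–100 a complete colorimetric transformation, and values above 100
arise only between essentially opposite colors. The second derived
scalar, the RGB sum response $765 - (R+G+B)$, measures overall
brightness loss and is the right signal when a colored species fades to
colorless.

**Conversion conventions.** The package fixes sRGB primaries, the D65
white point and the 2° observer throughout — the dominant convention
for consumer cameras; sRGB→XYZ uses IEC 61966-2-1 inverse companding
followed by the standard matrix, with Y(white) = 100. Achromatic pixels
get hue 0 by convention, and when two channels tie for the maximum the
hue sector is resolved in R-then-G-then-B order. All arithmetic is
double precision; rounding to integers (round half to even) happens
only when comparing against printed tables. Published HSV tables do not
all share one hue convention; values produced here follow the standard
hexcone formula, and only saturation/value (plus hue where it matches
the 0–360° convention) should be compared across sources.

**Reference-frame dependence.** ΔE is referenced to the first frame by
default, but the reference index is a parameter of `build_trace()`: the
metric is highly sensitive to this choice (a pre-reaction frame with
transient glare makes every subsequent ΔE wrong by a constant offset in
Lab space), so it is deliberately user-overridable rather than baked
in. `resample_trace()` re-anchors the reference after thinning for the
same reason.

## Kinetic extraction

`detect_onset()` and `detect_plateau()` work on a boxcar-smoothed ΔE
series differentiated by centered finite differences. The smoothing
window (default 5 samples) is a free parameter: too small and sensor
noise dominates the derivative, too large and sharp transitions smear
by about half a window. Onset is the earliest time the smoothed rate
exceeds `eps`; plateau is the earliest time the absolute rate stays
below `eps` for `min_run` consecutive windows *and* the trace has
already moved at least `min_excursion` ΔE units from the reference.
The excursion guard (default 3 ΔE, just above the ~2-unit perceptual
noise floor) exists because an unreacted flat baseline also has near-zero
rate; without it every trace would "plateau" at t = 0. For a clean
first-order trace $A(1-e^{-kt})$ the rate crosses `eps` at
$t^\* = \ln(Ak/\varepsilon)/k$, which the detector reproduces to within
a couple of smoothing windows — the resolution limit of any
finite-difference scheme.

`fit_rate()` fits two saturation laws to ΔE(t):
pseudo-first-order $A(1-e^{-kt})$ and second-order
$A\,kt/(1+kt)$. In the second-order form the initial concentration is
fixed at 1 because a unitless color trace cannot separate the rate
constant from the concentration scale — only their product is
identifiable. Fitting uses Levenberg–Marquardt least squares with a
deterministic initializer ($A_0$ = max ΔE, $k_0$ from the time to
half-maximum), so repeated runs give identical answers;
non-convergence is reported as a flagged result rather than an error
so that a single dead well cannot abort a plate-wide analysis.

`mutual_information()` is the equal-width histogram plug-in estimator
in nats, chosen for simplicity and determinism. It is biased upward at
small n relative to bins² (use generous samples), and it is invariant
under affine rescaling of either variable since equal-width bins are
recomputed on the transformed range; k-nearest-neighbor estimators are
a well-known lower-bias alternative we deliberately did not add.
`align_offline()` pairs sparse offline measurements (e.g. NMR
conversions) with the nearest-in-time trace sample, ties to the earlier
sample, dropping out-of-span points with a warning rather than
extrapolating.

## Spatial mixing metrics

`contact()` counts 4-adjacent pixel pairs that differ in a thresholded
frame — the interfacial perimeter between "mixed" and "unmixed"
regions in pixel-edge units. 4-connectivity is the standard perimeter
estimator; marching-squares contour length is the obvious alternative
and would scale every value by roughly √2 on diagonal interfaces
without changing the shape of the time series, which is what carries
the information. The count is zero for any uniform field, rises to a
peak at maximum heterogeneity, and decays toward zero as the system
homogenizes; it is invariant under mask complement, and a normalized
variant (per adjacent pair) is reported for comparability across ROI
sizes.

The gray-level co-occurrence matrix (GLCM) tallies pairs of quantized
gray levels at a fixed offset. Defaults: 16 levels, offset (1, 1) (one
row down, one column right), symmetric accumulation, single offset.
Features:

* ASM $\sum p_{ij}^2$ — pattern regularity (1 for a constant field),
* entropy $-\sum p_{ij}\log_2 p_{ij}$ in **bits** (base 2 chosen;
  bounded by $2\log_2 G$),
* homogeneity $\sum p_{ij}/(1+|i-j|)$ — the inverse-difference form;
  the inverse-difference-moment form $1/(1+(i-j)^2)$ is available via
  `form = "idm"`.

Quantization (`quantize_gray()`) is Rec. 601 luma followed by
equal-width binning of [0, 255]; a constant field therefore lands in a
single level regardless of its absolute brightness, which is why a
uniform white and a uniform black field produce the identical feature
triple (ASM 1, entropy 0, homogeneity 1) — the features see structure,
not color.

## What the synthetic generators emulate — and what they do not

Because colorimetric reaction videos have no deposited standard
datasets, every analysis stage is exercised against seedable
generators whose ground truth is known exactly:

* `gen_reaction()` — a uniformly colored vessel moving between two
  colors along a first- or second-order conversion curve, with i.i.d.
  Gaussian per-pixel channel noise clipped to [0, 255]. The default
  color path is **linear in Lab space**, so the ΔE trace follows the
  kinetic model exactly and rate-fit recovery can be tested against a
  sharp truth (noiseless recovery to 1e-6 relative). A literal
  channel-wise RGB blend is available (`blend = "rgb"`); because Lab is
  nonlinear in companded RGB it bends the ΔE trace by several percent,
  which is worth knowing when interpreting fitted constants from real
  footage of a linearly mixing chromophore.
* `gen_mixing()` — a circular dye blob stirred into solvent on an
  H×W lattice by operator splitting: a semi-Lagrangian swirl (rotation
  angle decaying linearly with radius, which shears the blob into
  filaments) followed by 5-point-stencil diffusion with zero-flux
  boundaries. The diffusion rate must lie in (0, 0.25], the explicit
  scheme's stability bound. The diffusion stencil conserves dye mass
  exactly; bilinear advection resampling does not, so the generator
  renormalizes the total after each advection substep — mass
  conservation is then exact by construction, matching a closed vessel.
  Defaults (64×64 grid, diffusion 0.08, swirl 0.35 rad/step, 120 steps
  at 5 fps, blob radius ≈ grid/6) were chosen once to put the system
  through the full regime sequence — coherent blob, filamentation,
  homogenization — within the run, the regime structure any stirred
  tracer experiment exhibits.
* `gen_plate()` — a plate of circular wells, each following its own
  rate constant, over a dark canvas, with the matching well ROISet and
  per-well truth; pixel area per well falls with the radius, which is
  the signal-to-noise limit of miniaturized plates.

These fixtures deliberately do **not** model lighting drift, shadows
and specular glare, lens vignetting, rolling shutter, lossy codec
chroma subsampling, vessel meniscus optics, or real turbulence (the
swirl is kinematic, not a Navier–Stokes solution). Passing tests
demonstrate the *analysis chain* is correct on data satisfying its
assumptions; they do not certify robustness to those real-world
effects, for which the usual mitigations are controlled illumination
and lossless or high-bitrate capture.

On the mixing fixture two analysis facts are tested because they carry
over to real stirred systems: the Contact series peaks strictly after
the start and decays below 10% of its peak as homogeneity is reached;
and the GLCM entropy peak falls in the same phase of mixing as the
fastest homogenization — located here as the steepest decay of the
pixel-wise ΔE distance to the final mixed state (`pixel_delta_e_trace()`
with `reference = "last"`), the right observable because a closed
mixing system conserves its *mean* color, making the ordinary
mean-color ΔE blind to rearrangement. "Same phase" is tested as
within 25% of the run duration.

## Numerical and interface choices

* Coordinates are 0-based, row-major, origin top-left, rectangles
  half-open — stated once and used everywhere (`frame_index`,
  `reference_index`, ROI definitions).
* Grid partitions assign remainder pixels to the last row/column of
  cells: the simplest deterministic rule, and exactness of the
  weighted-mean recombination is tested rather than assumed.
* Well membership is pixel-center Euclidean distance ≤ radius;
  overlapping wells warn rather than error because tightly packed
  plates are legitimate.
* Video containers are not decoded; `read_frames()` ingests directories
  of numbered lossless stills (PNG/TIFF) with an explicit fps, which
  avoids codec color shifts at the cost of one extraction step, and
  fixes channel order to RGB at the boundary.
* CSV exports round to 6 significant digits — diffable files that still
  carry far more precision than the ~0.5-intensity quantization of
  8-bit capture.
* Identical config + seed ⇒ byte-identical outputs; the run log echoes
  the config, package version, frame counts and seed, which is enough
  to re-run any analysis.

Test and acceptance problem sizes (600-sample traces, 50-replicate
recovery experiments, 64×64 mixing lattices, 16×16 oracle masks) were
chosen as the smallest sizes at which the statistical claims are
comfortably resolved, keeping the full suite fast enough to run on
every change.

## Known limitations

ΔE collapses a three-dimensional color trajectory to a scalar: a
multi-stage reaction whose path in Lab space bends or reverses can
look deceptively simple, and intermediate species can partially cancel.
Rate constants fitted to ΔE are calibration-free only up to the
amplitude scale; comparing k across experiments assumes a consistent
reference frame and lighting. The plateau detector's defaults do not
claim to reproduce any particular published end-point wall-time — `eps`
must be set relative to the noise floor of the actual footage. Only
rectangular, grid and circular-well ROIs are supported; hand-drawn
masks and automatic vessel detection are out of scope.
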