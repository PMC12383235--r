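---
title: "Methods: quantifying amyloid-beta prefibrillar assemblies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying amyloid-beta prefibrillar assemblies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abmorph)
```

## Scope

Amyloid-beta 42 (Abeta42) assembles through a heterogeneous family of
prefibrillar species — small spherical oligomers, curvilinear
protofibrils of remarkably constant ~2.8 nm diameter, ring-shaped
annular assemblies with a central channel, and finally mature fibrils.
`abmorph` implements the quantitative analyses used to characterize
these species across four modalities, together with synthetic-data
generators that emulate each modality with known ground truth:

* **Morphometry** — tracing elongated assemblies in AFM height maps and
  EM-style density fields; cross-sectional diameters at a threshold
  above baseline; annular ring geometry; length-distribution summaries.
* **Assembly kinetics** — thioflavin-T (ThT) lag-phase timing and
  real-time bidirectional elongation rates from AFM time series.
* **Electrophysiology** — single-channel idealization, windowed modal
  conductance, and the access-resistance (Hille) conductance-to-pore-
  diameter model.
* **Stoichiometry** — conversions between map volume, filament length,
  molecular mass and Abeta monomer counts.

Because every stage runs on generated data with exact ground truth, the
package's tests are parameter-recovery experiments: render, measure,
and compare with what was rendered.

## The generators and what they emulate

### Density fields

Tubes (oligomers, curvilinear protofibrils, fibrils) are solid
cylinders of constant density along a centerline; 2D fields can be
rendered in two conventions. `mode = "slice"` emulates a tomographic
slice (constant density inside the tube — a plateau cross-profile);
`mode = "projection"` emulates a class average (the line integral
through the cylinder — a dome profile `2*sqrt(r^2 - x^2)`). Gaussian
blur stands in for the finite resolution of the imaging and
reconstruction chain, and white Gaussian noise for shot/detector noise.
The default blur SD is 0.1 nm; see *Width conventions* below for why
diameter work uses low blur. Annuli are tori; when the stated channel
length differs from the wall thickness, the cross-section is an ellipse
with axial semi-axis `channel_length/2`. Annuli are rendered with 3x3(x3)
subvoxel coverage so hard edges land on the grid without a
half-voxel bias.

Centerlines are persistent random walks: Gaussian turning angles with
variance `step/persistence`. The real protofibrils are irregularly
curved with occasional tight turns, but no curvature statistics are
published; the default persistence length of 250 nm was chosen so that
assemblies several hundred nm long remain inside a 783-nm AFM field, as
observed, and is a free emulation parameter, not an inferred quantity.

What the generator does *not* emulate: contrast transfer functions,
projection physics, stain artifacts, or crowded fields of touching
particles (two assemblies closer than one tube diameter are refused,
because their tracing ground truth would be ambiguous). Passing tests
therefore demonstrate correctness of the measurement chain, not
robustness to every pathology of real micrographs.

### AFM time series

One oligomer of ~2.8 nm height sits on a flat support and elongates
bidirectionally along a fixed master centerline at `rate_end_a` and
`rate_end_b` (defaults 8 nm/min, one frame every 8 min, pixels 9-19 nm,
as in real-time contact-mode AFM of Abeta42 on mica). Ground-truth
lengths and per-end excursions are exact arc-length bookkeeping on the
master path. The imaging model is grayscale dilation with a spherical
cap of the probe's 20-nm nominal tip radius — the standard first-order
account of AFM broadening, which widens footprints to
`~2*sqrt(2*R*d)` while preserving apex heights; this is why widths, not
heights, are overestimated in AFM. Gaussian surface roughness
(default SD 0.05 nm) is added per frame. Master paths whose
self-clearance is below the apparent (tip-broadened) tube width plus a
pixel are rejected and regenerated deterministically from the seed,
because their images would merge into un-traceable masks.

### Channel traces

Gating is a continuous-time two-state Markov chain (exponential dwell
times); several open conductance levels can share the closed state,
with the level drawn at each opening. Current is `g * V(t)` under a
cycled step protocol (defaults: 2.5 s at -80 mV, 0.5 s at 0 mV, 2.5 s
at +80 mV), plus slow sinusoidal drift and white noise, then zero-phase
low-pass filtered with a linear-phase FIR at the stated cutoff (default
0.2 kHz at 2 kHz sampling). A linear-phase filter with matched -3 dB
point stands in for the recording Bessel filter; the analysis operates
on levels, not on phase detail. Default gating rates are 5/s each way:
the channels of interest stay open for long periods, and published
recordings show step-like, not buzzing, activity. No kinetics are
published; these defaults are emulation choices.

### Kinetic curves and length populations

ThT curves are logistics with the steepness chosen so that the
10%-of-plateau crossing falls exactly at the requested lag end
(`k = log(9)/(midpoint - lag)`), defaults 28 h lag and 50 h midpoint.
Length populations are lognormal with the analytic mode
(`exp(mu - sigma^2)`) pinned to the requested modal length; the default
log-scale SD of 0.35 reflects the broad, right-skewed spread of
measured assembly lengths, and the default 100 particles per time point
matches typical manual counting effort.

## Measurement conventions and numerical choices

### Tracing

Foreground is segmented at a robust background threshold
(median + max(3 MAD, 10% of amplitude)); Otsu's method was rejected
because it splits the background when the object occupies a tiny
fraction of a noisy frame. One-pixel gaps are closed morphologically
(filament footprints at 9-19 nm pixels are barely one pixel wide).
Each component is thinned (Zhang-Suen), the longest geodesic path
through the 8-connected skeleton is extracted (double-sweep shortest
paths), and both ends are extended by the local half-width from the
distance transform so lengths span the full object.

Path post-processing is regime-aware. At fine pixels (object half-width
at least 2 px) the path is smoothed and each vertex is moved to the
intensity-weighted centroid of its perpendicular profile (subpixel
ridge refinement). At coarse pixels the raw skeleton is kept: smoothing
or centroid refinement at that scale cuts corners and was measured to
shorten arc lengths — and hence growth rates — by 5-9%; the raw
skeleton's staircase error is smaller than that.

Objects touching the field border have censored lengths and are
flagged and excluded from length statistics; branched skeletons return
the longest branch with a flag.

### Width at a threshold above baseline

Cross-sectional profiles are interpolated perpendicular to the local
tangent; the baseline is the median of the outer 25% of offsets (robust
to a neighbour in one wing), and the width is read between the
*outermost* crossings of `baseline + 0.15 * (peak - baseline)`.
Outermost (rather than first-from-centre) crossings make the measure
robust to central dips, so the same code serves annuli; excursions above
the level narrower than 1.5 voxels are ignored as noise, and noisy
profiles (noise above 5% of amplitude) are lightly smoothed before
crossing detection — a clean profile is never smoothed, because
smoothing widens a threshold width by up to half a window.

Two facts shape how this convention is exercised:

* On a Gaussian profile of SD sigma the convention gives exactly
  `2*sigma*sqrt(2*ln(1/0.15)) ~ 3.896*sigma` — a closed form used as a
  high-precision oracle.
* The convention measures the *blurred* envelope. For a 2.8-nm tube the
  15% width exceeds 2.9 nm once the blur SD passes ~0.25 nm (dome
  profile) or ~0.15 nm (plateau profile). Diameter benchmarking
  therefore renders projection-mode fields at blur SD 0.1 nm and
  averages 21 adjacent profiles (~5 nm of arc) — the analogue of the
  summed slices and class averaging behind published density profiles,
  which place the per-profile noise far below the per-voxel noise of a
  raw field.

With those settings, 2.8-nm tubes rendered at per-voxel SNR 5 measure
2.87 +/- 0.04 nm over 50+ profiles (the package's acceptance test), the
residual +0.07 nm being blur plus pixelation.

### Ring geometry

Two orthogonal line profiles pass through the ring centre (central
axial slice for volumes). The outer diameter is the separation of the
outermost crossings at the threshold convention (or at baseline, via
`convention = "baseline"` — published ring diameters use both). The
inner (channel) diameter applies the same fractional convention to the
inverted dip: the level sits 15% of the dip depth below the rim. For
volumes, the channel length is the axial extent of the ring wall
sampled on the mid-ring circle, at the same convention.

On noiseless digitized rings the threshold convention would carry an
irreducible bias of ~0.35 voxel per side, because the level is read off
a digitization ramp rather than a resolved edge. Edges that rise from
10% to 90% of their amplitude within 2.5 voxels are therefore refined
to their half-amplitude point, the unbiased estimate of a sharp edge's
position; resolved (blurred) edges keep the threshold convention
untouched. Recovery of torus parameters is within one voxel at every
grid alignment tested.

### Heights

AFM heights are peak minus support plane, after first-order plane
fitting to the non-object pixels (the standard flattening applied to
raw scans). The plane fit refuses frames whose object covers more than
60% of the field.

### Growth tracking

The track anchors at the centroid of the frame-0 object; end identity
propagates by nearest-endpoint matching (robust to whole-filament
drift); the excursion of each end is the arc length along the current
path from the anchor-nearest point to that end, minus its frame-0
value — arc length, not Euclidean displacement, because the filaments
are curvilinear. The traced path is resampled at quarter-pixel spacing
before the anchor split; with vertex-level splitting the coarse
spacing systematically misallocated growth between the ends. Rates are
ordinary least squares of excursion on time (a plain linear best fit),
and `rate / 0.48 nm` converts to monomers added per minute, one
cross-beta strand per molecule. The published "~16 molecules per
minute" is the rounded presentation of 8.0/0.48 = 16.67. Both per-end
excursions and the total length are reported, since either may be the
quantity of interest.

### Lag-phase timing

The detector scales the curve by its plateau (mean of the top 5% of
values) and reports the first debounced upward crossing of 10% *of
maximum* — the conventional end-of-lag-phase point. The threshold is a
fraction of the maximal signal, not of a baseline-subtracted amplitude:
on a pure logistic the latter convention shifts the crossing by the
logistic's nonzero tail (+0.7 h under the default geometry), breaking
the closed-form identity the generator establishes. Instrument offsets
should be removed before detection (`normalize_curve` provides the
5%-tail amplitude normalization for that and for plotting). The default
crossing smooth (9 samples, ~4 h at 0.5-h sampling) was set by
simulation: bias below 0.05 h, and all of 100 replicates at 1% plateau
noise within 1 h of truth.

### Idealization and modal conductance

The baseline defaults to the near-0 mV epochs of the protocol — there
the channel contributes nothing regardless of gating state, so the
amplifier offset and drift are observable even when no all-closed epoch
exists. Conductance is `i/v` with samples below 5 mV masked (excluded,
never counted as zero conductance). Open levels are modes of the
conductance density that clear the baseline noise by 4 SDs; states are
assigned by half-amplitude thresholds, and events shorter than two
filter time constants are merged into their neighbours, since the
low-pass filter cannot resolve them. Windowed modal conductance
histograms the open-state samples of each 2500-ms window (10 pS bins,
below the smallest published level spacing; 1000-ms windows via
`window_ms`) and reports the centre of the highest bin; windows with no
open samples report 0 and are flagged. Closed samples are excluded from
the histogram (the mode would otherwise be trivially 0); negative
conductance samples are clipped into the zero bin rather than dropped,
keeping open probability unbiased; samples within three samples of a
transition are left out, because the filter smears them between levels.
Summaries report both the min-max range and the 20th-80th percentile
"typical" range of per-window modal values.

### The pore model

The access-resistance model adds one convergence resistance rho/(2d)
per mouth to the cylindrical pore term:

$$\frac{1}{g} = \frac{4 \rho l}{\pi d^2} + \frac{\rho}{d},$$

whose positive root is `d = a/2 + sqrt(a^2/4 + 4 a l / pi)` with
`a = rho*g` expressed as a length; for `l = 0` it reduces to
`d = rho*g` exactly. With the package defaults (l = 5.4 nm, rho = 80
ohm cm), 320 pS maps to 1.46 nm and 540 pS to 1.95 nm — the published
1.4 and 2.0 after rounding. The closed form is property-tested against
a numeric root-finder and round-trips with the inverse to 1e-9.

```{r}
hille_diameter(c(135, 320, 540), pore_model(5.4, 80))
```

### Stoichiometry constants

The density-to-mass conversion is 825 Da per cubic nanometre, applied
to volumes given in cubic Angstrom; that is the only reading under
which the standard worked example (64,000 A^3 -> 52.8 kDa -> a
dodecamer at 4.514 kDa per monomer) is arithmetically consistent. The
monomer mass was computed once from the canonical 42-residue sequence
with standard average residue masses and frozen (4514.04 Da; the
ordered core, residues 15-42, is 2833.35 Da and gives ~19 monomers for
the same map — the package exposes the calculation without asserting a
preferred count). Monomer counts report both the exact quotient and the
nearest integer; masses print at two significant figures in summaries.

## Problem sizes

The test-suite simulations are sized to be decisive rather than large:
diameter benchmarking uses three 60x60-nm fields at 0.2-nm voxels
(51 profiles); growth-rate recovery runs 20 seeds of six 1500-nm frames
with pixel sizes cycling through 9, 12, 15 and 19 nm; channel recovery
uses one 100-s trace (40 windows). These choices are stated here so
that anyone scaling them up knows the defaults are statistical, not
physical, limits.

## Known limitations

* Filament tracing assumes separated assemblies; crossing or bundled
  filaments are out of scope (the generator refuses them).
* 3D tracing projects through the volume and recovers the axial
  coordinate as an intensity centroid; strongly overlapping objects in
  projection would confuse it.
* The FD-histogram mode estimator is noisy at n = 100 particles per
  time point (about 80% of replicates land within 15% of the true mode
  at the default dispersion); medians are far more stable and are
  always reported alongside.
* No nucleation-polymerization rate-law fitting, no dwell-time (hidden
  Markov) kinetics, no ion-selectivity analysis, and no drift
  correction between AFM frames beyond anchor tracking.
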