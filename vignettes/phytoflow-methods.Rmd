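---
title: "Growth phenotyping from time-lapse stacks: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growth phenotyping from time-lapse stacks: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(phytoflow)
```

This vignette is the package's own account of the methods it implements:
the optical-flow model and its assumptions, the two leaf growth-rate
estimators and why both are kept, the geometric root-tip tracker, the
diel aggregation conventions, and what the synthetic scene generator
does and does not emulate. Nothing here states an empirical result that
the test suite or `scripts/acceptance.R` does not itself compute.

## Structure-tensor optical flow

Brightness constancy assumes a material point keeps its grey value, so
its image velocity $(u, v)$ satisfies $g_x u + g_y v + g_t = 0$ with
$(g_x, g_y, g_t)$ the spatiotemporal intensity gradient. A single pixel
gives one equation for two unknowns; the structure-tensor method
resolves this by total least squares over a local window: the tensor
$J = G_{\sigma_w} * (\nabla g \, \nabla g^\top)$ is a $3\times3$
positive semi-definite matrix per pixel, and the eigenvector $e$ of its
smallest eigenvalue is parallel to $(u, v, 1)$ wherever the local
gradient set spans a two-dimensional constraint space. We read off
$u = e_x e_t/(e_t^2+\varepsilon)$, $v = e_y e_t/(e_t^2+\varepsilon)$
(with $\varepsilon = 10^{-12}$ guarding all ratio denominators; the
sign convention was fixed against rendered scenes of known motion).

Assumptions and how they fail: brightness constancy breaks under
illumination change (the acquisition geometry this targets uses
constant infrared illumination precisely to avoid that); local motion
coherence breaks at occlusion boundaries such as the advancing root tip
edge (which is why root velocity is *not* computed from flow, see
below); large displacements violate the differential approximation
(handled by the coarse-to-fine pyramid, which pre-warps frames with the
flow found at half resolution).

Degeneracy is made explicit rather than patched over. With eigenvalues
$\lambda_1 \ge \lambda_2 \ge \lambda_3 \ge 0$: an untextured
neighbourhood has $\lambda_1 \approx 0$; one-dimensional texture (the
aperture problem) has $\lambda_2 \approx \lambda_3$; both are flagged
invalid when $\lambda_2-\lambda_3 < 10^{-3}\lambda_1$, and the
confidence map is the coherence
$(\lambda_2-\lambda_3)/(\lambda_2+\lambda_3+\varepsilon) \in [0,1]$.
A border margin of $\lceil 3\sigma_w \rceil$ px plus the derivative
radius is always invalid: no extrapolation.

Tunable parameters (defaults in `flow_params()`):

* `grad_sigma` = 1.0 px, `grad_sigma_t` = 1.0 frame — Gaussian
  derivative scales. Smaller is sharper but noisier; 1 px matches
  speckle-scale texture.
* `window_sigma` = 4.0 px — tensor integration window. Must cover
  enough texture to span both gradient directions; larger windows
  smooth real velocity gradients, biasing the divergence.
* `temporal_halfwidth` = 2 frames — the spatiotemporal block is
  `centre ± 2`.
* `confidence_threshold` = 0.3 — coherence gate for the valid mask.
* `pyramid_levels` = 2 — adequate up to a few px/frame. Leaf expansion
  displacements are far below 1 px/frame, so the leaf pipeline runs a
  single level (`run_analyze_leaf()` default); this halves cost with no
  measurable accuracy change.

The source the original acquisition method cites fixes its own kernels
and windows; since the defaults are not recoverable from the text, they
are exposed in configuration and were chosen once against the synthetic
fixtures (sub-0.05 px/frame median error on rendered translations).

## Leaf RGR: two estimators, kept deliberately

The relative growth rate of a leaf region is described in the
literature both as the divergence of the velocity field and by the
log-area formula $\mathrm{RGR} = (\ln A_1 - \ln A_0)/t$; which of the
two produced any given published figure is usually unstated. Both are
implemented and reported side by side:

* **Area method**: the AOI polygon is advected vertex-by-vertex along
  the per-frame flow (bilinearly interpolated, nearest-valid filled at
  low-confidence pixels — leaf edges often fail the confidence gate),
  and the shoelace areas at the window boundaries enter the formula
  exactly. By construction the series telescopes:
  $A_k = A_0 \exp(\sum_i \mathrm{RGR}_i \Delta t_i)$.
* **Divergence method**: mean of $\partial u/\partial x + \partial
  v/\partial y$ (central differences on a lightly mask-smoothed field)
  over AOI-interior pixels, averaged over the window's frames and
  converted to h⁻¹. The average is restricted to pixels whose
  smoothing kernel has full support inside the valid mask: a clipped
  kernel at the AOI rim biases the divergence low (about 2 % for a
  radius-22 region), which is exactly the kind of silent bias this
  package refuses.

Windows are tiled from the first frame, default 15 min (the windowing
used in this acquisition tradition); whether published series used
tiled or overlapping windows is unstated, so tiled was chosen and the
window length is configurable. Agreement of the two estimators (series
means within 2 % on rendered expansions) is the module's central
invariant and is asserted in the test suite. Individual 15-min windows
carry 2–4 % sampling noise (vertex interpolation, flow noise) with
occasional larger excursions; recovery claims are therefore made at
series level, with a generous per-window bound so an outlier still
fails loudly.

## Root velocity: geometric tip tracking

Root velocity is defined as the speed at which the tip is dislocated
from the mature, spatially fixed part of the root — a point-tracking
notion. Flow near the tip edge mixes the occlusion boundary with the
background, so the tip is tracked geometrically:

1. **Segmentation**: Otsu threshold (via `EBImage`), polarity
   auto-detected by which side of the threshold yields an elongated
   (major/minor moment ratio ≥ 3) largest component; small objects
   removed.
2. **Skeleton and tip**: Zhang–Suen thinning; the tip is the skeleton
   endpoint with maximal geodesic (along-skeleton, Dijkstra with
   Euclidean step weights) distance from the anchor — on curved roots
   the Euclidean-farthest endpoint can be the wrong one. Tied
   endpoints (equal branches) raise an explicit ambiguity error.
3. **Sub-pixel refinement**: the skeleton endpoint of a rounded cap
   sits about half a root-width behind the physical tip and jumps in
   whole pixels; the soft edge profile is sampled along the growth
   direction (on a lightly smoothed frame) and the threshold crossing
   interpolated linearly, giving ~0.03 px repeatability.
4. **Growth direction**: principal axis of the last ~15 skeleton
   points. Within each window, steps are projected on the
   *window-mean* tangent: the true direction changes negligibly within
   5 min, and a stable projection direction cancels lateral
   tip-localisation noise to first order (per-frame tangents jitter by
   up to ~0.3 rad, which would otherwise leak ~δ·θ of lateral error
   into the along-path estimate).
5. **Velocity**: along-path displacement (sum of projected steps,
   outliers beyond 5× the window median replaced by interpolation)
   divided by the window duration (default 5 min = 10 frames at 30 s),
   in mm h⁻¹. The chord (straight-line) velocity is reported alongside
   — the published definition does not say which was used; along-path
   was chosen so curved growth is never under-reported, and the chord
   column makes the difference visible.

The anchor is verified rather than assumed fixed: a patch around it is
tracked by normalised cross-correlation with quadratic sub-pixel peak
interpolation. Drift below 2 px ⇒ treated as fixed; beyond ⇒ warning
and anchor-motion correction of the tip track; chance-level correlation
(textureless patch) ⇒ explicit error.

Measured on rendered roots, the per-window relative error is ≤ 5 %
across 0.1–1.0 mm h⁻¹ (bracketing the 0.3–0.6 mm h⁻¹ treatment range)
at the default noise level, dominated near the low end by the
tip-localisation floor of a 0.8 px/window displacement.

## Diel aggregation

An experimental day runs light-on → light-on: each diurnal period is
paired with its following night, matching how such experiments pair
day/night bars per day. Labels are half-open — a sample exactly at
light-on is diurnal, exactly at light-off nocturnal — and windows are
assigned by their centre time (unbiased for symmetric windows).
Period means are arithmetic means of window values; daily shares are
$100\,m_p/(m_d+m_n)$ so nocturnal + diurnal = 100 exactly; standard
errors are across replicate plants only, with each replicate first
averaged within the (day, period) cell and normalised to its own daily
total. Empty cells are explicit missing values, never zeros; shares for
a day that lacks one period are undefined, never 100:0.

## The synthetic scene generator

Frames are always derived from continuous ground truth, never by
iterated resampling (which would accumulate blur and corrupt the
reference): the leaf scene warps one fixed band-limited speckle texture
(Gaussian-smoothed white noise, 2× oversampled master grid) through the
exact material map $x \mapsto c + e^{S(t)/2}(x-c)$ with
$S(t)=\int r\,d\tau$, so the true AOI area is $A_0 e^{S(t)}$ exactly;
the root scene renders a constant-width, soft-edged dark curve along an
arc-length-parametrised path whose drawn length follows
$\int v\,dt / \text{pixel size}$, so mature pixels are bit-static and
the tip position is analytic. Additive Gaussian sensor noise only
(defaults: leaf σ = 0.006 vs texture contrast 0.15; root σ = 0.02 vs
edge amplitude 0.55 — moderate-SNR CCD conditions; robustness is
additionally tested at SNR 10). Identical seeds give bit-identical
renders.

What it does not emulate — hence what passing tests do *not* show about
real data: photon/shot noise, optical blur and vignetting,
out-of-plane leaf motion (real leaves are mechanically fixed with
weights for this reason), root hairs and lateral roots, illumination
drift. The generator validates the *estimators*, not the acquisition
hardware.

**Diel root coverage.** At 0.01 mm/px a root growing 0.6 mm h⁻¹
traverses ~1.4 mm h⁻¹·px⁻¹-equivalent — far beyond a fixed frame over
24 h. Real rigs solve this with a movable stage that re-centres the
camera on the tip; the generator mirrors that with *re-staged bursts*:
every 30 min a fresh 5-min acquisition (one analysis window, 11 frames)
is rendered with the tip back in view and the velocity profile
evaluated at that burst's clock time. Burst analyses are concatenated
on the diel time axis.

**Treatment presets.** Only the period-level numbers are taken from the
study conditions: control ≈ 0.6 mm h⁻¹ (with a small light-on dip),
cooling ≈ 0.3 mm h⁻¹ constant, illumination ≈ 0.4 mm h⁻¹ diel mean with
near-equal day/night distribution. Transient shapes (a 30-min
rectangular control dip; an exponential morning trough of depth
0.18 mm h⁻¹ recovering with τ = 4 h plus a post-dusk dip of
0.15 mm h⁻¹, τ = 1 h, on a 0.43 mm h⁻¹ baseline) are package choices
shaped to the qualitative description of those regimes. The leaf
profile is shared across presets — leaf growth is insensitive to the
root-zone treatment — with plateaus 0.040 h⁻¹ (night) and 0.016 h⁻¹
(day): no absolute leaf RGR values are published for this material, so
the plateaus were fixed once from the two published constraints
(instantaneous night values "almost three times" day values; daily
shares roughly 70:30, which together pin the plateau ratio near 2.5)
at magnitudes typical of young tobacco leaves, giving shares ≈ 72:28.
A transient light-on dip (full stop for 20 min; half depth under root
illumination, where it is reported to be less pronounced) and an
optional day-by-day decline factor (0.85/day, applied per day so shares
are unaffected) complete the profile. Pixel calibrations default to
0.01 mm/px (root) and 0.02 mm/px (leaf) — the acquisition optics are
not specified anywhere, so these are deliberate, flagged conventions.

## Numerical choices and degenerate inputs

* Grey values are floating point on the scale read from disk, never
  renormalised — flow is intensity-scale invariant by construction and
  tested to 10⁻⁶.
* Gaussian derivative kernels are normalised so a unit ramp
  differentiates to exactly 1; all convolutions replicate borders.
* Self-intersecting advected polygons are repaired by convex-hull
  simplification with a warning; degenerate (≤ 0 area) polygons stop
  the series with a tracking-lost error rather than propagating
  nonsense.
* Globally constant stacks yield an all-invalid field plus a warning,
  not an exception; downstream consumers then fail loudly on their
  own minimum-valid-pixel gates (with the count in the message).
* TIFF export quantises to 8/16 bits; timelines and calibration travel
  in a plain-text YAML sidecar because TIFF tags for timelines are
  non-standard. Nominal cadence can be overridden by explicit
  per-frame timestamps (rigs drift).

## Problem sizes used in the test suite

The suite and acceptance script size the simulations to validate each
claim at the smallest scene that exercises it: flow oracles on
256×256×20 stacks; RGR recovery on a 4-h, 192-px scene (161 frames);
root recovery on 1-h single stacks plus 24-h burst series (48 windows
per preset); the acceptance script's leaf day runs at 160 px. These are
analysis-frame choices — the generator's growth regimes, cadences and
window lengths are never scaled.

## Known limitations

* Flow confidence gating rejects leaf-edge pixels; the AOI should sit
  on textured lamina. Whole-leaf AOIs work because vertex displacement
  is filled from the nearest valid interior pixels.
* The tip tracker assumes a single unbranched root in view; lateral
  roots of comparable length trigger ambiguity errors by design
  instead of guessing.
* Velocities below ~0.05 mm h⁻¹ at 0.01 mm/px approach the sub-pixel
  localisation floor for 5-min windows; lengthen the window or coarsen
  the calibration for very slow roots.
* The divergence estimator reports a spatial mean over the AOI; it
  does not produce pixel-wise growth maps (out of scope).
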