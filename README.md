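# phytoflow

Synchronous, high-temporal-resolution phenotyping of leaf expansion and
root elongation from grey-value time-lapse image stacks.

Plant growth is strongly structured over the diel (24-h) cycle: dicot leaf
expansion follows an endogenously controlled day/night rhythm, while root
elongation responds within minutes to the root-zone environment
(temperature, light). Quantifying both at once — for the same plant, at
minute-scale resolution, over full light–dark cycles — requires extracting
growth rates directly from time-lapse imagery. `phytoflow` implements that
analysis chain for two standard acquisition geometries: a leaf viewed from
above (frames every ~90 s) and a root tip growing along a Petri dish
(frames every ~30 s), plus the diel statistics used to summarise such
experiments and a fully ground-truthed synthetic scene generator to
validate every stage without real imagery.

## Methods at a glance

**Optical flow.** Dense velocity fields are estimated with the classical
structure-tensor method: under brightness constancy,
`g_x u + g_y v + g_t = 0`, the 3×3 spatiotemporal second-moment matrix
`J = G_σ * (∇g ∇gᵀ)` is diagonalised per pixel and the eigenvector of the
smallest eigenvalue — parallel to `(u, v, 1)` where the constraint is
solvable — gives the total-least-squares velocity in px/frame. Pixels
affected by the aperture problem (unseparated trailing eigenvalues) are
flagged invalid rather than assigned normal flow; a coarse-to-fine pyramid
handles displacements beyond ~1 px/frame.

**Leaf RGR.** The relative growth rate of a tracked area of interest
(AOI) is computed two ways and reported side by side: as the mean
divergence `∂u/∂x + ∂v/∂y` of the velocity field over the AOI interior,
and as `RGR = (ln A₁ − ln A₀)/t` on the polygon advected along the flow
(default window ≈ 15 min). On clean expansions the two must agree; their
disagreement is a built-in quality indicator.

**Root velocity.** The root tip is segmented (Otsu), skeletonised, and
located as the skeleton endpoint geodesically farthest from an anchor in
the mature, spatially fixed region; sub-pixel position comes from the
soft edge profile along the growth direction. Velocity per 5-min window
is the along-path tip displacement divided by the window duration, in
mm h⁻¹, with anchor-motion correction.

**Diel statistics.** Windowed series are partitioned into nocturnal and
diurnal periods per experimental day (day boundary at light-on,
half-open intervals), averaged per period, normalised to the daily total
(nocturnal + diurnal = 100 %), and pooled across replicate plants with
standard errors computed across plants, never across time windows.

## Worked example

Render a root elongating at 0.6 mm h⁻¹ for 30 min (the control-level
velocity regime) and recover its velocity in 5-min windows:

```r
library(phytoflow)
scene <- make_root_stack(root_scene_config(velocity_profile = 0.6,
                                           duration_h = 0.5, seed = 1))
vel <- tip_velocity_series(scene$stack)
round(vel[, c("window_start_s", "velocity_mm_h", "straight_mm_h")], 4)
#>   window_start_s velocity_mm_h straight_mm_h
#> 1              0        0.5951        0.5964
#> 2            300        0.5988        0.6001
#> 3            600        0.5943        0.5945
#> 4            900        0.6064        0.6081
#> 5           1200        0.6021        0.6023
#> 6           1500        0.5923        0.5928
```

Each row is one 5-min window; `velocity_mm_h` is the along-path tip
velocity, `straight_mm_h` the chord (straight-line) velocity — on this
straight root the two coincide; on curved roots the chord under-reports.
All six windows recover the configured 0.6 mm h⁻¹ within ~1 %.

The same round trip for a leaf expanding at a constant RGR of 0.015 h⁻¹:

```r
leaf <- make_leaf_stack(leaf_scene_config(image_size = 128,
                                          rgr_profile = 0.015,
                                          duration_h = 1.5, seed = 1))
rs <- rgr_series(leaf$stack, aoi(leaf$truth$aoi0),
                 flow_params(pyramid_levels = 1))
round(rs[, c("A0_mm2", "A1_mm2", "rgr_area_h", "rgr_div_h")], 5)
#>    A0_mm2  A1_mm2 rgr_area_h rgr_div_h
#> 1 1.66827 1.67442    0.01470   0.01520
#> 2 1.67442 1.68093    0.01553   0.01516
#> 3 1.68093 1.68710    0.01465   0.01521
#> 4 1.68710 1.69364    0.01547   0.01476
#> 5 1.69364 1.70005    0.01512   0.01516
#> 6 1.70005 1.70654    0.01524   0.01529
```

`rgr_area_h` (log-area method on the advected AOI) and `rgr_div_h` (mean
flow divergence) independently recover the configured rate per 15-min
window; their series means agree to well under 1 %.

A command-line front end wraps the same pipeline
(`inst/cli/phytoflow.R`: `simulate`, `analyze-leaf`, `analyze-root`,
`summarize`), writing CSV series and diel summary tables.

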