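---
title: "A wavefront-curvature model of unidirectional block in the infarct border zone"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A wavefront-curvature model of unidirectional block in the infarct border zone}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bzblock)
```

## The model

After myocardial infarction, a thin rim of surviving myocardium - the
infarct border zone - remains between the infarct and the epicardial
surface. Reentrant ventricular tachycardia (VT) in this substrate is
typically a figure-of-eight circuit: two counter-rotating loops sharing a
central isthmus that coincides with the thinnest border zone.

`bzblock` implements a quantitative model in which the controlling variable
is border-zone thickness $T$. When an activation wavefront propagates from
thinner into thicker tissue, the depolarizing current supplied by the thin
layer must charge a larger downstream volume: a source-sink mismatch that
bends the wavefront convex along the thickness axis and slows it,

$$\theta \;=\; \theta_o - \frac{D}{c}\,\frac{\Delta T}{T},$$

where $\theta_o$ is the plane-wave conduction velocity (0.4 mm/ms in
ventricular myocardium), $D$ the diffusion coefficient (0.1 mm$^2$/ms),
$c$ the space step over which the thickness change $\Delta T$ is measured
(1 mm by default), and $\Delta T$ the largest thin-to-thick change over $c$
in any direction about the point. With the default constants, $\theta$
reaches zero when $\Delta T/T = \theta_o c/D = 4$: the curvature becomes
critical and conduction blocks. Writing $\rho = (\Delta T/T)/c$ for the
implied wavefront curvature gives the equivalent form
$\theta = \theta_o - D\rho$.

Block at a given convexity is rate dependent. The circular-arc form
$\rho = 2\sin(\beta)/w$ links curvature to the width $w$ of the conducting
medium at the wavefront's leading edge ($\beta = 90°$ when a narrow isthmus
opens to an expanse). Experimentally, block through a narrow isthmus occurs
at $w = 0.6$ mm for a 200 ms activation interval, $w = 1.29$ mm at 150 ms,
and $w = 2.64$ mm at 117 ms. These three pairs are the package's default
`rate_block_calibration()`. Dividing the relative thickness change by the
calibrated critical curvature yields a *critical space step*
$c = (\Delta T/T)/\rho_{crit}(CL)$: a thin-to-thick transition completed
over a distance no longer than this blocks at that cycle length. For the
mean border-zone thicknesses (231 μm at the isthmus, 1440 μm along the
outer pathway, so $\Delta T/T = 5.23$) the chain gives critical transition
distances of about 1.6, 3.4 and 6.9 mm at 200, 150 and 117 ms - recomputed
by `worked_examples()`:

```{r}
worked_examples()
```

The consequence is *unidirectional* block: a premature wavefront (short
coupling interval, large critical space step) travelling thin-to-thick
across an isthmus end is halted there, while the same interface conducts
in the reverse thick-to-thin direction, and also conducts at the longer VT
cycle length. This is the mechanism by which an appropriately timed
premature stimulus creates a unidirectional block line (UBL) at the
isthmus entrance, the wavefront bifurcates around it, coalesces beyond it,
and re-enters - establishing the double-loop circuit.

## Model assumptions

* Conduction is isotropic; fiber direction and anisotropic safety-factor
  effects are not modeled.
* The effective refractory period (ERP) is spatially uniform
  (`refractory_model()`, default 100 ms, consistent with observed
  recovery times of ~103 ms being sufficient for breakthrough).
* Only thickness-axis (Z-axis) curvature is modeled; in-plane (XY)
  constriction curvature is out of scope.
* Thick-to-thin transitions facilitate conduction (concave wavefront).
  The model gives no magnitude for this, so edge velocities are capped at
  $1.5\,\theta_o$.

## Synthetic thickness maps

No raw canine maps are deposited, so the package generates the study
geometry. `make_isthmus_map()` embeds a thin channel (default 231 μm,
width 10 mm, length 23 mm - the mean measured isthmus length) in a thick
outer field (1440 μm), with three transition zones: a steep entrance ramp
(default 2 mm), a gradual exit ramp (default 6 mm), and steep lateral
ramps (default 1.5 mm). Ramps are linear in thickness over their stated
length, which makes $\Delta T/c$ constant across a ramp and every derived
quantity analytically checkable; the model prescribes only
"steep"/"gradual". The lateral default of 1.5 mm sits just inside the
~1.6 mm critical distance at the 200 ms VT rate, reproducing lateral
isthmus boundaries that block at VT rates, while the 2 mm entrance blocks
only at premature rates (critical distance 3.4 mm at 150 ms) and the 6 mm
exit conducts at both.

What the generator does *not* emulate: real border-zone thickness is
irregular rather than piecewise-linear, infarct holes and map-edge
truncation are absent (masked-out nodes are honored when reading external
rasters, but not generated), and thickness varies smoothly in three
dimensions rather than on a flat sheet. Passing tests therefore
demonstrate the internal consistency of the mechanism on idealized
geometry, not predictive accuracy on imaged hearts.

Maps are plain-text rasters (`write_map()`/`read_map()`, μm values,
optional `# spacing_mm=` header; a missing header falls back to 1 mm with
a warning).

## The wavefront simulator

`simulate_cycle()` marches activation over an 8-connected grid
(Dijkstra-style label setting): a node's activation time is the minimum
over incoming edges of the neighbor time plus edge length divided by the
edge velocity. Edge velocity applies the conduction law with the *signed*
directional $\Delta T/T$ over the edge, using the edge length as the local
space step; thick-to-thin edges are facilitated (capped as above). An edge
is impassable when its velocity is non-positive or when the rate-dependent
criterion predicts block: the local transition - the maximal
strictly-increasing thickness run through the edge, traced along the edge
direction - is compared against the critical space step at the cycle
length. Because the critical width is defined on [117, 200] ms but drive
trains and VT-scale cycles fall outside it, the simulator extends the
calibration log-linearly in $w$ versus cycle length (the calibration
triple is itself nearly exponential); `critical_width()` refuses
out-of-range cycle lengths unless an extrapolation mode is chosen
explicitly.

Numerical choices:

* **Grid metric.** On a uniform map, first-arrival times overestimate
  $r/\theta_o$ by at most the octile-metric factor $1/\cos(22.5°) \approx
  1.082$; tests assert this bound.
* **Tie-breaking.** Activation times are invariant to the order in which
  equal-time queue entries settle; a `tie_shuffle` option randomizes it so
  the property can be tested.
* **Refractoriness.** With a prior cycle supplied, an arrival earlier
  than the node's prior activation plus ERP fails at that interface (the
  wavefront is extinguished); a later wavefront from another direction may
  still capture the node.
* **Block-line drawing.** A halted interface is recorded where the
  wavefront from the thin end of a transition run fails; attempts from
  mid-transition nodes reached sideways belong to the same physical block
  line and are not drawn separately. Recorded interfaces between
  4-neighbors are chained into polylines by shared endpoints.
* **Degenerate inputs.** A fully blocked source yields an empty
  activation map with a diagnostic, not an error; uniform maps yield no
  blocked interfaces at any cycle length.

## The premature-stimulation protocol

`run_premature_protocol()` simulates the last S1 drive cycle, the S2 cycle
at the coupling interval, and - if a UBL forms - the first reentry cycle
V1:

1. **S2 block.** At a sufficiently short coupling interval the wavefront
   arriving from the gradual end is halted at the entrance ramp and along
   the lateral ramps: a single connected UBL capping the steep end on
   three sides.
2. **Pivot delay.** In mapped hearts, the bifurcated wavefronts round the
   UBL slowly: conduction about a pivot point is strongly slowed by
   convex curvature, and the observed arrival on the far side lags the
   block by on the order of 100 ms - far more than the geometric detour
   at $\theta_o$. A shortest-path solver prices edges independently of
   wavefront history and cannot produce this delay from geometry alone,
   so the package applies it as a lumped, configurable `pivot_delay`
   (default 100 ms) added to the V1 start times at the coalescence site.
   This is a deliberate deviation from a purely edge-local treatment:
   without it, recovery on the far side of the UBL never exceeds a
   physiological ERP on an open sheet and reentry could never be induced.
3. **V1 initiation.** V1 starts from the far side of the blocked
   interfaces with the largest activation-time discontinuity (the
   coalescence region distal to the UBL). The crossing back through the
   UBL is thick-to-thin - unidirectional block - and is admitted only
   where the proximal tissue has recovered (elapsed time at least ERP).
   The first re-excited proximal node is the breakthrough; its V1-minus-S2
   interval is the reexcitation interval.
4. **V1 rate.** Rate-dependent block during V1 is evaluated at the
   circuit's observed return time, estimated by a provisional V1 pass at
   the reexcitation scale and re-evaluated at the mean re-activation
   interval of the re-entered region (override with `v1_cycle_length`).
   At this VT-scale cycle length the lateral ramps still block -
   constraining V1 to the isthmus - while the exit conducts.

## Circuit metrics

`measure_circuit()` quantifies the overlap between the UBL and the VT
isthmus: distance from stimulus to the UBL leading edge (a), UBL
lateral-edge extent (b), isthmus length as the mean lateral-line arc
length (c), the axial overlap of UBL lateral edges with the lateral block
lines (d), the UBL-to-lateral-line distance as an error function (e), and
the percent overlap 100 d/c. The isthmus axis is estimated as the
principal direction of the lateral polylines' vertices; arc lengths of
disparate lateral lines are averaged arithmetically; distances are
segment-to-segment minima; dispersion uses the sample (n - 1) standard
deviation. All measurements are invariant under rigid motion of the
geometry. The per-experiment measurement tables of the 12 mapped canine
experiments ship as plain-text fixtures (`experiment_tables()`), and the
pooled means and standard deviations are recomputed from them. The pooled
lateral-alignment error (e) is not tabulated per experiment and therefore
cannot be reproduced from the fixtures.

## Problem sizes and defaults

The study geometry used throughout the tests is a 61 × 91 grid at 0.5 mm
spacing (30 × 45 mm of border zone). The half-millimetre step is chosen so
the 1.5 mm lateral ramp is resolved at its true length; at 1 mm spacing
the lattice renders it as a 2 mm transition, which no longer blocks at the
VT rate. The stimulus sits in the thick field beyond the exit end
(x = 42 mm on the channel axis), the drive train is 10 × 300 ms, and the
premature coupling interval 150 ms. A full protocol run takes a few
seconds; property tests use randomized maps of up to 7 × 7 nodes, where
the marching solver is checked against exhaustive relaxation.

## Known limitations

* The pivot delay is lumped, not emergent; its default reflects the scale
  of observed rounding times, and conclusions about absolute V1 timing
  inherit it. Relative statements (direction reversal, reexcitation
  shorter than the coupling interval, rate ordering of block) do not.
* Log-linear interpolation/extrapolation of the critical width rests on
  three calibration points; behavior far outside [117, 200] ms is a
  modeling convenience.
* The lattice quantizes transition lengths to multiples of the grid step
  along each direction, so block thresholds are sharp in the model but
  staircase-like on coarse grids.
* Electrogram morphology, fractionation, anisotropy, and multi-cycle VT
  stability are out of scope.
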