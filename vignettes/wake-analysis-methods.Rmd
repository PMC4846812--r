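---
title: "Wake reconstruction and weight support from transverse-plane PIV: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wake reconstruction and weight support from transverse-plane PIV: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(batwake)
```

## The measurement and the model behind the package

`batwake` analyses time-resolved stereo PIV measurements of animal wakes taken
on a fixed transverse plane behind a flying animal in a wind tunnel. Each
acquisition yields a sequence of vector fields: all three velocity components
(u streamwise, v spanwise, w vertical) on a regular y–z grid, at a frame rate
`f_L` (default 640 Hz), with the animal flying at the tunnel speed `U`
(1–5 m/s for the slow-flying bats this package was developed around). The
package covers everything that happens after the image cross-correlation:
vector validation, wake reconstruction, vortex identification and force
estimation. Camera calibration and correlation are out of scope, as is any
biological interpretation of the resulting wake topology.

Three physical ideas organise the code:

1. **Taylor frozen flow.** The wake convects past the sheet at `U` nearly
   rigidly, so acquisition time maps to streamwise distance, `x = U t`, and a
   frame sequence stacks into a pseudo-3D volume with out-of-plane spacing
   `U / f_L`. The sheet sits ~0.10 m behind the animal; at 2 m/s the wake is
   0.05 s old when measured, so deformation other than convection is treated
   as negligible. The volume is a *pseudo*-representation — no divergence-free
   projection or tomographic reconstruction is attempted, matching how such
   stacked volumes are used for structure identification in practice.

2. **Vorticity-moment (Trefftz-plane) force estimation.** The vertical force
   footprint of one frame is the first spanwise moment of streamwise
   vorticity,
   \[ F = 2\,\rho\,U \sum_{y > y_0} \omega_x(y,z)\,(y - y_0)\,\mathrm{d}y\,\mathrm{d}z, \]
   where \(y_0\) is the body symmetry plane and \(y - y_0\) the local
   semi-span arm. The factor 2 doubles the analysed semi-span: the imaged
   area covers more than half the span but not all of it, so one semi-plane
   is integrated and mirrored (an option integrates both semi-planes without
   doubling for full-span frames). Multiplying `F` by the inter-frame wake
   displacement `U/f_L` gives the per-slab impulse; summing over a transit
   recovers the hydrodynamic impulse of the wake. Averaged over a wingbeat
   and divided by `mass * g` (g = 9.81 m/s²) this yields percent weight
   support — the physical sanity check on every sequence. Sequences outside
   100 ± 20 % (inclusive boundaries) are discarded as having missed part of
   the wake.

3. **Q-criterion vortex identification.**
   \(Q = \tfrac12(\|\Omega\|_F^2 - \|S\|_F^2)\) on the smoothed isotropic
   volume marks rotation-dominated cores. Thresholds are absolute (default
   2500 s⁻², 2000 s⁻² for the weaker body-wake region, both configurable
   since Q normalisation conventions differ between implementations), and
   structures are 26-connected components of `{Q > threshold}` of at least 8
   voxels — the declared, reproducible counterpart of counting isosurface
   blobs by eye.

## The synthetic generator as ground truth

Because raw PIV recordings of this kind are rarely deposited, every stage is
validated against a vortex-filament generator with analytically known
answers. Wakes are closed polyline filaments with circulation Γ and a
Lamb–Oseen core \(r_c\); induced velocities are regularised Biot–Savart sums
in which each straight segment's kernel is multiplied by
\(1 - e^{-d^2/r_c^2}\). This choice (over a cutoff radius) gives closed-form
oracles: the tangential profile \(\Gamma/(2\pi r)(1 - e^{-r^2/r_c^2})\) and
the peak vorticity \(\Gamma/(\pi r_c^2)\) of a straight filament, and
\(\Gamma/(2R)\) at a ring centre. A closed loop carries vertical impulse
\(\rho\,\Gamma A\) (A its signed horizontal projection), the oracle for the
force estimator.

Four presets cover the wake topologies of interest: an isolated ring
(`single_ring`), the classical trailing pair (`trailing_pair`), a reversed
(upwash) loop above a start vortex (`reversed_loop` — the end-of-upstroke
signature responsible for momentary negative weight support at cruise), and a
flapping cruise wake (`cruise_wingbeat`): per wingbeat, a full-span
downstroke tip loop, an opposite-sense inner root loop (the reduced body-lift
feature typical of bat wakes), a reduced-span upstroke loop, a reversed loop
pair at the end of the upstroke, and a train of small tilted rings between
root and tip that emulates the pulsed, discrete loop structures seen along a
downstroke. The train defaults to 6 rings per side per downstroke, the
mid-range of visually counted structures in such wakes; their jets point up
and forward (normal 75° from vertical, tilted upstream), which keeps them
thin along x and disjoint at the out-of-plane resolution `U/f_L`.

Generator defaults are the study conditions and are not tuned per test:
`f_L = 640` Hz, ρ = 1.2 kg/m³, in-plane spacing 0.0024 m on a 127 × 85 grid
(~0.30 × 0.20 m, symmetric about y = 0 so the symmetry plane is a grid
plane), sheet distance 0.10 m, animal mass 9 g, wingbeat frequency 12 Hz
(the sheet-transit arithmetic of the original setup implies ~12.6 Hz at
2 m/s; 12 Hz is adopted as a round representative value), wake span 0.24 m.
Circulations are not free parameters: they are set by exact linear
calibration so the per-wingbeat loop impulse equals the weight-support
target (default 100 % of `m g T`), which puts the tip circulation near
0.17 m²/s at 4 m/s — a plausible magnitude for a ~9 g bat, though no
measured circulations exist for this species to anchor it. Measurement
imperfections are emulated at the vector level: additive Gaussian noise,
spurious vectors drawn uniformly within ±5 U (matching how gross
cross-correlation failures look relative to the free stream), and masked
dropout holes; all seeded and bit-reproducible.

What the generator does *not* emulate: leading-edge vortices, wake
self-deformation and instability, turbulence, correlated PIV noise, and
peak-locking. Passing tests therefore demonstrate correctness of the
*analysis* under frozen-flow conditions with idealised noise, not robustness
to every artefact of real recordings.

## Vector validation and repair

The original processing chain applied "1× outlier detection and a 2×
median-filter" in commercial software whose exact statistic is proprietary.
The package implements the standard median-test family those settings refer
to: one detection pass in which a vector is flagged when, for any component,
\[|u - \mathrm{med}| > k\,r_{med} + \epsilon, \qquad k = 2,\]
with med the median of the valid 3 × 3 neighbours (centre excluded, edge
cells use their sub-stencil, minimum 3 neighbours) and \(r_{med}\) the
median absolute residual about it divided by the Gaussian consistency
constant 0.6745, i.e. a robust estimate of the neighbourhood residual
standard deviation. The robust scale matters: at realistic
spurious densities a few percent of outliers land next to each other, and an
rms-type scale inflated by an outlying neighbour masks its companions,
whereas the median residual does not. The floor
\(\epsilon = 3 \times \mathrm{median}(r_{med})\) over the frame plays
the role of the epsilon in the normalised median test: a bare
\(2\sigma\)-type test flags several percent of honest Gaussian-noise vectors,
while the adaptive floor (a few noise standard deviations, vanishing exactly
on noise-free data) brings false positives to effectively zero without
affecting the detection of spurious vectors, which sit orders of magnitude
above it. Flagged vectors are replaced by the median of their clean
neighbours; cells left without enough clean neighbours, and masked holes, are
filled by row- and column-wise linear interpolation averaged where both
exist — exact for locally bilinear fields. Frames with under 50 % clean
vectors are refused outright: that is a failed acquisition, not a repair
problem.

## Numerical choices

* **Derivatives** are second-order central differences (one-sided at edges),
  matched to the resolution regime of PIV data; higher-order or spectral
  stencils would mostly amplify noise at 0.0024 m spacing.
* **Resampling** to the isotropic grid (default 0.0024 m) uses separable
  cubic splines with fmm end conditions, which reproduce cubics exactly —
  the behaviour the spline-interpolation step of the original chain relied
  on. The new grid covers the original extent with
  `floor(extent/spacing) + 1` points per axis.
* **Smoothing** is a truncated, unit-sum, separable 5 × 5 × 5 Gaussian. Only
  the kernel size is stated in the original chain; σ = 0.65 voxels is the
  documented default of the smoothing routine that kernel size refers to,
  and it is exposed in the configuration. Boundaries replicate the nearest
  edge value.
* **Momentary forces use raw repaired frames**, not the smoothed volume:
  smoothing redistributes vorticity and biases the first moment, and the
  momentary series is wanted at full temporal resolution. Whether the
  original analysis interpolated before or after force integration is
  unstated; volumes here serve fields and structures only. Both per-wingbeat
  and whole-sequence percentages are reported, since the original statistic
  is ambiguous between them.
* **Frame ordering**: the earliest-acquired frame lies farthest downstream
  (the wake shed first crossed the sheet first); an `"acquisition"`
  orientation flag provides the mirror image for flight-direction
  visualisation.
* **Body-centre location** automates the "symmetry plane of the wake
  structures" criterion: grid-plane candidate minimising the summed squared
  mismatch between \(\omega_x\) and its mirrored negation, searched over the
  central half of the grid; a manual override always wins. Accuracy is half
  a grid cell on symmetric synthetic wakes.
* **Wingbeat delimitation** (unstated in the original chain) estimates the
  period from the first significant autocorrelation maximum of the force
  series (parabolic refinement) and cuts at successive maxima of the
  period-smoothed series; explicit intervals always take precedence, and
  aperiodic series are an error rather than a guess.
* **Structure circulation** integrates the vorticity component along the
  structure's principal axis over a window around the largest connected
  in-slice cluster of member voxels (bounding box padded by 2.5 equivalent
  radii). The window must extend beyond the Q core — a Lamb–Oseen filament
  keeps ~30 % of its circulation outside the rotation-dominated region — and
  must *not* span a whole plane, through which any closed loop nets zero.
  Restricting to one in-slice cluster keeps the two crossings of a loop from
  cancelling; recovery is within 5 % for well-separated synthetic filaments
  and degrades gracefully when structures crowd each other.
* **Structure sense** (upwash/downwash) is the sign of the mean vertical
  velocity over member voxels. It reflects the *total* local flow: an
  isolated reversed loop classifies as upwash, but a small upwash ring
  embedded in the strong downwash of a lifting system can classify as
  downwash. This matches what colour-coded isosurfaces show.

## Problem sizes and runtime

Validation runs use the full acquisition grid (127 × 85 vectors at 0.0024 m)
with wake transits of 40–120 frames, and volumes up to ~170 × 126 × 84
voxels after isotropic resampling — one wingbeat of wake at cruise speed.
These sizes keep a complete synthetic study (ring-impulse oracle, ten noisy
cruise recoveries, and a full volume segmentation) in the minutes range on a
single core while exercising every code path at study resolution.

## Known limitations

* The outlier statistic matches the stated multipliers of the original
  chain, but the proprietary implementation may differ in detail; the
  false-positive/recall guarantees quoted here are for this package's rule.
* Structure counts depend on threshold, connectivity and `min_size`; the
  original counts were visual, so only self-consistency with the generator
  is claimed, not number-for-number agreement with the published figures.
* The frozen-flow volume is not divergence-free and its Q field is a
  pseudo-representation; thresholds tuned on it should not be compared
  across datasets with different `U/f_L`.
* `filter_sequences` treats the ±20 % boundary as inclusive; the original
  wording does not resolve this, and the choice is configurable.
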