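# batwake

Wake analysis for flapping-flight PIV: from time-resolved transverse-plane
velocity fields to vortex structures and weight support.

Wind-tunnel studies of animal flight measure the flow on a fixed laser sheet
behind the flying animal with time-resolved stereo particle image
velocimetry (PIV). The wake convecting through that plane is the animal's
aerodynamic footprint: trailing tip and root vortices, start and stop
vortices, and — averaged over a wingbeat — the vertical force that keeps the
animal airborne. `batwake` implements the post-correlation analysis chain
for such recordings, developed around the wake of slow-flying bats:

* **Vector validation and repair** — a one-pass normalised-median outlier
  test (threshold multiplier k = 2) with median replacement and
  interpolation of holes.
* **Pseudo-3D reconstruction** — frames stacked at streamwise spacing
  `U/f_L` (Taylor frozen flow), resampled to an isotropic 0.0024 m grid by
  cubic splines and smoothed with a 5×5×5 Gaussian kernel.
* **Vortex identification** — the Q-criterion
  `Q = ½(‖Ω‖² − ‖S‖²)`, thresholded (default 2500 s⁻²; 2000 s⁻² for the
  weaker body-wake region) and segmented into 26-connected structures with
  per-structure circulation, induced-flow sense and counts.
* **Weight support** — the Trefftz-plane vorticity-moment estimate

  `F = 2 ρ U Σ_{y>y₀} ω_x(y,z) (y − y₀) dy dz`,

  i.e. the first spanwise moment of streamwise vorticity about the body
  symmetry plane y₀, doubled for the analysed semi-span. Wingbeat means are
  expressed as percent of body weight `m g`; sequences outside 100 ± 20 %
  are rejected as having missed part of the wake.
* **A synthetic vortex-filament generator** (regularised Biot–Savart with
  Lamb–Oseen cores) whose loop wakes have analytically known impulse
  `ρ Γ A`, so the whole chain is validated end to end without experimental
  data.

## Worked example

A cruise-speed wingbeat wake calibrated to 100 % weight support, sampled
into noisy PIV frames at the study conditions (640 Hz, 0.0024 m vector
spacing, ~0.30 × 0.20 m plane), repaired, and analysed:

```r
library(batwake)

meta  <- sequence_meta(U = 4, mass = 0.009)          # 9 g animal at 4 m/s
wake  <- build_scenario("cruise_wingbeat", list(U = 4, mass = 0.009))
noise <- noise_spec(velocity_noise_sd = 0.04,        # 1% of U
                    spurious_fraction = 0.02, rng_seed = 1)

frames <- sample_plane_sequence(wake, meta, noise)
frames <- preprocess_sequence(frames, verbose = TRUE)
#> preprocess: 118 frames, 26171 vectors flagged, 0 holes filled

Tw <- attr(wake, "wingbeat_period")
tt <- vapply(frames$frames, function(f) f$timestamp, 0)
b  <- vapply(0:2, function(k) which.min(abs(tt - k * Tw)), 0L)
rec <- sequence_weight_support(frames,
                               wingbeats = data.frame(start = b[1:2],
                                                      end = b[2:3] - 1L))
rec
#> force_record: 118 frames, 2 wingbeats, weight support 99.5% (accepted)
rec$wingbeat
#>   wingbeat start end mean_force_N weight_support_pct accepted
#> 1        1     6  58       0.0884              100.1     TRUE
#> 2        2    59 112       0.0874               98.9     TRUE
```

The generator put exactly `m g T = 0.00736` N s of vertical impulse into
each wingbeat's loops; the vorticity-moment estimator reads 100.1 % and
98.9 % of body weight back out of the noisy frames, and the sequence passes
the ±20 % quality filter. For wake topology, continue to the volume:

```r
vol <- smooth_gaussian(resample_isotropic(stack_volume(frames), 0.0024))
q   <- q_criterion(vol)
st  <- characterize(segment_structures(q, threshold = 2500, min_size = 8), vol)
export_vtk(vol, "wake.vtk", fields = list(Q = q, omega_x = vorticity(vol, "x")))
```

`st$table` lists each structure's voxel count, volume, centroid, mean
vertical speed (upwash/downwash sense) and circulation;
`color_scale_limit(vol)` gives the vertical-speed colour limit
(mean |w| + 3 SD) used for rendering.

A command-line driver wraps the same steps
(`Rscript inst/cli/batwake.R pipeline --scenario cruise_wingbeat --seed 1
--out run1`), with subcommands `simulate`, `preprocess`, `analyze`,
`report`, and a plain-text key-value config whose defaults are the study
conditions.

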