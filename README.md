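# pindrop

Image-sensed droplet volumetry and feedback-controlled nanoliter dispensing,
as an R package.

Contacting (pin-based) dispensers deposit nanoliter droplets by dipping a
slotted pin into a sample reservoir and striking it against a chip; the
dispensed volume depends on the pin's downward velocity `v` and dipping depth
`h`, and slowly decays as the reservoir level falls. `pindrop` implements the
software side of such an instrument, hardware-free:

* **Imaging** — a top-view grayscale image of the deposited droplet is median
  filtered (10 × 10 window), segmented by Otsu's threshold (maximizing the
  between-class variance ω₀ω₁(μ₁ − μ₀)² of the gray-level histogram), and
  reduced to the pixel area of the largest connected foreground component,
  holes filled. Moore-neighbour tracing recovers the outer outline and inner
  edges.
* **Volumetry** — the footprint area `A` (pixels) becomes a volume through a
  spherical-cap model with contact angle θ and the fiducial scale
  `D_ref/D_pix` (mm per pixel):

  V = (π/3) · (D_ref/D_pix · R₀)³ · (cos³θ − 3 cos θ + 2),   R₀ = √(A/π)

  At θ = 90° this is exactly a hemisphere of the scaled footprint radius.
* **Dispense model** — the empirical law `Volume = f(v, h)`, represented by
  bilinear interpolation of a measured velocity × depth calibration grid
  (shipped as `inst/extdata/table1.csv`), with exact inversion of depth at
  fixed velocity.
* **Control** — a closed-loop simulator: model-inversion feedforward plus an
  integral correction on dipping depth regulates the measured volume to a
  setpoint (default 100 nL) against reservoir-level drift, with anti-windup
  at the depth bounds, alongside an open-loop baseline for comparison.
* **Synthetic bench** — seeded renderers for droplet and reference-point
  images (anti-aliased disk, illumination gradient, salt-and-pepper and
  Gaussian noise) with exact ground truth, and a stochastic dispense process
  (≈1 % multiplicative volume noise, monotone level drift), so the entire
  pipeline is testable without a camera or a robot.

Who it is for: engineers building or validating droplet-on-demand liquid
handlers (e.g. for MALDI-TOF sample spotting), and anyone who needs a
reproducible reference implementation of sessile-droplet volumetry from
top-view images.

## Worked example

```r
library(pindrop)

# pixel-to-mm scale from a rendered fiducial image (two dots 260 px apart)
ref <- render_reference_points(260, d_ref_mm = 1.2, seed = 1)
scale <- calibrate_scale(ref$image, 1.2)
scale
#> <scale_calibration> D_ref 1.2 mm / D_pix 260 px = 0.00461538 mm/px

# render a 100 nL droplet (theta = 86.3 deg) and measure it back
scene <- render_droplet(scene_spec(volume_nl = 100, theta_deg = 86.3, seed = 7))
measure_droplet(scene$image, 86.3, scale)
#> <droplet_measurement> 99.78 nL (area 20741 px, R0 81.25 px, theta 86.3 deg, k* = 145)

# closed-loop regulation vs the open-loop baseline under reservoir drift
cmp <- compare_strategies(controller_config(), process_spec(),
                          n_steps = 50, n_replicates = 20, seed = 1)
cmp
#> <strategy_comparison> setpoint 100 nL, 50 steps x 20 replicates
#>   closed loop: steady-state MAE 1.36 nL, mean 99.01 nL (SD 1.43)
#>   open loop:   steady-state MAE 49.67 nL, mean 50.33 nL (SD 7.27)
#>   closed loop wins on MAE in 100% of paired replicates

# repeatability statistics of a packaged measurement series
summarize_measurements(repeatability_table("volumes")$depth_3)
#> <run_summary> n = 10, mean 61.71, SD 0.13, CV 0.21%
```

Reading the numbers: the measured droplet comes back within 0.3 % of the
100 nL ground truth after the full filter → threshold → area → cap-model
chain; under a 0.02 mm/step reservoir drift the feedback loop holds the
50-step runs at 99.0 nL on average while the fixed-depth baseline decays to
≈50 nL; and the packaged repeat-dispense series at 3 mm depth reproduces its
published mean 61.71 nL and SD 0.13 nL.

## Command line

A thin CLI wraps the same functions (installed under `exec/`):

```sh
Rscript "$(Rscript -e 'cat(system.file("exec","pindrop",package="pindrop"))')" \
    generate --outdir /tmp/drops --n 10 --volume 100
# ... then: measure, calibrate-scale, simulate, compare  (--help on each)
```

## Further reading

The methods vignette (`vignettes/droplet-volumetry.Rmd`) documents the
models, the measurement conventions (window anchoring, tie-breaking, hole
filling), the controller design and its gain choice, what the synthetic
bench does and does not emulate, and known limitations.
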