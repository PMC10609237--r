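---
title: "Droplet volumetry and dispense control: models and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Droplet volumetry and dispense control: models and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pindrop)
```

`pindrop` turns top-view images of deposited nanoliter droplets into
calibrated volumes, and simulates the feedback loop a contacting dispenser
uses to hold those volumes at a setpoint. This vignette is the package's own
account of the underlying models, the conventions chosen where several were
defensible, and what the synthetic test bench does and does not establish
about real data.

## The sensing chain

### Gray levels and the histogram

Images are integer matrices of intensity *levels* in `[1, S]` with
`S = 256`; file I/O maps 8-bit storage `0..255` to levels `1..256` at the
boundary. Working 1-based keeps the histogram quantities literal: level `i`
has count $n_i$, total $N = \sum_i n_i$, and probabilities $p_i = n_i / N$
treated as a discrete distribution.

### Median filtering

Salt-and-pepper sensor noise is removed by a sliding-window median with a
10 × 10 default window, large enough to kill isolated specks without
rounding the droplet rim away. Three conventions cover cases the usual
odd-square presentation leaves open:

* **Anchoring.** An even window has no centre pixel. The output pixel sits
  at offset $(\lfloor (h-1)/2 \rfloor, \lfloor (w-1)/2 \rfloor)$ from the
  window's top-left corner, which is deterministic and reduces to the centre
  for odd windows. The induced half-pixel shift translates the image without
  changing any area.
* **Borders.** Reflect padding. Zero padding would darken the frame edge
  and, with a dark-foreground threshold, manufacture spurious foreground.
* **Even pixel counts.** The *lower* median (no interpolation), so output
  intensities remain in the input's value set — an integer image stays an
  integer image. A side effect worth knowing: on a 50/50 split the darker
  value wins, which slightly favours foreground at edges and in practice
  offsets most of the inward bias that curvature induces in a median filter.

### Otsu thresholding

The threshold $k^*$ maximizes the between-class variance
$\sigma_B^2(k) = \omega_0\omega_1(\mu_1 - \mu_0)^2$ over all $k$ with
$0 < \omega(k) < 1$, where $\omega_0, \omega_1$ are the class probabilities
and $\mu_0, \mu_1$ the class mean levels of the low class (levels
$1..k$) and high class ($k+1..S$). Two numerical notes:

* Ties are broken to the smallest maximizing $k$, for determinism. With a
  genuinely empty gap between two spectral modes the criterion is constant
  across the gap and the lowest level wins; any anti-aliased edge
  population breaks the plateau and places the maximum between the modes.
* The identities $\omega_0 + \omega_1 = 1$ and
  $\omega_0\mu_0 + \omega_1\mu_1 = \sum_i i\,p_i$ hold at every admissible
  $k$; the test suite asserts them to $10^{-9}$ during the scan
  (`otsu_scan()` exposes the full criterion curve).
* A histogram with a single occupied level admits no threshold and raises a
  degenerate-histogram error rather than returning an arbitrary level.

### Polarity, components, holes

Droplets image darker than the lit chip surface, so the default polarity
takes levels $\le k^*$ as foreground; it is an argument (and a CLI flag)
because other optics invert it. Foreground components are 8-connected
(background is its 4-connected dual). The droplet is the largest component
*after hole filling*: specular highlights punch holes into the imaged disk,
but the deposited droplet is a solid cap, so interior background regions are
counted as droplet. Smaller components are satellites and are reported, not
counted.

### Contours

Moore-neighbour tracing produces one closed outer contour per component and
one inner contour per hole, as ordered $(Y, X)$ coordinate lists (row
first, 0-based) whose consecutive points are 8-neighbours. The walk refuses
to cut corners: when a diagonal step would skip an orthogonal foreground
pixel that touches the just-scanned background diagonally, the orthogonal
pixel is visited first. With that refinement the union of contour pixels is
*exactly* the set of foreground pixels 8-adjacent to background (the test
suite asserts set equality against a brute-force boundary test on random
blobs), and termination is by repetition of the (pixel, backtrack) state,
which closes the loop even for one- and two-pixel objects.

## From area to volume

### Scale

An image of two fiducial marks a known distance $D_{ref}$ (mm) apart is
pushed through the same filter → threshold → components pipeline; $D_{pix}$
is the distance between the two nearest-neighbour component centroids.
Centroids of rendered dots are recovered to well under half a pixel, which
is the tolerance the tests enforce. Fewer than two detected marks (including
the overlapping-dots degenerate case) is a calibration failure, not a guess.

### The spherical cap

A sessile droplet small enough for surface tension to dominate gravity is a
spherical cap. Slicing a sphere of radius $R$ into infinitesimal disks gives
the cap volume

$$V \;=\; \int_{R-h}^{R} \pi\,(R^2 - y^2)\,dy \;=\; \pi R h^2 - \tfrac{1}{3}\pi h^3
\;=\; \tfrac{\pi h^2}{3}(3R - h),$$

which runs from $0$ at $h = 0$ through the hemisphere $2\pi R^3/3$ at
$h = R$ to the full sphere $4\pi R^3/3$ at $h = 2R$. (A superficially
similar form with $R^2 h$ in place of $R h^2$ circulates in print; it is
wrong — it goes negative for $h > \sqrt{3}R$ — and the package's quadrature
oracle test would catch it.) With contact angle $\theta$, the footprint
radius is $R_0 = R\sin\theta$ and the cap height $h = R(1 - \cos\theta)$,
which collapses to

$$V \;=\; \frac{\pi}{3}\left(\frac{D_{ref}}{D_{pix}} R_0\right)^3
\left(\cos^3\theta - 3\cos\theta + 2\right)$$

with $R_0$ in pixels. The shape factor
$g(\theta) = \cos^3\theta - 3\cos\theta + 2$ satisfies $g(0) = 0$,
$g(90^\circ) = 2$, $g(180^\circ) = 4$ and is strictly increasing, so volume
is strictly increasing in $\theta$ at fixed footprint.

**Footprint radius extraction.** The measured quantity is an area, not a
radius; `pindrop` uses the equivalent-circle radius $R_0 = \sqrt{A/\pi}$.
This is the unique rule that uses the measured area directly and agrees
with the exact radius for a perfect disk. It is a genuine design choice:
published per-droplet volumes from instruments of this type are not always
reproducible from their published areas under any single stated extraction
rule, so the package documents its rule explicitly rather than tuning
toward any particular printed volume table.

**Contact angles.** Angles are inputs (degrees), looked up from a fluid
table (density, viscosity, angle). An exact record match returns the
tabulated angle; otherwise the angle is interpolated piecewise-linearly in
viscosity and clamped to the tabulated range. With only four anchor fluids
shipped, any parametric fit (exponential, power law) would over-claim;
linear-with-clamping is the least-commitment interpolant, and over the
packaged anchors the angle decreases monotonically with viscosity.

## The dispense law and its inversion

The dispenser's output is an empirical function $\mathrm{Volume} = f(v, h)$
of pin velocity and dipping depth, represented as bilinear interpolation on
a measured 4 × 6 grid (`table1_grid()`). Bilinear is deliberate: the grid is
coarse and one region is non-monotone across depth, so shape-preserving
splines would over-fit; bilinear is exact at every node (asserted with
`==`, not a tolerance) and linear in between. Queries outside the calibrated
envelope clamp to the edge with a warning — behaviour out there was never
measured. The packaged grid also dips once with *velocity* (at 150 mm/s) in
its two deepest columns; the data ship as printed, uncorrected.

`invert_for_depth()` solves $f(v, h) = V$ for the smallest $h$ at fixed $v$
by exact per-segment linear solves on the piecewise-linear depth profile
(residual below 0.01 nL; cross-checked against bisection). Depth, not
velocity, is the actuation variable, matching how such instruments trim
volume in service. Unreachable targets raise an error carrying the
achievable `[min, max]` range.

**Extension.** The measured grid tops out near 76 nL, while practical
setpoints run to 200 nL, so the control simulator works on
`extend_calibration(grid, 5)`: depth nodes appended to 5 mm by continuing
each velocity's last segment linearly. Volume grows monotonically with
depth at the envelope edge, making a linear continuation the conservative
choice; it is still an extrapolation and is confined to the simulation
layer — measurement code never needs it.

## The control loop

The controller is model-inversion feedforward plus integral correction on
depth:

* feedforward: $h_{ff} = f^{-1}(v, V_{set})$, the model's best single guess;
* correction: an accumulator $I_{k+1} = I_k + \mathrm{clip}(K_i e_k,
  \pm\Delta_{max})$ on the volume error $e_k = V_{set} - V_k$;
* command: $h_{k+1} = \mathrm{clip}(h_{ff} + I_{k+1},\ [h_{lo}, h_{hi}])$.

Zero error leaves the command unchanged; a low measurement deepens the dip
(volume increases with depth); $K_i = 0$ reduces the loop *exactly* to the
open-loop baseline, trajectory for trajectory. When the command saturates at
a depth bound the accumulator freezes (anti-windup) and a warning is raised
after 5 consecutive saturated steps.

**Gain choice.** The modelled disturbance is a reservoir level falling
`drift_mm_per_step` = 0.02 mm per dispense — a ramp. A pure integral loop
tracks a ramp with steady-state error $\mathrm{drift}/K_i$ nL, so the
default gain must be read against the drift: $K_i = 0.02$ mm/nL leaves a
1 nL (1 %) standing error at the default drift while keeping the loop gain
$K_i \cdot \partial f/\partial h \approx 1.2$ inside the stable range and
the noise amplification modest. A materially smaller gain (e.g. 0.005)
cannot hold a 2 % band against this drift — the standing error alone would
be 4 nL — which is why the default is what it is.

Other defaults: setpoint 100 nL (the instrument class's working point),
velocity 1000 mm/s held fixed, `max_step_mm` 0.2 (one command may not move
the pin more than a fifth of the usable depth range), bounds `[2, 5]` mm
(the extended grid's envelope). `compare_strategies()` runs paired
replicates — closed and open loop see identical noise realizations per
seed — and reports settling step (first step after which the error stays
inside a 5 % band; the band is this package's definition), steady-state MAE
and volume SD over the trailing window (default 20 steps of 50).

## The synthetic bench

`render_droplet()` inverts the cap model: true volume, angle and scale give
the exact footprint radius, drawn as a darker disk on a lit background with
4 × 4 supersampled rim coverage (sub-pixel area fidelity, so round-trip
tolerances are meaningful), a linear illumination gradient across the frame
(default 15 levels peak-to-peak — enough to exercise the threshold under
non-uniform lighting without defeating a global threshold), salt-and-pepper
noise (default 0.5 % of pixels) and Gaussian noise (default σ = 2 levels).
Default levels are background 200, droplet 90. All randomness flows from the
scene seed; the same seed reproduces the image bit for bit.

`simulate_dispense()` draws volumes as
$f_{true}(v, h - k\cdot\mathrm{drift}) \cdot (1 + \varepsilon)$,
$\varepsilon \sim N(0, \mathrm{CV})$ truncated at zero, with CV = 1 % by
default — the repeatability scale of the packaged measurement series. An
exhausted reservoir (effective depth ≤ 0) is a dry-dip error, not a zero.

**What passing tests show, and what they do not.** The bench exercises
non-uniform illumination, impulse and Gaussian noise, sub-pixel geometry,
satellite specks and level drift. It does not render refraction at the
droplet rim, specular highlights, partial wetting irregularity,
non-circular footprints, gravity-flattened caps, motion blur or focus
error. Round-trip accuracy on the bench is therefore a statement about the
pipeline's internal consistency under controlled degradation, not a
validation against physical droplets; the contact angle in particular
enters as an input and its physical measurement is out of scope.

## Problem sizes and tolerances in the shipped tests

The suite keeps simulations small enough to run in seconds while leaving no
tolerance slack to chance: 500 random histograms against the exhaustive
Otsu oracle; full-stack round trips at footprint radii 40–100 px in
320 × 320 frames (recovery within 2 % at default noise, 0.5 % noiseless);
50-step control runs with 20 paired replicates (closed-loop steady mean
within 2 % of the setpoint, closed MAE below open MAE in every pair);
repeatability statistics asserted to the printed precision of the packaged
tables (the sample, $n-1$, SD is the convention that reproduces them).
`scripts/acceptance.R` recomputes the same quantities from scratch at any
seed.

## Known limitations

* The cap model assumes Bond number ≪ 1; hundreds-of-nanoliter droplets of
  aqueous fluids qualify, but larger or denser drops flatten and the model
  overestimates their height.
* The dispense law is purely empirical; between and especially beyond
  calibration nodes it interpolates, it does not explain. The depth
  extension used by the simulator inherits this with interest.
* Contact-angle interpolation rests on four anchors; fluids far outside
  their viscosity range clamp to an endpoint angle.
* The controller holds one setpoint per run; setpoint scheduling, velocity
  co-actuation and model re-identification online are out of scope.
* Thresholding is global and two-class; vignetting strong enough to merge
  the droplet and background modes would defeat it.
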