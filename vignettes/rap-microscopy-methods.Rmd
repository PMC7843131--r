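---
title: "Models and methods behind rapmicro"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind rapmicro}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rapmicro)
```

## The imaging geometry

A random-access parallel (RAP) microscope parks one objective lens above
every sample and a single fast camera at the focus of a large parabolic
mirror. Lighting exactly one sample's LED per camera frame selects which
sample the sensor sees, so the system hops between samples at the camera
frame rate with no moving parts. Two geometric consequences follow for a
sample whose objective axis sits a lateral distance $y$ (mm) from the
mirror axis:

1. **Oblique stretch.** The chief ray meets the detector at
   $\theta = 2\arctan\!\big(y/2f_M\big)$, where $f_M$ is the mirror focal
   length. The image forms normal to the chief ray, so the detector
   records it stretched along the displacement axis by
   $S = 1/\cos\theta \ge 1$ (`stretch_factor()`).
2. **Residual magnification.** The distance from the reflection point to
   the focus, $V(y) = \sqrt{y^2 + (f_M - y^2/4f_M)^2}$, grows with $y$,
   and the magnification is $M = V/f_L$ in both image axes
   (`magnification()`). The combined per-axis magnification is
   $(M\,S,\; M)$.

Both effects are exactly invertible, which is the point of the package:
`forward_project()` applies the anisotropic scaling (relative to the
on-axis view, so $y=0$ is the identity) and `rectify()` applies its exact
inverse. The remaining scalar optics are one-liners with the unit
conventions fixed at construction (mm for lengths, µm for the circle of
confusion and PSF widths, nm for wavelengths): depth of field
$2u^2Nc/f^2$ which reduces to $2Nc$ at the working condition $u=f$,
numerical aperture $\sin(\arctan(d/2f))$, defocus span $D_s\sin\theta$,
and the diffraction scale $0.6\,\lambda/\mathrm{NA}$.

Two readings in those conventions deserve a note. The circle of confusion
is taken as 36 µm — twice the 18 µm lateral resolution — because only
that reading reproduces the quoted 0.9 mm depth of field. The 0.6
resolution prefactor with the 6 mm/72 mm objective gives 8.97 µm where
9.1 µm is usually quoted (the classical 0.61 coefficient gives 9.12 µm);
we keep the 0.6 convention and accept the ~2 % discrepancy rather than
silently switching coefficients. Similarly, the defocus span at the
widest usable displacement evaluates to 2.03 mm; we report the exact
value and do not clamp it to the conventional "under 2 mm" summary.
Angles are radians internally (`as_degrees()` is presentation only), and
$y$ is non-negative because every formula is even in it.

## Rectification: numerical choices

Resampling is inverse-mapped bilinear interpolation about the geometric
image centre, with a constant fill for out-of-field samples. Bilinear is
deliberate: the raw data are 8-bit bright-field frames whose content is
low-frequency, and higher-order kernels buy nothing measurable while
introducing ringing at the dish walls. The transform centre is the image
centre (not an intensity centroid) because alignment places the chief ray
near the sensor centre. A request that would shrink an image below 2 px
is an error rather than a degenerate resample. On band-limited test
images the forward–inverse round trip stays below 2 % RMS of the dynamic
range across the usable displacement range; on a synthetic 200 µm grid
warped at $y = 70$ mm, rectification restores the cell aspect ratio to
1.00 ± 0.02 and corner positions to within half a pixel (the package's
`synth_grid_image()`, `locate_spots()` and `lattice_spacing()` make that
measurement reproducible). The same bilinear core is cross-checked in the
test suite against an independently implemented affine resampler.

Stack preprocessing mirrors the instrument's conventions:
`normalize_stack()` is a *per-stack* min–max map to [0, 255] (per-frame
scaling would distort the temporal signals the activity analyses use; a
constant stack has no contrast and comes back as zeros with a warning),
and `crop_center()` takes centred crops with the extra pixel of an odd
margin discarded on the high-index side.

## Scheduling and demultiplexing

Round-robin scheduling gives each of $n$ samples one frame per cycle, so
each runs at `base_fps / n`: a 500 fps camera covers 50 dishes at 10 fps
or two at 250 fps. The plate scan is block mode: groups of 8 wells are
interleaved for 100 cycles each (800 frames per block), then the scan
moves on — 80 wells in 8000 frames, 67 s at 120 fps. Disk bandwidth caps
the base rate as `disk_rate / frame_size` with frame sizes in binary
megabytes (2^20 bytes), the convention under which a 1280 × 1024
single-byte frame is exactly 1.25 MB and 150 MB/s sustains 120 fps; the
decimal convention reproduces neither printed number. Frame $k$ is
timestamped $(k-1)/\mathrm{fps}$; LED switching and exposure are treated
as instantaneous, which at sub-millisecond switching and 120–500 fps is
below one timestamp quantum. `demultiplex()`/`remultiplex()` are exact
inverses and conserve frames by construction; both are property-tested.

## Cardiac motion analysis

Contraction is visible dye-free as intensity change:
`motion_signal()` computes $|P_t - P_{t-n}|$ per pixel with the
conventional lag of $n = 6$ frames, and `roi_trace()` averages a
20 × 20 px window, yielding the familiar two transients per beat (one at
contraction, one at relaxation — the test suite asserts exactly two peaks
per cycle on simulated beats).

The activation-time definition is the package's own choice, since the
upstream description defers to prior optical-mapping practice: the motion
signal is smoothed with a 3 px spatial box and 3-frame temporal mean,
then each pixel's activation is the first crossing of 50 % of its own
temporal maximum, linearly interpolated between frames; pixels whose
maximum stays under 5 % of the global maximum are unactivated. All four
numbers are arguments, so alternative conventions are one call away.
`conduction_velocity()` fits activation time as an affine function of
position by least squares; speed is the reciprocal gradient magnitude
scaled by the pixel pitch, direction is the gradient orientation, and a
gradient below 1 µs/px is reported as quasi-simultaneous activation
rather than an absurd speed.

## Worm activity

`worm_activity()` implements the plate metric literally: over consecutive
frame pairs of a 0–255-normalized stack, count pixels whose absolute
change strictly exceeds 65 intensity units, sum, and divide by the number
of pairs. The threshold default is 65 — the documented value — rather
than 25 % of 255 (63.75); both are reachable through the argument. "100
frames analysed" is read as 100 frames, i.e. 99 pairs. The raw per-frame
count is the primary report, with the per-pixel fraction alongside, since
the narrative mixes both. `compare_groups()` is a two-tailed two-sample
t-test; Welch's unequal-variance flavour is the default (the pooled test
is an argument) because nothing in the protocol justifies assuming equal
well-to-well variance, and identical degenerate groups return p = 1 by
convention.

## PSF estimation from grid contrast

The lateral PSF width is inferred from how much a known calibration grid
(20 µm opaque lines, 40 µm period = 25 line pairs/mm) washes out: render
the binary transmission profile, convolve with a normalized Gaussian of
full width at half maximum $w$, and read the ratio of gap-centre to
line-centre intensity. Contrast is strictly decreasing in $w$, so
`fwhm_from_contrast()` inverts it by bisection to 0.05 µm.

Choices worth knowing: the PSF is an isotropic Gaussian parameterized by
FWHM (the simplest defensible shape, and pluggable); the default profile
is 1-D — a cut across a line far from crossings — with the separable 2-D
crossed-grid variant available (its contrast is the square of the 1-D
value, measured cell-centre to crossing); and contrast is *bright/dark*,
hence > 1, inverting the ratio as sometimes stated, because measured
values above 1 admit no other reading. The convolution is numeric
(periodic, area-weighted edges, ≥ 200 samples per period) so non-Gaussian
PSFs drop in; the Gaussian closed form via error functions is kept as the
independent oracle in the tests, which agree to better than 0.5 %.
Because the exact forward model behind published (contrast, FWHM) pairs
is unstated, the shipped contrast measurements
(`inst/extdata/grid_contrast_measurements.csv`) are used as an ordering
and range fixture, not as exact targets. Relative modulation below 1e-6
is reported as "saturated": it is below both the numeric floor of the
truncated kernel and anything measurable in 8-bit data.

## The synthetic-data generator

`simulate_monolayer()` renders a planar contraction wave: each pixel's
intensity is a baseline plus a smooth pulse — raised-cosine upstroke
(60 ms), plateau (200 ms), raised-cosine relaxation (120 ms) — delayed by
$(x\cos\varphi + y\sin\varphi)/v$ and repeating at the beat period (1 s
default, a typical spontaneous monolayer rate). Defaults are a
100 × 100 px field at 20 µm/px (a 2 × 2 mm field of view), 40 fps, and
20 mm/s wave speed, all in the range reported for cultured neonatal
cardiac monolayers. The ground-truth activation plane and speed come back
beside the pixels, so accuracy tests never reference biological data.

`simulate_worms()` renders each animal as a dark sinusoidal polyline
(soft-edged, 3 px wide) whose undulation phase advances by
$2\pi f/\mathrm{fps}$ per frame and whose centroid performs a reflected
random walk. The undulation amplitude default (2.5 px) keeps the
frame-to-frame body displacement at wild-type thrash rates comparable to
the body width at the 15 fps acquisition rate — the regime in which the
pixel-change metric tracks thrash frequency rather than saturating, and
the regime the instrument demonstrably operated in when it separated
wild-type from slow mitochondrial-mutant animals. Note that at 15 fps the
phase steps of 5 Hz and 10 Hz thrashing are congruent modulo $2\pi$
(temporal aliasing), so monotonicity of the metric across 2–10 Hz is a
property of adequately sampled motion; the corresponding property test
runs at 30 fps, while the strain-discrimination test (5 Hz vs 2 Hz) runs
at the instrument's 15 fps, where the two are far from aliased.

`render_plate()` composes the full forward model: per-sample geometric
distortion, brightness falloff $e^{-\beta y}$ (β = 0.004/mm default,
matching the qualitative dimming of far wells), displacement-dependent
Gaussian blur, optional chromatic defocus, and additive Gaussian noise
clipped to the 8-bit range — then interleaves everything per the LED
schedule. The chromatic focal shift of the singlet objectives (981 µm
red-to-blue) is modelled as extra Gaussian blur of width
$\mathrm{offset}\times\mathrm{NA}$, the diameter scale of the geometric
defocus disc; with NA = 0.042 that is ≈ 41 µm, enough to reproduce the
in-focus/out-of-focus flip between LED colours without any wave-optics
machinery.

Everything is seeded and bit-reproducible, including the acceptance
pipeline end to end.

### What the simulator does and does not establish

The generator reproduces the *geometry* and *phenomenology* the analysis
code depends on: travelling biphasic waves, undulating dark bodies,
anisotropic distortion, falloff, blur, interleaving. It does not attempt
biomechanics (no bending-wave dynamics, no worm-worm interaction),
electrophysiology (no reentry or spiral waves), or photon-level camera
physics (noise is additive Gaussian, not Poisson; vignetting beyond the
scalar falloff is absent). Passing tests therefore demonstrate that the
algorithms recover known ground truth through the instrument's
distortions — not that the biological effect sizes in real preparations
are what the simulator assumes.

## Problem sizes

The shipped tests and the acceptance computations run at deliberately
modest scale — 100 × 100 px cardiac fields (10 seeds), sixteen
64 × 64 px worm wells of 100 frames, 4 × 4 px coded frames for the
8000-frame scheduling round trip — sizes chosen so the whole suite
exercises every pipeline end to end in about a minute on one core while
leaving every algorithmic path identical to full-frame use.

## Known limitations

- Rectification corrects geometry only; off-axis blur, aberrations and
  vignetting are simulated but not deconvolved (by design).
- The activation-map definition is a reasonable convention, not a
  reimplementation of any specific prior tool; parameters are exposed.
- The PSF model's absolute FWHM values depend on the assumed Gaussian
  shape and 1-D geometry; ordering and round-trip consistency are
  guaranteed, absolute agreement with other models is not.
- Schedules are assumed perfectly honoured: no dropped frames, no
  exposure or switching time, no camera synchronization model.
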