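---
title: "Models and methods behind echotrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind echotrace}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

echotrace validates the signal chain of a combined B-mode ultrasound +
high-density surface EMG acquisition system entirely in software: it
generates the inputs such a system records — speckle image sequences with
exact displacement ground truth, trigger-locked evoked EMG over an
electrode grid, electrode-interface test signals — and runs the analyses a
validation protocol applies to them. Because every simulated scene carries
its exact ground truth, every tracking and averaging step can be scored
quantitatively without hardware or human data. This vignette documents the
models, the defaults and why they are what they are, the numerical choices,
and what passing tests do and do not establish.

## The B-mode rendering model

All image scenes share one renderer. A scene is a fixed cloud of point
scatterers with random complex reflectivity (Rayleigh amplitudes, uniform
phases — fully developed speckle), plus bright coherent structures
(polylines with boosted amplitude: spring edges, aponeuroses). Per frame:

1. every scatterer's material (frame-1) position is advected by the scene's
   continuous displacement field — never by integer-pixel shifting, so
   sub-pixel motion survives into the rendered images;
2. the complex field is deposited on the pixel grid with bilinear weights
   and convolved with a separable Gaussian point-spread function
   (defaults: sigma 0.1 mm axial x 0.2 mm lateral);
3. the envelope (modulus) is log-compressed to 8 bits against a reference
   fixed at 1.05x the first frame's envelope maximum, so the brightest
   structure sits just under full scale — no saturated plateau, which would
   destroy the intensity gradation that sub-pixel tracking relies on — and
   the mapping is identical across all frames of a sequence.

Row index is axial (depth), column index lateral; calibration defaults to
0.05 mm/px on both axes, which keeps a desk-scale scene a few hundred
pixels wide. All randomness flows from one explicit seed per scene
(`withr::with_seed`); identical parameters and seed give bit-identical
frames. Speckle decorrelation under deformation emerges naturally from
scatterers moving through the PSF. What the model omits: attenuation,
refraction, reverberation, shadowing, electronic noise per frame (a static
scene renders identical frames by design, so frozen-speckle tests are
exact), and any beamforming physics.

## The spring phantom

The in-vitro scene is a spring oscillating along the image's axial axis in
a water bath: true length `L(t) = L0 + (D/2) sin(2 pi f t)` with rest
length `L0` = 10 mm. The two spring ends are bright, laterally extended
edge structures whose axial separation is exactly `L(t)`; the whole scene
stretches uniformly about its centre, so the dense displacement field is
affine and the emitted ground truth is exact by construction. The
experiment preset crosses peak-to-peak amplitudes {0.4, 1.0, 1.4} mm with
nine frequencies {0.5, 0.7, 1, 2, 3, 5, 7, 8, 10} Hz — 27 conditions of
30 s at 80 frames/s. (Where sources differ on the lowest frequency, the
generator leaves frequency fully free and the preset uses these nine.)

Edge brightness is modulated along the edge with a 0.8 mm "coil pitch"
plus a slower incommensurate texture. A real spring images as a row of
coil cross-sections, not a featureless line; without this lateral
structure the correlation ridge is flat along the edge and the tracker's
lateral position is unconstrained (the aperture problem), which lets the
search window slide along the tilted edge and leak into the axial
estimate.

## The twitching muscle scene

The in-vivo scene is a gastrocnemius-like pennate muscle: two nearly
horizontal aponeuroses bounding a speckled fascicle region, fascicles
running obliquely between the sheets. Geometry: resting fascicle length
`L0` = 28 mm, resting thickness `T0` = 14 mm, hence 30 degrees resting
pennation — mid-range for a plantarflexor. Each stimulus (1 pps, 20 s by
default) drives a twitch `w(t)`, a difference of exponentials
`exp(-t/tau_d) - exp(-t/tau_r)` normalized to unit peak with
`tau_r` = 0.05 s, `tau_d` = 0.15 s (time-to-peak near 100 ms, as in
triceps surae). During the twitch the fascicles shorten,
`L(t) = L0 - a_s w(t)` (default `a_s` = 1 mm), and the muscle thickens,
`T(t) = T0 + a_t w(t)` (default `a_t` = 0.6 mm), with pennation following
`sin(theta) = T/L`. The superficial sheet is fixed (skin side); the deep
sheet carries the thickening; material points between the sheets
interpolate linearly in depth and shear laterally with the fascicle run
`h(t) = sqrt(L^2 - T^2)`. Parameters whose combination would drive
`T >= L` (pennation to 90 degrees) are rejected at construction.

The aponeuroses get mm-scale punctate amplitude texture. Fibrous sheets
image that way in practice, and the texture is load-bearing: a smooth
bright line has no trackable corners (minimum-eigenvalue response near
zero along it), so without texture the feature tracker cannot anchor the
thickness measurement.

Because fascicles run superficial-to-deep, the probe-grid columns are
initialized along fascicle lines (each column's lateral run is the
scene's `h0`), and the distance between the most superficial and deepest
fascicle-region probes of a column, rescaled by their known path-fraction
separation, is an exact fascicle-length measure under the true field.
This is the package's resolution of an under-specified measurement
definition, chosen so that the measured quantity and the emitted ground
truth agree by construction when tracking is perfect, leaving tracking
error as the only discrepancy the tests score.

## The M-wave grid

Evoked EMG over the default 8-row x 4-column grid (10 mm inter-electrode
distance, channels numbered column-major and carried explicitly in file
headers) is modelled as: a biphasic template (first derivative of a
Gaussian, 15 ms, 1 mV peak — a conventional stand-in for a compound
action potential), scaled per channel by a 2-D Gaussian amplitude profile
centred between columns 2 and 3 (under the ultrasound probe), delayed per
row by 0.4 ms per electrode of distance from an innervation row, inserted
at each trigger (1 pps), plus white noise (default 10 uV RMS, a typical
surface-EMG baseline), optional powerline interference (off by default:
the default grid is clean), and optional per-channel failure modes:
`open_contact` (25x nominal noise, no signal), `short_circuit_pair`
(sample-identical copy of a grid neighbour), `artifact_burst`
(intermittent low-frequency transients).

## Tracking methods

**Region tracking (spring).** Zero-normalized cross-correlation of a
10 x 15 px template (10 axial rows x 15 lateral columns — the long side
along the laterally extended edges) against every integer placement
within a +-10 px window centred on the previously tracked position; the
template itself stays the frame-1 reference by default so no drift
accumulates (`previous_frame` is available for large deformations). The
integer peak (ties broken by first occurrence in scan order, which is
deterministic) is refined by a separable 1-D parabola per axis,
`d = (c- - c+) / (2 (c- - 2 c0 + c+))`, clamped to (-0.5, 0.5); a
numerically perfect correlation skips refinement (the parabola would add
a small bias from asymmetric neighbours of an exact match). Parabolic
refinement is the cheapest method with bias well under 0.05 px — adequate
for resolving ~5 um motion on 50 um pixels. Peaks below correlation 0.5
mark the frame invalid and hold the last valid position. Spring length is
the calibrated distance between the per-end medians (median per
coordinate; even counts average the middle two) of four ROI centres per
edge. The bench widens the search margin per condition to the analytic
maximum frame-to-frame edge displacement `pi D f / rate` when that
exceeds the default.

**Feature tracking (muscle).** Shi-Tomasi detection (minimum eigenvalue
of the 5 x 5-box-integrated gradient structure tensor), greedy best-first
selection under an 8 px spacing floor, with an optional per-label quota
(`min_per_label`, 20 in the end-to-end wrapper) that tops up each
segment's representation — otherwise the speckle-rich fascicle region
crowds the sparse aponeurosis bands out of the 200-feature budget.
Tracking is pyramidal Lucas-Kanade (11 x 11 window, 3 levels,
forward-additive, 12 iterations, 0.01 px tolerance) with per-iteration
step capping at 1.5 px; a level whose accumulated motion exceeds four
window half-widths is rejected, and surviving features must keep a
window correlation of at least 0.5 between consecutive frames, else they
are dropped and the set replenished. Displacements are interpolated onto
the 8 x 10 probe grid by Delaunay triangle-based linear (barycentric)
interpolation per region label, with inverse-distance weighting over the
3 nearest same-region features outside the hull; fewer than 3 usable
same-region features marks the probe missing for that transition
(position held). Probes advect by their interpolated displacement
(Lagrangian). Thickness is measured at matched lateral coordinates — the
deep sheet's probe polyline is evaluated at each superficial probe's
lateral position — so aponeurosis tilt does not bias the distance.
Frames in which a series has no valid measurement are filled by linear
interpolation and flagged `interpolated`.

## Error metric and comparisons

The agreement metric is the normalized mean square error in percent,
`NMSE = 100 sum((f - g)^2) / sum(g^2)`, with `f` the prediction and `g`
the reference. It is deliberately asymmetric (only the reference
normalizes the error power). For spring series both inputs are *changes*
in length, so each series has its own mean removed first — the metric is
then invariant to the unknown absolute offset between image-derived and
servo-imposed lengths. For M-wave templates no mean is removed: evoked
templates share a true zero baseline, and demeaning would hide DC contact
artifacts that the with/without-probe comparison exists to expose. The
template comparison averages channels of the central columns (2, 3;
under the probe) and lateral columns (1, 4) separately.

Channel screening automates what is otherwise visual inspection, with
explicit criteria: RMS above 5x the grid median (open contact), pair
correlation above 0.999 with amplitude ratio within 1% (short circuit),
more than half the power in 45-65 Hz (powerline), excess kurtosis above
20 (artifact bursts); one primary flag per channel with precedence in
that order.

## Interface characterization

Noise: band-pass 10-1000 Hz (order-2 Butterworth, forward-backward),
RMS over the full trace, then quadratic subtraction of the amplifier's
0.8 uV referred-to-input noise; a measurement below the amplifier floor
errors rather than clipping, because it indicates an inconsistent
measurement. Impedance: each voltage/current record is demodulated by a
least-squares fit of `a sin + b cos + c` at the known frequency — chosen
over an FFT bin so non-integer cycle counts are handled exactly —
magnitude is the complex-amplitude ratio and phase the wrapped angle
difference. The lumped circuit is `R_series + (R_parallel || C_parallel)`;
with two electrodes in the loop the fitted values represent the series
total of both interfaces plus tissue. Default sweep: 10 log-spaced
frequencies over 10-1000 Hz, 2 s per record (unstated in the protocol;
2 s gives at least 20 cycles at the lowest frequency).

## Statistics

Model II regression is reduced major axis: `slope = sign(r) sd(y)/sd(x)`
— chosen among model-II variants because both compared series carry
comparable (tracking) error, and RMA is the conventional choice there;
the subtype is genuinely open in the protocol. The factorial ANOVA is
fixed-effects with main effects only on the spring bench (one NMSE per
cell, so interactions are not estimable); the statistical battery
elsewhere delegates to `t.test`, `wilcox.test`, `cor.test`, `ks.test`
and `aov`. Two deliberate conventions: a paired t on *identical* samples
returns t = 0, p = 1 (no evidence of difference) while a constant
non-zero difference errors (t genuinely undefined); an all-constant
response yields F = 0, p = 1 rather than 0/0. Filtering interprets
"4th-order noncausal Butterworth" as a design order of 4 applied forward
and backward (zero phase, effective magnitude order 8); the order is a
parameter for anyone preferring the other reading. Epoch length is
`round(epoch_ms fs / 1000)` — 82 samples for 40 ms at 2048 Hz. The
Kolmogorov-Smirnov comparison of intensity distributions runs on the
256-bin mean-histogram CDFs with an asymptotic p at the effective pixel
count; that p assumes independent pixels, which holds for the iid-pixel
images the calibration tests use but only approximately for speckle,
where pixels within a PSF footprint are correlated — treat the statistic,
not the p, as primary on real speckle.

## Problem sizes and reproducibility

The full protocol sizes are 30 s x 80 Hz (2400 frames) for each spring
condition, 20 s of 1 pps stimulation for muscle and EMG trials, and 10 s
noise records. The test suite exercises the full sizes where a claim
concerns them (the reference-error comparisons and the 82/2400/32/27
counts) and otherwise uses the same scenes at 1-2 s durations and, for
the muscle scene, 0.1 mm/px calibration — the package's standard
miniatures, chosen so the whole suite runs in minutes while leaving every
code path identical. Every simulator, bench, and fixture regenerates
bit-identically from its seed.

## Limitations

Synthetic speckle moves exactly with the displacement field; real tissue
decorrelates additionally through out-of-plane motion, probe pressure and
physiological noise, so the tracking errors measured here are lower
bounds on in-vivo performance and the reference error levels are treated
as upper bounds. Segmentations are supplied (by the simulator or the
user), not learned. The electrode material's acoustic effect is a label
in the bench tables, not an acoustic model. No stimulation-artifact
blanking is modelled (simulated triggers are clean).
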