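# echotrace

Combined B-mode ultrasound + high-density surface EMG acquisition systems
promise simultaneous views of a muscle's electrical activity and its tissue
motion from the same skin patch. Validating such a system raises a chain of
quantitative questions: can sub-millimetre tissue motion still be tracked
through the electrode material, are evoked EMG waveforms distorted by the
probe sitting on the electrodes, and does the electrode-skin interface stay
quiet and low-impedance? `echotrace` packages that entire validation chain
as software, for engineers and movement scientists building or assessing
such systems: it simulates every input the protocols need — speckle image
sequences with exact displacement ground truth, trigger-locked M-wave grids
with realistic failure modes, interface noise and impedance sweeps — and
implements the analyses that score them.

The agreement metric at the core is the normalized mean square error
between a predicted series *f* and a reference series *g*,

    NMSE = 100 · Σₙ [f(n) − g(n)]² / Σₙ g(n)²   (percent),

applied to tracked-vs-imposed spring length (2400 samples; 30 s at 80
frames/s) and to 82-sample M-wave templates (40 ms at 2048 samples/s,
averages of 20 consecutive evoked responses) on a 32-channel, 4-column ×
8-row electrode grid. Around it sit:

- a scatterer-field B-mode simulator (Gaussian PSF, envelope detection,
  log compression) with exact ground truth: an oscillating spring phantom
  and a twitching pennate-muscle scene;
- normalized cross-correlation ROI tracking with parabolic sub-pixel
  refinement, and the 8-ROI median-based spring-length pipeline;
- pyramidal Kanade-Lucas-Tomasi feature tracking, an 8 × 10 probe grid
  advected by Delaunay/barycentric interpolation, and fascicle-length /
  muscle-thickness twitch series;
- zero-phase Butterworth filtering, trigger-locked epoching, template
  averaging, per-channel NMSE maps with central-vs-lateral column
  comparison, and automated channel-quality screening;
- electrode-skin noise estimation (quadratic subtraction of the amplifier
  floor) and impedance spectra from sinusoidal sweeps;
- the statistical battery: paired t / Wilcoxon, factorial ANOVA, Pearson,
  Kolmogorov-Smirnov on intensity histograms, and model II (reduced major
  axis) regression, with broom-style `tidy()`/`glance()` methods and
  `autoplot()` figures.

## A worked example

Simulate the spring phantom at 1.0 mm peak-to-peak, 2 Hz, track its eight
edge ROIs, and score the result against the known motion:

```r
library(echotrace)

p   <- spring_scene_params(peak_to_peak_mm = 1.0, frequency_hz = 2,
                           duration_s = 5, seed = 42)
sim <- simulate_spring_sequence(p)

rois  <- spring_rois(sim)                      # 4 ROIs per spring end
track <- function(r) track_roi(sim$sequence, r)
lens  <- spring_length(lapply(rois$top, track), lapply(rois$bottom, track),
                       p$calib_mm_per_px, p$frame_rate_hz)
lens
#> # A tibble: 400 × 3
#>   frame time_s length_mm
#>   <int>  <dbl>     <dbl>
#> 1     1 0           10
#> 2     2 0.0125      10.1
#> 3     3 0.025       10.2
#> 4     4 0.0375      10.2

nmse(lens$length_mm, sim$truth$track$length_mm)
#> [1] 0.008     # percent
(max(lens$length_mm) - min(lens$length_mm)) / 2
#> [1] 0.4997    # mm, against a true half-amplitude of 0.5000
```

The tracked length follows the imposed 10 ± 0.5 mm sinusoid to within an
NMSE of 0.008 % and recovers the oscillation amplitude to 0.3 µm — the
kind of headroom that makes the protocol's reference error levels (tens of
percent at the smallest amplitudes on real hardware) comfortable upper
bounds. `autoplot(lens, truth = sim$truth)` overlays the two series.

Higher-level entry points run whole protocols: `run_bench("spring")` fills
the 27-condition amplitude × frequency table, `run_bench("mwave")`
produces the per-channel template NMSE map and the central-vs-lateral
comparison, `run_bench("twitch")` compares twitch series from two
independently seeded renderings of one scene, and
`run_bench("interface")` characterizes a lumped electrode-skin circuit.
`make_fixtures()` writes the miniature TIFF/CSV/JSON fixtures used in
examples and tests.

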