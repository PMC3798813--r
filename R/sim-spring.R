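#' Parameters for the oscillating-spring phantom scene
#'
#' Describes a water-bath phantom in which a spring oscillates sinusoidally
#' along the image's axial direction while being imaged in B-mode. The two
#' spring ends appear as bright, laterally extended edge structures whose
#' axial separation is the spring length; the validation protocol drives the
#' spring at three peak-to-peak amplitudes (0.4, 1.0, 1.4 mm) over nine
#' frequencies between 0.5 and 10 Hz for 30 s at 80 frames/s.
#'
#' @param rest_length_mm spring rest length (default 10 mm).
#' @param peak_to_peak_mm peak-to-peak length change `D`; the true length is
#'   `rest + (D/2) sin(2 pi f t)`. Zero is allowed (static phantom).
#' @param frequency_hz oscillation frequency; must be below the Nyquist
#'   frequency `frame_rate_hz / 2`.
#' @param duration_s recording length (default 30 s).
#' @param frame_rate_hz imaging frame rate (default 80 Hz).
#' @param calib_mm_per_px (axial, lateral) calibration (default 0.05 mm/px).
#' @param lateral_mm lateral field of view (default 8 mm).
#' @param margin_mm water margin beyond the maximal spring extent.
#' @param scatterer_density_mm2 speckle scatterers per square mm.
#' @param psf_sigma_mm Gaussian point-spread-function standard deviations,
#'   (axial, lateral), in mm.
#' @param edge_gain brightness of the spring-edge structures relative to the
#'   speckle background.
#' @param coil_pitch_mm lateral period of the bright coil echoes along each
#'   edge (a real spring images as a row of coil cross-sections, not a
#'   uniform line; this also gives the tracker lateral structure to lock
#'   onto). Default 0.8 mm.
#' @param edge_tilt axial slope of the edge lines (px of depth per px of
#'   lateral position); small non-zero values avoid perfectly grid-aligned
#'   structures.
#' @param seed integer seed; all randomness in the simulator flows from it.
#' @return A validated `spring_scene_params` list.
#' @export
spring_scene_params <- function(rest_length_mm = 10, peak_to_peak_mm = 1.0,
                                frequency_hz = 1, duration_s = 30,
                                frame_rate_hz = 80,
                                calib_mm_per_px = c(0.05, 0.05),
                                lateral_mm = 8, margin_mm = 2,
                                scatterer_density_mm2 = 30,
                                psf_sigma_mm = c(0.1, 0.2),
                                edge_gain = 8, edge_tilt = 0.02,
                                coil_pitch_mm = 0.8, seed = 1L) {
  if (peak_to_peak_mm < 0) abort("`peak_to_peak_mm` must be >= 0")
  if (duration_s <= 0) abort("`duration_s` must be positive")
  if (frame_rate_hz <= 0) abort("`frame_rate_hz` must be positive")
  if (frequency_hz >= frame_rate_hz / 2)
    abort(sprintf("frequency (%g Hz) must be below Nyquist (%g Hz)",
                  frequency_hz, frame_rate_hz / 2))
  if (frequency_hz <= 0) abort("`frequency_hz` must be positive")
  calib <- as.numeric(calib_mm_per_px)
  if (length(calib) != 2L || any(calib <= 0))
    abort("`calib_mm_per_px` must be two positive values")
  structure(
    list(rest_length_mm = rest_length_mm, peak_to_peak_mm = peak_to_peak_mm,
         frequency_hz = frequency_hz, duration_s = duration_s,
         frame_rate_hz = frame_rate_hz, calib_mm_per_px = calib,
         lateral_mm = lateral_mm, margin_mm = margin_mm,
         scatterer_density_mm2 = scatterer_density_mm2,
         psf_sigma_mm = as.numeric(psf_sigma_mm), edge_gain = edge_gain,
         edge_tilt = edge_tilt, coil_pitch_mm = coil_pitch_mm,
         seed = as.integer(seed)),
    class = "spring_scene_params")
}

#' Ground truth of the spring scene without rendering
#'
#' Evaluates the imposed length series and displacement field of
#' [spring_scene_params()] analytically — the `truth` component of
#' [simulate_spring_sequence()] at negligible cost.
#'
#' @param params a [spring_scene_params()] object.
#' @return a `ground_truth` object (see [simulate_spring_sequence()]).
#' @export
spring_ground_truth <- function(params) {
  p <- params
  if (!inherits(p, "spring_scene_params"))
    abort("`params` must come from spring_scene_params()")
  nf <- round(p$duration_s * p$frame_rate_hz)
  t <- (seq_len(nf) - 1) / p$frame_rate_hz
  L0 <- p$rest_length_mm
  L <- L0 + (p$peak_to_peak_mm / 2) * sin(2 * pi * p$frequency_hz * t)
  axial_mm <- L0 + p$peak_to_peak_mm + 2 * p$margin_mm
  z_c <- axial_mm / 2
  displace <- function(z_mm, x_mm, frame) {
    cbind(z_mm = (z_mm - z_c) * (L[frame] / L[1] - 1), x_mm = 0 * x_mm)
  }
  ground_truth(
    track = tibble(frame = seq_len(nf), time_s = t, length_mm = L),
    displace = displace,
    info = list(edge_top_mm = z_c - L[1] / 2, edge_bottom_mm = z_c + L[1] / 2,
                edge_x_mm = p$lateral_mm * c(0.08, 0.92), centre_mm = z_c,
                calib_mm_per_px = p$calib_mm_per_px))
}

#' Simulate a B-mode sequence of the oscillating spring phantom
#'
#' Renders the scene described by [spring_scene_params()]: a fixed speckle
#' scatterer cloud plus two bright edge structures, advected each frame by a
#' uniform axial stretch about the spring centre so that the edge separation
#' equals the true spring length, then imaged with the Gaussian-PSF
#' envelope/log-compression model. Identical parameters and seed give
#' bit-identical output.
#'
#' @param params a [spring_scene_params()] object.
#' @param render `"bmode"` (default) for the full speckle image;
#'   `"structure"` renders only the bright edge structures and returns the
#'   pre-compression envelope (useful for checking edge positions against
#'   ground truth without speckle).
#' @return A list with elements `sequence` (an [image_sequence()]) and
#'   `truth` (a `ground_truth` object whose `track` tibble holds `frame`,
#'   `time_s`, `length_mm`, and whose `displace(z_mm, x_mm, frame)` function
#'   evaluates the dense displacement field; `info` carries the edge depths
#'   at frame 1 and the scene geometry).
#' @export
simulate_spring_sequence <- function(params, render = c("bmode", "structure")) {
  render <- match.arg(render)
  p <- params
  if (!inherits(p, "spring_scene_params"))
    abort("`params` must come from spring_scene_params()")
  nf <- round(p$duration_s * p$frame_rate_hz)
  t <- (seq_len(nf) - 1) / p$frame_rate_hz
  L0 <- p$rest_length_mm
  L <- L0 + (p$peak_to_peak_mm / 2) * sin(2 * pi * p$frequency_hz * t)

  axial_mm <- L0 + p$peak_to_peak_mm + 2 * p$margin_mm
  z_c <- axial_mm / 2
  H <- round(axial_mm / p$calib_mm_per_px[1])
  W <- round(p$lateral_mm / p$calib_mm_per_px[2])
  kr <- gauss_kernel(p$psf_sigma_mm[1] / p$calib_mm_per_px[1])
  kc <- gauss_kernel(p$psf_sigma_mm[2] / p$calib_mm_per_px[2])

  # uniform axial stretch about the scene centre; material coords = frame-1
  stretch <- function(z_mm, frame) z_c + (z_mm - z_c) * L[frame] / L[1]

  # edge polylines in material (frame-1) coordinates
  x_edge <- p$lateral_mm * c(0.08, 0.92)
  tilt_mm <- p$edge_tilt * p$calib_mm_per_px[1] / p$calib_mm_per_px[2]
  edge_poly <- function(z_end) {
    cbind(z_end + tilt_mm * (x_edge - mean(x_edge)), x_edge)
  }
  z_top1 <- z_c - L[1] / 2
  z_bot1 <- z_c + L[1] / 2

  # coil echoes: the edge brightness is modulated along its length with the
  # coil pitch (plus a mild random texture), as a sprung coil images as a row
  # of bright cross-sections; this is what localizes the ROIs laterally
  modulate <- function(ed, phase) {
    carrier <- 0.5 * (1 + cos(2 * pi * ed$x_mm / p$coil_pitch_mm + phase))
    ed$amp <- ed$amp * (0.15 + 0.85 * carrier^2) *
      (1 + 0.2 * sin(2 * pi * ed$x_mm / (3.1 * p$coil_pitch_mm) + 2 * phase))
    ed
  }
  withr::with_seed(p$seed, {
    sc <- draw_scatterers(axial_mm, p$lateral_mm, p$scatterer_density_mm2)
    ed_top <- modulate(sample_polyline(edge_poly(z_top1), step_mm = 0.012,
                                       amp = p$edge_gain * 0.25),
                       runif(1, 0, 2 * pi))
    ed_bot <- modulate(sample_polyline(edge_poly(z_bot1), step_mm = 0.012,
                                       amp = p$edge_gain * 0.25),
                       runif(1, 0, 2 * pi))
  })

  if (render == "structure") {
    z0 <- c(ed_top$z_mm, ed_bot$z_mm); x0 <- c(ed_top$x_mm, ed_bot$x_mm)
    amp <- c(ed_top$amp, ed_bot$amp); ph <- c(ed_top$phase, ed_bot$phase)
  } else {
    z0 <- c(sc$z_mm, ed_top$z_mm, ed_bot$z_mm)
    x0 <- c(sc$x_mm, ed_top$x_mm, ed_bot$x_mm)
    amp <- c(sc$amp, ed_top$amp, ed_bot$amp)
    ph <- c(sc$phase, ed_top$phase, ed_bot$phase)
  }

  frames <- array(0, dim = c(nf, H, W))
  ref <- NULL
  for (i in seq_len(nf)) {
    env <- render_envelope(stretch(z0, i), x0, amp, ph, H, W,
                           p$calib_mm_per_px, kr, kc)
    if (render == "structure") {
      frames[i, , ] <- env
    } else {
      if (is.null(ref)) ref <- compression_reference(env)
      frames[i, , ] <- log_compress(env, ref)
    }
  }

  seq <- image_sequence(frames, p$frame_rate_hz, p$calib_mm_per_px,
                        metadata = list(scene = "spring", seed = p$seed,
                                        render = render))
  list(sequence = seq, truth = spring_ground_truth(p))
}
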