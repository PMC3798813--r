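#' Parameters for the twitching pennate-muscle scene
#'
#' A gastrocnemius-like B-mode scene: two bright, nearly horizontal
#' aponeuroses bounding a speckled fascicle region in which fascicles run
#' obliquely (pennation) from the superficial to the deep sheet. Each
#' electrical stimulus produces a twitch during which the fascicles shorten
#' along their own direction while the muscle thickens: thickness
#' `T(t) = T0 + thickening * w(t)` and fascicle length
#' `L(t) = L0 - shortening * w(t)`, with `w` the normalized
#' difference-of-exponentials pulse ([twitch_pulse()]) and the pennation
#' angle following `sin(theta) = T / L`. The deep aponeurosis carries the
#' thickening; tissue above the superficial sheet is stationary.
#'
#' @param resting_length_mm resting fascicle length `L0` (default 28 mm).
#' @param resting_thickness_mm resting inter-aponeurosis distance `T0`
#'   (default 14 mm, i.e. 30 degrees resting pennation).
#' @param shortening_mm twitch fascicle shortening amplitude (default 1).
#' @param thickening_mm twitch thickening amplitude (default 0.6).
#' @param tau_rise_s,tau_decay_s twitch time constants (defaults 0.05 and
#'   0.15 s, giving a time-to-peak near 100 ms as in triceps surae; rise
#'   must be faster than decay).
#' @param stim_rate_pps stimulus rate (default 1).
#' @param stim_onset_s time of the first stimulus (default 0.15 s).
#' @param duration_s scene duration (default 20 s).
#' @param frame_rate_hz frame rate (default 80).
#' @param calib_mm_per_px (axial, lateral) calibration (default 0.05).
#' @param lateral_mm lateral field of view; must cover the fascicles'
#'   lateral run `L0 cos(theta0)` (default 28 mm).
#' @param superficial_depth_mm depth of the superficial aponeurosis
#'   (default 3 mm).
#' @param margin_mm tissue margin below the deep aponeurosis.
#' @param scatterer_density_mm2,psf_sigma_mm,apo_gain speckle density, PSF
#'   widths and aponeurosis brightness relative to speckle.
#' @param seed integer seed.
#' @return validated `twitch_scene_params` list (with derived fields
#'   `h0_mm`, the resting lateral fascicle run, and `theta0_deg`).
#' @export
twitch_scene_params <- function(resting_length_mm = 28,
                                resting_thickness_mm = 14,
                                shortening_mm = 1.0, thickening_mm = 0.6,
                                tau_rise_s = 0.05, tau_decay_s = 0.15,
                                stim_rate_pps = 1, stim_onset_s = 0.15,
                                duration_s = 20, frame_rate_hz = 80,
                                calib_mm_per_px = c(0.05, 0.05),
                                lateral_mm = 28, superficial_depth_mm = 3,
                                margin_mm = 2, scatterer_density_mm2 = 30,
                                psf_sigma_mm = c(0.1, 0.2), apo_gain = 5,
                                seed = 1L) {
  if (shortening_mm < 0 || thickening_mm < 0)
    abort("twitch amplitudes must be >= 0")
  if (tau_rise_s >= tau_decay_s) abort("`tau_rise_s` must be < `tau_decay_s`")
  if (duration_s <= 0 || frame_rate_hz <= 0)
    abort("duration and frame rate must be positive")
  if (stim_rate_pps * duration_s < 1)
    abort("duration too short for one stimulus")
  T_max <- resting_thickness_mm + thickening_mm
  L_min <- resting_length_mm - shortening_mm
  if (T_max >= L_min)
    abort("thickening would cross the aponeuroses: need T0 + thickening < L0 - shortening")
  calib <- as.numeric(calib_mm_per_px)
  if (length(calib) != 2L || any(calib <= 0))
    abort("`calib_mm_per_px` must be two positive values")
  h0 <- sqrt(resting_length_mm^2 - resting_thickness_mm^2)
  if (lateral_mm < h0 + 1)
    abort("`lateral_mm` must cover the fascicles' lateral run plus margin")
  structure(
    list(resting_length_mm = resting_length_mm,
         resting_thickness_mm = resting_thickness_mm,
         shortening_mm = shortening_mm, thickening_mm = thickening_mm,
         tau_rise_s = tau_rise_s, tau_decay_s = tau_decay_s,
         stim_rate_pps = stim_rate_pps, stim_onset_s = stim_onset_s,
         duration_s = duration_s, frame_rate_hz = frame_rate_hz,
         calib_mm_per_px = calib, lateral_mm = lateral_mm,
         superficial_depth_mm = superficial_depth_mm, margin_mm = margin_mm,
         scatterer_density_mm2 = scatterer_density_mm2,
         psf_sigma_mm = as.numeric(psf_sigma_mm), apo_gain = apo_gain,
         h0_mm = h0,
         theta0_deg = asin(resting_thickness_mm / resting_length_mm) * 180 / pi,
         seed = as.integer(seed)),
    class = "twitch_scene_params")
}

#' Ground truth of the twitch scene without rendering
#'
#' Evaluates the parametric twitch model (length, thickness, stimulus
#' onsets, displacement field) of [twitch_scene_params()] at frame times —
#' the `truth` component of [simulate_twitch_sequence()] without the
#' rendering cost.
#'
#' @param params a [twitch_scene_params()] object.
#' @return a `ground_truth` object (see [simulate_twitch_sequence()]).
#' @export
twitch_ground_truth <- function(params) {
  p <- params
  if (!inherits(p, "twitch_scene_params"))
    abort("`params` must come from twitch_scene_params()")
  nf <- round(p$duration_s * p$frame_rate_hz)
  t <- (seq_len(nf) - 1) / p$frame_rate_hz
  n_stim <- floor(p$stim_rate_pps * p$duration_s)
  onsets <- p$stim_onset_s + (seq_len(n_stim) - 1) / p$stim_rate_pps
  w <- pulse_train(t, onsets, p$tau_rise_s, p$tau_decay_s)
  Tt <- p$resting_thickness_mm + p$thickening_mm * w
  Lt <- p$resting_length_mm - p$shortening_mm * w
  ht <- sqrt(Lt^2 - Tt^2)
  z_sup <- p$superficial_depth_mm
  T0 <- Tt[1]; h0 <- ht[1]
  displace <- function(z_mm, x_mm, frame) {
    xi <- (z_mm - z_sup) / T0
    below <- xi > 1; inside <- xi >= 0 & xi <= 1
    dz <- 0 * z_mm; dx <- 0 * x_mm
    dz[inside] <- xi[inside] * (Tt[frame] - T0)
    dx[inside] <- xi[inside] * (ht[frame] - h0)
    dz[below] <- Tt[frame] - T0
    cbind(z_mm = dz, x_mm = dx)
  }
  ground_truth(
    track = tibble(frame = seq_len(nf), time_s = t,
                   length_mm = Lt, thickness_mm = Tt),
    displace = displace,
    info = list(z_superficial_mm = z_sup, thickness0_mm = T0, h0_mm = h0,
                onsets_s = onsets, calib_mm_per_px = p$calib_mm_per_px,
                lateral_mm = p$lateral_mm))
}

#' Simulate a B-mode sequence of the twitching muscle scene
#'
#' Renders the scene of [twitch_scene_params()] and returns, besides the
#' image sequence, the exact ground truth (fascicle length and thickness
#' series, stimulus onsets, dense displacement field) and the frame-1
#' aponeurosis [segmentation()] in pixel coordinates.
#'
#' @param params a [twitch_scene_params()] object.
#' @return list with `sequence` ([image_sequence()]), `truth`
#'   (`ground_truth` with `track` columns `frame`, `time_s`, `length_mm`,
#'   `thickness_mm`), and `segmentation`.
#' @export
simulate_twitch_sequence <- function(params) {
  p <- params
  if (!inherits(p, "twitch_scene_params"))
    abort("`params` must come from twitch_scene_params()")
  nf <- round(p$duration_s * p$frame_rate_hz)
  t <- (seq_len(nf) - 1) / p$frame_rate_hz
  n_stim <- floor(p$stim_rate_pps * p$duration_s)
  onsets <- p$stim_onset_s + (seq_len(n_stim) - 1) / p$stim_rate_pps
  w <- pulse_train(t, onsets, p$tau_rise_s, p$tau_decay_s)

  Tt <- p$resting_thickness_mm + p$thickening_mm * w
  Lt <- p$resting_length_mm - p$shortening_mm * w
  ht <- sqrt(Lt^2 - Tt^2)          # lateral fascicle run
  z_sup <- p$superficial_depth_mm
  T0 <- Tt[1]; h0 <- ht[1]

  axial_mm <- z_sup + T0 + p$thickening_mm + p$margin_mm
  H <- round(axial_mm / p$calib_mm_per_px[1])
  W <- round(p$lateral_mm / p$calib_mm_per_px[2])
  kr <- gauss_kernel(p$psf_sigma_mm[1] / p$calib_mm_per_px[1])
  kc <- gauss_kernel(p$psf_sigma_mm[2] / p$calib_mm_per_px[2])

  # material (frame-1) coordinates -> frame-i positions
  advect <- function(z0, x0, i) {
    xi <- (z0 - z_sup) / T0
    below <- xi > 1; inside <- xi >= 0 & xi <= 1
    z <- z0; x <- x0
    z[inside] <- z_sup + xi[inside] * Tt[i]
    x[inside] <- x0[inside] + xi[inside] * (ht[i] - h0)
    z[below] <- z0[below] + (Tt[i] - T0)
    cbind(z, x)
  }
  tilt <- 0.01
  apo_line <- function(z) cbind(z + tilt * (c(0, p$lateral_mm) -
                                              p$lateral_mm / 2),
                                c(0, p$lateral_mm))
  # fibrous sheets image with punctate, mm-scale echo texture; this is also
  # what gives the tracker lateral purchase on the aponeuroses
  sheet_texture <- function(x_mm) {
    ph <- runif(3, 0, 2 * pi)
    0.25 + 0.75 * (0.5 * (1 + cos(2 * pi * x_mm / 1.1 + ph[1])))^2 *
      (1 + 0.4 * sin(2 * pi * x_mm / 2.7 + ph[2])) *
      (1 + 0.3 * sin(2 * pi * x_mm / 0.63 + ph[3]))
  }
  withr::with_seed(p$seed, {
    sc <- draw_scatterers(axial_mm, p$lateral_mm, p$scatterer_density_mm2)
    apo_s <- sample_polyline(apo_line(z_sup), step_mm = 0.012,
                             amp = p$apo_gain * 0.25)
    apo_d <- sample_polyline(apo_line(z_sup + T0), step_mm = 0.012,
                             amp = p$apo_gain * 0.25)
    apo_s$amp <- apo_s$amp * sheet_texture(apo_s$x_mm)
    apo_d$amp <- apo_d$amp * sheet_texture(apo_d$x_mm)
  })
  z0 <- c(sc$z_mm, apo_s$z_mm, apo_d$z_mm)
  x0 <- c(sc$x_mm, apo_s$x_mm, apo_d$x_mm)
  amp <- c(sc$amp, apo_s$amp, apo_d$amp)
  ph <- c(sc$phase, apo_s$phase, apo_d$phase)

  frames <- array(0, dim = c(nf, H, W))
  ref <- NULL
  for (i in seq_len(nf)) {
    pos <- advect(z0, x0, i)
    env <- render_envelope(pos[, 1], pos[, 2], amp, ph, H, W,
                           p$calib_mm_per_px, kr, kc)
    if (is.null(ref)) ref <- compression_reference(env)
    frames[i, , ] <- log_compress(env, ref)
  }

  mm2row <- function(z) z / p$calib_mm_per_px[1] + 1
  mm2col <- function(x) x / p$calib_mm_per_px[2] + 1
  seg_poly <- function(z) {
    v <- apo_line(z)
    cbind(mm2row(v[, 1]), mm2col(v[, 2]))
  }
  seg <- segmentation(seg_poly(z_sup), seg_poly(z_sup + T0))

  seq <- image_sequence(frames, p$frame_rate_hz, p$calib_mm_per_px,
                        metadata = list(scene = "twitch", seed = p$seed))
  list(sequence = seq, truth = twitch_ground_truth(p), segmentation = seg)
}
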