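# Shared rendering machinery for the synthetic B-mode scenes.
#
# Rendering model: a fixed cloud of point scatterers (random complex
# reflectivity), advected in continuous material coordinates by the scene's
# displacement field, deposited on the pixel grid with bilinear weights,
# convolved with a separable Gaussian point-spread function, envelope-detected
# (modulus of the complex field) and log-compressed to 8 bits. Sub-pixel
# motion therefore enters through continuous scatterer displacement, never
# through integer-pixel shifting, and speckle decorrelates under deformation
# the way coherent imaging does.

# 1-D Gaussian kernel, unit sum, support +-4 sigma
gauss_kernel <- function(sigma_px) {
  h <- max(1L, ceiling(4 * sigma_px))
  k <- exp(-0.5 * ((-h:h) / sigma_px)^2)
  k / sum(k)
}

# Draw a homogeneous random scatterer cloud over a scene (mm coordinates).
# Amplitudes are Rayleigh, phases uniform: fully developed speckle.
draw_scatterers <- function(axial_mm, lateral_mm, density_per_mm2) {
  n <- max(1L, round(axial_mm * lateral_mm * density_per_mm2))
  list(
    z_mm = runif(n, 0, axial_mm),
    x_mm = runif(n, 0, lateral_mm),
    amp = sqrt(stats::rexp(n, rate = 0.5)),
    phase = runif(n, 0, 2 * pi)
  )
}

# Densely sample a polyline (matrix of (z_mm, x_mm) vertices) at ~`step_mm`
# spacing; returns coherent bright-structure "scatterers".
sample_polyline <- function(vertices, step_mm, amp) {
  zs <- xs <- numeric(0)
  for (i in seq_len(nrow(vertices) - 1L)) {
    p <- vertices[i, ]; q <- vertices[i + 1L, ]
    len <- sqrt(sum((q - p)^2))
    m <- max(2L, ceiling(len / step_mm))
    tt <- seq(0, 1, length.out = m)[-m]
    zs <- c(zs, p[1] + tt * (q[1] - p[1]))
    xs <- c(xs, p[2] + tt * (q[2] - p[2]))
  }
  zs <- c(zs, vertices[nrow(vertices), 1])
  xs <- c(xs, vertices[nrow(vertices), 2])
  list(z_mm = zs, x_mm = xs, amp = rep(amp, length(zs)),
       phase = rep(0, length(zs)))
}

# Complex-field envelope of a set of point sources at mm positions.
render_envelope <- function(z_mm, x_mm, amp, phase, H, W, calib, kr, kc) {
  r_px <- z_mm / calib[1]
  c_px <- x_mm / calib[2]
  re <- cpp_splat_bilinear(r_px, c_px, amp * cos(phase), H, W)
  im <- cpp_splat_bilinear(r_px, c_px, amp * sin(phase), H, W)
  sqrt(cpp_sepconv(re, kr, kc)^2 + cpp_sepconv(im, kr, kc)^2)
}

# Log compression to 8 bits against a fixed reference level (taken from the
# first frame so the mapping is identical across a sequence).
log_compress <- function(env, ref, alpha = 60) {
  cpp_log8(env, ref, alpha)
}

# Reference level for log compression: slightly above the first frame's
# envelope maximum, so the brightest structure maps just under full scale and
# keeps its intensity gradation (no saturated plateau).
compression_reference <- function(env) {
  r <- 1.05 * max(env)
  if (r <= 0) 1 else r
}

#' Normalized twitch pulse
#'
#' Difference-of-exponentials pulse `e^(-t/tau_decay) - e^(-t/tau_rise)`,
#' normalized to unit peak; zero for `t < 0`. This conventional smooth
#' uni-modal shape stands in for the muscle's mechanical twitch response.
#'
#' @param t time in seconds (vector), measured from the stimulus.
#' @param tau_rise,tau_decay rise and decay time constants in seconds;
#'   `tau_rise < tau_decay`.
#' @return numeric vector in `[0, 1]` with unit peak.
#' @export
twitch_pulse <- function(t, tau_rise = 0.03, tau_decay = 0.12) {
  if (tau_rise >= tau_decay) abort("`tau_rise` must be < `tau_decay`")
  w <- ifelse(t <= 0, 0, exp(-t / tau_decay) - exp(-t / tau_rise))
  t_pk <- tau_rise * tau_decay / (tau_decay - tau_rise) *
    log(tau_decay / tau_rise)
  w / (exp(-t_pk / tau_decay) - exp(-t_pk / tau_rise))
}

# Superpose a pulse train: onset times (s), evaluated at times t.
pulse_train <- function(t, onsets, tau_rise, tau_decay) {
  out <- numeric(length(t))
  for (o in onsets) out <- out + twitch_pulse(t - o, tau_rise, tau_decay)
  out
}

# Ground-truth carrier emitted by every simulator.
ground_truth <- function(track, displace, info = list()) {
  structure(list(track = track, displace = displace, info = info),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d frames: %s\n", nrow(x$track),
              paste(setdiff(names(x$track), c("frame", "time_s")),
                    collapse = ", ")))
  invisible(x)
}
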