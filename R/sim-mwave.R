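#' Biphasic M-wave template waveform
#'
#' First derivative of a Gaussian, normalized to `peak_mv` millivolt peak
#' amplitude, centred in a window of `duration_ms`. A compound muscle action
#' potential recorded in monopolar configuration is well approximated by a
#' smooth biphasic wave of roughly this shape.
#'
#' @param fs_hz sampling rate.
#' @param duration_ms waveform duration (default 15 ms).
#' @param peak_mv peak amplitude in millivolts (default 1 mV).
#' @return numeric vector of `round(duration_ms * fs / 1000)` samples, in
#'   microvolts.
#' @export
mwave_template <- function(fs_hz = 2048, duration_ms = 15, peak_mv = 1) {
  n <- round(duration_ms * fs_hz / 1000)
  t <- seq_len(n) - (n + 1) / 2
  s <- n / 7                     # ~ +-3.5 sigma inside the window
  w <- -t * exp(-0.5 * (t / s)^2)
  1000 * peak_mv * w / max(abs(w))
}

#' Parameters for the trigger-locked M-wave grid simulation
#'
#' Describes electrically evoked monopolar surface EMG over a high-density
#' grid: each stimulus inserts, on every channel, a scaled and delayed copy
#' of the biphasic template plus additive white noise, optional powerline
#' interference, and optional per-channel failure modes. Channel amplitudes
#' follow a 2-D Gaussian over the grid centred between columns 2 and 3 (the
#' region under the ultrasound probe); rows farther from the innervation row
#' see the wave later (propagation delay).
#'
#' @param grid a [grid_geometry()] (default 8 rows x 4 columns).
#' @param fs_hz sampling rate (default 2048).
#' @param stim_rate_pps stimulation rate in pulses per second (default 1).
#' @param duration_s record length (default 20 s, i.e. 20 stimuli at 1 pps).
#' @param template_duration_ms,template_peak_mv shape of the per-channel
#'   M-wave (see [mwave_template()]).
#' @param amp_centre `(row, col)` of the spatial amplitude peak (default
#'   `c(4.5, 2.5)`, between columns 2 and 3).
#' @param amp_sigma spatial standard deviation of the amplitude profile, in
#'   electrode units.
#' @param row_delay_ms inter-row propagation delay per row of distance from
#'   the innervation row.
#' @param innervation_row row from which propagation delays are counted.
#' @param noise_rms_uv additive white-noise RMS per channel, microvolts.
#' @param powerline_uv,powerline_hz amplitude (default 0: clean) and
#'   frequency of sinusoidal powerline interference.
#' @param bad_channels named list mapping channel index (as character) to a
#'   failure mode: `"open_contact"` (large-amplitude noise, no signal),
#'   `"short_circuit_pair"` (channel becomes a sample-identical copy of a
#'   grid neighbour) or `"artifact_burst"` (intermittent high-amplitude
#'   movement artifacts).
#' @param seed integer seed.
#' @return validated `mwave_grid_params` list.
#' @export
mwave_grid_params <- function(grid = grid_geometry(), fs_hz = 2048,
                              stim_rate_pps = 1, duration_s = 20,
                              template_duration_ms = 15,
                              template_peak_mv = 1,
                              amp_centre = c(4.5, 2.5), amp_sigma = 3,
                              row_delay_ms = 0.4, innervation_row = 3,
                              noise_rms_uv = 10, powerline_uv = 0,
                              powerline_hz = 50, bad_channels = list(),
                              seed = 1L) {
  if (stim_rate_pps * duration_s < 1)
    abort("duration too short for a single stimulus")
  if (noise_rms_uv < 0) abort("`noise_rms_uv` must be >= 0")
  nch <- grid$rows * grid$cols
  if (length(bad_channels)) {
    idx <- as.integer(names(bad_channels))
    if (any(is.na(idx)) || any(idx < 1L) || any(idx > nch))
      abort("bad_channels indices must be valid channel numbers")
    modes <- unlist(bad_channels)
    ok <- modes %in% c("open_contact", "short_circuit_pair", "artifact_burst")
    if (!all(ok)) abort("unknown bad-channel failure mode")
  }
  structure(
    list(grid = grid, fs_hz = fs_hz, stim_rate_pps = stim_rate_pps,
         duration_s = duration_s, template_duration_ms = template_duration_ms,
         template_peak_mv = template_peak_mv, amp_centre = amp_centre,
         amp_sigma = amp_sigma, row_delay_ms = row_delay_ms,
         innervation_row = innervation_row, noise_rms_uv = noise_rms_uv,
         powerline_uv = powerline_uv, powerline_hz = powerline_hz,
         bad_channels = bad_channels, seed = as.integer(seed)),
    class = "mwave_grid_params")
}

#' Simulate a trigger-locked M-wave recording over the electrode grid
#'
#' @param params an [mwave_grid_params()] object.
#' @return an [emg_recording()] with `grid$rows * grid$cols` channels in
#'   column-major channel order, trigger indices spaced `fs / stim_rate`
#'   samples apart, and metadata recording the per-channel amplitude gains
#'   and the seed.
#' @export
simulate_mwave_grid <- function(params) {
  p <- params
  if (!inherits(p, "mwave_grid_params"))
    abort("`params` must come from mwave_grid_params()")
  fs <- p$fs_hz
  N <- round(p$duration_s * fs)
  cm <- channel_map(p$grid)
  nch <- nrow(cm)
  n_stim <- floor(p$stim_rate_pps * p$duration_s)
  triggers <- 1L + round((seq_len(n_stim) - 1L) * fs / p$stim_rate_pps)
  w <- mwave_template(fs, p$template_duration_ms, p$template_peak_mv)
  gains <- exp(-((cm$row - p$amp_centre[1])^2 +
                 (cm$col - p$amp_centre[2])^2) / (2 * p$amp_sigma^2))
  delays <- round(abs(cm$row - p$innervation_row) * p$row_delay_ms * fs / 1000)

  X <- matrix(0, nch, N)
  for (ch in seq_len(nch)) {
    for (tr in triggers) {
      i0 <- tr + delays[ch]
      i1 <- min(N, i0 + length(w) - 1L)
      if (i0 <= N)
        X[ch, i0:i1] <- X[ch, i0:i1] + gains[ch] * w[seq_len(i1 - i0 + 1L)]
    }
  }
  withr::with_seed(p$seed, {
    if (p$noise_rms_uv > 0)
      X <- X + matrix(rnorm(nch * N, sd = p$noise_rms_uv), nch, N)
    if (p$powerline_uv > 0) {
      t <- (seq_len(N) - 1) / fs
      phases <- runif(nch, 0, 2 * pi)
      for (ch in seq_len(nch))
        X[ch, ] <- X[ch, ] +
          p$powerline_uv * sqrt(2) * sin(2 * pi * p$powerline_hz * t + phases[ch])
    }
    for (ch_name in names(p$bad_channels)) {
      ch <- as.integer(ch_name)
      mode <- p$bad_channels[[ch_name]]
      if (mode == "open_contact") {
        # an open contact swamps the channel: noise at 25x the grid's
        # typical channel RMS (signal included), well beyond the 20x floor
        nominal <- max(median(sqrt(rowMeans(X^2))), p$noise_rms_uv, 1)
        X[ch, ] <- rnorm(N, sd = 25 * nominal)
      } else if (mode == "short_circuit_pair") {
        nb <- grid_neighbour(cm, ch)
        X[ch, ] <- X[nb, ]
      } else if (mode == "artifact_burst") {
        n_burst <- max(1L, round(p$duration_s / 4))
        for (b in seq_len(n_burst)) {
          at <- sample.int(N - fs %/% 4, 1)
          idx <- at:(at + fs %/% 4)
          X[ch, idx] <- X[ch, idx] +
            40 * p$noise_rms_uv * sin(2 * pi * 4 * seq_along(idx) / fs) *
            exp(-seq_along(idx) / (fs / 8))
        }
      }
    }
  })
  emg_recording(X, fs_hz = fs, grid = p$grid, trigger_samples = triggers,
                metadata = list(gains = gains, delays = delays, seed = p$seed,
                                bad_channels = p$bad_channels))
}

# nearest in-grid neighbour (same column, adjacent row if possible)
grid_neighbour <- function(cm, ch) {
  row <- cm$row[ch]; col <- cm$col[ch]
  target_row <- if (row < max(cm$row)) row + 1L else row - 1L
  which(cm$row == target_row & cm$col == col)[1]
}
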