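# Multichannel evoked-EMG analysis: zero-phase band-pass filtering,
# trigger-locked epoch extraction, template averaging, per-channel NMSE
# mapping over the grid, and automated channel-quality screening.

#' Zero-phase Butterworth band-pass filter
#'
#' Filters every channel with a Butterworth band-pass designed at
#' `order` and applied forward and backward (`signal::filtfilt`), giving
#' zero phase shift ("noncausal") and an effective magnitude order of
#' `2 * order`. Triggers and metadata pass through untouched.
#'
#' @param rec an [emg_recording()].
#' @param low_hz,high_hz band edges, `0 < low < high < fs/2` (defaults
#'   20-450 Hz, the analysis band).
#' @param order design order of the Butterworth prototype (default 4).
#' @return a filtered [emg_recording()].
#' @export
bandpass <- function(rec, low_hz = 20, high_hz = 450, order = 4) {
  fs <- rec$fs_hz
  if (low_hz <= 0 || high_hz <= low_hz || high_hz >= fs / 2)
    abort("band edges must satisfy 0 < low < high < fs/2")
  bf <- signal::butter(order, c(low_hz, high_hz) / (fs / 2), type = "pass")
  filtered <- t(apply(rec$samples, 1, function(x) signal::filtfilt(bf, x)))
  emg_recording(filtered, fs_hz = fs, grid = rec$grid,
                trigger_samples = rec$trigger_samples,
                metadata = rec$metadata)
}

#' Extract trigger-locked epochs
#'
#' Cuts `round(epoch_ms * fs / 1000)` samples per channel starting at each
#' stimulation trigger sample (82 samples for 40 ms at 2048 Hz). Triggers
#' whose epoch would overrun the record are skipped with a warning.
#'
#' @param rec an [emg_recording()] with at least one trigger.
#' @param epoch_ms epoch duration from the trigger's rising edge (default
#'   40 ms).
#' @return a 3-D array `channels x epochs x samples` with attributes
#'   `fs_hz` and `epoch_ms`.
#' @export
extract_epochs <- function(rec, epoch_ms = 40) {
  if (!length(rec$trigger_samples)) abort("recording has no triggers")
  len <- as.integer(round(epoch_ms * rec$fs_hz / 1000))
  N <- ncol(rec$samples)
  usable <- rec$trigger_samples[rec$trigger_samples + len - 1L <= N]
  dropped <- length(rec$trigger_samples) - length(usable)
  if (dropped > 0)
    warn(sprintf("%d trigger(s) too close to the record end were skipped",
                 dropped))
  if (!length(usable)) abort("no trigger leaves room for a full epoch")
  nch <- nrow(rec$samples)
  ep <- array(0, dim = c(nch, length(usable), len))
  for (k in seq_along(usable))
    ep[, k, ] <- rec$samples[, usable[k]:(usable[k] + len - 1L)]
  attr(ep, "fs_hz") <- rec$fs_hz
  attr(ep, "epoch_ms") <- epoch_ms
  ep
}

#' Average consecutive epochs into per-channel templates
#'
#' Sample-wise mean of the first `n_epochs` consecutive epochs per channel.
#'
#' @param epochs array from [extract_epochs()].
#' @param n_epochs number of consecutive epochs to average (default 20).
#' @return an `mwave_template_set`: matrix `channels x samples` with
#'   attributes `n_epochs_averaged`, `fs_hz`, `epoch_ms`.
#' @export
average_template <- function(epochs, n_epochs = 20) {
  avail <- dim(epochs)[2]
  if (avail < n_epochs)
    abort(sprintf("need %d epochs but only %d available", n_epochs, avail))
  tpl <- apply(epochs[, seq_len(n_epochs), , drop = FALSE], c(1, 3), mean)
  structure(tpl, class = "mwave_template_set",
            n_epochs_averaged = n_epochs,
            fs_hz = attr(epochs, "fs_hz"), epoch_ms = attr(epochs, "epoch_ms"))
}

#' Per-channel NMSE map between two template sets
#'
#' For every grid channel, the normalized mean square error (in percent)
#' between the with-probe template `f` and the without-probe template `g`:
#' `100 * sum((f - g)^2) / sum(g^2)`. No mean removal is applied — evoked
#' templates share a true zero baseline, and removing means would mask DC
#' contact artifacts the comparison should expose. Group means are computed
#' over the central columns (2 and 3, under the ultrasound probe) and the
#' lateral columns (1 and 4). Channels whose reference template is all zero
#' are flagged and excluded from the group means.
#'
#' @param set_with,set_without two `mwave_template_set`s on the same grid
#'   with equal epoch length; `set_with` is the comparison (`f`),
#'   `set_without` the reference (`g`).
#' @param grid the [grid_geometry()] the channels live on.
#' @return a tibble of class `nmse_map` with columns `channel`, `row`,
#'   `col`, `nmse_pct`, `group` (`"central"`/`"lateral"`), `excluded`;
#'   attribute `group_means` (named numeric). `glance()` returns the group
#'   means and grid mean as a one-row tibble.
#' @export
template_nmse_map <- function(set_with, set_without, grid = grid_geometry()) {
  if (!all(dim(set_with) == dim(set_without)))
    abort("template sets must have identical dimensions")
  cm <- channel_map(grid)
  if (nrow(cm) != nrow(set_with))
    abort("template set channel count does not match the grid")
  central <- c(2, 3)
  vals <- vapply(seq_len(nrow(cm)), function(ch) {
    g <- set_without[ch, ]
    if (sum(g^2) == 0) return(NA_real_)
    nmse(set_with[ch, ], g, demean = FALSE)
  }, numeric(1))
  out <- cm %>%
    mutate(nmse_pct = vals,
           group = ifelse(.data$col %in% central, "central", "lateral"),
           excluded = is.na(vals))
  gm <- c(
    central = mean(out$nmse_pct[out$group == "central" & !out$excluded]),
    lateral = mean(out$nmse_pct[out$group == "lateral" & !out$excluded]),
    grid = mean(out$nmse_pct[!out$excluded]))
  attr(out, "group_means") <- gm
  class(out) <- c("nmse_map", class(out))
  out
}

#' @export
glance.nmse_map <- function(x, ...) {
  gm <- attr(x, "group_means")
  tibble(central_mean_pct = gm[["central"]], lateral_mean_pct = gm[["lateral"]],
         grid_mean_pct = gm[["grid"]], n_excluded = sum(x$excluded))
}

#' Automated channel-quality screening
#'
#' Flags each channel with exactly one primary label, automating what is
#' usually done by visual inspection: `open_contact` if the channel RMS
#' exceeds 5x the grid-median RMS; `short_circuit` if some channel pair is
#' near-identical (correlation > 0.999 with amplitude ratio within 1%);
#' `powerline` if more than half the signal power in the 45-55 or 55-65 Hz
#' band; `artifact` if the amplitude distribution is strongly
#' heavy-tailed (excess kurtosis > 20); otherwise `ok`. Precedence:
#' open_contact > short_circuit > powerline > artifact.
#'
#' @param rec an [emg_recording()] of at least 1 s.
#' @return a tibble of class `channel_quality`: `channel`, `row`, `col`,
#'   `flag`, `rms_uv`, `powerline_fraction`, `max_xcorr`, `kurtosis`.
#' @export
screen_channels <- function(rec) {
  if (ncol(rec$samples) < rec$fs_hz)
    abort("need at least 1 s of data to screen channels")
  X <- rec$samples
  # screen the background: evoked responses are legitimately impulsive and
  # would trip the RMS and kurtosis criteria, so trigger-locked windows
  # (60 ms from each trigger) are excluded from the diagnostics
  if (length(rec$trigger_samples)) {
    w <- round(0.06 * rec$fs_hz)
    drop <- unique(unlist(lapply(rec$trigger_samples, function(tr)
      tr:min(tr + w, ncol(X)))))
    if (length(drop) < ncol(X) - rec$fs_hz / 2) X <- X[, -drop, drop = FALSE]
  }
  nch <- nrow(X)
  rms_ch <- sqrt(rowMeans(X^2))
  med <- median(rms_ch)

  # powerline band power fraction via the periodogram
  pl_frac <- vapply(seq_len(nch), function(ch) {
    x <- X[ch, ] - mean(X[ch, ])
    if (all(x == 0)) return(0)
    sp <- Mod(stats::fft(x))^2
    n <- length(x)
    fr <- (seq_len(n) - 1) * rec$fs_hz / n
    half <- fr <= rec$fs_hz / 2
    band <- half & ((fr >= 45 & fr <= 55) | (fr > 55 & fr <= 65))
    sum(sp[band]) / sum(sp[half])
  }, numeric(1))

  cc <- suppressWarnings(cor(t(X)))
  diag(cc) <- 0
  amp_ratio <- outer(rms_ch, rms_ch, "/")
  ident <- cc > 0.999 & amp_ratio >= 0.99 & amp_ratio <= 1.01
  max_xc <- apply(cc, 1, max, na.rm = TRUE)

  kurt <- vapply(seq_len(nch), function(ch) {
    x <- X[ch, ] - mean(X[ch, ])
    s2 <- mean(x^2)
    if (s2 == 0) return(0)
    mean(x^4) / s2^2 - 3
  }, numeric(1))

  flag <- rep("ok", nch)
  flag[kurt > 20] <- "artifact"
  flag[pl_frac > 0.5] <- "powerline"
  flag[apply(ident, 1, any, na.rm = TRUE)] <- "short_circuit"
  flag[rms_ch > 5 * med] <- "open_contact"

  out <- channel_map(rec$grid) %>%
    mutate(flag = flag, rms_uv = rms_ch, powerline_fraction = pl_frac,
           max_xcorr = max_xc, kurtosis = kurt)
  class(out) <- c("channel_quality", class(out))
  out
}
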