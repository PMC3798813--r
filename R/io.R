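# File formats: multi-page TIFF + JSON sidecar for image sequences, CSV +
# JSON header for EMG, CSV for ground truth, JSON for configuration. All
# readers validate and reject rather than guess: calibration, sampling rate
# and grid shape are never silently defaulted.

sidecar_path <- function(path) sub("\\.[^.]+$", ".json", path)

#' Write / read an image sequence (multi-page TIFF + JSON sidecar)
#'
#' Frames go to an 8-bit multi-page TIFF; acquisition metadata
#' (`frame_rate_hz`, `calib_mm_per_px`, plus any free-form metadata) to a
#' JSON sidecar next to it (same basename, `.json`). The write/read round
#' trip is bit-identical on frames.
#'
#' @param seq an [image_sequence()].
#' @param path TIFF file path (`.tif`).
#' @return `write_image_sequence` returns `path` invisibly;
#'   `read_image_sequence` returns an [image_sequence()].
#' @export
write_image_sequence <- function(seq, path) {
  pages <- lapply(seq_len(n_frames(seq)), function(i) get_frame(seq, i) / 255)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L, compression = "none")
  meta <- c(list(frame_rate_hz = seq$frame_rate_hz,
                 calib_mm_per_px = unname(seq$calib_mm_per_px)),
            seq$metadata)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_image_sequence
#' @export
read_image_sequence <- function(path) {
  sc <- sidecar_path(path)
  if (!file.exists(sc)) abort(paste0("missing JSON sidecar: ", sc))
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  for (field in c("frame_rate_hz", "calib_mm_per_px")) {
    if (is.null(meta[[field]]))
      abort(sprintf("sidecar is missing required field `%s`", field))
  }
  if (length(meta$calib_mm_per_px) != 2 || any(meta$calib_mm_per_px <= 0))
    abort("sidecar `calib_mm_per_px` must be two positive values")
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(unique(lapply(pages, dim))) != 1L)
    abort("frame size mismatch within TIFF stack")
  extra <- meta[setdiff(names(meta), c("frame_rate_hz", "calib_mm_per_px"))]
  image_sequence(lapply(pages, function(m) m + 0),
                 frame_rate_hz = meta$frame_rate_hz,
                 calib_mm_per_px = meta$calib_mm_per_px,
                 metadata = extra)
}

#' Write / read a multichannel EMG recording (CSV + JSON header)
#'
#' Samples are stored as a CSV with one column per channel (17 significant
#' digits, so doubles round-trip exactly); sampling rate, units, grid
#' geometry, trigger indices and the column-major channel map go to a JSON
#' header with the same basename. Readers reject channel counts that
#' disagree with the declared grid and unsorted trigger lists.
#'
#' @param rec an [emg_recording()].
#' @param path CSV file path (`.csv`).
#' @return `write_emg` returns `path` invisibly; `read_emg` an
#'   [emg_recording()].
#' @export
write_emg <- function(rec, path) {
  m <- formatC(t(rec$samples), format = "g", digits = 17)
  lines <- c(paste(sprintf("ch%02d", seq_len(nrow(rec$samples))),
                   collapse = ","),
             apply(m, 1, paste, collapse = ","))
  writeLines(lines, path)
  header <- list(fs_hz = rec$fs_hz, units = "uV",
                 grid = list(rows = rec$grid$rows, cols = rec$grid$cols,
                             ied_mm = rec$grid$ied_mm),
                 trigger_samples = rec$trigger_samples,
                 channel_map = as.data.frame(rec$channel_map))
  jsonlite::write_json(header, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_emg
#' @export
read_emg <- function(path) {
  hp <- sidecar_path(path)
  if (!file.exists(hp)) abort(paste0("missing JSON header: ", hp))
  h <- jsonlite::read_json(hp, simplifyVector = TRUE)
  for (field in c("fs_hz", "grid"))
    if (is.null(h[[field]]))
      abort(sprintf("header is missing required field `%s`", field))
  grid <- grid_geometry(h$grid$rows, h$grid$cols, h$grid$ied_mm)
  dat <- utils::read.csv(path, check.names = FALSE)
  if (ncol(dat) != grid$rows * grid$cols)
    abort(sprintf("data has %d channels but grid declares %d",
                  ncol(dat), grid$rows * grid$cols))
  trig <- as.integer(h$trigger_samples %||% integer())
  if (length(trig) > 1L && any(diff(trig) <= 0L))
    abort("header trigger_samples must be strictly increasing")
  emg_recording(t(as.matrix(dat)), fs_hz = h$fs_hz, grid = grid,
                trigger_samples = trig)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a ground-truth series as CSV
#'
#' @param truth a `ground_truth` object (its `track` tibble is written).
#' @param path CSV path.
#' @return `write_ground_truth` returns `path` invisibly;
#'   `read_ground_truth` a tibble.
#' @export
write_ground_truth <- function(truth, path) {
  utils::write.csv(as.data.frame(truth$track), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) as_tibble(utils::read.csv(path))

config_defaults <- function() {
  list(
    fs_hz = 2048, frame_rate_hz = 80,
    bandpass_low_hz = 20, bandpass_high_hz = 450, filter_order = 4,
    epoch_ms = 40, n_epochs = 20,
    noise_band_low_hz = 10, noise_band_high_hz = 1000,
    amplifier_noise_rms_uv = 0.8,
    min_corr = 0.5, search_margin_px = 10,
    seed = 1
  )
}

#' Load and validate an experiment configuration
#'
#' Reads a JSON configuration file, fills in defaults (sampling rate 2048
#' Hz, frame rate 80 Hz, analysis band-pass 20-450 Hz order 4, epoch 40 ms,
#' 20 epochs averaged, amplifier noise 0.8 uV, ...), rejects unknown keys,
#' and reports every out-of-range value at once. The derived
#' `epoch_samples = round(epoch_ms * fs_hz / 1000)` is appended (82 at the
#' defaults).
#'
#' @param path JSON file path, or `NULL` for the pure defaults.
#' @return named list of validated configuration values.
#' @export
load_config <- function(path = NULL) {
  cfg <- config_defaults()
  if (!is.null(path)) {
    user <- jsonlite::read_json(path, simplifyVector = TRUE)
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown))
      abort(paste0("unknown configuration keys: ",
                   paste(unknown, collapse = ", ")))
    cfg[names(user)] <- user
  }
  bad <- character()
  pos <- c("fs_hz", "frame_rate_hz", "bandpass_low_hz", "bandpass_high_hz",
           "filter_order", "epoch_ms", "n_epochs", "noise_band_low_hz",
           "noise_band_high_hz", "search_margin_px")
  for (k in pos) if (!is.numeric(cfg[[k]]) || cfg[[k]] <= 0)
    bad <- c(bad, sprintf("`%s` must be positive (got %s)", k, cfg[[k]]))
  if (cfg$bandpass_low_hz >= cfg$bandpass_high_hz)
    bad <- c(bad, "band edges reversed: bandpass_low_hz >= bandpass_high_hz")
  if (cfg$bandpass_high_hz >= cfg$fs_hz / 2)
    bad <- c(bad, "bandpass_high_hz must be below Nyquist (fs_hz / 2)")
  if (cfg$amplifier_noise_rms_uv < 0)
    bad <- c(bad, "`amplifier_noise_rms_uv` must be >= 0")
  if (cfg$min_corr < -1 || cfg$min_corr > 1)
    bad <- c(bad, "`min_corr` must lie in [-1, 1]")
  if (length(bad))
    abort(paste0("invalid configuration:\n",
                 paste0("  - ", bad, collapse = "\n")))
  cfg$epoch_samples <- as.integer(round(cfg$epoch_ms * cfg$fs_hz / 1000))
  cfg
}
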