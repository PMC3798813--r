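#' Image sequence container
#'
#' A time-ordered stack of 8-bit grayscale frames with acquisition metadata.
#' Row index is the axial (depth) direction and column index the lateral
#' direction, origin at the top-left. This is the carrier for all ultrasound
#' analyses: tracking works in pixels and converts to millimetres through the
#' per-axis calibration stored here.
#'
#' @param frames numeric array `T x H x W` of intensities in `[0, 255]`, or a
#'   list of `H x W` matrices (all the same size).
#' @param frame_rate_hz frame rate in Hz (scalar > 0).
#' @param calib_mm_per_px length-2 numeric, millimetres per pixel along the
#'   (axial, lateral) axes; both > 0.
#' @param metadata optional named list of free-form metadata.
#'
#' @return An object of class `image_sequence`: a list with elements
#'   `frames` (T x H x W array), `frame_rate_hz`, `calib_mm_per_px`
#'   (named `c(axial=, lateral=)`) and `metadata`.
#' @export
image_sequence <- function(frames, frame_rate_hz, calib_mm_per_px,
                           metadata = list()) {
  if (is.list(frames)) {
    dims <- unique(lapply(frames, dim))
    if (length(dims) != 1L) abort("all frames must share the same dimensions")
    frames <- aperm(simplify2array(frames), c(3, 1, 2))
  }
  if (length(dim(frames)) != 3L) abort("`frames` must be a T x H x W array")
  if (dim(frames)[1] < 1L) abort("an image sequence needs at least one frame")
  rng <- range(frames)
  if (rng[1] < 0 || rng[2] > 255)
    abort("frame intensities must lie in [0, 255]")
  if (!is.numeric(frame_rate_hz) || length(frame_rate_hz) != 1L ||
      frame_rate_hz <= 0)
    abort("`frame_rate_hz` must be a positive scalar")
  calib <- as.numeric(calib_mm_per_px)
  if (length(calib) != 2L || any(!is.finite(calib)) || any(calib <= 0))
    abort("`calib_mm_per_px` must be two positive values (axial, lateral)")
  names(calib) <- c("axial", "lateral")
  structure(
    list(frames = frames, frame_rate_hz = frame_rate_hz,
         calib_mm_per_px = calib, metadata = metadata),
    class = "image_sequence"
  )
}

#' @export
print.image_sequence <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "<image_sequence> %d frames of %d x %d px, %.5g fps, %.4g/%.4g mm/px (ax/lat), %.3g s\n",
    d[1], d[2], d[3], x$frame_rate_hz, x$calib_mm_per_px[1],
    x$calib_mm_per_px[2], d[1] / x$frame_rate_hz))
  invisible(x)
}

#' @export
dim.image_sequence <- function(x) dim(x$frames)

#' Number of frames in an image sequence
#' @param seq an [image_sequence()].
#' @return integer frame count.
#' @export
n_frames <- function(seq) dim(seq$frames)[1]

#' Extract one frame as a matrix
#' @param seq an [image_sequence()].
#' @param i frame index (1-based).
#' @return `H x W` numeric matrix.
#' @export
get_frame <- function(seq, i) {
  stopifnot(i >= 1, i <= n_frames(seq))
  seq$frames[i, , ]
}

#' Electrode grid geometry
#'
#' Geometry of a high-density surface-EMG electrode grid. The default is the
#' 32-electrode grid used throughout: 4 columns by 8 rows with 10 mm
#' inter-electrode distance.
#'
#' @param rows,cols number of electrode rows and columns (>= 1).
#' @param ied_mm inter-electrode (centre-to-centre) distance in mm.
#' @return A `grid_geometry` list with `rows`, `cols`, `ied_mm`.
#' @export
grid_geometry <- function(rows = 8, cols = 4, ied_mm = 10) {
  if (rows < 1 || cols < 1) abort("grid must have at least one row and column")
  if (ied_mm <= 0) abort("`ied_mm` must be positive")
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 ied_mm = ied_mm), class = "grid_geometry")
}

#' Channel map for a grid
#'
#' Channels are numbered column-major: column 1 rows 1..R, then column 2, and
#' so on (columns left to right, rows proximal to distal). The map is carried
#' in file headers so that data recorded under another convention can be
#' remapped on read.
#'
#' @param grid a [grid_geometry()].
#' @return tibble with columns `channel`, `row`, `col`.
#' @export
channel_map <- function(grid) {
  tibble(channel = seq_len(grid$rows * grid$cols),
         row = rep(seq_len(grid$rows), times = grid$cols),
         col = rep(seq_len(grid$cols), each = grid$rows))
}

#' Multichannel EMG recording container
#'
#' @param samples `C x N` numeric matrix of monopolar EMG, in microvolts;
#'   `C` must equal `rows * cols` of the grid.
#' @param fs_hz sampling rate in Hz (default 2048).
#' @param grid a [grid_geometry()].
#' @param trigger_samples strictly increasing integer vector of stimulation
#'   trigger sample indices (1-based, within the record). May be empty for
#'   spontaneous-activity recordings.
#' @param metadata optional named list.
#' @return An `emg_recording` object (list with the fields above plus the
#'   column-major `channel_map`).
#' @export
emg_recording <- function(samples, fs_hz = 2048, grid = grid_geometry(),
                          trigger_samples = integer(), metadata = list()) {
  samples <- as.matrix(samples)
  C <- nrow(samples)
  if (C != grid$rows * grid$cols)
    abort(sprintf("channel count (%d) must equal grid rows x cols (%d)",
                  C, grid$rows * grid$cols))
  if (fs_hz <= 0) abort("`fs_hz` must be positive")
  trig <- as.integer(trigger_samples)
  if (length(trig)) {
    if (any(trig < 1L) || any(trig > ncol(samples)))
      abort("trigger indices must lie within [1, N]")
    if (any(diff(trig) <= 0L))
      abort("trigger indices must be strictly increasing")
  }
  structure(
    list(samples = samples, fs_hz = fs_hz, grid = grid,
         trigger_samples = trig, channel_map = channel_map(grid),
         metadata = metadata),
    class = "emg_recording"
  )
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf(
    "<emg_recording> %d ch x %d samples (%.3g s at %g Hz), %d triggers, grid %dx%d\n",
    nrow(x$samples), ncol(x$samples), ncol(x$samples) / x$fs_hz, x$fs_hz,
    length(x$trigger_samples), x$grid$rows, x$grid$cols))
  invisible(x)
}

#' Aponeurosis segmentation
#'
#' Two sub-pixel polylines bounding the fascicle region: the superficial
#' aponeurosis and, strictly deeper at every shared lateral coordinate, the
#' deep aponeurosis. The fascicle region is the closed polygon between them.
#'
#' @param superficial,deep two-column matrices `(row_px, col_px)` of polyline
#'   vertices, ordered by increasing column.
#' @return A `segmentation` object with elements `superficial`, `deep` and
#'   `fascicle_region` (closed polygon, two-column matrix).
#' @export
segmentation <- function(superficial, deep) {
  superficial <- as.matrix(superficial); deep <- as.matrix(deep)
  if (ncol(superficial) != 2L || ncol(deep) != 2L)
    abort("polylines must be two-column (row_px, col_px) matrices")
  shared <- range(superficial[, 2], deep[, 2])
  at <- seq(max(min(superficial[, 2]), min(deep[, 2])),
            min(max(superficial[, 2]), max(deep[, 2])), length.out = 25)
  sup_r <- stats::approx(superficial[, 2], superficial[, 1], xout = at)$y
  deep_r <- stats::approx(deep[, 2], deep[, 1], xout = at)$y
  if (any(deep_r <= sup_r))
    abort("deep aponeurosis must lie strictly below the superficial one")
  region <- rbind(superficial, deep[rev(seq_len(nrow(deep))), , drop = FALSE],
                  superficial[1, , drop = FALSE])
  structure(list(superficial = superficial, deep = deep,
                 fascicle_region = region),
            class = "segmentation")
}

#' Evaluate a polyline's row (depth) at given columns
#' @param polyline two-column `(row, col)` matrix.
#' @param col_px lateral positions (px) at which to interpolate.
#' @return numeric vector of row positions.
#' @keywords internal
polyline_row_at <- function(polyline, col_px) {
  stats::approx(polyline[, 2], polyline[, 1], xout = col_px, rule = 2)$y
}
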