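#' Rectangular region-of-interest specification
#'
#' @param top_left integer `(row, col)` of the ROI's top-left pixel in
#'   frame 1 (1-based).
#' @param height_px,width_px ROI size in pixels; the default 10 x 15
#'   (10 axial rows by 15 lateral columns) matches the edge-tracking
#'   protocol's ROI size, oriented with the long side along the laterally
#'   extended spring edges.
#' @param search_margin_px half-width of the exhaustive search window around
#'   the predicted position, in pixels.
#' @return An `roi_spec` list.
#' @export
roi_spec <- function(top_left, height_px = 10, width_px = 15,
                     search_margin_px = 10) {
  if (height_px < 3 || width_px < 3) abort("ROI dimensions must be >= 3 px")
  structure(list(top_left = as.integer(top_left),
                 height_px = as.integer(height_px),
                 width_px = as.integer(width_px),
                 search_margin_px = as.integer(search_margin_px)),
            class = "roi_spec")
}

roi_centre <- function(roi) {
  c(roi$top_left[1] + (roi$height_px - 1) / 2,
    roi$top_left[2] + (roi$width_px - 1) / 2)
}

#' Parabolic sub-pixel peak refinement
#'
#' Given a 3 x 3 neighbourhood of correlation values whose centre is the
#' integer-lattice maximum, fits an independent 1-D parabola along each axis
#' and returns the vertex offsets `d = (c_minus - c_plus) /
#' (2 (c_minus - 2 c_0 + c_plus))`, clamped to `(-0.5, 0.5)`. A flat axis
#' (zero curvature) yields offset 0 and sets the `flat` attribute.
#'
#' @param neigh 3 x 3 numeric matrix of correlation values.
#' @return numeric `(d_row, d_col)` in `(-0.5, 0.5)`, with attribute `flat`
#'   (logical).
#' @export
subpixel_refine <- function(neigh) {
  neigh <- as.matrix(neigh)
  if (!all(dim(neigh) == c(3L, 3L))) abort("`neigh` must be 3 x 3")
  if (neigh[2, 2] < max(neigh))
    abort("centre of the neighbourhood must be its maximum")
  vertex <- function(cm, c0, cp) {
    denom <- 2 * (cm - 2 * c0 + cp)
    if (denom == 0) return(c(0, TRUE))
    d <- (cm - cp) / denom
    c(min(max(d, -0.499), 0.499), FALSE)
  }
  vr <- vertex(neigh[1, 2], neigh[2, 2], neigh[3, 2])
  vc <- vertex(neigh[2, 1], neigh[2, 2], neigh[2, 3])
  out <- c(d_row = vr[1], d_col = vc[1])
  attr(out, "flat") <- as.logical(vr[2] || vc[2])
  out
}

#' Track an ROI through an image sequence by normalized cross-correlation
#'
#' The ROI's content in the reference frame is matched against every integer
#' placement within `search_margin_px` of the predicted position (the
#' position tracked in the previous frame) by zero-normalized
#' cross-correlation, and the integer peak is refined to sub-pixel precision
#' with [subpixel_refine()]. Zero-normalization makes the track invariant to
#' constant intensity offsets. Frames whose peak correlation falls below
#' `min_corr` are flagged invalid and hold the last valid position.
#'
#' @param seq an [image_sequence()].
#' @param roi an [roi_spec()].
#' @param reference `"first_frame"` (default; the template is taken once from
#'   frame 1, so no drift accumulates) or `"previous_frame"` (template
#'   re-extracted each frame; tolerates large appearance change at the cost
#'   of drift).
#' @param min_corr validity threshold on the peak correlation (default 0.5).
#' @return A tibble of class `roi_track` with columns `frame`, `time_s`,
#'   `row`, `col` (sub-pixel centre position), `peak_corr`, `valid`.
#' @export
track_roi <- function(seq, roi, reference = c("first_frame", "previous_frame"),
                      min_corr = 0.5) {
  reference <- match.arg(reference)
  fr0 <- get_frame(seq, 1)
  H <- nrow(fr0); W <- ncol(fr0)
  tl <- roi$top_left
  if (tl[1] < 1 || tl[2] < 1 || tl[1] + roi$height_px - 1 > H ||
      tl[2] + roi$width_px - 1 > W)
    abort("ROI must lie fully inside frame 1")
  templ <- fr0[tl[1]:(tl[1] + roi$height_px - 1),
               tl[2]:(tl[2] + roi$width_px - 1), drop = FALSE]
  if (var(as.vector(templ)) == 0)
    abort("ROI has zero intensity variance in the reference frame")

  nf <- n_frames(seq)
  m <- roi$search_margin_px
  ctr0 <- roi_centre(roi)
  pos <- matrix(NA_real_, nf, 2)
  corr <- numeric(nf)
  valid <- logical(nf)
  pos[1, ] <- ctr0; corr[1] <- 1; valid[1] <- TRUE

  # current integer top-left estimate (template anchor within the frame)
  cur_tl <- tl
  for (i in seq(2, length.out = nf - 1)) {
    fr <- get_frame(seq, i)
    r1 <- max(1L, cur_tl[1] - m); c1 <- max(1L, cur_tl[2] - m)
    r2 <- min(H, cur_tl[1] + roi$height_px - 1L + m)
    c2 <- min(W, cur_tl[2] + roi$width_px - 1L + m)
    cmap <- cpp_zncc_map(fr[r1:r2, c1:c2, drop = FALSE], templ)
    pk <- which(cmap == max(cmap), arr.ind = TRUE)[1, ]  # first in scan order
    corr[i] <- cmap[pk[1], pk[2]]
    new_tl <- c(r1 + pk[1] - 1L, c1 + pk[2] - 1L)
    dsub <- c(0, 0)
    # a numerically perfect match is already at the true position; the
    # parabola would otherwise add a small bias from asymmetric neighbours
    if (corr[i] < 1 - 1e-9 &&
        pk[1] > 1 && pk[1] < nrow(cmap) && pk[2] > 1 && pk[2] < ncol(cmap)) {
      dsub <- subpixel_refine(cmap[(pk[1] - 1):(pk[1] + 1),
                                   (pk[2] - 1):(pk[2] + 1)])
    }
    if (corr[i] >= min_corr) {
      valid[i] <- TRUE
      cur_tl <- new_tl
      pos[i, ] <- new_tl + c((roi$height_px - 1) / 2, (roi$width_px - 1) / 2) +
        dsub
      if (reference == "previous_frame") {
        if (new_tl[1] >= 1 && new_tl[2] >= 1 &&
            new_tl[1] + roi$height_px - 1 <= H &&
            new_tl[2] + roi$width_px - 1 <= W) {
          templ <- fr[new_tl[1]:(new_tl[1] + roi$height_px - 1),
                      new_tl[2]:(new_tl[2] + roi$width_px - 1), drop = FALSE]
        }
      }
    } else {
      valid[i] <- FALSE
      pos[i, ] <- pos[max(which(valid[seq_len(i - 1)])), ]  # hold last valid
    }
  }

  out <- tibble(frame = seq_len(nf),
                time_s = (seq_len(nf) - 1) / seq$frame_rate_hz,
                row = pos[, 1], col = pos[, 2],
                peak_corr = corr, valid = valid)
  class(out) <- c("roi_track", class(out))
  out
}

#' Spring length from two groups of ROI tracks
#'
#' Per frame, the median centre position of the ROIs at each spring end is
#' taken (median of each coordinate independently; with an even count the
#' mean of the middle two), and the Euclidean distance between the two group
#' medians — in millimetres via the per-axis calibration — is the spring
#' length. Frames where every track of a group is invalid get `NA`.
#'
#' @param tracks_a,tracks_b lists of `roi_track` tibbles for the two spring
#'   ends (at least one track per group, all the same length).
#' @param calib_mm_per_px `(axial, lateral)` calibration in mm/px.
#' @param frame_rate_hz frame rate used for the time base.
#' @return A tibble of class `length_series` with `frame`, `time_s`,
#'   `length_mm`.
#' @export
spring_length <- function(tracks_a, tracks_b, calib_mm_per_px, frame_rate_hz) {
  lens <- vapply(c(tracks_a, tracks_b), nrow, integer(1))
  if (length(unique(lens)) != 1L) abort("all tracks must have equal length")
  nf <- lens[1]
  med_group <- function(tracks) {
    rows <- sapply(tracks, `[[`, "row")   # nf x k
    cols <- sapply(tracks, `[[`, "col")
    ok <- sapply(tracks, `[[`, "valid")
    rows <- as.matrix(rows); cols <- as.matrix(cols); ok <- as.matrix(ok)
    any_ok <- rowSums(ok) > 0
    cbind(row = apply(rows, 1, median), col = apply(cols, 1, median),
          ok = any_ok)
  }
  a <- med_group(tracks_a); b <- med_group(tracks_b)
  d_mm <- sqrt(((a[, 1] - b[, 1]) * calib_mm_per_px[1])^2 +
               ((a[, 2] - b[, 2]) * calib_mm_per_px[2])^2)
  d_mm[!(a[, 3] & b[, 3])] <- NA_real_
  out <- tibble(frame = seq_len(nf), time_s = (seq_len(nf) - 1) / frame_rate_hz,
                length_mm = d_mm)
  class(out) <- c("length_series", class(out))
  out
}

#' Normalized mean square error between two change series
#'
#' `NMSE = 100 * sum((f - g)^2) / sum(g^2)`, in percent, where `f` is the
#' predicted change series and `g` the imposed (reference) change series.
#' Both inputs are understood as *changes* about their operating point; with
#' `demean = TRUE` (default) each series has its own mean removed first, so
#' the measure is invariant to the unknown absolute offset between an
#' image-derived and a servo-imposed length. Note NMSE is not symmetric in
#' its arguments: `nmse(f, g) != nmse(g, f)` in general because only `g`
#' normalizes the error power.
#'
#' @param f,g equal-length numeric vectors (predicted, reference).
#' @param demean subtract each series' own mean first (default `TRUE`); use
#'   `FALSE` for signals with a meaningful shared zero baseline such as
#'   evoked-response templates.
#' @return NMSE in percent (scalar).
#' @export
nmse <- function(f, g, demean = TRUE) {
  if (length(f) != length(g)) abort("`f` and `g` must have equal length")
  if (length(g) < 1L) abort("series must be non-empty")
  keep <- is.finite(f) & is.finite(g)
  f <- f[keep]; g <- g[keep]
  if (demean) { f <- f - mean(f); g <- g - mean(g) }
  den <- sum(g^2)
  if (den == 0) abort("reference series has zero power; NMSE undefined")
  100 * sum((f - g)^2) / den
}

#' Default 8-ROI layout on a simulated spring sequence
#'
#' Places four ROIs along each bright spring edge (centred axially on the
#' edge's frame-1 depth, spread over the central lateral span), mirroring the
#' protocol's "eight 10 x 15 pixel ROIs defining the longitudinal edges at
#' each end of the spring".
#'
#' @param sim result of [simulate_spring_sequence()].
#' @param n_per_edge ROIs per edge (default 4).
#' @param height_px,width_px,search_margin_px passed to [roi_spec()].
#' @return list with elements `top` and `bottom`, each a list of
#'   [roi_spec()]s.
#' @export
spring_rois <- function(sim, n_per_edge = 4, height_px = 10, width_px = 15,
                        search_margin_px = 10) {
  info <- sim$truth$info
  calib <- info$calib_mm_per_px
  W <- dim(sim$sequence)[3]
  xs <- round(seq(0.25, 0.75, length.out = n_per_edge) * W)
  mk <- function(z_mm) {
    r_ctr <- z_mm / calib[1] + 1       # mm -> 1-based px row
    lapply(xs, function(xc) {
      roi_spec(c(round(r_ctr - (height_px - 1) / 2),
                 round(xc - (width_px - 1) / 2)),
               height_px, width_px, search_margin_px)
    })
  }
  list(top = mk(info$edge_top_mm), bottom = mk(info$edge_bottom_mm))
}

#' The 27-condition spring oscillation protocol
#'
#' Enumerates the in-vitro validation protocol: three peak-to-peak amplitudes
#' (0.4, 1.0, 1.4 mm) crossed with nine oscillation frequencies (0.5, 0.7, 1,
#' 2, 3, 5, 7, 8, 10 Hz), optionally duplicated over the two detection
#' conditions (with/without the electrode material under the probe — a label
#' only, since the material is acoustically transparent by design).
#'
#' @param conditions character vector of condition labels (default
#'   `"without"`).
#' @return tibble with columns `amplitude_mm`, `frequency_hz`, `condition`.
#' @export
spring_conditions <- function(conditions = "without") {
  tidyr::expand_grid(
    amplitude_mm = c(0.4, 1.0, 1.4),
    frequency_hz = c(0.5, 0.7, 1, 2, 3, 5, 7, 8, 10),
    condition = conditions)
}

#' Run the spring tracking benchmark over a condition table
#'
#' For each condition, simulates the spring phantom, tracks the eight edge
#' ROIs, computes the tracked length series and its NMSE (in percent) against
#' the imposed ground-truth length. The search margin is widened per
#' condition to cover the analytic maximum frame-to-frame edge displacement
#' `pi * D * f / frame_rate`.
#'
#' @param conditions tibble from [spring_conditions()] (or any tibble with
#'   `amplitude_mm`, `frequency_hz`, `condition` columns).
#' @param duration_s,frame_rate_hz protocol timing (defaults 30 s, 80 Hz).
#' @param seed base seed; each condition derives its own stream from it.
#' @param ... further arguments passed to [spring_scene_params()].
#' @return the `conditions` tibble with an `nmse_pct` column appended.
#' @export
run_spring_experiment <- function(conditions = spring_conditions(),
                                  duration_s = 30, frame_rate_hz = 80,
                                  seed = 1L, ...) {
  res <- purrr::pmap_dbl(
    list(conditions$amplitude_mm, conditions$frequency_hz,
         seq_len(nrow(conditions))),
    function(D, f, k) {
      p <- spring_scene_params(peak_to_peak_mm = D, frequency_hz = f,
                               duration_s = duration_s,
                               frame_rate_hz = frame_rate_hz,
                               seed = seed + 1000L * k, ...)
      sim <- simulate_spring_sequence(p)
      step_px <- pi * D * f / frame_rate_hz / p$calib_mm_per_px[1]
      margin <- max(10L, ceiling(step_px) + 3L)
      rois <- spring_rois(sim, search_margin_px = margin)
      tr <- function(r) track_roi(sim$sequence, r)
      ls <- spring_length(lapply(rois$top, tr), lapply(rois$bottom, tr),
                          p$calib_mm_per_px, frame_rate_hz)
      nmse(ls$length_mm, sim$truth$track$length_mm)
    })
  dplyr::mutate(conditions, nmse_pct = res)
}
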