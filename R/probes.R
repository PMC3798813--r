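# Measurement probe grid: an 8 x 10 set of virtual landmarks whose motion
# is interpolated from the sparse tracked features (triangle-based linear
# interpolation within each segment) and accumulated frame to frame
# (Lagrangian advection). The twitch series are read off the probes.

#' Initialize the 8 x 10 measurement probe grid
#'
#' Probe columns are anchored at `n_cols` lateral positions on the
#' superficial aponeurosis; each column runs to the deep aponeurosis along
#' the fascicle direction (a lateral run of `fascicle_dx_px` pixels, 0 for
#' vertical columns). The outer rows (1 and 8) lie on the two aponeurosis
#' polylines; the inner 6 rows are equally spaced across the fascicle
#' region, at fractions `1/7 .. 6/7` of the superficial-to-deep path.
#'
#' @param segmentation a [segmentation()] in pixel coordinates.
#' @param n_rows,n_cols grid size (defaults 8 x 10).
#' @param fascicle_dx_px lateral pixel run of a fascicle crossing the whole
#'   region (default 0: vertical columns).
#' @param lateral_range_px optional `(min, max)` lateral span for the column
#'   anchors; defaults to the segmentation's shared span minus the fascicle
#'   run.
#' @return tibble of class `probe_grid`: `probe`, `grid_row`, `grid_col`,
#'   `row`, `col` (px), `label`, `xi` (path fraction); attribute
#'   `fascicle_dx_px`.
#' @export
probe_grid <- function(segmentation, n_rows = 8, n_cols = 10,
                       fascicle_dx_px = 0, lateral_range_px = NULL) {
  span <- c(max(min(segmentation$superficial[, 2]),
                min(segmentation$deep[, 2])),
            min(max(segmentation$superficial[, 2]),
                max(segmentation$deep[, 2])))
  if (is.null(lateral_range_px)) {
    lateral_range_px <- c(span[1] + 2, span[2] - 2 - max(fascicle_dx_px, 0))
    if (fascicle_dx_px < 0)
      lateral_range_px <- c(span[1] + 2 - fascicle_dx_px, span[2] - 2)
  }
  if (diff(lateral_range_px) <= 0)
    abort("segmentation too narrow for the probe grid and fascicle run")
  anchors <- seq(lateral_range_px[1], lateral_range_px[2],
                 length.out = n_cols)
  xi <- (seq_len(n_rows) - 1) / (n_rows - 1)
  g <- tidyr::expand_grid(grid_col = seq_len(n_cols),
                          grid_row = seq_len(n_rows))
  x0 <- anchors[g$grid_col]
  xi_g <- xi[g$grid_row]
  # the two aponeurosis rows sit vertically above/below the column anchor
  # (so thickness pairs at matched lateral coordinates); the fascicle rows
  # follow the fascicle line from the superficial anchor
  apo <- g$grid_row == 1L | g$grid_row == n_rows
  col <- ifelse(apo, x0, x0 + xi_g * fascicle_dx_px)
  r_sup <- polyline_row_at(segmentation$superficial, x0)
  r_deep_f <- polyline_row_at(segmentation$deep, x0 + fascicle_dx_px)
  r_deep_v <- polyline_row_at(segmentation$deep, x0)
  row <- ifelse(apo & xi_g == 1, r_deep_v,
                r_sup + xi_g * (r_deep_f - r_sup))
  lab <- dplyr::case_when(g$grid_row == 1 ~ "superficial_apo",
                          g$grid_row == n_rows ~ "deep_apo",
                          TRUE ~ "fascicle")
  out <- tibble(probe = seq_len(nrow(g)), grid_row = g$grid_row,
                grid_col = g$grid_col, row = row, col = col, label = lab,
                xi = xi_g)
  attr(out, "fascicle_dx_px") <- fascicle_dx_px
  class(out) <- c("probe_grid", class(out))
  out
}

# inverse-distance weighting over the k nearest same-region features
idw_displacement <- function(fr, fc, dr, dc, pr, pc, k = 3) {
  d2 <- (fr - pr)^2 + (fc - pc)^2
  nn <- order(d2)[seq_len(min(k, length(d2)))]
  w <- 1 / pmax(sqrt(d2[nn]), 1e-6)
  w <- w / sum(w)
  c(sum(w * dr[nn]), sum(w * dc[nn]))
}

#' Interpolate feature displacements onto probes
#'
#' Per region label, the same-region features are triangulated (Delaunay)
#' and each probe's displacement is the barycentric (triangle-based linear)
#' interpolation of its enclosing triangle's vertex displacements. Probes
#' outside the convex hull fall back to inverse-distance weighting of the 3
#' nearest same-region features. Probes whose region holds fewer than 3
#' non-collinear features get `NA` displacement (callers hold the previous
#' value).
#'
#' @param features tibble with `row`, `col`, `d_row`, `d_col`, `label`.
#' @param probes tibble with `row`, `col`, `label` (e.g. a [probe_grid()]).
#' @return `probes` with `d_row`, `d_col` columns appended.
#' @export
interpolate_probe_displacement <- function(features, probes) {
  d_row <- rep(NA_real_, nrow(probes))
  d_col <- rep(NA_real_, nrow(probes))
  for (lab in unique(probes$label)) {
    pi <- which(probes$label == lab)
    fi <- which(features$label == lab)
    if (length(fi) < 3) next
    fr <- features$row[fi]; fc <- features$col[fi]
    # collinearity guard: triangulation needs 2-D spread
    spread <- svd(cbind(fr - mean(fr), fc - mean(fc)))$d
    if (spread[2] < 1e-8) next
    dup <- duplicated(cbind(fr, fc))
    lin_r <- tryCatch(
      interp::interpp(x = fc[!dup], y = fr[!dup], z = features$d_row[fi][!dup],
                      xo = probes$col[pi], yo = probes$row[pi])$z,
      error = function(e) rep(NA_real_, length(pi)))
    lin_c <- tryCatch(
      interp::interpp(x = fc[!dup], y = fr[!dup], z = features$d_col[fi][!dup],
                      xo = probes$col[pi], yo = probes$row[pi])$z,
      error = function(e) rep(NA_real_, length(pi)))
    for (j in seq_along(pi)) {
      if (is.na(lin_r[j]) || is.na(lin_c[j])) {
        v <- idw_displacement(fr, fc, features$d_row[fi], features$d_col[fi],
                              probes$row[pi[j]], probes$col[pi[j]])
        d_row[pi[j]] <- v[1]; d_col[pi[j]] <- v[2]
      } else {
        d_row[pi[j]] <- lin_r[j]; d_col[pi[j]] <- lin_c[j]
      }
    }
  }
  probes$d_row <- d_row
  probes$d_col <- d_col
  probes
}

#' Advect the probe grid through tracked features
#'
#' For each frame transition, per-feature displacements are formed from the
#' [track_features()] output (features present in both frames) and
#' interpolated onto the current probe positions; probes move by their
#' interpolated displacement (Lagrangian update). Probes with no usable
#' interpolation in a frame hold their position.
#'
#' @param tracks a `feature_tracks` tibble from [track_features()].
#' @param probes a [probe_grid()].
#' @return tibble of class `probe_tracks`: per frame and probe, `frame`,
#'   `probe`, `grid_row`, `grid_col`, `label`, `xi`, `row`, `col`,
#'   `missing` (no interpolation available that transition).
#' @export
track_probe_grid <- function(tracks, probes) {
  frames <- sort(unique(tracks$frame))
  cur <- probes
  out <- vector("list", length(frames))
  out[[1]] <- mutate(cur, frame = frames[1], missing = FALSE)
  by_frame <- split(tracks, tracks$frame)
  for (k in seq(2, length.out = length(frames) - 1)) {
    a <- by_frame[[as.character(frames[k - 1])]]
    b <- by_frame[[as.character(frames[k])]]
    shared <- intersect(a$id, b$id)
    a <- a[match(shared, a$id), ]; b <- b[match(shared, b$id), ]
    feats <- tibble(row = a$row, col = a$col, label = a$label,
                    d_row = b$row - a$row, d_col = b$col - a$col)
    cur2 <- interpolate_probe_displacement(feats, cur)
    miss <- is.na(cur2$d_row) | is.na(cur2$d_col)
    cur$row <- ifelse(miss, cur$row, cur$row + cur2$d_row)
    cur$col <- ifelse(miss, cur$col, cur$col + cur2$d_col)
    out[[k]] <- mutate(cur, frame = frames[k], missing = miss)
  }
  res <- bind_rows(out)
  attr(res, "fascicle_dx_px") <- attr(probes, "fascicle_dx_px")
  class(res) <- c("probe_tracks", class(res))
  res
}

#' Twitch series from tracked probes
#'
#' Fascicle-region length: per probe column, the distance (in mm, per-axis
#' calibrated) between the most superficial and the deepest fascicle-region
#' probes, rescaled by their path-fraction separation to the full
#' superficial-to-deep fascicle length; averaged over columns. Thickness:
#' the mean over columns of the axial distance between the two
#' aponeurosis-row probes (the polylines advected by their own probes).
#' Columns with missing probes are excluded from that frame's mean.
#'
#' @param probe_tracks output of [track_probe_grid()].
#' @param calib_mm_per_px `(axial, lateral)` mm/px.
#' @param frame_rate_hz frame rate for the time base.
#' @param fill_gaps linearly interpolate frames where every column was
#'   excluded (default TRUE; such frames are flagged).
#' @return tibble of class `twitch_series`: `frame`, `time_s`,
#'   `fascicle_length_mm`, `thickness_mm`, `interpolated`.
#' @export
twitch_series <- function(probe_tracks, calib_mm_per_px, frame_rate_hz,
                          fill_gaps = TRUE) {
  fas_rows <- sort(unique(probe_tracks$grid_row[probe_tracks$label ==
                                                  "fascicle"]))
  r_top <- min(fas_rows); r_bot <- max(fas_rows)
  xi_span <- unique(probe_tracks$xi[probe_tracks$grid_row == r_bot]) -
    unique(probe_tracks$xi[probe_tracks$grid_row == r_top])

  one_frame <- function(d) {
    by_col <- split(d, d$grid_col)
    len <- vapply(by_col, function(g) {
      a <- which(g$grid_row == r_top); b <- which(g$grid_row == r_bot)
      if (any(g$missing[c(a, b)])) return(NA_real_)
      sqrt(((g$row[a] - g$row[b]) * calib_mm_per_px[1])^2 +
             ((g$col[a] - g$col[b]) * calib_mm_per_px[2])^2) / xi_span
    }, numeric(1))
    # thickness at matched lateral coordinates: the deep polyline (as
    # sampled by its probes) is evaluated at each superficial probe's
    # lateral position, so aponeurosis tilt does not bias the distance
    sup <- d[d$label == "superficial_apo" & !d$missing, ]
    deep <- d[d$label == "deep_apo" & !d$missing, ]
    thick <- NA_real_
    if (nrow(sup) >= 1 && nrow(deep) >= 2) {
      deep_at <- stats::approx(deep$col, deep$row, xout = sup$col,
                               rule = 2)$y
      thick <- mean((deep_at - sup$row) * calib_mm_per_px[1])
    }
    tibble(fascicle_length_mm = mean(len, na.rm = TRUE),
           thickness_mm = thick)
  }
  per_frame <- probe_tracks %>%
    group_by(.data$frame) %>%
    dplyr::group_modify(~one_frame(.x)) %>%
    dplyr::ungroup()
  out <- per_frame %>%
    mutate(time_s = (.data$frame - 1) / frame_rate_hz,
           interpolated = !is.finite(.data$fascicle_length_mm) |
             !is.finite(.data$thickness_mm)) %>%
    select("frame", "time_s", "fascicle_length_mm", "thickness_mm",
           "interpolated")
  if (fill_gaps && any(out$interpolated) && !all(out$interpolated)) {
    for (cn in c("fascicle_length_mm", "thickness_mm")) {
      v <- out[[cn]]
      ok <- is.finite(v)
      out[[cn]] <- stats::approx(out$frame[ok], v[ok], xout = out$frame,
                                 rule = 2)$y
    }
  }
  class(out) <- c("twitch_series", class(out))
  out
}

#' Track a simulated twitch scene end to end
#'
#' Convenience wrapper: detect and track features, initialize the probe
#' grid along the scene's fascicle direction, advect it, and extract the
#' twitch series.
#'
#' @param sim result of [simulate_twitch_sequence()].
#' @param ... passed to [track_features()].
#' @return list with `tracks`, `probes`, `series` (a `twitch_series`).
#' @export
track_twitch_scene <- function(sim, min_per_label = 20, ...) {
  tracks <- track_features(sim$sequence, sim$segmentation,
                           min_per_label = min_per_label, ...)
  dx_px <- sim$truth$info$h0_mm / sim$sequence$calib_mm_per_px[2]
  probes <- probe_grid(sim$segmentation, fascicle_dx_px = dx_px)
  pt <- track_probe_grid(tracks, probes)
  list(tracks = tracks, probes = pt,
       series = twitch_series(pt, sim$sequence$calib_mm_per_px,
                              sim$sequence$frame_rate_hz))
}
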