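# Shared miniature scenes, built once per test run. Sizes are kept small
# (short durations, coarse calibration for the muscle scene) so the whole
# suite stays fast; the full-protocol durations are exercised in the
# acceptance tests only.

scene_cache <- new.env(parent = emptyenv())

cached <- function(key, build) {
  if (is.null(scene_cache[[key]])) scene_cache[[key]] <- build()
  scene_cache[[key]]
}

small_spring <- function(D = 1.0, f = 2, duration = 2, seed = 7) {
  key <- paste("spring", D, f, duration, seed)
  cached(key, function() {
    simulate_spring_sequence(spring_scene_params(
      peak_to_peak_mm = D, frequency_hz = f, duration_s = duration,
      seed = seed))
  })
}

small_twitch <- function(duration = 2, seed = 5) {
  key <- paste("twitch", duration, seed)
  cached(key, function() {
    simulate_twitch_sequence(twitch_scene_params(
      duration_s = duration, calib_mm_per_px = c(0.1, 0.1), seed = seed))
  })
}

small_twitch_tracked <- function(duration = 2, seed = 5) {
  key <- paste("twitch-tracked", duration, seed)
  cached(key, function() track_twitch_scene(small_twitch(duration, seed)))
}

# a single speckle frame for feature/ROI tests
speckle_frame <- function() {
  cached("frame", function() get_frame(small_spring()$sequence, 1))
}

# track all 8 default ROIs of a spring simulation and return the length series
spring_pipeline <- function(sim, search_margin_px = 10) {
  rois <- spring_rois(sim, search_margin_px = search_margin_px)
  tr <- function(r) track_roi(sim$sequence, r)
  spring_length(lapply(rois$top, tr), lapply(rois$bottom, tr),
                sim$sequence$calib_mm_per_px, sim$sequence$frame_rate_hz)
}

# brute-force barycentric interpolation oracle: Delaunay triangles from
# deldir (independent of interp::interpp), point-in-triangle search, and
# hand-computed barycentric weights
barycentric_oracle <- function(fx, fy, fz, px, py) {
  dxy <- deldir::deldir(fx, fy, suppressMsge = TRUE)
  tris <- deldir::triang.list(dxy)
  out <- rep(NA_real_, length(px))
  for (k in seq_along(px)) {
    for (tr in tris) {
      x <- tr$x; y <- tr$y
      den <- (y[2] - y[3]) * (x[1] - x[3]) + (x[3] - x[2]) * (y[1] - y[3])
      if (abs(den) < 1e-12) next
      l1 <- ((y[2] - y[3]) * (px[k] - x[3]) +
               (x[3] - x[2]) * (py[k] - y[3])) / den
      l2 <- ((y[3] - y[1]) * (px[k] - x[3]) +
               (x[1] - x[3]) * (py[k] - y[3])) / den
      l3 <- 1 - l1 - l2
      if (l1 >= -1e-9 && l2 >= -1e-9 && l3 >= -1e-9) {
        idx <- vapply(seq_len(3), function(i) {
          which.min((fx - x[i])^2 + (fy - y[i])^2)
        }, integer(1))
        out[k] <- l1 * fz[idx[1]] + l2 * fz[idx[2]] + l3 * fz[idx[3]]
        break
      }
    }
  }
  out
}
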