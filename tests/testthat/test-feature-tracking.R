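# KLT detection/tracking oracles, probe interpolation vs a brute-force
# barycentric oracle, twitch-series recovery, and series alignment.

test_that("feature detection handles degenerate and point images", {
  expect_equal(nrow(detect_features(matrix(5, 50, 50))), 0)
  img <- matrix(0, 60, 80)
  rr <- outer(1:60, rep(1, 80)); cc <- outer(rep(1, 60), 1:80)
  img <- exp(-((rr - 31)^2 + (cc - 46)^2) / 8)   # isolated bright point
  f <- detect_features(img, min_score = 1e-8)
  expect_equal(nrow(f), 1)
  expect_lt(abs(f$row - 31), 0.51)
  expect_lt(abs(f$col - 46), 0.51)
})

test_that("selected features honour the minimum spacing", {
  f <- detect_features(speckle_frame(), max_n = 200, min_spacing_px = 8)
  expect_gt(nrow(f), 50)
  d <- as.matrix(stats::dist(cbind(f$row, f$col)))
  diag(d) <- Inf
  expect_gte(min(d), 8)
})

test_that("a static sequence keeps all features at zero displacement", {
  fr <- speckle_frame()
  seq <- image_sequence(replicate(4, fr, simplify = FALSE), 80, c(0.05, 0.05))
  tr <- track_features(seq, max_n = 60, replenish = FALSE)
  wide <- split(tr, tr$frame)
  ids <- wide[[1]]$id
  expect_true(all(vapply(wide, function(x) all(ids %in% x$id), logical(1))))
  last <- wide[[length(wide)]]
  expect_equal(last$row, wide[[1]]$row[match(last$id, ids)], tolerance = 1e-6)
  expect_equal(last$col, wide[[1]]$col[match(last$id, ids)], tolerance = 1e-6)
})

test_that("a global 2 px shift is recovered within 0.1 px", {
  fr <- speckle_frame()
  H <- nrow(fr)
  shifted <- rbind(matrix(0, 2, ncol(fr)), fr[1:(H - 2), ])
  seq <- image_sequence(list(fr, shifted), 80, c(0.05, 0.05))
  tr <- track_features(seq, max_n = 80, replenish = FALSE)
  a <- tr[tr$frame == 1, ]; b <- tr[tr$frame == 2, ]
  shared <- intersect(a$id, b$id)
  expect_gt(length(shared), 40)
  # away from the zero-padded border the shift is uniform
  interior <- shared[a$row[match(shared, a$id)] > 15]
  dr <- b$row[match(interior, b$id)] - a$row[match(interior, a$id)]
  dc <- b$col[match(interior, b$id)] - a$col[match(interior, a$id)]
  expect_lt(stats::median(abs(dr - 2)), 0.1)
  expect_lt(stats::median(abs(dc)), 0.1)
})

test_that("fascicle features persist through the default twitch scene", {
  res <- small_twitch_tracked()
  tr <- res$tracks
  fas <- tr[tr$label == "fascicle", ]
  # of the features detected on frame 1, >= 80% persist >= 10 frames
  born_first <- unique(fas$id[fas$frame == 1])
  life <- tapply(fas$frame, fas$id, function(x) max(x) - min(x) + 1)
  expect_gte(mean(life[as.character(born_first)] >= 10, na.rm = TRUE), 0.8)
})

test_that("uniform displacement passes through probe interpolation exactly", {
  withr::local_seed(1)
  feats <- tibble::tibble(row = runif(30, 10, 90), col = runif(30, 10, 90),
                          d_row = 1.5, d_col = -0.5, label = "fascicle")
  probes <- tibble::tibble(row = runif(10, 20, 80), col = runif(10, 20, 80),
                           label = "fascicle")
  out <- interpolate_probe_displacement(feats, probes)
  expect_equal(out$d_row, rep(1.5, 10), tolerance = 1e-9)
  expect_equal(out$d_col, rep(-0.5, 10), tolerance = 1e-9)
})

test_that("affine fields are interpolated exactly inside the hull", {
  withr::local_seed(2)
  fr <- runif(40, 0, 100); fc <- runif(40, 0, 100)
  aff <- function(r, c) 0.3 + 0.02 * r - 0.01 * c
  feats <- tibble::tibble(row = fr, col = fc, d_row = aff(fr, fc),
                          d_col = -aff(fr, fc) / 2, label = "fascicle")
  pr <- runif(15, 30, 70); pc <- runif(15, 30, 70)  # interior probes
  probes <- tibble::tibble(row = pr, col = pc, label = "fascicle")
  out <- interpolate_probe_displacement(feats, probes)
  expect_equal(out$d_row, aff(pr, pc), tolerance = 1e-6)
  expect_equal(out$d_col, -aff(pr, pc) / 2, tolerance = 1e-6)
})

test_that("interpolation agrees with a brute-force barycentric oracle", {
  withr::local_seed(3)
  for (rep in 1:5) {
    fr <- runif(25, 0, 50); fc <- runif(25, 0, 50)
    z <- sin(fr / 7) + cos(fc / 9)      # smooth non-linear field
    feats <- tibble::tibble(row = fr, col = fc, d_row = z, d_col = 0,
                            label = "fascicle")
    pr <- runif(8, 15, 35); pc <- runif(8, 15, 35)
    probes <- tibble::tibble(row = pr, col = pc, label = "fascicle")
    got <- interpolate_probe_displacement(feats, probes)$d_row
    want <- barycentric_oracle(fc, fr, z, pc, pr)
    inside <- !is.na(want)
    expect_gt(sum(inside), 0)
    expect_equal(got[inside], want[inside], tolerance = 1e-6)
  }
})

test_that("probes with too few same-region features are marked missing", {
  feats <- tibble::tibble(row = c(1, 2), col = c(1, 2), d_row = 1, d_col = 1,
                          label = "fascicle")
  probes <- tibble::tibble(row = 5, col = 5, label = "fascicle")
  out <- interpolate_probe_displacement(feats, probes)
  expect_true(is.na(out$d_row))
})

test_that("twitch amplitude and thickness are recovered from the scene", {
  res <- small_twitch_tracked()
  sim <- small_twitch()
  tr <- sim$truth$track; s <- res$series
  expect_equal(nrow(s), nrow(tr))
  # twitch shortening within 10% of the configured 1.0 mm
  est_short <- max(s$fascicle_length_mm) - min(s$fascicle_length_mm)
  expect_lt(abs(est_short - 1.0) / 1.0, 0.1)
  # resting thickness of the undeformed scene within 0.1 mm
  expect_lt(abs(s$thickness_mm[1] - tr$thickness_mm[1]), 0.1)
  # strong agreement with the ground-truth series
  expect_gt(cor(s$fascicle_length_mm, tr$length_mm)^2, 0.95)
  expect_gt(cor(s$thickness_mm, tr$thickness_mm)^2, 0.95)
})

test_that("tracking degrades gracefully when features are removed", {
  sim <- small_twitch()
  full <- small_twitch_tracked()$series
  thin <- track_twitch_scene(sim, max_n = 140)$series   # ~30% fewer features
  amp <- function(s) max(s$fascicle_length_mm) - min(s$fascicle_length_mm)
  expect_lt(abs(amp(thin) - amp(full)) / amp(full), 0.05)
})

test_that("series alignment finds lags and model-II slopes", {
  withr::local_seed(4)
  a <- sin(seq(0, 6 * pi, length.out = 200)) + rnorm(200, sd = 0.05)
  same <- align_and_compare(a, a, max_lag = 20)
  expect_equal(same$lag, 0)
  expect_equal(same$r_squared, 1)
  expect_equal(same$slope, 1)
  for (k in c(3, 11)) {
    delayed <- c(rep(a[1], k), a[seq_len(200 - k)])
    expect_equal(align_and_compare(a, delayed, max_lag = 20)$lag, k)
  }
  scaled <- align_and_compare(a, 0.8 * a + 5, max_lag = 20)
  expect_equal(scaled$slope, 0.8, tolerance = 1e-9)
  expect_equal(scaled$r_squared, 1, tolerance = 1e-9)
  expect_error(align_and_compare(rep(1, 100), a[1:100], max_lag = 10),
               "constant")
})
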