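# Generator properties: frame counts, determinism, ground-truth
# consistency, conservation, intensity range, failure modes.

test_that("spring ground truth follows the imposed sinusoid exactly", {
  p <- spring_scene_params(peak_to_peak_mm = 1.4, frequency_hz = 1,
                           duration_s = 30)
  gt <- spring_ground_truth(p)
  expect_equal(nrow(gt$track), 2400)
  t <- gt$track$time_s
  expect_equal(gt$track$length_mm,
               p$rest_length_mm + 0.7 * sin(2 * pi * t), tolerance = 1e-12)
  expect_equal(max(gt$track$length_mm) - min(gt$track$length_mm), 1.4,
               tolerance = 1e-9)
  # analytic maximum frame-to-frame edge displacement: pi * D * f / rate
  step <- max(abs(diff(gt$track$length_mm)))
  expect_lt(abs(step - pi * 1.4 * 1 / 80), 2e-4)
})

test_that("spring simulator rejects invalid parameters", {
  expect_error(spring_scene_params(frequency_hz = 40, frame_rate_hz = 80),
               "Nyquist")
  expect_error(spring_scene_params(calib_mm_per_px = c(0.05, -1)), "positive")
  expect_error(spring_scene_params(duration_s = 0), "positive")
})

test_that("identical seed gives bit-identical spring output", {
  a <- simulate_spring_sequence(spring_scene_params(duration_s = 0.25,
                                                    seed = 42))
  b <- simulate_spring_sequence(spring_scene_params(duration_s = 0.25,
                                                    seed = 42))
  expect_identical(a$sequence$frames, b$sequence$frames)
  expect_identical(a$truth$track, b$truth$track)
  c <- simulate_spring_sequence(spring_scene_params(duration_s = 0.25,
                                                    seed = 43))
  expect_false(identical(a$sequence$frames, c$sequence$frames))
})

test_that("zero peak-to-peak freezes the speckle", {
  sim <- simulate_spring_sequence(spring_scene_params(
    peak_to_peak_mm = 0, duration_s = 0.2, seed = 3))
  for (i in 2:n_frames(sim$sequence))
    expect_identical(get_frame(sim$sequence, i), get_frame(sim$sequence, 1))
})

test_that("frames are 8-bit and frame count matches duration x rate", {
  sim <- small_spring()
  expect_equal(dim(sim$sequence)[1], round(2 * 80))
  expect_gte(min(sim$sequence$frames), 0)
  expect_lte(max(sim$sequence$frames), 255)
  expect_identical(sim$sequence$frames, round(sim$sequence$frames))
})

test_that("structure-layer edge separation matches ground truth within 0.02 mm", {
  p <- spring_scene_params(peak_to_peak_mm = 1.4, frequency_hz = 2,
                           duration_s = 0.5, seed = 9)
  sim <- simulate_spring_sequence(p, render = "structure")
  gt <- sim$truth
  calib <- p$calib_mm_per_px
  H <- dim(sim$sequence)[2]
  mid <- round(gt$info$centre_mm / calib[1])
  for (i in seq(1, n_frames(sim$sequence), by = 7)) {
    env <- get_frame(sim$sequence, i)
    prof <- rowSums(env)
    centroid <- function(rows) {
      w <- prof[rows]
      sum((rows - 1) * calib[1] * w) / sum(w)
    }
    z_top <- centroid(1:mid)
    z_bot <- centroid((mid + 1):H)
    expect_lt(abs((z_bot - z_top) - gt$track$length_mm[i]), 0.02)
  }
})

test_that("the dense displacement field advects points consistently", {
  p <- spring_scene_params(peak_to_peak_mm = 1.0, frequency_hz = 2,
                           duration_s = 1)
  gt <- spring_ground_truth(p)
  # the two edges, displaced by the field, stay separated by the length
  z <- c(gt$info$edge_top_mm, gt$info$edge_bottom_mm)
  for (i in c(11, 27, 66)) {
    d <- gt$displace(z, c(0, 0), i)
    sep <- diff(z + d[, 1])
    expect_equal(sep, gt$track$length_mm[i], tolerance = 1e-9)
  }
})

test_that("twitch ground truth follows the parametric model", {
  p <- twitch_scene_params(duration_s = 20)
  gt <- twitch_ground_truth(p)
  expect_length(gt$info$onsets_s, 20)          # 1 pps for 20 s
  expect_equal(nrow(gt$track), 1600)
  t <- gt$track$time_s
  w <- Reduce(`+`, lapply(gt$info$onsets_s, function(o)
    twitch_pulse(t - o, p$tau_rise_s, p$tau_decay_s)))
  expect_equal(gt$track$length_mm, p$resting_length_mm - p$shortening_mm * w,
               tolerance = 1e-12)
  expect_equal(gt$track$thickness_mm,
               p$resting_thickness_mm + p$thickening_mm * w,
               tolerance = 1e-12)
  # peak shortening reaches the configured amplitude at the pulse peak
  expect_equal(min(gt$track$length_mm),
               p$resting_length_mm - p$shortening_mm * max(w),
               tolerance = 1e-12)
  expect_gt(max(w), 0.99)   # frame sampling captures the unit peak
})

test_that("zero twitch amplitudes give constant ground truth", {
  p <- twitch_scene_params(shortening_mm = 0, thickening_mm = 0,
                           duration_s = 2)
  gt <- twitch_ground_truth(p)
  expect_equal(diff(range(gt$track$length_mm)), 0)
  expect_equal(diff(range(gt$track$thickness_mm)), 0)
})

test_that("impossible thickening is rejected", {
  expect_error(twitch_scene_params(resting_length_mm = 15,
                                   resting_thickness_mm = 13,
                                   thickening_mm = 3),
               "cross the aponeuroses")
})

test_that("twitch scene returns a valid segmentation and matching thickness", {
  sim <- small_twitch()
  seg <- sim$segmentation
  expect_s3_class(seg, "segmentation")
  mid_col <- mean(range(seg$superficial[, 2]))
  gap_px <- polyline_row_at(seg$deep, mid_col) -
    polyline_row_at(seg$superficial, mid_col)
  expect_equal(gap_px * 0.1, sim$truth$info$thickness0_mm, tolerance = 0.05)
})

test_that("twitch pulse is unit-peak, causal, and uni-modal", {
  t <- seq(-0.1, 1, by = 1e-3)
  w <- twitch_pulse(t, 0.05, 0.15)
  expect_equal(max(w), 1, tolerance = 1e-4)   # grid sampling near the peak
  expect_true(all(w[t <= 0] == 0))
  pk <- which.max(w)
  expect_true(all(diff(w[seq_len(pk)]) >= 0))
  expect_true(all(diff(w[pk:length(w)]) <= 0))
  expect_error(twitch_pulse(1, 0.2, 0.1), "tau_rise")
})

test_that("M-wave grid has 32 column-major channels and spaced triggers", {
  rec <- simulate_mwave_grid(mwave_grid_params(duration_s = 20, seed = 1))
  expect_equal(nrow(rec$samples), 32)
  expect_length(rec$trigger_samples, 20)
  expect_true(all(diff(rec$trigger_samples) == 2048))
  cm <- rec$channel_map
  expect_equal(cm$row[1:8], 1:8)     # column-major: first 8 channels = col 1
  expect_true(all(cm$col[1:8] == 1))
})

test_that("noiseless M-wave epochs are identical and template equals an epoch", {
  p <- mwave_grid_params(duration_s = 5, noise_rms_uv = 0, seed = 1)
  rec <- simulate_mwave_grid(p)
  ep <- extract_epochs(rec)
  tpl <- average_template(ep, n_epochs = 5)
  for (k in 2:dim(ep)[2]) expect_equal(ep[, k, ], ep[, 1, ])
  expect_equal(unclass(tpl)[, ], ep[, 1, ], ignore_attr = TRUE)
})

test_that("bad-channel failure modes are injected as declared", {
  p <- mwave_grid_params(duration_s = 3, seed = 4,
                         bad_channels = list(`5` = "open_contact",
                                             `12` = "short_circuit_pair"))
  rec <- simulate_mwave_grid(p)
  rms_ch <- sqrt(rowMeans(rec$samples^2))
  expect_gt(rms_ch[5], 20 * p$noise_rms_uv)
  nb <- echotrace:::grid_neighbour(rec$channel_map, 12)
  expect_identical(rec$samples[12, ], rec$samples[nb, ])
  expect_error(mwave_grid_params(bad_channels = list(`40` = "open_contact")),
               "valid channel")
  expect_error(mwave_grid_params(duration_s = 0.5), "too short")
})

test_that("interface sweep reproduces closed-form impedances", {
  # pure resistor: flat magnitude, zero phase
  r_only <- circuit_impedance(list(R_series = 1e6, R_parallel = 0,
                                   C_parallel = 0), c(10, 100, 1000))
  expect_equal(r_only$magnitude_ohm, rep(1e6, 3))
  expect_equal(r_only$phase_deg, rep(0, 3))
  # ideal 10 nF capacitor at 1/(2 pi R C): |Z| ~ 100 kOhm, phase -90 deg
  sw <- simulate_interface_signals(
    list(R_series = 0, R_parallel = 1e12, C_parallel = 1e-8),
    freqs_hz = 159.155, fs_hz = 10000, duration_s = 1, seed = 2)
  est <- estimate_impedance_sweep(sw, 10000)
  expect_equal(est$magnitude_ohm, 1e5, tolerance = 0.01)
  expect_equal(est$phase_deg, -90, tolerance = 0.5)
  # default sweep covers 10-1000 Hz
  dflt <- simulate_interface_signals(list(R_series = 1e3, R_parallel = 1e5,
                                          C_parallel = 1e-8), seed = 1)
  fr <- vapply(dflt, `[[`, numeric(1), "frequency_hz")
  expect_equal(range(fr), c(10, 1000))
  expect_error(simulate_interface_signals(list(R_series = 1, R_parallel = 1,
                                               C_parallel = 0),
                                          freqs_hz = 0), "positive")
})
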