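# ZNCC region tracking: sub-pixel refinement closed forms, constructed-shift
# oracles, offset invariance, median-based length, NMSE identities, and the
# 27-condition protocol surface.

test_that("parabolic sub-pixel refinement matches its closed form", {
  sym <- matrix(c(0.5, 0.8, 0.5, 0.8, 1.0, 0.8, 0.5, 0.8, 0.5), 3, 3)
  expect_equal(as.numeric(subpixel_refine(sym)), c(0, 0))
  # (0.7, 1.0, 0.9) along a row: vertex at +0.25 toward the 0.9 side
  m <- matrix(c(0, 0.7, 0, 0.5, 1.0, 0.5, 0, 0.9, 0), 3, 3)
  expect_equal(as.numeric(subpixel_refine(m))[2], 0.25)
  expect_error(subpixel_refine(matrix(c(0, 0, 0, 0, 0.5, 2, 0, 0, 0), 3, 3)),
               "maximum")
  flat <- subpixel_refine(matrix(1, 3, 3))
  expect_equal(as.numeric(flat), c(0, 0))
  expect_true(attr(flat, "flat"))
})

test_that("a static sequence tracks at zero displacement with correlation 1", {
  fr <- speckle_frame()
  seq <- image_sequence(replicate(5, fr, simplify = FALSE), 80, c(0.05, 0.05))
  tr <- track_roi(seq, roi_spec(c(40, 40)))
  expect_equal(tr$row, rep(tr$row[1], 5))
  expect_equal(tr$col, rep(tr$col[1], 5))
  expect_true(all(tr$peak_corr[-1] > 1 - 1e-9))
  expect_true(all(tr$valid))
})

test_that("constructed integer shifts are recovered exactly", {
  fr <- speckle_frame()
  H <- nrow(fr)
  for (k in 1:5) {
    shifted <- rbind(matrix(0, k, ncol(fr)), fr[1:(H - k), ])
    seq <- image_sequence(list(fr, shifted), 80, c(0.05, 0.05))
    tr <- track_roi(seq, roi_spec(c(60, 40)))
    expect_equal(tr$row[2] - tr$row[1], k)
    expect_equal(tr$col[2] - tr$col[1], 0)
  }
})

test_that("tracks are invariant to a constant intensity offset", {
  sim <- small_spring(D = 1.0, f = 2, duration = 0.5)
  roi <- spring_rois(sim)$top[[2]]
  t0 <- track_roi(sim$sequence, roi)
  shifted <- image_sequence(sim$sequence$frames / 2 + 40, 80, c(0.05, 0.05))
  roi2 <- roi  # same geometry; intensities rescaled and offset
  t1 <- track_roi(shifted, roi2)
  expect_equal(t1$row, t0$row, tolerance = 1e-9)
  expect_equal(t1$col, t0$col, tolerance = 1e-9)
})

test_that("zero-variance ROI is rejected", {
  fr <- speckle_frame()
  fr[1:20, 1:30] <- 0
  seq <- image_sequence(list(fr, fr), 80, c(0.05, 0.05))
  expect_error(track_roi(seq, roi_spec(c(2, 2))), "variance")
})

test_that("spring length is the calibrated distance between group medians", {
  mk <- function(rows, cols) {
    tibble::tibble(frame = 1:4, time_s = (0:3) / 80, row = rows, col = cols,
                   peak_corr = 1, valid = TRUE)
  }
  a <- lapply(c(100, 100, 102, 102), function(r) mk(rep(r, 4), rep(50, 4)))
  b <- lapply(c(300, 300, 302, 302), function(r) mk(rep(r, 4), rep(50, 4)))
  ls <- spring_length(a, b, c(0.05, 0.05), 80)
  expect_equal(ls$length_mm, rep(10, 4))   # medians 101 and 301 -> 200 px
  # identical groups -> zero length
  z <- spring_length(a, a, c(0.05, 0.05), 80)
  expect_equal(z$length_mm, rep(0, 4))
  # unequal track lengths -> error
  short <- mk(rep(1, 4), rep(1, 4))[1:3, ]
  expect_error(spring_length(a, c(b[-4], list(short)), c(0.05, 0.05), 80),
               "equal length")
})

test_that("NMSE satisfies its defining identities", {
  g <- c(0.5, -1, 2, 0.25)
  expect_equal(nmse(g, g), 0)
  expect_equal(nmse(2 * g, g, demean = FALSE), 100)
  expect_equal(nmse(c(1, 1, 2, 0), c(1, 2, 2, 0), demean = FALSE),
               100 / 9)
  expect_error(nmse(g, rep(0, 4), demean = FALSE), "zero power")
  expect_error(nmse(1:3, 1:4), "equal length")
  # asymmetry: swapping prediction and reference changes the value
  f <- g + c(0.2, -0.1, 0.3, 0)
  expect_false(isTRUE(all.equal(nmse(f, g, demean = FALSE),
                                nmse(g, f, demean = FALSE))))
})

test_that("the protocol preset enumerates 27 conditions", {
  cond <- spring_conditions()
  expect_equal(nrow(cond), 27)
  expect_setequal(unique(cond$amplitude_mm), c(0.4, 1.0, 1.4))
  expect_setequal(unique(cond$frequency_hz),
                  c(0.5, 0.7, 1, 2, 3, 5, 7, 8, 10))
  expect_equal(nrow(spring_conditions(c("without", "with"))), 54)
})

test_that("tracked amplitude is accurate and NMSE decreases with amplitude", {
  res <- vapply(c(0.4, 1.0, 1.4), function(D) {
    sim <- small_spring(D = D, f = 2, duration = 2)
    ls <- spring_pipeline(sim)
    amp <- (max(ls$length_mm) - min(ls$length_mm)) / 2
    c(amp = amp, nmse = nmse(ls$length_mm, sim$truth$track$length_mm))
  }, numeric(2))
  # amplitude within 5% for D >= 1.0 mm
  expect_lt(abs(res["amp", 2] - 0.5), 0.025)
  expect_lt(abs(res["amp", 3] - 0.7), 0.035)
  # NMSE non-increasing in amplitude at fixed frequency
  expect_gte(res["nmse", 1], res["nmse", 2])
  expect_gte(res["nmse", 2], res["nmse", 3])
})

test_that("run_spring_experiment produces one NMSE per condition", {
  cond <- spring_conditions()[c(1, 14, 27), ]
  res <- run_spring_experiment(cond, duration_s = 0.5, seed = 11)
  expect_equal(nrow(res), 3)
  expect_true(all(is.finite(res$nmse_pct)))
  expect_true(all(res$nmse_pct >= 0))
})
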