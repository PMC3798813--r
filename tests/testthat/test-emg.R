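# EMG pipeline: zero-phase filtering, epoching, template averaging and its
# 1/sqrt(n) law, the NMSE map and its equivariance, channel screening, and
# the central-vs-lateral null.

make_rec <- function(X, fs = 2048, trig = integer()) {
  g <- grid_geometry(rows = nrow(X), cols = 1)
  emg_recording(X, fs_hz = fs, grid = g, trigger_samples = trig)
}

test_that("band-pass removes DC, passes the mid-band, and is zero-phase", {
  fs <- 2048
  t <- (0:8191) / fs
  dc <- matrix(rep(50, length(t)), 1)
  out <- bandpass(make_rec(dc, fs))$samples[1, ]
  expect_lt(abs(mean(out)), 50 * 1e-3)
  sine <- matrix(sin(2 * pi * 100 * t), 1)
  out <- bandpass(make_rec(sine, fs))$samples[1, ]
  mid <- 2000:6000
  expect_equal(max(abs(out[mid])), 1, tolerance = 0.02)
  # symmetric pulse keeps its peak sample (no group delay)
  pulse <- matrix(exp(-((seq_along(t) - 4096) / 30)^2), 1)
  out <- bandpass(make_rec(pulse, fs))$samples[1, ]
  expect_equal(which.max(out), 4096)
  expect_error(bandpass(make_rec(sine, fs), low_hz = 500, high_hz = 100),
               "band edges")
})

test_that("epoch extraction yields round(epoch_ms * fs / 1000) samples", {
  X <- matrix(rnorm(2 * 2048 * 3), 2)
  ep <- extract_epochs(make_rec(X, 2048, trig = c(1, 2049, 4097)), 40)
  expect_equal(dim(ep)[3], 82)
  ep <- extract_epochs(make_rec(X[, 1:3000], 1000, trig = c(1, 1001)), 40)
  expect_equal(dim(ep)[3], 40)
  # trigger too close to the end is skipped with a warning
  expect_warning(
    ep <- extract_epochs(make_rec(X, 2048, trig = c(1, 2049, ncol(X) - 30)),
                         40),
    "skipped")
  expect_equal(dim(ep)[2], 2)
  expect_error(
    suppressWarnings(extract_epochs(make_rec(X, 2048, trig = ncol(X) - 10L),
                                    40)),
    "no trigger")
  expect_error(extract_epochs(make_rec(X, 2048), 40), "no triggers")
})

test_that("template averaging is the sample-wise mean of consecutive epochs", {
  w <- mwave_template(2048, 15, 1)
  ep <- array(0, dim = c(1, 25, 82))
  for (k in 1:25) ep[1, k, ] <- c(w, rep(0, 82 - length(w))) + k
  tpl <- average_template(ep, n_epochs = 20)
  expect_equal(as.numeric(tpl[1, ]),
               c(w, rep(0, 82 - length(w))) + mean(1:20))
  one <- average_template(ep, n_epochs = 1)
  expect_equal(as.numeric(one[1, ]), ep[1, 1, ])
  expect_error(average_template(ep[, 1:5, , drop = FALSE], 20), "5")
})

test_that("template noise falls as 1/sqrt(n)", {
  withr::local_seed(8)
  ns <- c(1, 2, 5, 10, 20)
  res <- sapply(ns, function(n) {
    mean(replicate(40, {
      ep <- array(rnorm(1 * 20 * 82), dim = c(1, 20, 82))
      rms(as.numeric(average_template(ep, n_epochs = n)))
    }))
  })
  slope <- stats::coef(stats::lm(log(res) ~ log(ns)))[2]
  expect_lt(abs(slope - (-0.5)) / 0.5, 0.1)
  # and the n = 20 residual is sigma / sqrt(20) within 20%
  expect_lt(abs(res[5] - 1 / sqrt(20)) / (1 / sqrt(20)), 0.2)
})

test_that("the NMSE map reproduces closed-form cases and group structure", {
  set.seed(10)
  g <- matrix(rnorm(32 * 82), 32)
  class(g) <- "mwave_template_set"
  same <- template_nmse_map(g, g)
  expect_equal(nrow(same), 32)
  expect_equal(same$nmse_pct, rep(0, 32))
  expect_equal(unname(attr(same, "group_means")), c(0, 0, 0))
  scaled <- g * 1.1
  class(scaled) <- "mwave_template_set"
  up <- template_nmse_map(scaled, g)
  expect_equal(up$nmse_pct, rep(1, 32), tolerance = 1e-9)
  expect_setequal(up$group[up$col %in% c(2, 3)], "central")
  expect_setequal(up$group[up$col %in% c(1, 4)], "lateral")
  # an all-zero reference channel is excluded from group means
  g0 <- g; g0[1, ] <- 0
  class(g0) <- "mwave_template_set"
  ex <- template_nmse_map(g, g0)
  expect_true(ex$excluded[1])
  expect_false(any(ex$excluded[-1]))
  expect_true(is.finite(glance(ex)$grid_mean_pct))
})

test_that("simulated same-condition trials match the noise-power oracle", {
  tpl_rms <- rms(mwave_template())
  sig <- 0.1 * tpl_rms
  mk <- function(seed) {
    p <- mwave_grid_params(duration_s = 20, noise_rms_uv = sig, seed = seed)
    average_template(extract_epochs(simulate_mwave_grid(p)))
  }
  t1 <- mk(21); t2 <- mk(22)
  map <- template_nmse_map(t2, t1, grid_geometry())
  gains <- simulate_mwave_grid(mwave_grid_params(duration_s = 2,
                                                 seed = 1))$metadata$gains
  # per channel: E[NMSE] = 100 * 82 * 2 sigma^2 / 20 / sum(g^2)
  oracle <- 100 * 82 * 2 * sig^2 / 20 /
    (gains^2 * sum(mwave_template()^2))
  expect_lt(mean(map$nmse_pct) / mean(oracle), 2)
  expect_gt(mean(map$nmse_pct) / mean(oracle), 0.5)
})

test_that("the NMSE map is permutation-equivariant in the channels", {
  set.seed(11)
  f <- matrix(rnorm(32 * 82), 32); g <- matrix(rnorm(32 * 82), 32) + 2
  class(f) <- class(g) <- "mwave_template_set"
  base <- template_nmse_map(f, g)
  perm <- sample(32)
  fp <- f[perm, ]; gp <- g[perm, ]
  class(fp) <- class(gp) <- "mwave_template_set"
  permuted <- template_nmse_map(fp, gp)
  expect_equal(permuted$nmse_pct, base$nmse_pct[perm], tolerance = 1e-12)
})

test_that("channel screening flags injected faults and only those", {
  clean <- simulate_mwave_grid(mwave_grid_params(duration_s = 3, seed = 31))
  q <- screen_channels(clean)
  expect_true(all(q$flag == "ok"))

  bad <- simulate_mwave_grid(mwave_grid_params(
    duration_s = 3, seed = 32,
    bad_channels = list(`7` = "open_contact", `20` = "short_circuit_pair")))
  q <- screen_channels(bad)
  expect_equal(q$flag[7], "open_contact")
  nb <- echotrace:::grid_neighbour(bad$channel_map, 20)
  expect_equal(q$flag[20], "short_circuit")
  expect_equal(q$flag[nb], "short_circuit")
  expect_true(all(q$flag[-c(7, 20, nb)] == "ok"))

  pl <- simulate_mwave_grid(mwave_grid_params(duration_s = 3, seed = 33,
                                              noise_rms_uv = 2,
                                              powerline_uv = 40))
  q <- screen_channels(pl)
  expect_true(any(q$flag == "powerline"))
})

test_that("central and lateral columns are exchangeable under the null", {
  # flat spatial gain: both groups see identical statistics; the paired t
  # p-values over seeded replicates must be uniform
  tpl_rms <- rms(mwave_template(512))
  run <- function(seed) {
    mk <- function(s) {
      p <- mwave_grid_params(fs_hz = 512, duration_s = 6,
                             noise_rms_uv = 0.1 * tpl_rms,
                             amp_sigma = 1e6, seed = s)
      average_template(extract_epochs(simulate_mwave_grid(p)), n_epochs = 6)
    }
    map <- template_nmse_map(mk(2 * seed), mk(2 * seed + 1))
    central <- map$nmse_pct[map$group == "central"]
    lateral <- map$nmse_pct[map$group == "lateral"]
    paired_t(central, lateral)$p_value
  }
  ps <- vapply(1:200, run, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})
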