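# End-to-end reproductions of the validation protocols ("benches"):
# simulate, analyze, run the statistics, and return a machine-readable
# report. Every bench is reproducible bit-identically from (config, seed).

#' Run a validation bench
#'
#' * `spring`: the 27-condition oscillation protocol — tracked-vs-imposed
#'   length NMSE per amplitude x frequency (x detection condition), plus a
#'   main-effects factorial ANOVA when both conditions are run.
#' * `twitch`: two independently seeded speckle renderings of the same
#'   twitch scene, tracked independently; the length and thickness series
#'   are aligned and compared (lag, Pearson r^2, model-II slope).
#' * `mwave`: two simulated stimulation trials with shared templates and
#'   independent noise; per-channel template NMSE map and the
#'   central-vs-lateral column comparison.
#' * `interface`: noise-pipeline and impedance-sweep characterization of a
#'   lumped electrode-skin circuit, with closed-form reference values.
#'
#' @param name one of `"spring"`, `"twitch"`, `"mwave"`, `"interface"`.
#' @param seed integer master seed for the bench.
#' @param config named list overriding bench defaults (see the individual
#'   `bench_*` functions' arguments).
#' @return a `bench_report`: list with `bench`, `seed`, `config`, `tables`
#'   (named list of tibbles), `runtime_s`.
#' @export
run_bench <- function(name, seed = 1L, config = list()) {
  benches <- list(spring = bench_spring, twitch = bench_twitch,
                  mwave = bench_mwave, interface = bench_interface)
  if (!name %in% names(benches))
    abort(paste0("unknown bench `", name, "`; valid names: ",
                 paste(names(benches), collapse = ", ")))
  t0 <- proc.time()[3]
  tables <- do.call(benches[[name]], c(list(seed = seed), config))
  structure(list(bench = name, seed = seed, config = config,
                 tables = tables, runtime_s = proc.time()[3] - t0),
            class = "bench_report")
}

#' @export
print.bench_report <- function(x, ...) {
  cat(sprintf("<bench_report> %s (seed %d, %.1f s)\n", x$bench, x$seed,
              x$runtime_s))
  for (nm in names(x$tables)) {
    cat("--", nm, "--\n")
    print(x$tables[[nm]])
  }
  invisible(x)
}

bench_spring <- function(seed = 1L, conditions = c("without", "with"),
                         duration_s = 30, frame_rate_hz = 80, ...) {
  cond <- spring_conditions(conditions)
  res <- run_spring_experiment(cond, duration_s = duration_s,
                               frame_rate_hz = frame_rate_hz, seed = seed,
                               ...)
  tables <- list(nmse = res)
  if (length(conditions) > 1) {
    tab <- dplyr::rename(res, response = "nmse_pct")
    tables$anova <- factorial_anova(
      tab, c("amplitude_mm", "frequency_hz", "condition"))
  }
  tables
}

bench_twitch <- function(seed = 1L, duration_s = 4, max_lag = 20, ...) {
  run_one <- function(s) {
    p <- twitch_scene_params(duration_s = duration_s, seed = s, ...)
    track_twitch_scene(simulate_twitch_sequence(p))$series
  }
  s1 <- run_one(seed); s2 <- run_one(seed + 1L)
  cmp <- bind_rows(
    mutate(align_and_compare(s1$fascicle_length_mm, s2$fascicle_length_mm,
                             max_lag), measure = "fascicle_length"),
    mutate(align_and_compare(s1$thickness_mm, s2$thickness_mm, max_lag),
           measure = "thickness"))
  list(comparison = select(cmp, "measure", dplyr::everything()),
       series_a = s1, series_b = s2)
}

bench_mwave <- function(seed = 1L, second_seed = seed + 1L,
                        noise_rel_rms = 0.1, duration_s = 20, ...) {
  tpl_rms <- rms(mwave_template())
  run_one <- function(s) {
    p <- mwave_grid_params(noise_rms_uv = noise_rel_rms * tpl_rms,
                           duration_s = duration_s, seed = s, ...)
    rec <- bandpass(simulate_mwave_grid(p))
    average_template(extract_epochs(rec))
  }
  t1 <- run_one(seed); t2 <- run_one(second_seed)
  map <- template_nmse_map(t2, t1)
  central <- map$nmse_pct[map$group == "central" & !map$excluded]
  lateral <- map$nmse_pct[map$group == "lateral" & !map$excluded]
  list(nmse_map = map, group_means = glance(map),
       central_vs_lateral = tibble(
         t_p = stats::t.test(central, lateral)$p.value,
         wilcoxon_p = suppressWarnings(
           stats::wilcox.test(central, lateral)$p.value)))
}

bench_interface <- function(seed = 1L,
                            circuit = list(R_series = 1e3, R_parallel = 1e6,
                                           C_parallel = 4.7e-9),
                            noise_rms_v = 1e-8, fs_hz = 10000,
                            amplifier_rms_uv = 0.8,
                            interface_noise_uv = 0.9, ...) {
  sweep <- simulate_interface_signals(circuit, noise_rms_v = noise_rms_v,
                                      fs_hz = fs_hz, seed = seed)
  est <- estimate_impedance_sweep(sweep, fs_hz)
  truth <- circuit_impedance(circuit, est$frequency_hz)
  imp <- mutate(est,
                true_magnitude_ohm = truth$magnitude_ohm,
                true_phase_deg = truth$phase_deg)
  # noise bench: white interface + amplifier noise, then the pipeline
  total <- sqrt(interface_noise_uv^2 + amplifier_rms_uv^2)
  trace <- withr::with_seed(seed, rnorm(10 * fs_hz, sd = total *
                                          sqrt(fs_hz / 2) / sqrt(990)))
  # scale so the 10-1000 Hz band holds `total` uV RMS: white noise of
  # density total/sqrt(990) uV/sqrt(Hz) over the fs/2 bandwidth
  noise <- suppressWarnings(noise_pipeline(trace, fs_hz, amplifier_rms_uv))
  list(impedance = imp, noise = noise)
}

#' Generate the package's standard small fixtures
#'
#' Writes, bit-identically for a given seed: a 50-frame spring clip (2 Hz,
#' 1.0 mm) with its ground truth, a 50-frame twitch clip, a 5-stimulus EMG
#' recording, and one impedance sweep record — the miniature counterparts
#' of the full protocols, for tests and examples.
#'
#' @param out_dir output directory (created if missing).
#' @param seed integer seed.
#' @return named list of the file paths written.
#' @export
make_fixtures <- function(out_dir, seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  sp <- simulate_spring_sequence(spring_scene_params(
    peak_to_peak_mm = 1.0, frequency_hz = 2, duration_s = 50 / 80,
    seed = seed))
  paths$spring_tif <- file.path(out_dir, "spring_clip.tif")
  write_image_sequence(sp$sequence, paths$spring_tif)
  paths$spring_truth <- file.path(out_dir, "spring_truth.csv")
  write_ground_truth(sp$truth, paths$spring_truth)

  tw <- simulate_twitch_sequence(twitch_scene_params(
    duration_s = 50 / 80, stim_rate_pps = 2, stim_onset_s = 0.1,
    seed = seed))
  paths$twitch_tif <- file.path(out_dir, "twitch_clip.tif")
  write_image_sequence(tw$sequence, paths$twitch_tif)
  paths$twitch_truth <- file.path(out_dir, "twitch_truth.csv")
  write_ground_truth(tw$truth, paths$twitch_truth)

  rec <- simulate_mwave_grid(mwave_grid_params(duration_s = 5, seed = seed))
  paths$emg <- file.path(out_dir, "mwave_5stim.csv")
  write_emg(rec, paths$emg)

  sw <- simulate_interface_signals(
    list(R_series = 1e3, R_parallel = 1e6, C_parallel = 4.7e-9),
    freqs_hz = 100, duration_s = 0.5, noise_rms_v = 0, seed = seed)[[1]]
  paths$sweep <- file.path(out_dir, "impedance_100hz.csv")
  utils::write.csv(data.frame(voltage_v = sw$voltage_v,
                              current_a = sw$current_a),
                   paths$sweep, row.names = FALSE)
  paths
}
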