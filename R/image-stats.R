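# Region-of-interest intensity statistics and distribution comparison
# between imaging conditions (e.g. with/without electrode material in the
# acoustic path).

#' ROI intensity report
#'
#' Per-frame mean pixel intensity inside a standardized ROI, the trial mean,
#' and the average intensity histogram (the mean number of pixels at each of
#' the 256 intensity levels, averaged over frames).
#'
#' @param seq an [image_sequence()].
#' @param roi an [roi_spec()]; must lie inside the frames.
#' @return an `intensity_report`: list with `roi`, `per_frame` (tibble
#'   `frame`, `mean_intensity`), `trial_mean`, `histogram` (tibble
#'   `intensity` 0-255, `mean_count`), `n_px` (ROI pixel count).
#' @export
roi_intensity <- function(seq, roi) {
  d <- dim(seq)
  tl <- roi$top_left
  if (tl[1] < 1 || tl[2] < 1 || tl[1] + roi$height_px - 1 > d[2] ||
      tl[2] + roi$width_px - 1 > d[3])
    abort("ROI must lie fully inside the frames")
  nf <- d[1]
  counts <- matrix(0, nf, 256)
  means <- numeric(nf)
  for (i in seq_len(nf)) {
    px <- seq$frames[i, tl[1]:(tl[1] + roi$height_px - 1),
                     tl[2]:(tl[2] + roi$width_px - 1)]
    means[i] <- mean(px)
    counts[i, ] <- tabulate(as.integer(round(px)) + 1L, nbins = 256)
  }
  structure(
    list(roi = roi,
         per_frame = tibble(frame = seq_len(nf), mean_intensity = means),
         trial_mean = mean(means),
         histogram = tibble(intensity = 0:255, mean_count = colMeans(counts)),
         n_px = roi$height_px * roi$width_px),
    class = "intensity_report")
}

#' @export
print.intensity_report <- function(x, ...) {
  cat(sprintf("<intensity_report> %d frames, %d px ROI, trial mean %.2f\n",
              nrow(x$per_frame), x$n_px, x$trial_mean))
  invisible(x)
}

# Two-sample Kolmogorov-Smirnov on binned (histogram) data: D is the
# maximum gap between the normalized cumulative histograms; the p-value
# uses the asymptotic Kolmogorov distribution with the effective sample
# size n1 n2 / (n1 + n2). Valid when bin counts represent independent
# draws.
ks_binned <- function(count_a, count_b, n_a = sum(count_a),
                      n_b = sum(count_b)) {
  if (sum(count_a) <= 0 || sum(count_b) <= 0) abort("empty histogram")
  cdf_a <- cumsum(count_a) / sum(count_a)
  cdf_b <- cumsum(count_b) / sum(count_b)
  D <- max(abs(cdf_a - cdf_b))
  n_eff <- n_a * n_b / (n_a + n_b)
  lambda <- (sqrt(n_eff) + 0.12 + 0.11 / sqrt(n_eff)) * D
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  list(statistic = D, p_value = min(max(p, 0), 1))
}

#' Compare two ROI intensity reports
#'
#' The mean histograms are compared as empirical distributions with a
#' discrete two-sample Kolmogorov-Smirnov test (maximum gap between the
#' normalized cumulative histograms; asymptotic p with the effective pixel
#' count — which assumes independent pixels, an approximation for speckle).
#' Per-frame means are compared with a paired t-test and Wilcoxon
#' signed-rank when frame counts match, unpaired otherwise.
#'
#' @param report_a,report_b two [roi_intensity()] reports with the same bin
#'   count.
#' @return one-row tibble: `mean_diff`, `t_p`, `signrank_p`, `paired`,
#'   `ks_stat`, `ks_p`.
#' @export
compare_intensity <- function(report_a, report_b) {
  ha <- report_a$histogram$mean_count
  hb <- report_b$histogram$mean_count
  if (length(ha) != length(hb)) abort("histograms must share the bin count")
  ks <- ks_binned(ha, hb, report_a$n_px, report_b$n_px)
  ma <- report_a$per_frame$mean_intensity
  mb <- report_b$per_frame$mean_intensity
  paired <- length(ma) == length(mb)
  tt <- tryCatch(stats::t.test(ma, mb, paired = paired)$p.value,
                 error = function(e) NA_real_)
  wt <- tryCatch(
    suppressWarnings(stats::wilcox.test(ma, mb, paired = paired)$p.value),
    error = function(e) NA_real_)
  tibble(mean_diff = mean(ma) - mean(mb), t_p = tt, signrank_p = wt,
         paired = paired, ks_stat = ks$statistic, ks_p = ks$p_value)
}
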