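# Sparse feature tracking: Shi-Tomasi corner detection (minimum eigenvalue
# of the gradient structure tensor) plus pyramidal Kanade-Lucas-Tomasi
# iterative alignment, with drop-and-replenish across the sequence.

# central-difference gradients (borders replicated)
image_gradients <- function(img) {
  H <- nrow(img); W <- ncol(img)
  gz <- (img[c(2:H, H), ] - img[c(1, 1:(H - 1)), ]) / 2
  gx <- (img[, c(2:W, W)] - img[, c(1, 1:(W - 1))]) / 2
  list(gz = gz, gx = gx)
}

# minimum-eigenvalue corner response with a box integration window
corner_response <- function(img, window_px = 5) {
  g <- image_gradients(img)
  box <- rep(1, window_px) / window_px
  A <- cpp_sepconv(g$gz * g$gz, box, box)
  B <- cpp_sepconv(g$gz * g$gx, box, box)
  C <- cpp_sepconv(g$gx * g$gx, box, box)
  (A + C - sqrt((A - C)^2 + 4 * B^2)) / 2
}

# bilinear sampling of img at (row, col) matrices/vectors (1-based, sub-px)
bilinear_sample <- function(img, r, c) {
  H <- nrow(img); W <- ncol(img)
  r <- pmin(pmax(r, 1), H - 1e-9); c <- pmin(pmax(c, 1), W - 1e-9)
  r0 <- floor(r); c0 <- floor(c)
  fr <- r - r0; fc <- c - c0
  r1 <- pmin(r0 + 1, H); c1 <- pmin(c0 + 1, W)
  i00 <- (c0 - 1) * H + r0; i10 <- (c0 - 1) * H + r1
  i01 <- (c1 - 1) * H + r0; i11 <- (c1 - 1) * H + r1
  img[i00] * (1 - fr) * (1 - fc) + img[i10] * fr * (1 - fc) +
    img[i01] * (1 - fr) * fc + img[i11] * fr * fc
}

#' Detect trackable features in a frame
#'
#' Features are local maxima of the Shi-Tomasi corner strength (minimum
#' eigenvalue of the locally integrated gradient structure tensor),
#' selected greedily best-first under a minimum-spacing constraint. When a
#' [segmentation()] is supplied, each feature is labelled by the segment
#' that contains it (`superficial_apo` / `deep_apo` within `apo_band_px` of
#' the respective polyline, `fascicle` strictly between them); unlabelled
#' features are dropped.
#'
#' @param frame numeric image matrix (non-constant).
#' @param segmentation optional [segmentation()] in pixel coordinates.
#' @param max_n maximum number of features (default 200).
#' @param min_score absolute corner-strength threshold; default
#'   `0.01 * max(response)`.
#' @param min_spacing_px minimum pairwise distance between selected
#'   features (default 8).
#' @param apo_band_px half-width of the aponeurosis bands (default 4 px).
#' @param min_per_label if positive, top up each label to at least this many
#'   features (spacing still enforced, `max_n` may be exceeded); keeps the
#'   sparse aponeurosis bands represented when the speckle-rich fascicle
#'   region dominates the score ranking.
#' @return tibble: `row`, `col` (px), `score`, `label`.
#' @export
detect_features <- function(frame, segmentation = NULL, max_n = 200,
                            min_score = NULL, min_spacing_px = 8,
                            apo_band_px = 4, min_per_label = 0) {
  if (var(as.vector(frame)) == 0)
    return(tibble(row = numeric(), col = numeric(), score = numeric(),
                  label = character()))
  resp <- corner_response(frame)
  if (is.null(min_score)) min_score <- 0.01 * max(resp)
  H <- nrow(resp); W <- ncol(resp)
  # strict local maxima over the 8-neighbourhood (borders excluded)
  inner <- resp[2:(H - 1), 2:(W - 1)]
  is_max <- inner >= min_score
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    is_max <- is_max & (inner >= resp[2:(H - 1) + dr, 2:(W - 1) + dc])
  }
  idx <- which(is_max, arr.ind = TRUE)
  if (!nrow(idx))
    return(tibble(row = numeric(), col = numeric(), score = numeric(),
                  label = character()))
  cand <- tibble(row = idx[, 1] + 1, col = idx[, 2] + 1,
                 score = inner[idx])
  cand <- cand[order(-cand$score), ]

  if (!is.null(segmentation)) {
    sup_r <- polyline_row_at(segmentation$superficial, cand$col)
    deep_r <- polyline_row_at(segmentation$deep, cand$col)
    lab <- rep(NA_character_, nrow(cand))
    lab[abs(cand$row - sup_r) <= apo_band_px] <- "superficial_apo"
    lab[abs(cand$row - deep_r) <= apo_band_px] <- "deep_apo"
    fas <- is.na(lab) & cand$row > sup_r + apo_band_px &
      cand$row < deep_r - apo_band_px
    lab[fas] <- "fascicle"
    cand$label <- lab
    cand <- cand[!is.na(cand$label), ]
  } else {
    cand$label <- "unlabelled"
  }

  # greedy best-first selection with spacing enforcement
  keep <- integer(0)
  for (i in seq_len(nrow(cand))) {
    if (length(keep) >= max_n) break
    if (!length(keep)) { keep <- i; next }
    d2 <- (cand$row[keep] - cand$row[i])^2 + (cand$col[keep] - cand$col[i])^2
    if (min(d2) >= min_spacing_px^2) keep <- c(keep, i)
  }
  if (min_per_label > 0) {
    for (lab in unique(cand$label)) {
      short <- min_per_label - sum(cand$label[keep] == lab)
      if (short <= 0) next
      for (i in setdiff(which(cand$label == lab), keep)) {
        if (short <= 0) break
        d2 <- (cand$row[keep] - cand$row[i])^2 +
          (cand$col[keep] - cand$col[i])^2
        if (min(d2) >= min_spacing_px^2) {
          keep <- c(keep, i); short <- short - 1
        }
      }
    }
  }
  cand[keep, ]
}

# one pyramidal LK alignment step for a batch of features between two
# images; returns updated positions and convergence flags
lk_align <- function(img_from, img_to, rows, cols, window_px = 11,
                     pyramid_levels = 3, max_iter = 12, eps_px = 0.01) {
  stopifnot(window_px %% 2 == 1)
  hw <- (window_px - 1) / 2
  # build pyramids
  pyr_from <- list(img_from); pyr_to <- list(img_to)
  k <- c(0.25, 0.5, 0.25)
  for (l in seq_len(pyramid_levels - 1)) {
    a <- cpp_sepconv(pyr_from[[l]], k, k); b <- cpp_sepconv(pyr_to[[l]], k, k)
    ri <- seq(1, nrow(a), by = 2); ci <- seq(1, ncol(a), by = 2)
    pyr_from[[l + 1]] <- a[ri, ci]; pyr_to[[l + 1]] <- b[ri, ci]
  }
  n <- length(rows)
  d_r <- numeric(n); d_c <- numeric(n)
  ok <- rep(TRUE, n)
  off <- as.matrix(expand.grid(dr = -hw:hw, dc = -hw:hw))

  for (l in pyramid_levels:1) {
    s <- 2^(l - 1)
    I <- pyr_from[[l]]; J <- pyr_to[[l]]
    gI <- image_gradients(I)
    r_l <- (rows - 1) / s + 1; c_l <- (cols - 1) / s + 1
    d_r <- d_r; d_c <- d_c          # carried over, already in full-res px
    for (i in seq_len(n)) {
      if (!ok[i]) next
      # window sampling clamps at the borders; a window that degenerates
      # there is caught by the structure-tensor conditioning guard below
      wr <- r_l[i] + off[, "dr"]; wc <- c_l[i] + off[, "dc"]
      Ti <- bilinear_sample(I, wr, wc)
      gz <- bilinear_sample(gI$gz, wr, wc)
      gx <- bilinear_sample(gI$gx, wr, wc)
      Gzz <- sum(gz * gz); Gzx <- sum(gz * gx); Gxx <- sum(gx * gx)
      det <- Gzz * Gxx - Gzx^2
      if (det < 1e-12) { ok[i] <- FALSE; next }
      vr <- d_r[i] / s; vc <- d_c[i] / s
      for (it in seq_len(max_iter)) {
        # sampling clamps at the borders; divergence is caught by the step
        # cap here and the appearance check downstream
        e <- bilinear_sample(J, wr + vr, wc + vc) - Ti
        bz <- sum(gz * e); bx <- sum(gx * e)
        sr <- -(Gxx * bz - Gzx * bx) / det
        sc <- -(Gzz * bx - Gzx * bz) / det
        step <- sqrt(sr^2 + sc^2)
        if (step > 1.5) { sr <- sr * 1.5 / step; sc <- sc * 1.5 / step }
        vr <- vr + sr; vc <- vc + sc
        if (step < eps_px) break
      }
      # reject only if the level's result wandered implausibly far
      if (vr^2 + vc^2 > (4 * hw)^2) { ok[i] <- FALSE; next }
      d_r[i] <- vr * s; d_c[i] <- vc * s
    }
  }
  list(d_row = d_r, d_col = d_c, ok = ok)
}

#' Track features through an image sequence (pyramidal KLT)
#'
#' Features detected on the initialization frame are aligned frame-to-frame
#' by iterative coarse-to-fine Lucas-Kanade least squares. Features that
#' fail to converge, leave the frame, or whose local appearance decorrelates
#' below `min_ncc` are dropped; when `replenish = TRUE` (default) the set
#' is topped up to `max_n` with fresh detections each frame (new features
#' inherit labels from the advected segmentation bands).
#'
#' @param seq an [image_sequence()].
#' @param segmentation optional [segmentation()] for labelling (frame-1
#'   pixel coordinates).
#' @param max_n,min_spacing_px,apo_band_px detection parameters (see
#'   [detect_features()]).
#' @param window_px odd LK window size (default 11).
#' @param pyramid_levels number of pyramid levels (default 3).
#' @param min_ncc drop threshold on the window's normalized correlation
#'   between consecutive frames (default 0.6).
#' @param replenish top up lost features each frame (default TRUE).
#' @return tibble of class `feature_tracks`: `frame`, `id`, `row`, `col`,
#'   `label`, `age` (frames since detection). Errors if every feature is
#'   lost, naming the frame.
#' @export
track_features <- function(seq, segmentation = NULL, max_n = 200,
                           min_spacing_px = 8, apo_band_px = 4,
                           window_px = 11, pyramid_levels = 3,
                           min_ncc = 0.5, replenish = TRUE,
                           min_per_label = 0) {
  fr_prev <- get_frame(seq, 1)
  feats <- detect_features(fr_prev, segmentation, max_n = max_n,
                           min_spacing_px = min_spacing_px,
                           apo_band_px = apo_band_px,
                           min_per_label = min_per_label)
  if (!nrow(feats)) abort("no features detected on the initialization frame")
  cur <- mutate(feats, id = seq_len(nrow(feats)), age = 0L)
  next_id <- nrow(feats) + 1L
  out <- vector("list", n_frames(seq))
  out[[1]] <- mutate(cur, frame = 1L)
  hw <- (window_px - 1) / 2
  off <- as.matrix(expand.grid(dr = -hw:hw, dc = -hw:hw))

  for (i in seq(2, length.out = n_frames(seq) - 1)) {
    fr <- get_frame(seq, i)
    al <- lk_align(fr_prev, fr, cur$row, cur$col, window_px = window_px,
                   pyramid_levels = pyramid_levels)
    new_r <- cur$row + al$d_row; new_c <- cur$col + al$d_col
    # appearance check: NCC of the window before/after
    ncc <- rep(-1, nrow(cur))
    for (k in seq_len(nrow(cur))) {
      if (!al$ok[k]) next
      if (new_r[k] < 1 || new_c[k] < 1 ||
          new_r[k] > nrow(fr) || new_c[k] > ncol(fr)) next
      # window sampling clamps at the borders, so edge features are judged
      # on their in-frame content rather than dropped outright
      a <- bilinear_sample(fr_prev, cur$row[k] + off[, 1], cur$col[k] + off[, 2])
      b <- bilinear_sample(fr, new_r[k] + off[, 1], new_c[k] + off[, 2])
      if (sd(a) == 0 || sd(b) == 0) next
      ncc[k] <- cor(a, b)
    }
    alive <- al$ok & ncc >= min_ncc
    cur <- cur[alive, ]
    cur$row <- new_r[alive]; cur$col <- new_c[alive]
    cur$age <- cur$age + 1L

    label_short <- min_per_label > 0 && nrow(cur) > 0 &&
      any(table(factor(cur$label, levels = unique(feats$label))) <
            min_per_label)
    if (replenish && (nrow(cur) < max_n || label_short)) {
      seg_i <- segmentation
      if (!is.null(seg_i) && nrow(cur) > 0) {
        # advect the label bands by the median tracked displacement
        med_dr <- median(al$d_row[alive])
        seg_i$superficial[, 1] <- seg_i$superficial[, 1] + med_dr
        seg_i$deep[, 1] <- seg_i$deep[, 1] + med_dr
      }
      fresh <- detect_features(fr, seg_i, max_n = max_n,
                               min_spacing_px = min_spacing_px,
                               apo_band_px = apo_band_px,
                               min_per_label = min_per_label)
      if (nrow(fresh) && nrow(cur)) {
        far <- vapply(seq_len(nrow(fresh)), function(k) {
          min((cur$row - fresh$row[k])^2 + (cur$col - fresh$col[k])^2) >=
            min_spacing_px^2
        }, logical(1))
        fresh <- fresh[far, ]
      }
      if (nrow(fresh)) {
        take <- utils::head(fresh, max(max_n - nrow(cur), 0L))
        if (min_per_label > 0) {
          rest <- dplyr::anti_join(fresh, take, by = c("row", "col"))
          for (lab in unique(feats$label)) {
            short <- min_per_label - sum(cur$label == lab) -
              sum(take$label == lab)
            if (short > 0)
              take <- bind_rows(take,
                                utils::head(rest[rest$label == lab, ], short))
          }
        }
        take <- mutate(take, id = next_id + seq_len(nrow(take)) - 1L,
                       age = 0L)
        next_id <- next_id + nrow(take)
        cur <- bind_rows(cur, take)
      }
    }
    if (!nrow(cur))
      abort(sprintf("all features lost at frame %d", i))
    out[[i]] <- mutate(cur, frame = as.integer(i))
    fr_prev <- fr
  }
  res <- bind_rows(out) %>%
    select("frame", "id", "row", "col", "score", "label", "age")
  class(res) <- c("feature_tracks", class(res))
  res
}
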