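# Image primitives (no R image-processing package is available in this stack,
# so grayscale morphology and smoothing are implemented here on base matrices;
# watershed and the Euclidean distance transform live in src/).

# shift with replicate (clamped-index) padding
shift_mat <- function(x, dr, dc) {
  H <- nrow(x); W <- ncol(x)
  ri <- pmin(pmax(seq_len(H) + dr, 1L), H)
  ci <- pmin(pmax(seq_len(W) + dc, 1L), W)
  x[ri, ci, drop = FALSE]
}

disc_offsets <- function(radius_px) {
  r <- floor(radius_px)
  g <- expand.grid(dr = -r:r, dc = -r:r)
  g[g$dr^2 + g$dc^2 <= radius_px^2, , drop = FALSE]
}

gray_erode <- function(x, offsets) {
  out <- NULL
  for (i in seq_len(nrow(offsets))) {
    s <- shift_mat(x, offsets$dr[i], offsets$dc[i])
    out <- if (is.null(out)) s else pmin(out, s)
  }
  out
}

gray_dilate <- function(x, offsets) {
  out <- NULL
  for (i in seq_len(nrow(offsets))) {
    s <- shift_mat(x, offsets$dr[i], offsets$dc[i])
    out <- if (is.null(out)) s else pmax(out, s)
  }
  out
}

binary_dilate <- function(mask, radius_px) {
  if (radius_px < 1) return(mask)
  gray_dilate(mask * 1, disc_offsets(radius_px)) > 0
}

#' Separable Gaussian smoothing of an image
#'
#' @param x numeric matrix.
#' @param sigma Gaussian SD in px (0 returns `x` unchanged).
#' @return Smoothed matrix (replicate edge padding).
#' @export
gaussian_smooth <- function(x, sigma = 1) {
  if (sigma <= 0) return(x)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-0.5 * ((-r:r) / sigma)^2)
  k <- k / sum(k)
  out <- matrix(0, nrow(x), ncol(x))
  for (i in -r:r) out <- out + k[i + r + 1] * shift_mat(x, i, 0L)
  out2 <- matrix(0, nrow(x), ncol(x))
  for (j in -r:r) out2 <- out2 + k[j + r + 1] * shift_mat(out, 0L, j)
  out2
}

#' Subtract the local background with a morphological white top-hat
#'
#' White top-hat (image minus its grayscale opening with a disc structuring
#' element) removes any background varying on scales larger than the disc
#' while preserving compact bright features such as FAs; output is >= 0 by
#' construction. The disc radius must exceed the largest expected FA minor
#' axis.
#'
#' @param frame numeric matrix (raw intensities).
#' @param radius_um structuring-element radius, um.
#' @param pixel_size um/px.
#' @return Background-subtracted matrix.
#' @export
subtract_local_background <- function(frame, radius_um, pixel_size) {
  r_px <- radius_um / pixel_size
  if (r_px < 1) stop("top-hat radius is smaller than 1 px")
  off <- disc_offsets(r_px)
  opening <- gray_dilate(gray_erode(frame, off), off)
  pmax(frame - opening, 0)
}

#' Segmentation parameters
#'
#' @param smoothing_sigma_px Gaussian pre-smoothing SD, px.
#' @param mad_k threshold = median + `mad_k` * MAD of the (smoothed,
#'   background-subtracted) frame; robust statistics are used instead of Otsu
#'   because FA-sparse frames violate bimodality.
#' @param min_area_um2 regions smaller than this are discarded.
#' @param tophat_radius_um disc radius for [subtract_local_background()].
#' @param min_seed_sep_um minimum separation between watershed seed maxima.
#' @param abs_threshold optional absolute intensity floor added to the robust
#'   threshold (`max(median + k * MAD, abs_threshold)`); useful on noiseless
#'   synthetic data where the MAD collapses to 0.
#' @return A list of class `segment_config`.
#' @export
segment_config <- function(smoothing_sigma_px = 1, mad_k = 6,
                           min_area_um2 = 0.2, tophat_radius_um = 2,
                           min_seed_sep_um = 0.5, abs_threshold = NULL) {
  structure(as.list(environment()), class = "segment_config")
}

local_maxima_seeds <- function(s, fg, min_sep_px) {
  is_max <- s >= gray_dilate(s, disc_offsets(1.5)) & fg
  idx <- which(is_max)
  if (length(idx) == 0) return(matrix(integer(0), ncol = 2))
  H <- nrow(s)
  ord <- idx[order(-s[idx], idx)]        # intensity desc, index tie-break
  rows <- (ord - 1L) %% H
  cols <- (ord - 1L) %/% H
  keep <- logical(length(ord))
  for (i in seq_along(ord)) {
    if (i == 1) { keep[1] <- TRUE; next }
    sel <- which(keep[seq_len(i - 1)])
    d2 <- (rows[sel] - rows[i])^2 + (cols[sel] - cols[i])^2
    keep[i] <- all(d2 >= min_sep_px^2)
  }
  cbind(rows[keep], cols[keep])          # 0-based
}

#' Segment focal adhesions in one frame
#'
#' Gaussian smoothing, robust (median + k * MAD) foreground thresholding,
#' seed detection at local maxima with a minimum separation, and
#' marker-controlled watershed on the inverted smoothed intensity to split
#' touching adhesions. Regions below the minimum area are discarded. The
#' input frame is expected to be background-subtracted
#' ([subtract_local_background()]).
#'
#' @param frame background-subtracted numeric matrix.
#' @param pixel_size um/px.
#' @param config a [segment_config()].
#' @param cell_mask optional logical matrix; when given, the
#'   `dist_to_edge_norm` feature is filled in and segmentation is restricted
#'   to the mask.
#' @param raw optional raw (un-subtracted) frame for the raw-intensity and
#'   local-background features; defaults to `frame`.
#' @return A list with `labels` (integer matrix, 0 = background) and
#'   `records` (data frame, one row per adhesion with >= 30 feature columns;
#'   centroids 0-based px, geometric features in um).
#' @export
segment_frame <- function(frame, pixel_size, config = segment_config(),
                          cell_mask = NULL, raw = NULL) {
  if (is.null(raw)) raw <- frame
  s <- gaussian_smooth(frame, config$smoothing_sigma_px)
  # robust threshold over the cell interior: outside pixels (flat after
  # background filling) would deflate the MAD
  stat_px <- if (!is.null(cell_mask)) s[cell_mask] else s
  thr <- median(stat_px) + config$mad_k * mad(stat_px)
  if (!is.null(config$abs_threshold)) thr <- max(thr, config$abs_threshold)
  fg <- s > thr
  if (!is.null(cell_mask)) fg <- fg & cell_mask
  empty <- list(labels = matrix(0L, nrow(frame), ncol(frame)),
                records = empty_records())
  if (!any(fg)) return(empty)
  seeds <- local_maxima_seeds(s, fg, config$min_seed_sep_um / pixel_size)
  if (nrow(seeds) == 0) return(empty)
  seed_mat <- matrix(0L, nrow(frame), ncol(frame))
  seed_mat[!fg] <- -1L
  seed_mat[cbind(seeds[, 1] + 1L, seeds[, 2] + 1L)] <- seq_len(nrow(seeds))
  labels <- watershed_flood(-s, seed_mat)
  min_px <- config$min_area_um2 / pixel_size^2
  tab <- tabulate(labels[labels > 0])
  drop <- which(tab < min_px)
  if (length(drop)) labels[labels %in% drop] <- 0L
  # relabel compactly, preserving order
  kept <- sort(unique(labels[labels > 0]))
  relab <- integer(max(kept, 0))
  relab[kept] <- seq_along(kept)
  labels[labels > 0] <- relab[labels[labels > 0]]
  records <- region_features(labels, frame, raw, pixel_size, cell_mask)
  list(labels = labels, records = records)
}

empty_records <- function() {
  region_features(matrix(0L, 2, 2), matrix(0, 2, 2), matrix(0, 2, 2), 1, NULL)
}

# ~32 geometric and intensity features per labelled region
region_features <- function(labels, frame, raw, pixel_size, cell_mask) {
  ids <- sort(unique(labels[labels > 0]))
  ps <- pixel_size
  H <- nrow(labels)
  edt_norm <- NULL
  if (!is.null(cell_mask)) {
    e <- mask_edt(cell_mask)
    edt_norm <- e / max(e)
  }
  rows <- lapply(ids, function(L) {
    idx <- which(labels == L)
    r <- (idx - 1L) %% H        # 0-based
    c <- (idx - 1L) %/% H
    val <- frame[idx]
    rawv <- raw[idx]
    n <- length(idx)
    cr <- mean(r); cc <- mean(c)
    wsum <- sum(val)
    wcr <- if (wsum > 0) sum(r * val) / wsum else cr
    wcc <- if (wsum > 0) sum(c * val) / wsum else cc
    # second central moments (+1/12 px discretization term)
    mrr <- mean((r - cr)^2) + 1 / 12
    mcc <- mean((c - cc)^2) + 1 / 12
    mrc <- mean((r - cr) * (c - cc))
    eig <- eigen(matrix(c(mrr, mrc, mrc, mcc), 2), symmetric = TRUE)
    l1 <- max(eig$values[1], 1e-12); l2 <- max(eig$values[2], 0)
    major_px <- 4 * sqrt(l1); minor_px <- 4 * sqrt(l2)
    v1 <- eig$vectors[, 1]
    orientation <- atan2(v1[2], v1[1]) %% pi
    ecc <- sqrt(max(0, 1 - l2 / l1))
    # perimeter: count exposed 4-neighbour pixel edges on a padded patch
    bb0 <- c(min(r), min(c), max(r), max(c))
    ph <- bb0[3] - bb0[1] + 3L; pw <- bb0[4] - bb0[2] + 3L
    patch <- matrix(FALSE, ph, pw)
    patch[cbind(r - bb0[1] + 2L, c - bb0[2] + 2L)] <- TRUE
    perim_px <- sum(patch & !rbind(patch[-1, , drop = FALSE], FALSE)) +
                sum(patch & !rbind(FALSE, patch[-ph, , drop = FALSE])) +
                sum(patch & !cbind(patch[, -1, drop = FALSE], FALSE)) +
                sum(patch & !cbind(FALSE, patch[, -pw, drop = FALSE]))
    # convex hull area (px^2) for solidity
    if (n >= 3) {
      pts <- cbind(r, c)
      hull <- grDevices::chull(pts)
      hp <- pts[hull, , drop = FALSE]
      k <- nrow(hp)
      sh <- abs(sum(hp[, 1] * hp[c(2:k, 1), 2] - hp[c(2:k, 1), 1] * hp[, 2])) / 2
      convex_px <- sh + k / 2 + 1
    } else convex_px <- n
    convex_px <- max(convex_px, n)
    bb <- c(min(r), min(c), max(r), max(c))
    dist_edge <- if (!is.null(edt_norm))
      edt_norm[round(cr) + 1, round(cc) + 1] else NA_real_
    # local background: raw mean in a padded bounding box, excluding all
    # labelled pixels
    rr <- max(1, bb[1] - 2):min(H, bb[3] + 4)
    cc2 <- max(1, bb[2] - 2):min(ncol(labels), bb[4] + 4)
    patch_lab <- labels[rr, cc2]
    patch_raw <- raw[rr, cc2]
    lb <- if (any(patch_lab == 0)) mean(patch_raw[patch_lab == 0]) else NA_real_
    data.frame(
      label = L,
      area_um2 = n * ps^2,
      n_pixels = n,
      centroid_row = cr, centroid_col = cc,
      weighted_centroid_row = wcr, weighted_centroid_col = wcc,
      major_axis_um = major_px * ps, minor_axis_um = minor_px * ps,
      orientation_rad = orientation, eccentricity = ecc,
      perimeter_um = perim_px * ps,
      equivalent_diameter_um = 2 * sqrt(n / pi) * ps,
      aspect_ratio = major_px / max(minor_px, 1e-12),
      solidity = min(1, n / convex_px),
      convex_area_um2 = convex_px * ps^2,
      extent = n / ((bb[3] - bb[1] + 1) * (bb[4] - bb[2] + 1)),
      bbox_min_row = bb[1], bbox_min_col = bb[2],
      bbox_max_row = bb[3], bbox_max_col = bb[4],
      bbox_height_um = (bb[3] - bb[1] + 1) * ps,
      bbox_width_um = (bb[4] - bb[2] + 1) * ps,
      total_intensity = sum(val),
      mean_intensity = mean(val),
      max_intensity = max(val),
      min_intensity = min(val),
      sd_intensity = if (n > 1) sd(val) else 0,
      median_intensity = median(val),
      integrated_raw_intensity = sum(rawv),
      mean_raw_intensity = mean(rawv),
      local_background = lb,
      dist_to_edge_norm = dist_edge)
  })
  if (length(rows) == 0) {
    out <- region_features_template()
  } else {
    out <- do.call(rbind, rows)
  }
  out
}

region_features_template <- function() {
  cols <- c("label", "area_um2", "n_pixels", "centroid_row", "centroid_col",
            "weighted_centroid_row", "weighted_centroid_col", "major_axis_um",
            "minor_axis_um", "orientation_rad", "eccentricity", "perimeter_um",
            "equivalent_diameter_um", "aspect_ratio", "solidity",
            "convex_area_um2", "extent", "bbox_min_row", "bbox_min_col",
            "bbox_max_row", "bbox_max_col", "bbox_height_um", "bbox_width_um",
            "total_intensity", "mean_intensity", "max_intensity",
            "min_intensity", "sd_intensity", "median_intensity",
            "integrated_raw_intensity", "mean_raw_intensity",
            "local_background", "dist_to_edge_norm")
  df <- as.data.frame(setNames(rep(list(numeric(0)), length(cols)), cols))
  df
}

#' Segment every frame of a movie
#'
#' Applies [subtract_local_background()] and [segment_frame()] per frame.
#'
#' @param movie an `fa_movie` (or any list with `frames`, `pixel_size`,
#'   `cell_mask`).
#' @param config a [segment_config()].
#' @return A list with `records` (all frames, 0-based `frame` column),
#'   `labels` (integer array like `frames`) and `bg_subtracted` (numeric
#'   array of top-hat frames).
#' @export
segment_movie <- function(movie, config = segment_config()) {
  d <- dim(movie$frames)
  labels <- array(0L, d)
  bgsub <- array(0, d)
  recs <- vector("list", d[3])
  cell_mask <- movie$cell_mask
  for (fr in seq_len(d[3])) {
    raw <- movie$frames[, , fr]
    # the cell edge is an intensity step; a top-hat applied across it leaves a
    # bright rim. Filling the outside with the in-cell median flattens the
    # step so the top-hat sees only compact features.
    filled <- raw
    if (!is.null(cell_mask)) filled[!cell_mask] <- median(raw[cell_mask])
    bg <- subtract_local_background(filled, config$tophat_radius_um,
                                    movie$pixel_size)
    seg <- segment_frame(bg, movie$pixel_size, config,
                         cell_mask = movie$cell_mask, raw = raw)
    labels[, , fr] <- seg$labels
    bgsub[, , fr] <- bg
    if (nrow(seg$records) > 0) {
      seg$records$frame <- fr - 1L       # 0-based frames
      recs[[fr]] <- seg$records
    }
  }
  records <- do.call(rbind, recs[!vapply(recs, is.null, logical(1))])
  if (is.null(records)) {
    records <- region_features_template()
    records$frame <- integer(0)
  }
  list(records = records, labels = labels, bg_subtracted = bgsub)
}

#' Per-frame photobleaching correction factors
#'
#' The reference signal is the mean cytoplasmic intensity over the cell mask
#' with (dilated) FA pixels excluded, so genuine FA disassembly is not
#' corrected away; the camera dark level, estimated outside the cell, is
#' subtracted first. Factors are `reference[1] / reference[t]`, optionally
#' smoothed with a mono-exponential fit. Multiplying frame `t` by
#' `factors[t]` flattens the reference signal.
#'
#' @param movie an `fa_movie`-like list with `frames`.
#' @param cell_mask logical matrix covering the cytoplasm.
#' @param fa_labels integer array of per-frame FA labels (from
#'   [segment_movie()]), or `NULL` for none.
#' @param smooth fit `log(reference)` linearly in time and use the fitted
#'   exponential (default `TRUE`).
#' @param fa_dilate_px dilation of the FA mask before exclusion.
#' @return Numeric vector of multiplicative factors, one per frame; attribute
#'   `reference` holds the raw reference trace.
#' @export
estimate_bleach_correction <- function(movie, cell_mask, fa_labels = NULL,
                                       smooth = TRUE, fa_dilate_px = 2) {
  d <- dim(movie$frames)
  outside <- !binary_dilate(cell_mask, 3)
  ref <- numeric(d[3])
  for (fr in seq_len(d[3])) {
    fa <- if (!is.null(fa_labels)) binary_dilate(fa_labels[, , fr] > 0,
                                                 fa_dilate_px)
          else matrix(FALSE, d[1], d[2])
    region <- cell_mask & !fa
    if (sum(region) < 100)
      stop("bleach-correction reference region has fewer than 100 px")
    dark <- if (any(outside)) mean(movie$frames[, , fr][outside]) else 0
    ref[fr] <- mean(movie$frames[, , fr][region]) - dark
  }
  if (any(ref <= 0)) stop("non-positive bleach reference signal")
  if (smooth && d[3] >= 3) {
    tt <- seq_len(d[3]) - 1
    fitc <- coef(lm(log(ref) ~ tt))
    fitted <- exp(fitc[1] + fitc[2] * tt)
    factors <- fitted[1] / fitted
  } else {
    factors <- ref[1] / ref
  }
  attr(factors, "reference") <- ref
  factors
}

#' Per-pixel log-ratio image of two channels
#'
#' `log(a / max(b, denom_floor))` inside the mask, `NA` elsewhere; used for
#' two-colour comparisons of FA composition (e.g. zyxin/vinculin ratio maps
#' displayed on a logarithmic scale).
#'
#' @param channel_a,channel_b aligned numeric matrices of equal shape.
#' @param fa_mask logical matrix of pixels to evaluate.
#' @param denom_floor strictly positive floor applied to the denominator.
#' @return Matrix of log-ratios with `NA` outside the mask; attribute
#'   `floored` marks in-mask pixels where the denominator was below the
#'   floor.
#' @export
ratio_image <- function(channel_a, channel_b, fa_mask, denom_floor = 1) {
  if (!all(dim(channel_a) == dim(channel_b)) ||
      !all(dim(channel_a) == dim(fa_mask)))
    stop("channel and mask shapes differ")
  if (denom_floor <= 0) stop("'denom_floor' must be > 0")
  out <- log(channel_a / pmax(channel_b, denom_floor))
  out[!fa_mask] <- NA_real_
  attr(out, "floored") <- fa_mask & (channel_b < denom_floor)
  out
}
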