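#' Configuration of a synthetic FA time-lapse movie
#'
#' Describes the stated world of the generator: a 2-h movie at 3-min frame
#' intervals (the acquisition protocol being emulated), an elliptical cell on
#' a fluorescent cytoplasmic background, elongated FA blobs placed
#' peripherally and centrally, a drug frame after which every pre-existing
#' adhesion's intensity decays as `exp(-(t - t_drug)/tau)` with per-protein
#' time constants (fast ~7.5, mid ~16, slow ~26.5 min, the midpoints of the
#' published 7-8 / ~16 / 25-28 min groups), central adhesions decaying
#' `central_speedup` times faster (1.3-2x in the source regime), mild global
#' photobleaching, and shot + read noise.
#'
#' @param frame_shape `c(rows, cols)` in px.
#' @param pixel_size um per px.
#' @param frame_interval min per frame.
#' @param n_frames number of frames.
#' @param drug_frame 0-based frame index at which the relaxing drug is added
#'   (`NA` for an untreated movie); must be `< n_frames`.
#' @param cell_center `c(row, col)` 0-based px (default: frame centre).
#' @param cell_axes ellipse semi-axes `c(row, col)` in px.
#' @param n_peripheral,n_central number of adhesions per location class.
#' @param protein_group `"fast"`, `"mid"` or `"slow"`; selects `tau_presets`.
#' @param tau_presets named decay time constants, min.
#' @param central_speedup factor >= 1 by which central adhesions decay faster.
#' @param peripheral_d_range,central_d_min normalized boundary-distance ranges
#'   used to place peripheral/central adhesions (the classifier's default
#'   peripheral band is 0.25).
#' @param background_level cytoplasmic fluorescence, photons/px.
#' @param outside_level non-fluorescent offset outside the cell, photons/px.
#' @param read_noise_sd Gaussian read noise SD, photons.
#' @param shot_noise apply Poisson shot noise on total photons.
#' @param photobleach_tau global photobleaching time constant, min (mild by
#'   default so bleach correction is exercised without dominating).
#' @param peak_range per-adhesion peak amplitude range above background,
#'   photons.
#' @param major_range_um,aspect_range FA major-axis length (um) and
#'   major/minor aspect-ratio ranges.
#' @param min_sep_um minimum centre-to-centre separation when placing
#'   adhesions, um.
#' @param birth_rate expected number of new (drug-insensitive) adhesions born
#'   per frame after `drug_frame`; default 0 so recovery tests are clean.
#' @param death_threshold fraction of the pre-drug peak below which an
#'   adhesion is considered dead in the ground truth (default 0.05).
#' @param jitter_sd_px per-frame centroid jitter SD (default 0: static FAs).
#' @param seed RNG seed.
#' @return A list of class `movie_config`.
#' @export
movie_config <- function(frame_shape = c(160, 160), pixel_size = 0.25,
                         frame_interval = 3, n_frames = 45, drug_frame = 5,
                         cell_center = NULL, cell_axes = c(72, 60),
                         n_peripheral = 12, n_central = 8,
                         protein_group = "mid",
                         tau_presets = c(fast = 7.5, mid = 16, slow = 26.5),
                         central_speedup = 1.5,
                         peripheral_d_range = c(0.03, 0.20),
                         central_d_min = 0.45,
                         background_level = 100, outside_level = 10,
                         read_noise_sd = 3, shot_noise = TRUE,
                         photobleach_tau = 300,
                         peak_range = c(500, 800),
                         major_range_um = c(1.2, 2.5),
                         aspect_range = c(2, 3.5),
                         min_sep_um = 2,
                         birth_rate = 0, death_threshold = 0.05,
                         jitter_sd_px = 0, seed = 1) {
  if (is.null(cell_center)) cell_center <- (frame_shape - 1) / 2
  if (!is.na(drug_frame) && drug_frame >= n_frames)
    stop("'drug_frame' must be < n_frames")
  stop_if_negative(background_level = background_level,
                   outside_level = outside_level,
                   read_noise_sd = read_noise_sd, birth_rate = birth_rate)
  if (central_speedup < 1) stop("'central_speedup' must be >= 1")
  if (!protein_group %in% names(tau_presets))
    stop("'protein_group' must be one of: ",
         paste(names(tau_presets), collapse = ", "))
  if (any(tau_presets <= 0)) stop("'tau_presets' must be > 0")
  if (pixel_size <= 0) stop("'pixel_size' must be > 0")
  structure(as.list(environment()), class = "movie_config")
}

#' Binary cell mask (filled ellipse) for a movie configuration
#'
#' @param config a [movie_config()].
#' @return Logical matrix of `config$frame_shape`.
#' @export
generate_cell_mask <- function(config) {
  a <- config$cell_axes[1]; b <- config$cell_axes[2]
  if (a <= 0 || b <= 0) stop("cell ellipse axes must be > 0")
  H <- config$frame_shape[1]; W <- config$frame_shape[2]
  cr <- config$cell_center[1]; cc <- config$cell_center[2]
  if (cr - a < 0 || cr + a > H - 1 || cc - b < 0 || cc + b > W - 1)
    stop("cell ellipse exceeds the frame")
  rows <- matrix(0:(H - 1), H, W)
  cols <- matrix(0:(W - 1), H, W, byrow = TRUE)
  ((rows - cr) / a)^2 + ((cols - cc) / b)^2 <= 1
}

# Sample adhesion positions in a normalized-boundary-distance band with a
# minimum separation; 100 rejection attempts per adhesion before giving up.
place_adhesions <- function(d_norm, n, d_lo, d_hi, min_sep_px, taken, class_name) {
  cand <- which(d_norm >= d_lo & d_norm <= d_hi)
  if (length(cand) == 0 && n > 0)
    stop(sprintf("no pixels available to place %s adhesions", class_name))
  H <- nrow(d_norm)
  out <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (att in seq_len(100)) {
      idx <- cand[sample.int(length(cand), 1)]
      rc <- c((idx - 1) %% H, (idx - 1) %/% H)   # 0-based (row, col)
      all_taken <- rbind(taken, out)
      if (nrow(all_taken) == 0 ||
          min(sqrt(rowSums(sweep(all_taken, 2, rc)^2))) >= min_sep_px) {
        out <- rbind(out, rc)
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop(sprintf("could not place a %s adhesion inside the cell mask after 100 attempts",
                   class_name))
  }
  out
}

render_blob <- function(frame, row0, col0, sig_r, sig_c, theta, amp) {
  H <- nrow(frame); W <- ncol(frame)
  ext <- ceiling(4 * max(sig_r, sig_c)) + 1
  r_lo <- max(0, floor(row0) - ext); r_hi <- min(H - 1, ceiling(row0) + ext)
  c_lo <- max(0, floor(col0) - ext); c_hi <- min(W - 1, ceiling(col0) + ext)
  rr <- r_lo:r_hi; cc <- c_lo:c_hi
  dr <- matrix(rr - row0, length(rr), length(cc))
  dc <- matrix(cc - col0, length(rr), length(cc), byrow = TRUE)
  u <- (dr * cos(theta) + dc * sin(theta)) / sig_r
  v <- (-dr * sin(theta) + dc * cos(theta)) / sig_c
  frame[rr + 1, cc + 1] <- frame[rr + 1, cc + 1] + amp * exp(-0.5 * (u^2 + v^2))
  frame
}

#' Generate a synthetic FA time-lapse movie with ground truth
#'
#' Renders each adhesion as an anisotropic 2-D Gaussian blob (sigma = axis
#' length / 2.355, i.e. the axes are FWHMs, matching the diffraction-blurred
#' appearance of FAs in TIRF imaging) on an elliptical cell-shaped background.
#' Blob intensity is constant before `drug_frame`, then multiplied by
#' `exp(-(t - t_drug) / tau_true)`; central adhesions use
#' `tau_true / central_speedup`. A global multiplicative photobleaching
#' factor `exp(-t / photobleach_tau)` applies to all fluorescence. Poisson
#' shot noise acts on total photons, followed by Gaussian read noise. An
#' adhesion's ground-truth `death_frame` is the first frame at which its drug
#' decay factor falls below `death_threshold` (default 5% of the pre-drug
#' peak); frame intervals are half-open `[birth, death)`.
#'
#' @param config a [movie_config()].
#' @return An object of class `fa_movie`: list with `frames` (array
#'   `rows x cols x n_frames`, photons), `pixel_size`, `frame_interval`,
#'   `drug_frame`, `cell_mask`, `truth` (list of `summary` and `per_frame`
#'   data frames) and `config`.
#' @export
generate_movie <- function(config) {
  stopifnot(inherits(config, "movie_config"))
  mask <- generate_cell_mask(config)
  edt <- mask_edt(mask)
  d_norm <- edt / max(edt)
  ps <- config$pixel_size
  with_seed(config$seed, {
    pos_per <- place_adhesions(d_norm, config$n_peripheral,
                               config$peripheral_d_range[1],
                               config$peripheral_d_range[2],
                               config$min_sep_um / ps,
                               matrix(numeric(0), ncol = 2), "peripheral")
    pos_cen <- place_adhesions(d_norm, config$n_central,
                               config$central_d_min, 1,
                               config$min_sep_um / ps, pos_per, "central")
    n_ad <- nrow(pos_per) + nrow(pos_cen)
    loc <- c(rep("peripheral", nrow(pos_per)), rep("central", nrow(pos_cen)))
    pos <- rbind(pos_per, pos_cen)
    tau_base <- config$tau_presets[[config$protein_group]]
    summary <- data.frame(
      id = seq_len(n_ad),
      protein_group = rep(config$protein_group, n_ad),
      location_class = loc,
      centroid_row = as.numeric(pos[, 1]), centroid_col = as.numeric(pos[, 2]),
      major_um = runif(n_ad, config$major_range_um[1], config$major_range_um[2]),
      aspect = runif(n_ad, config$aspect_range[1], config$aspect_range[2]),
      orientation = runif(n_ad, 0, pi),
      peak_intensity = runif(n_ad, config$peak_range[1], config$peak_range[2]),
      birth_frame = rep(0L, n_ad),
      stringsAsFactors = FALSE)
    summary$minor_um <- summary$major_um / summary$aspect
    summary$tau_true <- ifelse(summary$location_class == "central",
                               tau_base / config$central_speedup, tau_base)
    # births of new, drug-insensitive adhesions after the drug (default off)
    if (config$birth_rate > 0 && !is.na(config$drug_frame)) {
      for (fr in (config$drug_frame + 1):(config$n_frames - 1)) {
        n_new <- rpois(1, config$birth_rate)
        if (n_new == 0) next
        pnew <- place_adhesions(d_norm, n_new, 0.03, 1,
                                config$min_sep_um / ps,
                                as.matrix(summary[, c("centroid_row", "centroid_col")]),
                                "newborn")
        for (k in seq_len(nrow(pnew))) {
          nb <- summary[1, ]
          nb$id <- max(summary$id) + 1L
          nb$location_class <- if (d_norm[pnew[k, 1] + 1, pnew[k, 2] + 1] <=
                                   config$peripheral_d_range[2])
            "peripheral" else "central"
          nb$centroid_row <- pnew[k, 1]; nb$centroid_col <- pnew[k, 2]
          nb$major_um <- runif(1, config$major_range_um[1], config$major_range_um[2])
          nb$aspect <- runif(1, config$aspect_range[1], config$aspect_range[2])
          nb$minor_um <- nb$major_um / nb$aspect
          nb$orientation <- runif(1, 0, pi)
          nb$peak_intensity <- runif(1, config$peak_range[1], config$peak_range[2])
          nb$birth_frame <- fr
          nb$tau_true <- Inf            # stable new adhesion
          summary <- rbind(summary, nb)
        }
      }
    }
    dt <- config$frame_interval
    drug <- config$drug_frame
    # ground-truth death: first frame with decay factor < threshold
    summary$death_frame <- vapply(seq_len(nrow(summary)), function(i) {
      if (is.na(drug) || !is.finite(summary$tau_true[i])) return(NA_integer_)
      k <- ceiling(summary$tau_true[i] * log(1 / config$death_threshold) / dt)
      dfr <- as.integer(max(drug, summary$birth_frame[i]) + k)
      if (dfr >= config$n_frames) NA_integer_ else dfr
    }, integer(1))
    summary$censored <- is.na(summary$death_frame)
    H <- config$frame_shape[1]; W <- config$frame_shape[2]
    frames <- array(0, dim = c(H, W, config$n_frames))
    per_frame <- vector("list", config$n_frames)
    for (fr in 0:(config$n_frames - 1)) {
      bleach <- exp(-fr * dt / config$photobleach_tau)
      img <- matrix(config$outside_level, H, W)
      img[mask] <- img[mask] + (config$background_level - config$outside_level) * bleach
      decay <- vapply(seq_len(nrow(summary)), function(i) {
        if (fr < summary$birth_frame[i]) return(0)
        if (is.na(drug) || fr < drug || !is.finite(summary$tau_true[i])) return(1)
        exp(-(fr - max(drug, summary$birth_frame[i])) * dt / summary$tau_true[i])
      }, numeric(1))
      rows_fr <- summary$centroid_row
      cols_fr <- summary$centroid_col
      if (config$jitter_sd_px > 0) {
        rows_fr <- rows_fr + rnorm(nrow(summary), sd = config$jitter_sd_px)
        cols_fr <- cols_fr + rnorm(nrow(summary), sd = config$jitter_sd_px)
      }
      for (i in seq_len(nrow(summary))) {
        if (decay[i] <= 0) next
        img <- render_blob(img, rows_fr[i], cols_fr[i],
                           summary$major_um[i] / ps / 2.355,
                           summary$minor_um[i] / ps / 2.355,
                           summary$orientation[i],
                           summary$peak_intensity[i] * decay[i] * bleach)
      }
      if (config$shot_noise) img[] <- rpois(length(img), pmax(img, 0))
      if (config$read_noise_sd > 0)
        img <- img + rnorm(length(img), sd = config$read_noise_sd)
      frames[, , fr + 1] <- pmax(img, 0)
      per_frame[[fr + 1]] <- data.frame(
        id = summary$id, frame = rep(fr, nrow(summary)),
        centroid_row = rows_fr, centroid_col = cols_fr,
        decay_factor = decay, bleach_factor = rep(bleach, nrow(summary)),
        amplitude = summary$peak_intensity * decay * bleach)
    }
    structure(list(frames = frames, pixel_size = ps, frame_interval = dt,
                   drug_frame = drug, cell_mask = mask,
                   truth = list(summary = summary,
                                per_frame = do.call(rbind, per_frame)),
                   config = config),
              class = "fa_movie")
  })
}

#' @export
print.fa_movie <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("Synthetic FA movie: %d x %d px, %d frames @ %g min (%.1f um/px)\n",
              d[1], d[2], d[3], x$frame_interval, x$pixel_size))
  cat(sprintf("  drug at frame %s; %d adhesions (%s group)\n",
              ifelse(is.na(x$drug_frame), "none", x$drug_frame),
              nrow(x$truth$summary), x$config$protein_group))
  invisible(x)
}
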