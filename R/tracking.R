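#' Link per-frame adhesion detections into tracks
#'
#' Greedy nearest-neighbour frame-to-frame assignment: candidate pairs
#' between active tracks and new detections are sorted by centroid distance
#' (ties by smaller label), gated at `max_displacement_um`, and assigned
#' greedily; unmatched detections start new tracks. A track missing more than
#' `max_gap_frames` consecutive frames is terminated with
#' `death_frame = last_seen + 1` (half-open `[birth, death)` intervals).
#' Adhesions are near-stationary at 3-min sampling, so greedy linking is
#' adequate and fully deterministic.
#'
#' @param records data frame of detections (from [segment_movie()]): columns
#'   `frame` (0-based), `label`, `centroid_row`, `centroid_col` plus any
#'   feature columns (carried along).
#' @param pixel_size um/px.
#' @param max_displacement_um gating distance, um (default 1).
#' @param max_gap_frames tolerated missing frames inside a track (default 1).
#' @param n_frames total frames in the movie (for end-of-movie censoring);
#'   default: `max(records$frame) + 1`.
#' @return An object of class `adhesion_tracks`: list with `detections` (long
#'   data frame with `track_id`) and `summary` (per track: `track_id`,
#'   `birth_frame`, `death_frame`, `censored`, `n_detections`, mean
#'   centroid).
#' @export
link_tracks <- function(records, pixel_size, max_displacement_um = 1,
                        max_gap_frames = 1, n_frames = NULL) {
  if (nrow(records) == 0) {
    return(structure(list(
      detections = cbind(records, track_id = integer(0)),
      summary = data.frame(track_id = integer(0), birth_frame = integer(0),
                           death_frame = integer(0), censored = logical(0),
                           n_detections = integer(0),
                           centroid_row = numeric(0),
                           centroid_col = numeric(0))),
      class = "adhesion_tracks"))
  }
  records <- records[order(records$frame, records$label), ]
  if (is.null(n_frames)) n_frames <- max(records$frame) + 1L
  gate_px <- max_displacement_um / pixel_size
  frames <- sort(unique(records$frame))
  records$track_id <- NA_integer_
  # active track state
  act_id <- integer(0); act_r <- numeric(0); act_c <- numeric(0)
  act_last <- integer(0)
  next_id <- 1L
  birth <- integer(0); last_seen <- integer(0)
  for (fr in frames) {
    rows_fr <- which(records$frame == fr)
    # retire tracks that exceeded the gap
    live <- (fr - act_last) <= (max_gap_frames + 1L)
    act_id <- act_id[live]; act_r <- act_r[live]; act_c <- act_c[live]
    act_last <- act_last[live]
    det_r <- records$centroid_row[rows_fr]
    det_c <- records$centroid_col[rows_fr]
    det_lab <- records$label[rows_fr]
    if (length(act_id) > 0 && length(rows_fr) > 0) {
      dmat <- outer(act_r, det_r, "-")^2 + outer(act_c, det_c, "-")^2
      cand <- which(dmat <= gate_px^2, arr.ind = TRUE)
      if (nrow(cand) > 0) {
        dist <- sqrt(dmat[cand])
        ord <- order(dist, det_lab[cand[, 2]], act_id[cand[, 1]])
        used_t <- logical(length(act_id)); used_d <- logical(length(rows_fr))
        for (k in ord) {
          ti <- cand[k, 1]; di <- cand[k, 2]
          if (used_t[ti] || used_d[di]) next
          used_t[ti] <- TRUE; used_d[di] <- TRUE
          id <- act_id[ti]
          records$track_id[rows_fr[di]] <- id
          act_r[ti] <- det_r[di]; act_c[ti] <- det_c[di]
          act_last[ti] <- fr
          last_seen[id] <- fr
        }
      }
    }
    # unmatched detections start new tracks
    new_d <- which(is.na(records$track_id[rows_fr]))
    for (di in new_d) {
      records$track_id[rows_fr[di]] <- next_id
      act_id <- c(act_id, next_id)
      act_r <- c(act_r, det_r[di]); act_c <- c(act_c, det_c[di])
      act_last <- c(act_last, fr)
      birth[next_id] <- fr
      last_seen[next_id] <- fr
      next_id <- next_id + 1L
    }
  }
  ids <- seq_len(next_id - 1L)
  death <- last_seen + 1L
  censored <- death >= n_frames |
    (n_frames - 1L - last_seen) <= max_gap_frames
  summary <- data.frame(
    track_id = ids,
    birth_frame = as.integer(birth),
    death_frame = as.integer(ifelse(censored, n_frames, death)),
    censored = censored,
    n_detections = as.integer(table(factor(records$track_id, levels = ids))),
    centroid_row = as.numeric(tapply(records$centroid_row, records$track_id,
                                     mean)[as.character(ids)]),
    centroid_col = as.numeric(tapply(records$centroid_col, records$track_id,
                                     mean)[as.character(ids)]))
  structure(list(detections = records, summary = summary),
            class = "adhesion_tracks")
}

#' @export
print.adhesion_tracks <- function(x, ...) {
  cat(sprintf("%d adhesion tracks (%d detections)\n",
              nrow(x$summary), nrow(x$detections)))
  invisible(x)
}

#' Classify tracks as peripheral or central
#'
#' A track's mean centroid is mapped to a normalized distance `d` from the
#' cell boundary (Euclidean distance transform of the cell mask divided by
#' its in-mask maximum, so `d = 0` on the boundary and `d = 1` at the
#' innermost point); the track is peripheral iff `d <= peripheral_band`.
#' Centroids outside the mask get `d = 0` (nearest-boundary) with a warning.
#'
#' @param tracks an `adhesion_tracks` object.
#' @param cell_mask logical matrix.
#' @param peripheral_band normalized-distance threshold (default 0.25).
#' @return `tracks` with `location_class` and `edge_dist_norm` columns added
#'   to the summary.
#' @export
classify_location <- function(tracks, cell_mask, peripheral_band = 0.25) {
  e <- mask_edt(cell_mask)
  dn <- e / max(e)
  s <- tracks$summary
  if (nrow(s) == 0) {
    s$location_class <- character(0); s$edge_dist_norm <- numeric(0)
    tracks$summary <- s
    return(tracks)
  }
  ij <- cbind(pmin(pmax(round(s$centroid_row) + 1, 1), nrow(dn)),
              pmin(pmax(round(s$centroid_col) + 1, 1), ncol(dn)))
  d <- dn[ij]
  outside <- !cell_mask[ij]
  if (any(outside)) {
    warning(sprintf("%d track centroid(s) outside the cell mask; classified by nearest boundary",
                    sum(outside)))
    d[outside] <- 0
  }
  s$edge_dist_norm <- d
  s$location_class <- ifelse(d <= peripheral_band, "peripheral", "central")
  tracks$summary <- s
  tracks
}

#' Lifespan table of adhesion tracks
#'
#' One row per track with birth, death and lifespan in minutes
#' (`frames * frame_interval`), location class (if classified) and whether
#' the track was alive when the drug was added.
#'
#' @param tracks an `adhesion_tracks` object.
#' @param frame_interval min/frame.
#' @param drug_frame 0-based frame of drug addition (optional).
#' @return Data frame with `track_id`, `birth_min`, `death_min`,
#'   `lifespan_min`, `censored`, `location_class`, `alive_at_drug`.
#' @export
lifespan_table <- function(tracks, frame_interval, drug_frame = NA) {
  s <- tracks$summary
  n <- nrow(s)
  data.frame(
    track_id = s$track_id,
    birth_min = s$birth_frame * frame_interval,
    death_min = s$death_frame * frame_interval,
    lifespan_min = (s$death_frame - s$birth_frame) * frame_interval,
    censored = s$censored,
    location_class = if ("location_class" %in% names(s)) s$location_class
                     else rep(NA_character_, n),
    alive_at_drug = if (!is.na(drug_frame))
      s$birth_frame <= drug_frame & s$death_frame > drug_frame
      else rep(NA, n))
}
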