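disassembly_curve <- function(times, value, kind) {
  structure(data.frame(time_min = times, value = value),
            kind = kind, class = c("disassembly_curve", "data.frame"))
}

#' Survival curve of the adhesion cohort present at drug addition
#'
#' The cohort is every track alive at `drug_frame`; the curve is the fraction
#' of the cohort whose `death_frame` exceeds `drug_frame + t/frame_interval`
#' (relative number of surviving FAs). Censored tracks count as surviving.
#'
#' @param tracks an `adhesion_tracks` object.
#' @param drug_frame 0-based frame of drug addition.
#' @param frame_interval min/frame.
#' @param n_frames number of movie frames (default: max death frame).
#' @param location restrict to `"peripheral"` or `"central"` tracks
#'   (requires [classify_location()]); `NULL` for all.
#' @return A `disassembly_curve` (kind `"survival"`): non-increasing values
#'   in `[0, 1]` starting at 1, times in minutes since the drug.
#' @export
survival_curve <- function(tracks, drug_frame, frame_interval,
                           n_frames = NULL, location = NULL) {
  s <- tracks$summary
  if (!is.null(location)) s <- s[s$location_class == location, ]
  cohort <- s[s$birth_frame <= drug_frame & s$death_frame > drug_frame, ]
  if (nrow(cohort) == 0) stop("no tracks alive at the drug frame")
  if (is.null(n_frames)) n_frames <- max(s$death_frame)
  k <- 0:(n_frames - 1 - drug_frame)
  frac <- vapply(k, function(kk)
    mean(cohort$death_frame > drug_frame + kk | cohort$censored), numeric(1))
  disassembly_curve(k * frame_interval, frac, "survival")
}

#' Average normalized intensity decay of the adhesion cohort
#'
#' Each cohort track's intensity series is normalized to its value at
#' `drug_frame` and the curves are averaged pointwise. Two measurement modes:
#'
#' * fixed footprint (default when `movie` and `labels` are given): intensity
#'   at every frame is the bleach-corrected sum of the raw frame over the
#'   track's (dilated) segmentation footprint at `drug_frame`, minus a local
#'   background estimated as the median of a surrounding ring (segmented
#'   pixels excluded; outside-cell pixels filled with the in-cell median
#'   first). For a decaying blob of constant shape this is exactly
#'   proportional to its amplitude — no threshold-clipping bias — and the
#'   measurement continues smoothly through the track's disappearance.
#' * per-frame segmentation (`tracks` only): the `total_intensity` feature of
#'   each detection is used, and dead tracks contribute 0 after their death
#'   (dropping them instead would bias the decay shallow).
#'
#' @param tracks an `adhesion_tracks` object.
#' @param drug_frame 0-based frame of drug addition.
#' @param frame_interval min/frame.
#' @param movie an `fa_movie`-like list with `frames` (and optionally
#'   `cell_mask`) for fixed-footprint measurement.
#' @param labels integer label array from [segment_movie()].
#' @param bleach_factors per-frame factors from
#'   [estimate_bleach_correction()] (default: no correction).
#' @param footprint_dilate_px dilation of the reference footprint, px.
#' @param ring_width_px width of the background ring around the footprint.
#' @param location restrict to one location class; `NULL` for all.
#' @param n_frames number of movie frames.
#' @return A `disassembly_curve` (kind `"intensity"`), value 1 at t = 0.
#'   Tracks with non-positive intensity at the drug frame are excluded with a
#'   warning.
#' @export
intensity_decay_curve <- function(tracks, drug_frame, frame_interval,
                                  movie = NULL, labels = NULL,
                                  bleach_factors = NULL,
                                  footprint_dilate_px = 2,
                                  ring_width_px = 5,
                                  location = NULL, n_frames = NULL) {
  s <- tracks$summary
  if (!is.null(location)) s <- s[s$location_class == location, ]
  cohort <- s[s$birth_frame <= drug_frame & s$death_frame > drug_frame, ]
  if (nrow(cohort) == 0) stop("no tracks alive at the drug frame")
  det <- tracks$detections
  if (is.null(n_frames))
    n_frames <- if (!is.null(labels)) dim(labels)[3] else max(det$frame) + 1
  k <- 0:(n_frames - 1 - drug_frame)
  if (!is.null(bleach_factors)) stopifnot(length(bleach_factors) >= n_frames)
  series <- matrix(NA_real_, nrow(cohort), length(k))
  fixed_fp <- !is.null(labels) && !is.null(movie)
  if (fixed_fp) {
    cm <- movie$cell_mask
    filled <- lapply(k, function(kk) {
      img <- movie$frames[, , drug_frame + kk + 1]
      if (!is.null(cm)) img[!cm] <- median(img[cm])
      img
    })
    seg_any <- lapply(k, function(kk)
      binary_dilate(labels[, , drug_frame + kk + 1] > 0, 1))
  }
  dropped <- 0
  for (i in seq_len(nrow(cohort))) {
    id <- cohort$track_id[i]
    dsub <- det[det$track_id == id, ]
    if (fixed_fp) {
      at_drug <- dsub[dsub$frame == drug_frame, ]
      if (nrow(at_drug) == 0) { dropped <- dropped + 1; next }
      fp <- labels[, , drug_frame + 1] == at_drug$label[1]
      fp <- binary_dilate(fp, footprint_dilate_px)
      ring0 <- binary_dilate(fp, ring_width_px) & !fp
      n_fp <- sum(fp)
      vals <- vapply(seq_along(k), function(ki) {
        fr <- drug_frame + k[ki] + 1
        img <- filled[[ki]]
        ring <- ring0 & !seg_any[[ki]]
        bgl <- if (any(ring)) median(img[ring]) else median(img)
        v <- sum(img[fp]) - n_fp * bgl
        if (!is.null(bleach_factors)) v <- v * bleach_factors[fr]
        v
      }, numeric(1))
    } else {
      vals <- rep(0, length(k))          # dead or missing -> 0
      rows <- dsub$frame >= drug_frame & dsub$frame <= drug_frame + max(k)
      dsub <- dsub[rows, ]
      v <- dsub$total_intensity
      if (!is.null(bleach_factors)) v <- v * bleach_factors[dsub$frame + 1]
      vals[dsub$frame - drug_frame + 1] <- v
    }
    if (!is.finite(vals[1]) || vals[1] <= 0) { dropped <- dropped + 1; next }
    series[i, ] <- vals / vals[1]
  }
  if (dropped > 0)
    warning(sprintf("%d track(s) excluded: no positive intensity at the drug frame",
                    dropped))
  series <- series[rowSums(is.na(series)) == 0, , drop = FALSE]
  if (nrow(series) == 0) stop("no usable tracks for the intensity curve")
  disassembly_curve(k * frame_interval, colMeans(series), "intensity")
}

#' Fit a single-exponential decay time constant
#'
#' Least-squares fit of `y = exp(-t / tau)` (amplitude fixed to 1, since
#' decay curves are normalized at the drug time) to a disassembly curve; a
#' free-amplitude variant `y = A exp(-t / tau)` is available. `tau` is
#' initialized from a log-linear regression on values > 0.05.
#'
#' @param curve a `disassembly_curve` (or data frame with `time_min`,
#'   `value`).
#' @param free_amplitude fit the amplitude too (default `FALSE`).
#' @return A list of class `decay_fit`: `tau` (min), `amplitude`, `rss`,
#'   `ci_tau` (approximate 95%), `converged`.
#' @export
fit_single_exponential <- function(curve, free_amplitude = FALSE) {
  t <- curve$time_min; y <- curve$value
  if (length(t) < 5) stop("need at least 5 points")
  fail <- list(tau = NA_real_, amplitude = NA_real_, rss = NA_real_,
               ci_tau = c(NA_real_, NA_real_), converged = FALSE)
  class(fail) <- "decay_fit"
  pos <- y > 0.05 & t >= 0
  if (sum(pos) < 2) return(fail)
  sl <- unname(coef(lm(log(y[pos]) ~ t[pos]))[2])
  if (!is.finite(sl) || sl >= 0) return(fail)   # non-decaying curve
  tau0 <- -1 / sl
  if (free_amplitude) {
    obj <- function(p) sum((y - exp(p[2]) * exp(-t / exp(p[1])))^2)
    fit <- optim(c(log(tau0), 0), obj, method = "Nelder-Mead",
                 control = list(reltol = 1e-14, maxit = 2000))
    tau <- exp(fit$par[1]); A <- exp(fit$par[2]); rss <- fit$value
    conv <- fit$convergence == 0
  } else {
    obj <- function(ltau) sum((y - exp(-t / exp(ltau)))^2)
    fit <- optimize(obj, log(tau0) + c(-3, 3), tol = 1e-12)
    tau <- exp(fit$minimum); A <- 1; rss <- fit$objective
    conv <- TRUE
  }
  # crude curvature-based CI on log(tau)
  h <- 1e-3
  f0 <- if (free_amplitude) NA else rss
  ci <- c(NA_real_, NA_real_)
  if (!free_amplitude) {
    fp <- obj(log(tau) + h); fm <- obj(log(tau) - h)
    curv <- (fp + fm - 2 * f0) / h^2
    if (is.finite(curv) && curv > 0) {
      s2 <- rss / max(length(t) - 1, 1)
      se <- sqrt(2 * s2 / curv)
      ci <- tau * exp(c(-1.96, 1.96) * se)
    }
  }
  structure(list(tau = tau, amplitude = A, rss = rss, ci_tau = ci,
                 converged = conv), class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("Single-exponential decay: tau = %.3g min (A = %.3g, RSS = %.3g)\n",
              x$tau, x$amplitude, x$rss))
  invisible(x)
}

#' Disassembly statistic K_dis = k_off - k_on
#'
#' A net-flux summary of the FRAP-derived exchange rates: positive `K_dis`
#' means unbinding exceeds (apparent) binding and the protein is in a
#' disassembly state; `k_on > k_off` is an assembly state; equality within
#' `tol` is a stable state (ILK in the drug-induced central adhesions is the
#' canonical example).
#'
#' @param k_on,k_off rates in 1/min (convert FRAP fits from 1/s upstream:
#'   multiply by 60).
#' @param tol absolute tolerance for the stable state.
#' @param protein optional label.
#' @return A list of class `kdis_record`: `protein`, `k_on`, `k_off`,
#'   `K_dis` (1/min), `state`.
#' @export
compute_kdis <- function(k_on, k_off, tol = 1e-9, protein = NA_character_) {
  stop_if_negative(k_on = k_on, k_off = k_off)
  K <- k_off - k_on
  state <- if (abs(K) <= tol) "stable" else if (K > 0) "disassembly" else "assembly"
  structure(list(protein = protein, k_on = k_on, k_off = k_off,
                 K_dis = K, state = state),
            class = "kdis_record")
}

#' @export
print.kdis_record <- function(x, ...) {
  cat(sprintf("%s: k_on = %.4g, k_off = %.4g /min -> K_dis = %.4g /min (%s)\n",
              ifelse(is.na(x$protein), "protein", x$protein),
              x$k_on, x$k_off, x$K_dis, x$state))
  invisible(x)
}

#' Predicted mono-exponential disassembly curve
#'
#' `y(t) = exp(-K_dis t)`: assuming FA disassembly is a mono-exponential
#' process driven by the net unbinding flux, the structure relaxes to 1/e
#' (~37%) of its initial value at `t = 1/K_dis`.
#'
#' @param K_dis disassembly rate, 1/min.
#' @param times minutes since drug addition.
#' @return A `disassembly_curve` (kind `"predicted"`); attribute
#'   `non_disassembling` is `TRUE` when `K_dis <= 0` (the prediction then
#'   does not decay).
#' @export
predicted_disassembly <- function(K_dis, times) {
  if (inherits(K_dis, "kdis_record")) K_dis <- K_dis$K_dis
  out <- disassembly_curve(times, exp(-K_dis * times), "predicted")
  attr(out, "K_dis") <- K_dis
  attr(out, "non_disassembling") <- K_dis <= 0
  out
}

#' Compare a predicted with a measured disassembly curve
#'
#' The predicted curve is linearly interpolated onto the measured grid over
#' `[0, t_max]` minutes (default 60, > 2 time constants of the slowest
#' protein group); the report contains the RMS difference and the ratio of
#' implied rates `K_dis / (1 / tau_measured)` with `tau_measured` from a
#' single-exponential fit of the measured curve.
#'
#' @param predicted a `disassembly_curve` from [predicted_disassembly()].
#' @param measured a measured `disassembly_curve` (survival or intensity).
#' @param t_max comparison window, min.
#' @return A list with `rms`, `rate_ratio`, `K_dis`, `tau_measured`, `n`
#'   (grid points compared).
#' @export
compare_disassembly <- function(predicted, measured, t_max = 60) {
  tm <- measured$time_min
  keep <- tm >= max(0, min(predicted$time_min)) &
          tm <= min(t_max, max(predicted$time_min))
  if (!any(keep)) stop("predicted and measured time grids do not overlap")
  tg <- tm[keep]
  p <- approx(predicted$time_min, predicted$value, xout = tg)$y
  m <- measured$value[keep]
  rms <- sqrt(mean((p - m)^2))
  K <- attr(predicted, "K_dis")
  if (is.null(K)) {
    fitp <- fit_single_exponential(predicted)
    K <- 1 / fitp$tau
  }
  fitm <- fit_single_exponential(measured[measured$time_min <= t_max, ,
                                          drop = FALSE])
  list(rms = rms, rate_ratio = K * fitm$tau, K_dis = K,
       tau_measured = fitm$tau, n = length(tg))
}

#' Multi-protein disassembly report
#'
#' Runs [compare_disassembly()] per protein and adds the Kendall rank
#' concordance between the predicted rates (`K_dis`) and the measured rates
#' (`1/tau`) across proteins.
#'
#' @param predicted named list of predicted `disassembly_curve`s.
#' @param measured named list of measured `disassembly_curve`s (same names).
#' @param t_max comparison window, min.
#' @return A list with `per_protein` (data frame) and `kendall_concordance`.
#' @export
disassembly_report <- function(predicted, measured, t_max = 60) {
  stopifnot(length(predicted) == length(measured),
            all(names(predicted) %in% names(measured)))
  rows <- lapply(names(predicted), function(nm) {
    cmp <- compare_disassembly(predicted[[nm]], measured[[nm]], t_max)
    data.frame(protein = nm, rms = cmp$rms, rate_ratio = cmp$rate_ratio,
               K_dis = cmp$K_dis, rate_measured = 1 / cmp$tau_measured)
  })
  per <- do.call(rbind, rows)
  tau_conc <- if (nrow(per) >= 2)
    cor(per$K_dis, per$rate_measured, method = "kendall") else NA_real_
  list(per_protein = per, kendall_concordance = tau_conc)
}
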