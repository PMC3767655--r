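mk_tracks <- function(summary, detections = data.frame()) {
  structure(list(summary = summary, detections = detections),
            class = "adhesion_tracks")
}

test_that("survival curve counts the surviving fraction", {
  s <- data.frame(track_id = 1:4, birth_frame = 0L,
                  death_frame = c(20L, 20L, 8L, 8L),
                  censored = c(TRUE, TRUE, FALSE, FALSE),
                  n_detections = 5L, centroid_row = 0, centroid_col = 0)
  sv <- survival_curve(mk_tracks(s), drug_frame = 4, frame_interval = 3,
                       n_frames = 20)
  expect_equal(sv$value[1], 1)
  expect_true(all(diff(sv$value) <= 0))
  # half the cohort dead from frame 8 on (t >= 12 min)
  expect_equal(sv$value[sv$time_min == 12], 0.5)
  expect_equal(sv$value[sv$time_min == 9], 1)
  # no deaths -> constant 1
  s2 <- s; s2$censored <- TRUE; s2$death_frame <- 20L
  sv2 <- survival_curve(mk_tracks(s2), 4, 3, n_frames = 20)
  expect_true(all(sv2$value == 1))
  expect_error(survival_curve(mk_tracks(s[0, ]), 4, 3), "alive")
})

test_that("constant-intensity tracks give a flat normalized curve; gain cancels", {
  det <- do.call(rbind, lapply(1:3, function(id)
    data.frame(frame = 0:9, label = id, track_id = id,
               centroid_row = 10 * id, centroid_col = 10,
               total_intensity = 500 * id, area_um2 = 1)))
  s <- data.frame(track_id = 1:3, birth_frame = 0L, death_frame = 10L,
                  censored = TRUE, n_detections = 10L,
                  centroid_row = c(10, 20, 30), centroid_col = 10)
  ic <- intensity_decay_curve(mk_tracks(s, det), drug_frame = 2,
                              frame_interval = 3, n_frames = 10)
  expect_equal(ic$value, rep(1, 8), tolerance = 1e-12)
  det2 <- det; det2$total_intensity <- det$total_intensity * 2
  ic2 <- intensity_decay_curve(mk_tracks(s, det2), 2, 3, n_frames = 10)
  expect_equal(ic2$value, ic$value, tolerance = 1e-12)
})

test_that("doubling the camera gain leaves the fixed-footprint curve unchanged", {
  ch <- get_tiny_chain()
  mv <- ch$movie
  ic1 <- intensity_decay_curve(ch$tracks, mv$drug_frame, mv$frame_interval,
                               movie = mv, labels = ch$seg$labels)
  mv2 <- mv; mv2$frames <- mv$frames * 2
  ic2 <- intensity_decay_curve(ch$tracks, mv$drug_frame, mv$frame_interval,
                               movie = mv2, labels = ch$seg$labels)
  expect_equal(ic2$value, ic1$value, tolerance = 1e-9)
})

test_that("single-exponential fit is exact on noiseless data and flags failure", {
  t <- seq(0, 60, by = 3)
  cv <- structure(data.frame(time_min = t, value = exp(-t / 16)),
                  class = c("disassembly_curve", "data.frame"))
  fit <- fit_single_exponential(cv)
  expect_equal(fit$tau, 16, tolerance = 1e-6)
  fit2 <- fit_single_exponential(
    structure(data.frame(time_min = t, value = 0.8 * exp(-t / 16)),
              class = c("disassembly_curve", "data.frame")),
    free_amplitude = TRUE)
  expect_equal(fit2$tau, 16, tolerance = 1e-4)
  expect_equal(fit2$amplitude, 0.8, tolerance = 1e-4)
  rising <- structure(data.frame(time_min = t, value = 1 + t / 100),
                      class = c("disassembly_curve", "data.frame"))
  expect_false(fit_single_exponential(rising)$converged)
})

test_that("K_dis arithmetic and state classification", {
  k <- compute_kdis(0.03, 0.05)
  expect_equal(k$K_dis, 0.02)
  expect_identical(k$state, "disassembly")
  expect_identical(compute_kdis(0.04, 0.04)$state, "stable")
  expect_identical(compute_kdis(0.05, 0.03)$state, "assembly")
  expect_lt(compute_kdis(0.05, 0.03)$K_dis, 0)
  expect_error(compute_kdis(-0.1, 0.2), "k_on")
})

test_that("the predicted curve relaxes to 1/e at t = 1/K_dis", {
  pred <- predicted_disassembly(0.1, c(0, 10, 20))
  expect_equal(pred$value[1], 1)
  expect_equal(pred$value[2], 0.3679, tolerance = 1e-4)
  pred2 <- predicted_disassembly(0.04, 1 / 0.04)
  expect_equal(pred2$value, exp(-1), tolerance = 1e-12)
  flagged <- predicted_disassembly(-0.01, 0:10)
  expect_true(attr(flagged, "non_disassembling"))
})

test_that("curve comparison matches a quadrature oracle", {
  tg <- seq(0, 60, by = 0.1)
  p <- predicted_disassembly(0.1, tg)
  m <- structure(data.frame(time_min = tg, value = exp(-0.05 * tg)),
                 class = c("disassembly_curve", "data.frame"))
  cmp <- compare_disassembly(p, m)
  expect_equal(cmp$rate_ratio, 2, tolerance = 1e-3)
  # brute-force integral oracle for the RMS
  rms_oracle <- sqrt(integrate(function(t) (exp(-0.1 * t) - exp(-0.05 * t))^2,
                               0, 60)$value / 60)
  expect_equal(cmp$rms, rms_oracle, tolerance = 0.01)
  # identical curves
  cmp0 <- compare_disassembly(p, structure(
    data.frame(time_min = tg, value = exp(-0.1 * tg)),
    class = c("disassembly_curve", "data.frame")))
  expect_lt(cmp0$rms, 1e-9)
  expect_equal(cmp0$rate_ratio, 1, tolerance = 1e-3)
  expect_error(compare_disassembly(
    predicted_disassembly(0.1, 100:120), m[m$time_min < 50, ]), "overlap")
})

test_that("multi-protein report ranks concordantly for nested exponentials", {
  tg <- seq(0, 60, by = 3)
  rates <- c(a = 0.13, b = 0.06, c = 0.038)
  pred <- lapply(rates, function(k) predicted_disassembly(k, tg))
  meas <- lapply(rates, function(k) structure(
    data.frame(time_min = tg, value = exp(-k * 1.05 * tg)),
    class = c("disassembly_curve", "data.frame")))
  rep <- disassembly_report(pred, meas)
  expect_equal(rep$kendall_concordance, 1)
  expect_true(all(rep$per_protein$rms < 0.05))
})
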