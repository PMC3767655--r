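gauss_frame <- function(H, W, row0, col0, sig_r, sig_c, amp, offset = 0) {
  rr <- matrix(0:(H - 1), H, W)
  cc <- matrix(0:(W - 1), H, W, byrow = TRUE)
  offset + amp * exp(-0.5 * (((rr - row0) / sig_r)^2 + ((cc - col0) / sig_c)^2))
}

test_that("top-hat removes flat and sloped backgrounds but keeps blobs", {
  const <- matrix(57.3, 48, 48)
  th <- subtract_local_background(const, radius_um = 2, pixel_size = 0.25)
  expect_true(all(th == 0))
  blob0 <- gauss_frame(48, 48, 24, 24, 2, 2, 100, offset = 0)
  blob_c <- blob0 + 200
  th0 <- subtract_local_background(blob0, 2, 0.25)
  thc <- subtract_local_background(blob_c, 2, 0.25)
  expect_lt(max(abs(th0 - thc)), 1)       # offset invariance
  # linear ramp: peak preserved within 10%
  ramp <- matrix(rep(seq(0, 50, length.out = 48), each = 48), 48, 48)
  thr <- subtract_local_background(blob0 + ramp, 2, 0.25)
  expect_lt(abs(max(thr) / 100 - 1), 0.1)
  expect_error(subtract_local_background(const, 0.1, 0.25), "1 px")
})

test_that("blank noisy frames yield no detections; empty frames are not errors", {
  set.seed(1)
  noise <- matrix(rpois(64 * 64, 100), 64, 64)
  seg <- segment_frame(subtract_local_background(noise, 2, 0.25), 0.25)
  expect_identical(nrow(seg$records), 0L)
  seg0 <- segment_frame(matrix(0, 32, 32), 0.25)
  expect_identical(nrow(seg0$records), 0L)
})

test_that("well-separated blobs are each detected once with >= 30 features", {
  H <- 96
  f <- matrix(0, H, H)
  centers <- rbind(c(20, 20), c(20, 70), c(48, 45), c(75, 20), c(75, 70))
  for (i in 1:5) f <- f + gauss_frame(H, H, centers[i, 1], centers[i, 2],
                                      3, 1.5, 600)
  set.seed(2)
  f <- f + matrix(rnorm(H * H, 0, 5), H, H)
  seg <- segment_frame(pmax(f, 0), 0.25)
  expect_identical(nrow(seg$records), 5L)
  feat_cols <- setdiff(names(seg$records), c("label", "frame"))
  expect_gte(length(feat_cols), 30)
  # centroid localization: median error below 1 px
  err <- sapply(1:5, function(i) {
    d <- sqrt((seg$records$centroid_row - centers[i, 1])^2 +
              (seg$records$centroid_col - centers[i, 2])^2)
    min(d)
  })
  expect_lt(median(err), 1)
})

test_that("watershed splits a touching pair 1.2 um apart", {
  H <- 64
  # 1.2 um at 0.25 um/px = 4.8 px apart; blobs merge into one mask component
  f <- gauss_frame(H, H, 32, 30, 2.5, 2, 500) +
       gauss_frame(H, H, 32, 34.8, 2.5, 2, 500)
  seg <- segment_frame(f, 0.25, segment_config(abs_threshold = 25))
  expect_identical(nrow(seg$records), 2L)
})

test_that("segmentation is deterministic", {
  set.seed(3)
  f <- gauss_frame(64, 64, 30, 30, 3, 1.5, 500) + matrix(rnorm(64^2, 0, 5), 64, 64)
  s1 <- segment_frame(pmax(f, 0), 0.25)
  s2 <- segment_frame(pmax(f, 0), 0.25)
  expect_identical(s1$labels, s2$labels)
  expect_identical(s1$records, s2$records)
})

test_that("area and total intensity of an isolated blob match analytic values", {
  H <- 96
  sig_r <- 4; sig_c <- 2; A <- 800; thr <- 40
  f <- gauss_frame(H, H, 48, 48, sig_r, sig_c, A)
  cfg <- segment_config(smoothing_sigma_px = 0, abs_threshold = thr)
  seg <- segment_frame(f, pixel_size = 0.25, config = cfg)
  expect_identical(nrow(seg$records), 1L)
  # level-set oracle: area above thr and the integral of the Gaussian over it
  area_px <- 2 * pi * sig_r * sig_c * log(A / thr)
  x <- thr / A
  total <- 2 * pi * sig_r * sig_c * A * (1 - x)   # integral over the level set
  expect_lt(abs(seg$records$n_pixels / area_px - 1), 0.1)
  expect_lt(abs(seg$records$total_intensity / total - 1), 0.1)
})

test_that("bleach correction flattens a bleaching movie and is monotone", {
  cfg <- movie_config(frame_shape = c(96, 96), cell_axes = c(40, 36),
                      n_frames = 10, drug_frame = NA, n_peripheral = 2,
                      n_central = 2, photobleach_tau = 120, seed = 8)
  mv <- generate_movie(cfg)
  seg <- segment_movie(mv)
  fac <- estimate_bleach_correction(mv, mv$cell_mask, seg$labels)
  expect_true(all(diff(fac) > 0))          # decaying reference -> factors >= 1
  expect_true(all(fac >= 1 - 1e-9))
  ref <- attr(fac, "reference")
  corrected <- ref * fac
  expect_lt(sd(corrected) / mean(corrected), 0.01)
  # no bleaching: factors stay at 1 within noise
  cfg2 <- movie_config(frame_shape = c(96, 96), cell_axes = c(40, 36),
                       n_frames = 6, drug_frame = NA, n_peripheral = 2,
                       n_central = 2, photobleach_tau = Inf, seed = 8)
  mv2 <- generate_movie(cfg2)
  fac2 <- estimate_bleach_correction(mv2, mv2$cell_mask, NULL)
  expect_lt(max(abs(fac2 - 1)), 0.02)
  small <- matrix(FALSE, 96, 96); small[1:5, 1:5] <- TRUE
  expect_error(estimate_bleach_correction(mv2, small, NULL), "100 px")
})

test_that("ratio imaging follows its contracts", {
  a <- matrix(10, 8, 8); b <- matrix(10, 8, 8)
  m <- matrix(TRUE, 8, 8); m[1, ] <- FALSE
  r <- ratio_image(a, b, m, denom_floor = 1)
  expect_true(all(r[m] == 0))
  expect_true(all(is.na(r[!m])))
  r2 <- ratio_image(2 * a, b, m)
  expect_equal(unique(r2[m]), log(2))
  bfl <- b; bfl[3, 3] <- 0.1
  r3 <- ratio_image(a, bfl, m, denom_floor = 1)
  expect_equal(r3[3, 3], log(10 / 1))
  expect_true(attr(r3, "floored")[3, 3])
  expect_error(ratio_image(a, matrix(1, 4, 4), m), "shape")
})
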