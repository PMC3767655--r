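fake_records <- function(tracks_spec, n_frames) {
  # tracks_spec: list of list(row, col, frames, drift = c(dr, dc))
  rows <- list()
  for (i in seq_along(tracks_spec)) {
    sp <- tracks_spec[[i]]
    drift <- if (is.null(sp$drift)) c(0, 0) else sp$drift
    for (fr in sp$frames) {
      rows[[length(rows) + 1]] <- data.frame(
        frame = fr, label = i,
        centroid_row = sp$row + drift[1] * fr,
        centroid_col = sp$col + drift[2] * fr,
        total_intensity = if (is.null(sp$intensity)) 1000 else sp$intensity,
        area_um2 = 1)
    }
  }
  do.call(rbind, rows)
}

test_that("a stationary detection yields one track with the full lifespan", {
  rec <- fake_records(list(list(row = 20, col = 20, frames = 0:9)), 10)
  tr <- link_tracks(rec, pixel_size = 0.25, n_frames = 10)
  expect_identical(nrow(tr$summary), 1L)
  expect_identical(tr$summary$birth_frame, 0L)
  expect_true(tr$summary$censored)
  expect_identical(tr$summary$death_frame - tr$summary$birth_frame, 10L)
})

test_that("a vanishing detection dies at the right frame", {
  rec <- fake_records(list(list(row = 20, col = 20, frames = 0:5)), 12)
  tr <- link_tracks(rec, pixel_size = 0.25, n_frames = 12)
  expect_false(tr$summary$censored)
  expect_lte(abs(tr$summary$death_frame - 6L), 1L)
})

test_that("two distant slowly-moving detections keep their identities", {
  rec <- fake_records(list(
    list(row = 20, col = 20, frames = 0:9, drift = c(0.3, 0)),
    list(row = 20, col = 40, frames = 0:9, drift = c(-0.3, 0))), 10)
  tr <- link_tracks(rec, pixel_size = 0.25, max_displacement_um = 1,
                    n_frames = 10)
  expect_identical(nrow(tr$summary), 2L)
  det <- tr$detections
  # identity: each track keeps its original label throughout
  expect_true(all(tapply(det$label, det$track_id,
                         function(l) length(unique(l))) == 1))
})

test_that("gap bridging keeps a track together within max_gap", {
  rec <- fake_records(list(list(row = 20, col = 20, frames = c(0:3, 5:8))), 9)
  tr <- link_tracks(rec, 0.25, max_gap_frames = 1, n_frames = 9)
  expect_identical(nrow(tr$summary), 1L)
  tr2 <- link_tracks(fake_records(list(list(row = 20, col = 20,
                                            frames = c(0:3, 6:8))), 9),
                     0.25, max_gap_frames = 1, n_frames = 9)
  expect_identical(nrow(tr2$summary), 2L)
})

test_that("no detection joins two tracks and no track has duplicates per frame", {
  ch <- get_tiny_chain()
  det <- ch$tracks$detections
  expect_false(any(is.na(det$track_id)))
  expect_false(any(duplicated(det[, c("track_id", "frame")])))
  # every detection belongs to exactly one track by construction of track_id
  expect_identical(nrow(det), nrow(ch$seg$records))
})

test_that("tracking and classification are deterministic", {
  ch <- get_tiny_chain()
  mv <- ch$movie
  tr2 <- link_tracks(ch$seg$records, mv$pixel_size,
                     n_frames = dim(mv$frames)[3])
  tr2 <- suppressWarnings(classify_location(tr2, mv$cell_mask))
  expect_identical(ch$tracks$summary, tr2$summary)
  expect_identical(ch$tracks$detections, tr2$detections)
})

test_that("location classification follows the normalized boundary distance", {
  mask <- generate_cell_mask(movie_config(frame_shape = c(96, 96),
                                          cell_axes = c(40, 36)))
  mk <- function(row, col) {
    structure(list(
      summary = data.frame(track_id = 1L, birth_frame = 0L, death_frame = 5L,
                           censored = FALSE, n_detections = 5L,
                           centroid_row = row, centroid_col = col),
      detections = data.frame()), class = "adhesion_tracks")
  }
  # on the boundary -> peripheral
  on_edge <- classify_location(mk(47.5, 47.5 + 35.9), mask)
  expect_identical(on_edge$summary$location_class, "peripheral")
  # innermost point -> central (d = 1)
  centre <- classify_location(mk(47.5, 47.5), mask)
  expect_identical(centre$summary$location_class, "central")
  expect_equal(centre$summary$edge_dist_norm, 1, tolerance = 0.05)
  # outside the mask -> warned, peripheral
  expect_warning(out <- classify_location(mk(2, 2), mask), "outside")
  expect_identical(out$summary$location_class, "peripheral")
})

test_that("classification agrees with the generator's labels", {
  ch <- get_tiny_chain()
  s <- ch$tracks$summary
  tru <- ch$movie$truth$summary
  idx <- sapply(seq_len(nrow(s)), function(i)
    which.min((tru$centroid_row - s$centroid_row[i])^2 +
              (tru$centroid_col - s$centroid_col[i])^2))
  d <- sqrt((tru$centroid_row[idx] - s$centroid_row)^2 +
            (tru$centroid_col[idx] - s$centroid_col)^2)
  ok <- d < 4
  expect_gte(sum(ok), nrow(tru) - 1)
  agree <- mean(s$location_class[ok] == tru$location_class[idx[ok]])
  expect_gte(agree, 0.95)
})

test_that("lifespan table converts frames to minutes", {
  rec <- fake_records(list(list(row = 10, col = 10, frames = 4:9)), 20)
  tr <- link_tracks(rec, 0.25, n_frames = 20)
  lt <- lifespan_table(tr, frame_interval = 3, drug_frame = 5)
  expect_equal(lt$birth_min, 12)
  expect_equal(lt$lifespan_min, 18)       # frames [4, 10) at 3 min
  expect_true(lt$alive_at_drug)
  empty <- link_tracks(rec[0, ], 0.25, n_frames = 5)
  expect_identical(nrow(lifespan_table(empty, 3)), 0L)
})

test_that("lifespans order by decay group across synthetic movies", {
  taus <- c(fast = 7.5, slow = 26.5)
  med <- sapply(names(taus), function(g) {
    cfg <- movie_config(frame_shape = c(96, 96), cell_axes = c(40, 36),
                        n_frames = 40, drug_frame = 3, n_peripheral = 5,
                        n_central = 0, protein_group = g, seed = 13)
    mv <- generate_movie(cfg)
    seg <- segment_movie(mv)
    tr <- link_tracks(seg$records, mv$pixel_size, n_frames = 40)
    lt <- lifespan_table(tr, mv$frame_interval, mv$drug_frame)
    median(lt$lifespan_min[lt$alive_at_drug])
  })
  expect_lt(med["fast"], med["slow"])
})
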