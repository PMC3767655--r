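# Shared fixtures, built once per session and cached; all synthetic, seeded.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# small noisy mid-group movie + full segmentation/tracking, reused widely
tiny_movie_config <- function(...) {
  movie_config(frame_shape = c(112, 112), cell_axes = c(50, 42),
               n_frames = 30, drug_frame = 4,
               n_peripheral = 6, n_central = 4,
               protein_group = "mid", seed = 42, ...)
}

get_tiny_movie <- function() fixture("tiny_movie", function() {
  generate_movie(tiny_movie_config())
})

get_tiny_chain <- function() fixture("tiny_chain", function() {
  mv <- get_tiny_movie()
  seg <- segment_movie(mv)
  tracks <- link_tracks(seg$records, mv$pixel_size,
                        n_frames = dim(mv$frames)[3])
  tracks <- classify_location(tracks, mv$cell_mask)
  list(movie = mv, seg = seg, tracks = tracks)
})

# noiseless movie with homogeneous blobs whose segmentation threshold is
# matched to the 5% ground-truth death criterion
noiseless_movie_config <- function(...) {
  movie_config(frame_shape = c(112, 112), cell_axes = c(50, 42),
               n_frames = 32, drug_frame = 4,
               n_peripheral = 6, n_central = 4,
               protein_group = "mid",
               shot_noise = FALSE, read_noise_sd = 0, photobleach_tau = Inf,
               peak_range = c(650, 650),
               major_range_um = c(1.8, 1.8), aspect_range = c(2.5, 2.5),
               seed = 11, ...)
}

# segmentation threshold matching the generator's death criterion: 5% of the
# (smoothing-attenuated) blob peak
death_matched_seg_config <- function(cfg, smoothing_sigma = 1) {
  sa <- cfg$major_range_um[1] / cfg$pixel_size / 2.355
  sb <- sa / cfg$aspect_range[1]
  att <- (sa * sb) / sqrt((sa^2 + smoothing_sigma^2) * (sb^2 + smoothing_sigma^2))
  segment_config(abs_threshold = cfg$death_threshold * cfg$peak_range[1] * att,
                 min_area_um2 = 0.05)
}

postbleach_intensity <- function(cv) {
  bi <- attr(cv, "bleach_index")
  cv$intensity[bi:nrow(cv)]
}

# standard FRAP ground truth used across FRAP tests (pools consistent with
# the rates: N_FA / N_C = k_on / k_off)
std_frap_params <- function(k_on = 0.01, k_off = 0.005, D_C = 1.2, ...) {
  exchange_params(D_C = D_C, k_on = k_on, k_off = k_off,
                  N_FA = 1000 * k_on / max(k_off, k_on, 1e-12),
                  N_C = 1000 * k_off / max(k_off, k_on, 1e-12),
                  K_bleach = calibrate_bleach_depth(0.6), ...)
}

get_noiseless_exchange_curve <- function() fixture("noiseless_exchange", function() {
  p <- std_frap_params()
  simulate_recovery(p, frap_times(t_end = 6 / p$k_off))
})
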