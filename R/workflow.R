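# deterministic fan-out of one user seed into per-module child seeds
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 7919 + index * 104729) %% 2147483647)
}

#' Configuration of the end-to-end synthetic relaxation experiment
#'
#' Describes a full run: for every protein (labelled by decay group), a FRAP
#' dataset and a time-lapse movie are generated from one shared kinetic
#' ground truth; the analysis chain then recovers the rates from the FRAP
#' side, the decay time constants from the imaging side, and compares the
#' predicted `exp(-K_dis t)` disassembly curve with the measured one. With
#' `simulate = FALSE`, movie TIFFs and FRAP trace CSVs are read from
#' `movie_paths` / `frap_paths` instead.
#'
#' @param out_dir output directory (created).
#' @param proteins data frame with columns `name` and `group` (each name maps
#'   to exactly one of `"fast"`, `"mid"`, `"slow"`).
#' @param seed master seed; every stage derives its own child seed from it.
#' @param simulate generate inputs (default) or load them from paths.
#' @param kon_frac ground-truth `k_on / k_off` after the drug (< 1, so
#'   proteins are in a disassembly state); ties the FRAP world to the movie
#'   world via `K_dis = k_off (1 - kon_frac) = 1 / tau`.
#' @param frap list of FRAP-side options: `noise_sd`, `n_curves`, `D_C`,
#'   `N_C`.
#' @param movie named list of [movie_config()] overrides.
#' @param segmentation named list of [segment_config()] overrides.
#' @param tracking list with `max_displacement_um`, `max_gap_frames`.
#' @param comparison list with `t_max` (min).
#' @param movie_paths,frap_paths named character vectors (per protein) used
#'   when `simulate = FALSE`.
#' @param write_movies also write the generated movies as multi-page TIFFs.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("fadyn-run-"),
                            proteins = data.frame(
                              name = c("zyxin", "paxillin", "vinculin"),
                              group = c("fast", "mid", "slow")),
                            seed = 1,
                            simulate = TRUE,
                            kon_frac = 0.5,
                            frap = list(noise_sd = 0.01, n_curves = 25,
                                        D_C = 1.2, N_C = 1000),
                            movie = list(),
                            segmentation = list(),
                            tracking = list(max_displacement_um = 1,
                                            max_gap_frames = 1),
                            comparison = list(t_max = 60),
                            movie_paths = NULL, frap_paths = NULL,
                            write_movies = FALSE) {
  stopifnot(is.data.frame(proteins), all(c("name", "group") %in% names(proteins)))
  if (anyDuplicated(proteins$name))
    stop("every protein label must map to exactly one group")
  if (!all(proteins$group %in% c("fast", "mid", "slow")))
    stop("protein groups must be fast, mid or slow")
  if (kon_frac <= 0 || kon_frac >= 1) stop("'kon_frac' must be in (0, 1)")
  structure(as.list(environment()), class = "pipeline_config")
}

validate_pipeline_config <- function(config) {
  if (!config$simulate) {
    for (p in config$proteins$name) {
      mp <- config$movie_paths[[p]]; fp <- config$frap_paths[[p]]
      if (is.null(mp) || !file.exists(mp))
        stop(sprintf("missing movie path for protein '%s'", p))
      if (is.null(fp) || !file.exists(fp))
        stop(sprintf("missing FRAP trace path for protein '%s'", p))
    }
  }
  invisible(TRUE)
}

analyze_movie_side <- function(movie, seg_cfg, trk, comparison) {
  seg <- segment_movie(movie, seg_cfg)
  tracks <- link_tracks(seg$records, movie$pixel_size,
                        max_displacement_um = trk$max_displacement_um,
                        max_gap_frames = trk$max_gap_frames,
                        n_frames = dim(movie$frames)[3])
  tracks <- classify_location(tracks, movie$cell_mask)
  bleach <- estimate_bleach_correction(movie, movie$cell_mask, seg$labels)
  surv <- survival_curve(tracks, movie$drug_frame, movie$frame_interval,
                         n_frames = dim(movie$frames)[3])
  inten <- intensity_decay_curve(tracks, movie$drug_frame,
                                 movie$frame_interval,
                                 movie = movie, labels = seg$labels,
                                 bleach_factors = bleach)
  # the headline per-protein time constants refer to peripheral FAs; central
  # ones decay `central_speedup` times faster and are reported separately
  inten_per <- intensity_decay_curve(tracks, movie$drug_frame,
                                     movie$frame_interval,
                                     movie = movie, labels = seg$labels,
                                     bleach_factors = bleach,
                                     location = "peripheral")
  inten_cen <- tryCatch(
    intensity_decay_curve(tracks, movie$drug_frame, movie$frame_interval,
                          movie = movie, labels = seg$labels,
                          bleach_factors = bleach, location = "central"),
    error = function(e) NULL)
  list(tracks = tracks, bleach = bleach, survival = surv, intensity = inten,
       intensity_peripheral = inten_per, intensity_central = inten_cen,
       tau_fit = fit_single_exponential(inten_per),
       tau_fit_central = if (!is.null(inten_cen))
         fit_single_exponential(inten_cen) else NULL)
}

#' Run the end-to-end synthetic relaxation experiment
#'
#' Stages, in order: simulate (or load) inputs, segment, track, classify,
#' bleach-correct, build survival and intensity-decay curves, fit decay time
#' constants, fit the FRAP exchange model, form `K_dis = k_off - k_on`,
#' generate the predicted disassembly curve and compare it with the measured
#' one. All outputs (curves CSV, fits JSON, comparison report JSON) are
#' written under `config$out_dir` together with the configuration, its MD5
#' hash and the package version; a given seed reproduces the run exactly.
#'
#' @param config a [pipeline_config()].
#' @return The report bundle (list), invisibly also written to
#'   `out_dir/report.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  validate_pipeline_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- "setup"
  result <- tryCatch({
    seg_cfg <- do.call(segment_config, config$segmentation)
    per_protein <- list()
    predicted <- list(); measured <- list()
    taus <- c(fast = 7.5, mid = 16, slow = 26.5)
    for (i in seq_len(nrow(config$proteins))) {
      p <- config$proteins$name[i]; grp <- config$proteins$group[i]
      tau <- taus[[grp]]
      K_dis_true <- 1 / tau                      # 1/min
      k_off_s <- K_dis_true / 60 / (1 - config$kon_frac)
      k_on_s <- config$kon_frac * k_off_s
      stage <- sprintf("frap:%s", p)
      if (config$simulate) {
        N_C <- config$frap$N_C
        params <- exchange_params(D_C = config$frap$D_C, k_on = k_on_s,
                                  k_off = k_off_s, N_FA = N_C * config$kon_frac,
                                  N_C = N_C,
                                  K_bleach = calibrate_bleach_depth(0.6))
        times <- frap_times(t_end = 6 / k_off_s)
        ds <- generate_frap_dataset(params, times,
                                    noise_sd = config$frap$noise_sd,
                                    n_curves = config$frap$n_curves,
                                    seed = derive_seed(config$seed, 10 + i))
        traces <- ds$curves
      } else {
        traces <- read_frap_csv(config$frap_paths[[p]])
      }
      avg <- normalize_and_average(traces)
      efit <- fit_exchange(avg, D_C = config$frap$D_C,
                           N_FA = config$frap$N_C * config$kon_frac,
                           N_C = config$frap$N_C)
      kdis <- compute_kdis(efit$k_on * 60, efit$k_off * 60, protein = p)
      stage <- sprintf("movie:%s", p)
      if (config$simulate) {
        mv_cfg <- do.call(movie_config, modifyList(
          list(protein_group = grp, seed = derive_seed(config$seed, 20 + i)),
          config$movie))
        movie <- generate_movie(mv_cfg)
        if (config$write_movies)
          write_tiff16(movie$frames,
                       file.path(config$out_dir, paste0(p, "-movie.tif")))
      } else {
        frames <- read_tiff16(config$movie_paths[[p]])
        mv_cfg <- do.call(movie_config, config$movie)
        movie <- structure(list(frames = frames,
                                pixel_size = mv_cfg$pixel_size,
                                frame_interval = mv_cfg$frame_interval,
                                drug_frame = mv_cfg$drug_frame,
                                cell_mask = generate_cell_mask(mv_cfg),
                                truth = NULL, config = mv_cfg),
                           class = "fa_movie")
      }
      stage <- sprintf("analyze:%s", p)
      ana <- analyze_movie_side(movie, seg_cfg, config$tracking,
                                config$comparison)
      pred <- predicted_disassembly(kdis, ana$intensity_peripheral$time_min)
      predicted[[p]] <- pred
      measured[[p]] <- ana$intensity_peripheral
      per_protein[[p]] <- list(
        group = grp, tau_true = if (config$simulate) tau else NA,
        frap_fit = list(k_on_per_s = efit$k_on, k_off_per_s = efit$k_off,
                        R_f = efit$R_f, T_half_s = efit$T_half,
                        converged = efit$converged),
        K_dis_per_min = kdis$K_dis, state = kdis$state,
        tau_measured_min = ana$tau_fit$tau,
        tau_measured_central_min = if (!is.null(ana$tau_fit_central))
          ana$tau_fit_central$tau else NA,
        n_tracks = nrow(ana$tracks$summary))
      curves <- rbind(
        data.frame(protein = p, kind = "survival",
                   time_min = ana$survival$time_min, value = ana$survival$value),
        data.frame(protein = p, kind = "intensity",
                   time_min = ana$intensity$time_min, value = ana$intensity$value),
        data.frame(protein = p, kind = "predicted",
                   time_min = pred$time_min, value = pred$value))
      write.csv(curves, file.path(config$out_dir, paste0(p, "-curves.csv")),
                row.names = FALSE)
    }
    stage <- "comparison"
    report <- disassembly_report(predicted, measured,
                                 t_max = config$comparison$t_max)
    cfg_path <- file.path(config$out_dir, "config.json")
    cfg_out <- config[setdiff(names(config), c("proteins", "out_dir"))]
    cfg_out$proteins <- as.list(config$proteins)
    jsonlite::write_json(cfg_out, cfg_path, auto_unbox = TRUE, digits = NA,
                         force = TRUE)
    bundle <- list(
      package_version = as.character(utils::packageVersion("fadyn")),
      config_md5 = unname(tools::md5sum(cfg_path)),
      seed = config$seed,
      per_protein = per_protein,
      comparison = list(per_protein = report$per_protein,
                        kendall_concordance = report$kendall_concordance))
    jsonlite::write_json(bundle, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    bundle
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(result)
}
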