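#' Generate synthetic FRAP curves with known ground truth
#'
#' Each curve is the noiseless forward solution of the diffusion-exchange
#' model ([simulate_recovery()]) plus i.i.d. Gaussian noise relative to the
#' normalized intensity. Identical `(params, seed)` reproduce identical
#' curves.
#'
#' @param params an [exchange_params()] ground truth.
#' @param times sample times, s (>= 3 pre-bleach samples).
#' @param noise_sd relative Gaussian noise SD per sample (>= 0).
#' @param n_curves number of curves (>= 1).
#' @param seed RNG seed.
#' @return A list with `curves` (list of [frap_curve()]s; noise leaves the
#'   pre-bleach segment un-renormalized so these behave like raw traces) and
#'   `truth` (list with `params`, `noise_sd`, `seed`).
#' @export
generate_frap_dataset <- function(params, times, noise_sd = 0.02,
                                  n_curves = 25, seed = 1) {
  stopifnot(inherits(params, "exchange_params"))
  if (n_curves < 1) stop("'n_curves' must be >= 1")
  stop_if_negative(noise_sd = noise_sd)
  clean <- simulate_recovery(params, times)
  bi <- attr(clean, "bleach_index")
  curves <- with_seed(seed, {
    lapply(seq_len(n_curves), function(i) {
      y <- clean$intensity + if (noise_sd > 0)
        rnorm(nrow(clean), sd = noise_sd) else 0
      frap_curve(clean$time_s, y, bleach_index = bi, normalized = FALSE)
    })
  })
  list(curves = curves,
       truth = list(params = params, noise_sd = noise_sd, seed = seed))
}

#' Write/read FRAP traces as CSV
#'
#' Long-format CSV with columns `curve`, `time_s`, `intensity`,
#' `is_prebleach`.
#'
#' @param curves list of [frap_curve()]s.
#' @param path CSV file path.
#' @return `write_frap_csv` the path invisibly; `read_frap_csv` a list of
#'   [frap_curve()]s.
#' @export
write_frap_csv <- function(curves, path) {
  rows <- do.call(rbind, lapply(seq_along(curves), function(i) {
    cv <- curves[[i]]
    data.frame(curve = i, time_s = cv$time_s, intensity = cv$intensity,
               is_prebleach = cv$is_prebleach)
  }))
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_frap_csv
#' @export
read_frap_csv <- function(path) {
  df <- read.csv(path)
  lapply(split(df, df$curve), function(d) {
    bi <- which(!d$is_prebleach)[1]
    frap_curve(d$time_s, d$intensity, bleach_index = bi, normalized = FALSE)
  })
}

#' Default FRAP sampling grid
#'
#' Pre-bleach samples, a dense early post-bleach segment resolving the
#' diffusive phase, then sparser sampling out to `t_end` for the slow
#' exchange phase.
#'
#' @param t_end last post-bleach time, s.
#' @param n_pre number of pre-bleach samples.
#' @param n_early,n_late early (0-5 s, linear) and late (log-spaced) sample
#'   counts.
#' @return Numeric vector of times (s), bleach at t = 0.
#' @export
frap_times <- function(t_end = 300, n_pre = 5, n_early = 40, n_late = 80) {
  pre <- seq(-n_pre, -1) * 0.5
  early <- seq(0, 5, length.out = n_early)
  late <- exp(seq(log(5.5), log(t_end), length.out = n_late))
  c(pre, early, late)
}
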