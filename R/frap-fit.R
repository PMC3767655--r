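#' Fit the cytoplasmic diffusion coefficient from a short-timescale FRAP curve
#'
#' On a 2-3 s timescale the contribution of slow binding exchange to the
#' recovery is negligible, so the curve is fitted with the pure-diffusion
#' closed-form series ([pure_diffusion_recovery()]) over `(D, K_bleach)` by
#' least squares. Samples beyond `t_max` are ignored.
#'
#' @param curve a [frap_curve()].
#' @param w Gaussian spot e^-2 radius, um.
#' @param t_max post-bleach window to fit, s (default 3).
#' @return A list with `D` (um^2/s), `K_bleach`, `ci_D` (approximate 95%
#'   interval), `ssr` and `converged`.
#' @export
fit_diffusion <- function(curve, w, t_max = 3) {
  pb <- postbleach(curve)
  keep <- pb$t <= t_max
  t <- pb$t[keep]; y <- pb$y[keep]
  if (length(t) < 4) stop("need at least 4 post-bleach samples within t_max")
  F0 <- y[1]
  if (F0 >= 1 || sd(y) < 1e-12) {
    return(list(D = NA_real_, K_bleach = NA_real_, ci_D = c(NA, NA),
                ssr = NA_real_, converged = FALSE))
  }
  K0 <- tryCatch(calibrate_bleach_depth(min(max(1 - F0, 0.02), 0.95)),
                 error = function(e) 1)
  obj <- function(p) {
    Fm <- pure_diffusion_recovery(exp(p[1]), w, exp(p[2]), t)
    sum((Fm - y)^2)
  }
  fit <- optim(c(log(1), log(K0)), obj, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-12), hessian = TRUE)
  se_logD <- tryCatch({
    n <- length(t)
    s2 <- fit$value / max(n - 2, 1)
    sqrt(2 * s2 * diag(solve(fit$hessian))[1])
  }, error = function(e) NA_real_)
  D <- exp(fit$par[1])
  list(D = D, K_bleach = exp(fit$par[2]),
       ci_D = D * exp(c(-1.96, 1.96) * se_logD),
       ssr = fit$value, converged = fit$convergence == 0)
}

#' Fit apparent k_on and k_off with the full diffusion-exchange model
#'
#' Least-squares fit of [simulate_recovery()] to a normalized averaged FRAP
#' curve with the cytoplasmic diffusion coefficient and the measured pools
#' entered as fixed inputs (the published procedure, which stabilizes the
#' fit); free parameters are `k_on`, `k_off` and the bleach depth `K_bleach`.
#' The likelihood surface of diffusion-exchange fits is multi-modal, so a
#' multi-start strategy is used: a 4 x 4 logarithmic grid over `k_on, k_off in
#' [1e-4, 1e-1] /s` plus one start at the pool-implied ratio
#' `k_on = k_off * N_FA / N_C` is screened, and the best `n_polish` starts are
#' refined with Nelder-Mead in log space. The lowest-SSR solution wins; ties
#' are broken toward smaller `k_off`.
#'
#' @param curve a [frap_curve()] (normalized, averaged).
#' @param D_C fixed cytoplasmic diffusion coefficient, um^2/s.
#' @param N_FA,N_C fixed molecule pools over the FA footprint (used to place
#'   starting values; see Details of [exchange_params()]).
#' @param w Gaussian spot e^-2 radius, um.
#' @param r_FA adhesion disc radius, um.
#' @param n_polish number of screened starts refined by the optimizer.
#' @param dr radial grid spacing for the forward model, um.
#' @return An object of class `exchange_fit`: list with `k_on`, `k_off`,
#'   `K_bleach` (1/s, 1/s, unitless), `ssr`, `R_f`, `T_half`, `converged`,
#'   `n_starts_agreeing`, `at_boundary` and the `fitted_curve`.
#' @export
fit_exchange <- function(curve, D_C, N_FA, N_C, w = 0.385, r_FA = 0.56,
                         n_polish = 3, dr = NULL) {
  stop_if_negative(D_C = D_C, N_FA = N_FA, N_C = N_C)
  pb <- postbleach(curve)
  t_post <- pb$t; y <- pb$y
  t_model <- c(-3, -2, -1, t_post)     # model needs a pre-bleach segment
  F0 <- y[1]
  K0 <- tryCatch(calibrate_bleach_depth(min(max(1 - F0, 0.02), 0.95)),
                 error = function(e) 1)
  forward <- function(k_on, k_off, K) {
    p <- exchange_params(D_C = D_C, D_M = 0, k_on = k_on, k_off = k_off,
                         N_FA = N_FA, N_C = N_C, w = w, K_bleach = K,
                         r_FA = r_FA)
    cv <- simulate_recovery(p, t_model, dr = dr)
    postbleach(cv)$y
  }
  ssr_of <- function(k_on, k_off, K) {
    ym <- tryCatch(forward(k_on, k_off, K), error = function(e) NULL)
    if (is.null(ym)) return(Inf)
    sum((ym - y)^2)
  }
  grid <- 10^seq(-4, -1, length.out = 4)
  starts <- expand.grid(k_on = grid, k_off = grid)
  if (N_C > 0 && N_FA > 0) {
    ratio <- N_FA / N_C
    extra <- data.frame(k_on = pmin(pmax(grid * ratio, 1e-5), 1), k_off = grid)
    starts <- rbind(starts, extra)
  }
  screen <- vapply(seq_len(nrow(starts)), function(i)
    ssr_of(starts$k_on[i], starts$k_off[i], K0), numeric(1))
  ord <- order(screen, starts$k_off)
  polish_idx <- head(ord[is.finite(screen[ord])], n_polish)
  results <- list()
  for (i in polish_idx) {
    p0 <- log(c(starts$k_on[i], starts$k_off[i], K0))
    fit <- tryCatch(
      optim(p0, function(p) ssr_of(exp(p[1]), exp(p[2]), exp(p[3])),
            method = "Nelder-Mead",
            control = list(maxit = 800, reltol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(fit)) results[[length(results) + 1]] <- fit
  }
  if (length(results) == 0) {
    return(structure(list(k_on = NA_real_, k_off = NA_real_,
                          K_bleach = NA_real_, ssr = NA_real_, R_f = NA_real_,
                          T_half = NA_real_, converged = FALSE,
                          n_starts_agreeing = 0L, at_boundary = FALSE,
                          fitted_curve = NULL),
                     class = "exchange_fit"))
  }
  ssrs <- vapply(results, function(f) f$value, numeric(1))
  koffs <- vapply(results, function(f) exp(f$par[2]), numeric(1))
  best <- order(ssrs, koffs)[1]          # ties toward smaller k_off
  bf <- results[[best]]
  k_on <- exp(bf$par[1]); k_off <- exp(bf$par[2]); K <- exp(bf$par[3])
  agree <- sum(vapply(results, function(f) {
    all(abs(exp(f$par[1:2]) - c(k_on, k_off)) <= 0.05 * c(k_on, k_off))
  }, logical(1)))
  at_boundary <- k_on < 0.8e-4 || k_on > 1.25e-1 ||
                 k_off < 0.8e-4 || k_off > 1.25e-1
  if (at_boundary)
    warning("fitted rate at or beyond the multi-start grid boundary")
  fitted_y <- forward(k_on, k_off, K)
  fitted_curve <- frap_curve(c(-3, -2, -1, t_post),
                             c(1, 1, 1, fitted_y),
                             bleach_index = 4L, normalized = FALSE)
  structure(list(k_on = k_on, k_off = k_off, K_bleach = K, ssr = bf$value,
                 R_f = mobile_fraction(fitted_curve),
                 T_half = half_time(fitted_curve),
                 converged = bf$convergence == 0,
                 n_starts_agreeing = as.integer(agree),
                 at_boundary = at_boundary,
                 fitted_curve = fitted_curve),
            class = "exchange_fit")
}

#' @export
print.exchange_fit <- function(x, ...) {
  cat("Diffusion-exchange FRAP fit\n")
  cat(sprintf("  k_on  = %.4g /s\n  k_off = %.4g /s\n", x$k_on, x$k_off))
  cat(sprintf("  K_bleach = %.3g, SSR = %.3g\n", x$K_bleach, x$ssr))
  cat(sprintf("  R_f = %.3f, T_1/2 = %.3g s, converged = %s (%d starts agree)\n",
              x$R_f, x$T_half, x$converged, x$n_starts_agreeing))
  invisible(x)
}

resolve_curve <- function(x) {
  if (inherits(x, "exchange_fit")) {
    if (is.null(x$fitted_curve)) stop("fit holds no fitted curve")
    x$fitted_curve
  } else x
}

#' Mobile fraction of a FRAP curve
#'
#' `R_f = (F_plateau - F(0+)) / (1 - F(0+))`, where the plateau is the mean of
#' the last 10% of post-bleach samples (for a fitted model curve, its values
#' on the data grid). `R_f = 1` means full recovery on the observation window.
#'
#' @param x a [frap_curve()] or an `exchange_fit`.
#' @return Mobile fraction in `[0, 1]` (clamped at 0 with a warning when the
#'   plateau does not exceed the post-bleach floor).
#' @export
mobile_fraction <- function(x) {
  pb <- postbleach(resolve_curve(x))
  F0 <- pb$y[1]
  n <- length(pb$y)
  plateau <- mean(tail(pb$y, max(ceiling(0.1 * n), 1)))
  if (plateau <= F0) {
    warning("no recovery above the post-bleach floor; R_f set to 0")
    return(0)
  }
  (plateau - F0) / (1 - F0)
}

#' Half-time to recovery of a FRAP curve
#'
#' First time the curve crosses `F(0+) + 0.5 (F_plateau - F(0+))`, by linear
#' interpolation between samples.
#'
#' @inheritParams mobile_fraction
#' @return `T_half` in seconds (`NA` if the curve never crosses).
#' @export
half_time <- function(x) {
  pb <- postbleach(resolve_curve(x))
  F0 <- pb$y[1]
  n <- length(pb$y)
  plateau <- mean(tail(pb$y, max(ceiling(0.1 * n), 1)))
  target <- F0 + 0.5 * (plateau - F0)
  above <- which(pb$y >= target)
  above <- above[above > 1]
  if (length(above) == 0 || plateau <= F0) return(NA_real_)
  i <- above[1]
  t0 <- pb$t[i - 1]; t1 <- pb$t[i]
  y0 <- pb$y[i - 1]; y1 <- pb$y[i]
  if (y1 == y0) return(t1)
  t0 + (target - y0) / (y1 - y0) * (t1 - t0)
}
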