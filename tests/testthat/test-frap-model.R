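test_that("closed-form series has the right bleach depth and limits", {
  K <- calibrate_bleach_depth(0.6)
  # F(0+) = (1 - exp(-K))/K by construction
  expect_equal(pure_diffusion_recovery(1.2, 0.385, K, 0), 0.4,
               tolerance = 1e-8)
  # infinite-reservoir limit: full recovery
  expect_equal(pure_diffusion_recovery(1.2, 0.385, K, 1e7), 1,
               tolerance = 1e-3)
  # monotone recovery
  y <- pure_diffusion_recovery(1.2, 0.385, K, seq(0, 60, by = 0.25))
  expect_true(all(diff(y) > 0))
})

test_that("bleach-depth calibration covers the 50-75% operating window", {
  for (frac in c(0.5, 0.6, 0.75)) {
    K <- calibrate_bleach_depth(frac)
    expect_equal((1 - exp(-K)) / K, 1 - frac, tolerance = 1e-8)
  }
})

test_that("PDE solution matches the pure-diffusion series in the zero-binding limit", {
  K <- calibrate_bleach_depth(0.6)
  p <- exchange_params(D_C = 1.2, k_on = 0, k_off = 0, K_bleach = K)
  times <- c(-3, -2, -1, seq(0, 30, length.out = 60))
  pde <- simulate_recovery(p, times)
  ser <- pure_diffusion_recovery(1.2, p$w, K, times)
  post <- times >= 0
  expect_lt(max(abs(pde$intensity[post] - ser$intensity[post])), 0.01)
})

test_that("PDE conserves mass after the bleach", {
  p <- std_frap_params()
  cv <- simulate_recovery(p, c(-3, -2, -1, seq(0, 500, length.out = 40)))
  m <- attr(cv, "mass")
  expect_lt(max(abs(m / m[1] - 1)), 1e-3)
})

test_that("noiseless simulated recovery is non-decreasing after the bleach", {
  for (rates in list(c(0.01, 0.005), c(0.002, 0.002), c(0.001, 0.01))) {
    p <- std_frap_params(k_on = rates[1], k_off = rates[2])
    cv <- simulate_recovery(p, c(-3, -2, -1,
                                 exp(seq(log(0.01), log(6 / rates[2]),
                                         length.out = 60))))
    y <- postbleach_intensity(cv)
    expect_true(all(diff(y) > -1e-9))
  }
})

test_that("parameter validation names the offending field", {
  expect_error(exchange_params(D_C = -1), "D_C")
  expect_error(exchange_params(k_on = -0.1), "k_on")
  expect_error(exchange_params(D_M = 0.05), "D_M")
  expect_error(exchange_params(R_dom = 1), "R_dom")
  expect_error(exchange_params(k_on = 0.1, k_off = 0), "steady state")
})

test_that("simulate_recovery rejects bad grids and time vectors", {
  p <- std_frap_params()
  times <- c(-3, -2, -1, seq(0, 10, 0.5))
  expect_error(simulate_recovery(p, times, dr = p$w / 5), "grid")
  expect_error(simulate_recovery(p, c(-1, seq(0, 10, 0.5))), "pre-bleach")
})

test_that("normalization sets the pre-bleach mean to exactly 1", {
  t <- c(-3, -2, -1, seq(0, 20, 0.5))
  raw <- list(time_s = t, intensity = 350 * c(1, 1.01, 0.99, rep(0.5, 41)),
              bleach_index = 4L)
  avg <- normalize_and_average(list(raw))
  expect_equal(mean(avg$intensity[avg$is_prebleach]), 1, tolerance = 1e-12)
})

test_that("averaging identical traces reproduces the trace; gain cancels", {
  cv <- get_noiseless_exchange_curve()
  tr <- list(time_s = cv$time_s, intensity = cv$intensity * 123.4,
             bleach_index = attr(cv, "bleach_index"))
  avg <- normalize_and_average(list(tr, tr, tr))
  expect_equal(avg$intensity, cv$intensity, tolerance = 1e-9)
  expect_identical(attr(avg, "n_averaged"), 3L)
  # rescaling raw units leaves the normalized curve (hence any fit) unchanged
  tr2 <- tr; tr2$intensity <- tr$intensity * 73
  avg2 <- normalize_and_average(list(tr2, tr2, tr2))
  expect_equal(avg2$intensity, avg$intensity, tolerance = 1e-12)
})

test_that("traces bleached at different samples are aligned at the bleach point", {
  y1 <- c(1, 1, 1, 0.4, 0.5, 0.6, 0.7)
  tr1 <- list(time_s = c(-2, -1.5, -1, 0, 1, 2, 3) , intensity = y1,
              bleach_index = 4L)
  tr2 <- list(time_s = c(-3, -2.5, -2, -1.5, -1, 0, 1, 2, 3),
              intensity = c(1, 1, 1, 1, 1, 0.4, 0.5, 0.6, 0.7),
              bleach_index = 6L)
  avg <- normalize_and_average(list(tr1, tr2))
  bi <- attr(avg, "bleach_index")
  expect_equal(avg$time_s[bi], 0)
  expect_equal(avg$intensity[bi:(bi + 3)], c(0.4, 0.5, 0.6, 0.7),
               tolerance = 1e-12)
})

test_that("degenerate traces are excluded with a warning, all-excluded errors", {
  good <- list(time_s = c(-1, -0.5, 0, 1), intensity = c(2, 2, 1, 1.5),
               bleach_index = 3L)
  bad <- list(time_s = c(-1, -0.5, 0, 1), intensity = c(0, 0, 1, 1.5),
              bleach_index = 3L)
  expect_warning(avg <- normalize_and_average(list(good, bad)), "excluded")
  expect_identical(attr(avg, "n_averaged"), 1L)
  expect_error(suppressWarnings(normalize_and_average(list(bad))),
               "all traces excluded")
})

test_that("pool estimation is a linear calibration", {
  expect_equal(estimate_pools(1000, 400, 1), list(N_FA = 1000, N_C = 400))
  expect_equal(estimate_pools(0, 5, 2), list(N_FA = 0, N_C = 10))
  expect_equal(with(estimate_pools(7, 7, 3), N_FA - N_C), 0)
  expect_error(estimate_pools(-1, 1, 1), "fa_region_sum")
})
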