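test_that("a single-cycle window reduces the curvature estimator to the per-cycle form", {
  set.seed(2)
  n <- 40L
  nx <- cbind(rpois(n, 6) + 3L, rpois(n, 1), rpois(n, 6) + 3L)
  ny <- nx[, c(3, 2, 1)]
  t <- seq(0, by = 0.00123, length.out = n)
  raw <- fake_raw_trace(t, L = 50, nx = nx, ny = ny)
  ref <- sliding_curvature_estimate(raw, T_ms = 1)  # window < cycle spacing
  per_cycle <- (50 / 4) * (nx[, 1L] - nx[, 3L]) /
    (nx[, 3L] + nx[, 1L] - 2 * nx[, 2L])
  expect_equal(ref$x, per_cycle)   # centres are zero
  expect_equal(ref$y, -per_cycle)
})

test_that("identical counts give a constant refined position", {
  n <- 30L
  nx <- matrix(rep(c(8L, 1L, 4L), each = n), ncol = 3)
  raw <- fake_raw_trace(seq(0, by = 0.001, length.out = n), 50, nx, nx)
  ref <- sliding_curvature_estimate(raw, T_ms = 20)
  expect_equal(ref$x, rep(ref$x[1L], n))
  expect_length(ref$x, n)
})

test_that("curvature averaging reduces localization variance", {
  path <- static_path(16)
  raw <- run_acquisition(path, beam_config(), seed = 12)
  expect_gt(sum(raw$valid), 1e4)
  ref <- sliding_curvature_estimate(raw, T_ms = 20)
  per_cycle <- raw$est_x[raw$valid & raw$L == 50]
  expect_lt(var(ref$x), var(per_cycle))
})

test_that("principal-axis alignment puts the net movement on +x", {
  # pure y movement
  tr <- data.frame(t = 1:50, x = rnorm(50, 0, 0.01), y = seq(0, 100, length.out = 50))
  al <- align_principal_axis(tr)
  expect_gt(al$x[50] - al$x[1], 99)
  expect_lt(abs(abs(attr(al, "rotation_angle")) - pi / 2), 0.05)
  # diagonal movement: rotated by -45 degrees
  d <- seq(0, 70, length.out = 60) / sqrt(2)
  tr <- data.frame(t = 1:60, x = d, y = d)
  al <- align_principal_axis(tr)
  expect_equal(abs(attr(al, "rotation_angle")), pi / 4, tolerance = 1e-6)
  expect_lt(max(abs(al$y - mean(al$y))), 1e-9)
  # isometry: pairwise path length preserved
  set.seed(5)
  tr <- data.frame(t = 1:100, x = cumsum(rnorm(100)), y = cumsum(rnorm(100)))
  al <- align_principal_axis(tr)
  len0 <- sum(sqrt(diff(tr$x)^2 + diff(tr$y)^2))
  len1 <- sum(sqrt(diff(al$x)^2 + diff(al$y)^2))
  expect_equal(len0, len1, tolerance = 1e-10)
  expect_error(align_principal_axis(data.frame(t = 1:5, x = rep(1, 5), y = rep(2, 5))),
               "degenerate")
})

test_that("noiseless staircases are recovered exactly", {
  st <- make_staircase(c(16, 16), samples_per_plateau = 50L)
  fit <- fit_steps(st$x)
  expect_identical(fit$change_points, as.integer(st$change_points))
  expect_equal(fit$levels_on, c(0, 16, 32))
  # reconstruction error exactly zero
  expect_equal(step_function(fit), st$x)
})

test_that("noisy 8/16 nm staircases are recovered with high recall", {
  set.seed(31)
  recalls <- lvl_err <- numeric(20)
  for (r in seq_len(20)) {
    sizes <- sample(c(8, 16), 10, replace = TRUE)
    st <- make_staircase(sizes, samples_per_plateau = 30L, noise_sd = 2)
    fit <- fit_steps(st$x)
    recalls[r] <- mean(vapply(st$change_points, function(cp)
      any(abs(fit$change_points - cp) <= 2), logical(1L)))
    lvl_err[r] <- if (length(fit$levels_on) == length(st$levels))
      mean(abs(fit$levels_on - st$levels)) else NA
  }
  expect_gte(mean(recalls), 0.95)
  expect_lt(mean(lvl_err, na.rm = TRUE), 1)
})

test_that("flat noise yields no change points and spikes never become steps", {
  set.seed(8)
  flat <- rnorm(500, 0, 2)
  expect_length(fit_steps(flat)$change_points, 0L)
  spike <- c(rep(0, 120), 30, rep(0, 120))
  expect_length(fit_steps(spike)$change_points, 0L)
  # spike riding on noise
  noisy_spike <- rnorm(241, 0, 1); noisy_spike[121] <- 30
  expect_length(fit_steps(noisy_spike)$change_points, 0L)
})

test_that("steps below 2 nm are removed in a single round", {
  set.seed(9)
  st <- make_staircase(c(16, 1.5, 16), samples_per_plateau = 40L, noise_sd = 0.2)
  fit <- fit_steps(st$x)
  expect_true(all(abs(fit$steps_on) >= 2))
  # the 1.5 nm step is gone; the 16 nm neighbours remain
  expect_length(fit$steps_on, 2L)
  expect_equal(fit$steps_on, c(16, 16), tolerance = 0.8)
})

test_that("refitting a fitted step function returns it unchanged", {
  set.seed(10)
  st <- make_staircase(sample(c(8, 16), 8, replace = TRUE), 30L, noise_sd = 2)
  fit1 <- fit_steps(st$x)
  f1 <- step_function(fit1)
  fit2 <- fit_steps(f1)
  expect_identical(fit2$change_points, fit1$change_points)
  expect_equal(step_function(fit2), f1)
})

test_that("change-point count is non-increasing in the penalty", {
  set.seed(11)
  st <- make_staircase(sample(c(8, 16), 8, replace = TRUE), 20L, noise_sd = 3)
  counts <- vapply(c(0.5, 1, 2, 4, 8), function(pm)
    length(fit_steps(st$x, penalty_mult = pm)$change_points), numeric(1L))
  expect_true(all(diff(counts) <= 0))
})

test_that("step fitting commutes with global translation", {
  set.seed(12)
  st <- make_staircase(c(8, 8, 16), 30L, noise_sd = 2)
  f0 <- fit_steps(st$x)
  f1 <- fit_steps(st$x + 500)
  expect_identical(f1$change_points, f0$change_points)
  expect_equal(f1$levels_on, f0$levels_on + 500)
})

test_that("off-axis plateaus are segment means at the on-axis change points", {
  y <- rep(0, 90)
  off <- offaxis_plateaus(y, c(30L, 60L))
  expect_equal(off$levels, c(0, 0, 0))
  expect_equal(off$steps, c(0, 0))
  # a 60 nm lateral shift exactly at an on-axis change point
  y <- c(rep(0, 45), rep(60, 45))
  off <- offaxis_plateaus(y, 45L)
  expect_equal(off$steps, 60)
  # random series: plateau level equals the arithmetic mean of its segment
  set.seed(13)
  y <- rnorm(100)
  off <- offaxis_plateaus(y, c(20L, 50L))
  expect_equal(off$levels,
               c(mean(y[1:20]), mean(y[21:50]), mean(y[51:100])))
  expect_error(offaxis_plateaus(y, c(50L, 20L)), "strictly increasing")
  expect_error(offaxis_plateaus(y, 100L), "strictly increasing")
})

test_that("trace QC passes clean traces and fails drowned ones", {
  set.seed(14)
  p <- kinetic_params(tau_2HB = 9, tau_1HB = 40, detach_rate = 0)
  path <- simulate_motor_path(p, 1.5)
  raw <- run_acquisition(path, beam_config(), seed = 15)
  ref <- align_principal_axis(sliding_curvature_estimate(raw))
  fit <- fit_trace_steps(ref)
  qc <- trace_qc(raw, ref, fit, qc_thresholds(min_photons = 5, min_sbr = 2,
                                              max_precision_nm = 5))
  expect_true(qc$pass)
  expect_lte(qc$metrics$mean_precision_nm, 5)
  # background-dominated acquisition fails on SBR
  raw_bg <- run_acquisition(static_path(0.3),
                            beam_config(brightness = 0.002, background = 8),
                            seed = 16)
  ref_bg <- sliding_curvature_estimate(raw_bg)
  ref_bg$y <- ref_bg$y + seq(0, 1e-3, length.out = nrow(ref_bg))  # non-degenerate
  al_bg <- align_principal_axis(ref_bg)
  fit_bg <- fit_trace_steps(al_bg)
  qc_bg <- trace_qc(raw_bg, al_bg, fit_bg, qc_thresholds(min_sbr = 2))
  expect_false(qc_bg$pass)
  expect_lt(qc_bg$metrics$mean_sbr, 2)
  # all-zero thresholds always pass
  expect_true(trace_qc(raw_bg, al_bg, fit_bg, qc_thresholds())$pass)
})
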