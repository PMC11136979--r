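test_that("the bound-dwell density is a proper density with mean 2*tau2 + tau1", {
  for (taus in list(c(6, 9), c(9, 6), c(6, 6), c(4, 15), c(10, 9.999))) {
    tau1 <- taus[1L]; tau2 <- taus[2L]
    f <- function(t) dwell_bound_density(t, tau1, tau2)
    expect_gte(min(f(seq(0.001, 300, by = 0.05))), 0)
    expect_equal(integrate(f, 0, Inf)$value, 1, tolerance = 1e-6)
    m <- integrate(function(t) t * f(t), 0, Inf)$value
    expect_equal(m, 2 * tau2 + tau1, tolerance = 1e-4)
  }
  # continuous through the tau1 = tau2 degeneracy
  t <- seq(0.1, 100, by = 0.1)
  d_lo <- dwell_bound_density(t, 9 * (1 - 1e-7), 9)
  d_hi <- dwell_bound_density(t, 9 * (1 + 1e-7), 9)
  expect_equal(d_lo, d_hi, tolerance = 1e-5)
  # generative form matches the density (moment check)
  set.seed(20)
  s <- rdwell_bound(2e4, 6, 9)
  expect_lt(abs(mean(s) - 24), 3 * sd(s) / sqrt(length(s)))
})

test_that("the unbound-only MLE is the sample mean in closed form", {
  set.seed(21)
  u <- rexp(500, 1 / 6)
  fit <- fit_dwell_model(u)
  expect_equal(fit$tau_1HB, mean(u), tolerance = 1e-12)
  expect_true(is.na(fit$tau_2HB))
})

test_that("the joint dwell fit recovers its generating parameters", {
  set.seed(22)
  u <- rdwell_unbound(2000, 6)
  b <- rdwell_bound(2000, 6, 9)
  fit <- fit_dwell_model(u, b)
  expect_lt(abs(fit$tau_1HB - 6) / 6, 0.1)
  expect_lt(abs(fit$tau_2HB - 9) / 9, 0.1)
  expect_true(fit$se_tau_1HB > 0 && fit$se_tau_2HB > 0)
  # optimizer never degrades the moment-based start
  nll0 <- -sum(dwell_unbound_density(u, mean(u), log = TRUE)) -
    sum(dwell_bound_density(b, mean(u), (mean(b) - mean(u)) / 2, log = TRUE))
  expect_gte(fit$loglik, -nll0)
})

test_that("degenerate dwell inputs are rejected", {
  expect_error(fit_dwell_model(numeric(0)), "non-empty")
  expect_error(fit_dwell_model(c(1, 2, -3)), "positive")
  expect_error(fit_dwell_model(c(1, 2, 3), c(1, 2, 3, 4, 5)), "at least 5")
})

test_that("the rational velocity relation is recovered from noiseless points", {
  v <- c(232, 541, 297)
  t1 <- 1000 * 9.1 / v - 8.8
  fit <- fit_velocity_relation(v, t1)
  expect_equal(fit$dx_nm, 9.1, tolerance = 1e-9)
  expect_equal(fit$t_2HB_ms, 8.8, tolerance = 1e-9)
  expect_lt(max(abs(fit$residuals)), 1e-10)
  # two points: exact interpolation
  fit2 <- fit_velocity_relation(v[1:2], t1[1:2] + c(1, -1))
  expect_lt(max(abs(fit2$residuals)), 1e-10)
  # fitted curve is monotone decreasing in v (dx > 0)
  expect_gt(fit$dx_nm, 0)
  expect_error(fit_velocity_relation(c(300, 300), c(1, 2)), "singular")
})

test_that("trace velocity is net displacement over duration", {
  fit <- make_step_fit(levels_on = c(0, 80, 160), dwells = c(0.2, 0.2, 0.1))
  expect_equal(trace_velocity(fit), 160 / 0.5)
  expect_equal(trace_velocity(make_step_fit(5, dwells = 1)), 0)
  # simulated path: velocity near the renewal prediction
  set.seed(23)
  p <- kinetic_params(tau_2HB = 9, tau_1HB = 6, detach_rate = 0)
  path <- simulate_motor_path(p, 1.5)  # ~100 cycles
  v <- trace_velocity(path_step_fit(path))
  expect_lt(abs(v - 16000 / 15) / (16000 / 15), 0.15)
})

test_that("off-axis pair collection pairs B-U steps with the following U-B step", {
  states <- structure(list(labels = c("B", "U", "B", "B", "U", "B"),
                           loglik = 0), class = "state_sequence")
  fit <- make_step_fit(levels_on = cumsum(c(0, 8, 8, 16, 8, 8)),
                       levels_off = cumsum(c(0, 2, -2, 0, 3, -1)))
  pr <- substep_offaxis_pairs(states, fit)
  expect_equal(unname(pr), cbind(c(2, 3), c(-2, -1)))
})

test_that("off-axis correlation summaries match their construction", {
  a <- c(-3, -1, 0.5, 2, 4)
  oc <- offaxis_correlation(cbind(a, -a))
  expect_equal(oc$correlation, -1)
  expect_equal(min(oc$semi_axes), 0, tolerance = 1e-9)
  # degenerate ellipse along the anti-diagonal (eigenvector sign is arbitrary)
  expect_lt(min(abs(abs(oc$orientation) - c(pi / 4, 3 * pi / 4))), 1e-9)
  # independent isotropic pairs: near-zero correlation, near-circular ellipse
  set.seed(24)
  pr <- matrix(rnorm(2e4), ncol = 2)
  oc <- offaxis_correlation(pr)
  expect_lt(abs(oc$correlation), 0.1)
  expect_lt(abs(oc$semi_axes[1L] / oc$semi_axes[2L] - 1), 0.1)
  expect_error(offaxis_correlation(pr[1:2, ]), "at least 3")
})

test_that("simulated off-axis pairing is recovered through the pipeline objects", {
  set.seed(25)
  p <- kinetic_params(tau_2HB = 9, tau_1HB = 6, offaxis_corr = 0.5,
                      detach_rate = 0)
  pairs <- NULL
  while (is.null(pairs) || nrow(pairs) < 2000) {
    path <- simulate_motor_path(p, 10)
    fit <- path_step_fit(path)
    st <- structure(list(labels = ifelse(path$events$state == "1HB", "U", "B"),
                         loglik = 0), class = "state_sequence")
    pairs <- rbind(pairs, substep_offaxis_pairs(st, fit))
  }
  r <- offaxis_correlation(pairs[1:2000, ])$correlation
  expect_lt(abs(r - 0.5), 0.06)
})

test_that("microtubule switches are detected from off-axis jumps and reversals", {
  # one injected 60 nm lateral jump
  fit <- make_step_fit(levels_on = cumsum(c(0, rep(16, 6))),
                       levels_off = c(0, 0, 0, 60, 60, 60, 60))
  ev <- detect_switches(fit)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$offaxis_jump, 60)
  expect_false(ev$direction_reversed)
  # all lateral steps below the microtubule diameter: nothing flagged
  fit <- make_step_fit(levels_on = cumsum(c(0, rep(16, 6))),
                       levels_off = cumsum(c(0, 10, -10, 8, -4, 6, 2)))
  expect_equal(nrow(detect_switches(fit)), 0L)
  # direction reversal without any off-axis jump
  fit <- make_step_fit(levels_on = c(0, 16, 32, 48, 32, 16, 0, -16),
                       levels_off = rep(0, 8))
  ev <- detect_switches(fit)
  expect_equal(nrow(ev), 1L)
  expect_true(ev$direction_reversed)
  expect_lt(abs(ev$offaxis_jump), 25)
  # a single back-step is not a reversal
  fit <- make_step_fit(levels_on = c(0, 16, 32, 16, 32, 48, 64),
                       levels_off = rep(0, 7))
  expect_equal(nrow(detect_switches(fit)), 0L)
})
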