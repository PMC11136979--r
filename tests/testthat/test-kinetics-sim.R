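test_that("presets encode the construct geometry and ATP-dependent kinetics", {
  for (atp in c("low", "mid", "high")) {
    k <- make_preset("K28C", atp)
    t <- make_preset("T324C", atp)
    expect_equal(k$substep1_mean, 8)
    expect_equal(k$substep2_mean, 8)
    expect_equal(t$substep1_mean, 6)
    expect_equal(t$substep2_mean, 10)
    expect_lt(t$substep1_mean, t$substep2_mean)
    # binding-site periodicity for every preset
    expect_equal(k$substep1_mean + k$substep2_mean, 16)
    expect_equal(t$substep1_mean + t$substep2_mean, 16)
  }
  # ATP binds in the 1HB state: its dwell shortens at higher ATP
  expect_lt(make_preset("K28C", "mid")$tau_1HB,
            make_preset("K28C", "low")$tau_1HB)
  expect_error(make_preset("K99C", "low"), "K28C, T324C")
  expect_error(make_preset("K28C", "huge"), "low, mid, high")
})

test_that("kinetic parameter validation rejects inconsistent inputs", {
  expect_error(kinetic_params(tau_2HB = -1, tau_1HB = 5), "positive")
  expect_error(kinetic_params(9, 6, substep1_mean = 7, substep2_mean = 8),
               "16 nm")
  expect_error(kinetic_params(9, 6, offaxis_corr = 1.5), "\\[-1, 1\\]")
  expect_error(kinetic_params(9, 6, reversal_prob = 2), "\\[0, 1\\]")
  expect_error(simulate_motor_path(kinetic_params(9, 6), -1), "positive")
})

test_that("a path without switching or detachment stays on one microtubule", {
  p <- kinetic_params(tau_2HB = 9, tau_1HB = 6, switch_rate = 0,
                      detach_rate = 0, seed = 11)
  path <- simulate_motor_path(p, 2)
  expect_true(all(path$events$mt_id == 1L))
  expect_equal(path$duration, 2)
  expect_true(all(diff(path$events$time) > 0))
  # plus-end directed: on-axis positions never decrease without a switch
  expect_true(all(diff(path$events$x_on) >= 0))
  # states alternate through 2HB / 1HB
  expect_true(all(path$events$state %in% c("2HB", "1HB")))
})

test_that("certain reversal at a switch flips the on-axis direction", {
  p <- kinetic_params(tau_2HB = 9, tau_1HB = 6, switch_rate = 0.9,
                      reversal_prob = 1, detach_rate = 0, seed = 5)
  path <- simulate_motor_path(p, 4)
  ev <- path$events
  sw <- which(diff(ev$mt_id) > 0) + 1L
  expect_gt(length(sw), 0L)
  s1 <- sw[1L]
  inc_before <- diff(ev$x_on[1:s1])
  after <- ev$x_on[s1:min(nrow(ev), s1 + 10L)]
  until_next <- which(diff(ev$mt_id[s1:nrow(ev)]) > 0)[1L]
  if (!is.na(until_next) && until_next < 10L) after <- ev$x_on[s1:(s1 + until_next - 1L)]
  expect_true(all(inc_before[inc_before != 0] > 0))
  expect_true(all(diff(after) <= 0))
})

test_that("simulation is bit-reproducible under a fixed seed", {
  p <- kinetic_params(tau_2HB = 9, tau_1HB = 6, switch_rate = 0.5,
                      detach_rate = 0.2, seed = 123)
  a <- simulate_motor_path(p, 3)
  b <- simulate_motor_path(p, 3)
  expect_identical(a$events, b$events)
  expect_identical(a$duration, b$duration)
})

test_that("dwell means, cycle displacement and velocity match the renewal model", {
  p <- kinetic_params(tau_2HB = 9, tau_1HB = 6, detach_rate = 0, seed = 42)
  # >= 1e4 full cycles at 15 ms/cycle
  path <- simulate_motor_path(p, 160)
  ev <- path$events
  dt <- diff(ev$time) * 1000  # ms
  st <- ev$state[-nrow(ev)]
  d2 <- dt[st == "2HB"]; d1 <- dt[st == "1HB"]
  expect_gt(length(d1), 1e4)
  expect_lt(abs(mean(d1) - 6), 3 * sd(d1) / sqrt(length(d1)))
  expect_lt(abs(mean(d2) - 9), 3 * sd(d2) / sqrt(length(d2)))
  # displacement per full cycle (2HB plateau to 2HB plateau): the paired
  # substeps always rejoin the 16 nm binding-site lattice
  x2 <- ev$x_on[ev$state == "2HB"]
  steps <- diff(x2)
  expect_equal(mean(steps), 16, tolerance = 1e-9)
  expect_lt(max(abs(steps - 16)), 1e-9)
  # mean velocity 16 nm / (tau1 + tau2)
  v <- (ev$x_on[nrow(ev)] - ev$x_on[1L]) / path$duration
  expect_lt(abs(v - 16000 / 15) / (16000 / 15), 0.02)
})

test_that("paired off-axis displacements carry the configured correlation", {
  p <- kinetic_params(tau_2HB = 9, tau_1HB = 6, offaxis_corr = 0.5,
                      detach_rate = 0, seed = 7)
  path <- simulate_motor_path(p, 40)
  ev <- path$events
  into_1hb <- which(ev$state == "1HB")
  into_1hb <- into_1hb[into_1hb < nrow(ev)]
  d1 <- ev$x_off[into_1hb] - ev$x_off[into_1hb - 1L]
  d2 <- ev$x_off[into_1hb + 1L] - ev$x_off[into_1hb]
  r <- cor(d1, d2)
  se_z <- 1 / sqrt(length(d1) - 3)
  expect_lt(abs(atanh(r) - atanh(0.5)), 3 * se_z)
})

test_that("emitter_position is the right-continuous event lookup", {
  p <- kinetic_params(tau_2HB = 9, tau_1HB = 6, detach_rate = 0, seed = 3)
  path <- simulate_motor_path(p, 1)
  ev <- path$events
  expect_equal(unname(emitter_position(path, 0)[1L, ]), c(0, 0))
  # exactly at an event time: position after the event
  i <- min(5L, nrow(ev))
  at <- emitter_position(path, ev$time[i])
  expect_equal(unname(at[1L, ]), c(ev$x_on[i], ev$x_off[i]))
  # random times against a linear-scan oracle
  set.seed(1)
  ts <- runif(200, 0, path$duration)
  got <- emitter_position(path, ts)
  for (j in seq_along(ts)) {
    k <- max(which(ev$time <= ts[j]))
    expect_identical(unname(got[j, ]), c(ev$x_on[k], ev$x_off[k]))
  }
  expect_error(emitter_position(path, -0.1), "within")
  expect_error(emitter_position(path, path$duration + 1), "within")
})

test_that("the ground-truth step fit mirrors the event timeline", {
  p <- kinetic_params(tau_2HB = 9, tau_1HB = 6, detach_rate = 0, seed = 9)
  path <- simulate_motor_path(p, 1)
  fit <- path_step_fit(path)
  K <- nrow(path$events)
  expect_s3_class(fit, "step_fit")
  expect_length(fit$levels_on, K)
  expect_equal(length(fit$change_points), K - 1L)
  expect_equal(fit$steps_on, diff(path$events$x_on))
  expect_equal(sum(fit$dwells), path$duration)
})
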