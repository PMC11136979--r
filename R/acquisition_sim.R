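#' MINFLUX beam and timing configuration
#'
#' Describes the line-minimum excitation beam, the photon budget and the
#' timing of one two-dimensional localization cycle.  The intensity around
#' the line minimum is quadratic, so the expected photon count at probing
#' position p for an emitter at e is
#' \code{brightness * (e - p)^2 + background} per exposure.  A 2D cycle
#' consists of three exposures per axis; its duration is
#' \code{6*exposure_us + 6*switch_dead_us + 2*recalc_dead_ns/1000}
#' microseconds (1230.001 us with the defaults).
#'
#' The default photon budget (\code{brightness}, \code{background}) is chosen
#' so that the single-localization standard deviation at the final
#' L = 50 nm is ~4-5 nm, the regime of MINFLUX kinesin tracking.
#'
#' @param L_schedule zoom-in schedule of probing-pattern sizes L (nm),
#'   strictly decreasing, final entry 50 nm.  Each L is executed once
#'   (centred on the latest estimate); the final L then repeats until the
#'   trace ends.
#' @param repeats_per_step successful localizations per schedule entry before
#'   zooming in further; the final entry is open-ended.
#' @param exposure_us exposure time per probing position (us).
#' @param switch_dead_us dead time for switching between exposures (us).
#' @param recalc_dead_ns dead time for recalculating the position update (ns).
#' @param brightness expected photons per exposure per nm^2 of squared
#'   emitter-probe offset (quadratic coefficient).
#' @param background expected background photons per exposure.
#' @param max_fail_run number of consecutive failed cycles after which a
#'   trace is terminated.
#' @return An object of class \code{"beam_config"}.
#' @export
beam_config <- function(L_schedule = c(150, 100, 75, 50),
                        repeats_per_step = rep(1L, length(L_schedule)),
                        exposure_us = 200, switch_dead_us = 5,
                        recalc_dead_ns = 0.5,
                        brightness = 0.007, background = 0.1,
                        max_fail_run = 50L) {
  if (length(L_schedule) < 1L || any(L_schedule <= 0) ||
      any(diff(L_schedule) >= 0))
    stop("L_schedule must be strictly decreasing and positive")
  if (utils::tail(L_schedule, 1L) != 50)
    stop("the final L of the schedule must be 50 nm")
  if (length(repeats_per_step) != length(L_schedule) || any(repeats_per_step < 1))
    stop("repeats_per_step must align with L_schedule and be >= 1")
  if (exposure_us <= 0) stop("exposure_us must be > 0")
  if (brightness < 0 || background < 0)
    stop("brightness and background must be non-negative")
  structure(list(L_schedule = L_schedule,
                 repeats_per_step = as.integer(repeats_per_step),
                 exposure_us = exposure_us, switch_dead_us = switch_dead_us,
                 recalc_dead_ns = recalc_dead_ns,
                 brightness = brightness, background = background,
                 max_fail_run = as.integer(max_fail_run)),
            class = "beam_config")
}

#' Duration of one 2D localization cycle
#'
#' @param config a \code{\link{beam_config}}.
#' @return Cycle time in microseconds (1230.001 us with defaults).
#' @export
cycle_time_us <- function(config) {
  6 * config$exposure_us + 6 * config$switch_dead_us +
    2 * config$recalc_dead_ns / 1000
}

#' Expected photon counts of a line-minimum probing triplet
#'
#' Quadratic intensity about the zero: for probing positions
#' \code{center - L/2}, \code{center}, \code{center + L/2} the expectations
#' are \code{brightness * (emitter - p)^2 + background}.
#'
#' @param emitter emitter coordinate (nm) along the probed axis.
#' @param center beam-pattern centre (nm).
#' @param L probing-pattern size (nm), > 0.
#' @param brightness,background photon-budget parameters, see
#'   \code{\link{beam_config}}.
#' @return Numeric vector \code{c(lambda_minus, lambda_0, lambda_plus)}.
#' @export
expected_counts <- function(emitter, center, L, brightness, background) {
  if (L <= 0) stop("L must be > 0")
  if (brightness < 0 || background < 0)
    stop("brightness and background must be non-negative")
  p <- c(center - L / 2, center, center + L / 2)
  brightness * (emitter - p)^2 + background
}

#' Sample a photon triplet (shot noise)
#'
#' Independent Poisson draws at the three probing positions.
#'
#' @param lambdas expected counts, e.g. from \code{\link{expected_counts}}.
#' @return Integer vector \code{c(n_minus, n_0, n_plus)}.
#' @export
sample_triplet <- function(lambdas) {
  if (length(lambdas) != 3L || any(!is.finite(lambdas)) || any(lambdas < 0))
    stop("lambdas must be three finite non-negative expected counts")
  n <- stats::rpois(3L, lambdas)
  names(n) <- c("n_minus", "n_0", "n_plus")
  n
}

#' Vectorized MINFLUX position corrections with validity rules
#'
#' Computes the correction \code{(L/4) * (n_minus - n_plus) /
#' (n_plus + n_minus - 2*n_0)} for each triplet and applies the two failure
#' rules: a localization fails if fewer than five photons were collected, or
#' if \code{2*(n_plus + n_minus - 2*n_0) < |n_minus - n_plus|}, which caps
#' valid corrections at L/2.  A zero denominator that survives both rules
#' (symmetric counts with no curvature information) yields a zero correction.
#'
#' @param n_minus,n_0,n_plus photon counts at \code{-L/2}, 0, \code{+L/2}.
#' @param L probing-pattern size (nm), > 0.
#' @return A list with \code{valid} (logical), \code{delta} (nm correction,
#'   \code{NA} where invalid) and \code{reason} (\code{"too_few_photons"},
#'   \code{"excess_correction"} or \code{NA} where valid).
#' @export
minflux_correction <- function(n_minus, n_0, n_plus, L) {
  if (L <= 0) stop("L must be > 0")
  total <- n_minus + n_0 + n_plus
  denom <- n_plus + n_minus - 2 * n_0
  diff_ <- n_minus - n_plus
  too_few <- total < 5
  excess <- !too_few & (2 * denom < abs(diff_))
  valid <- !too_few & !excess
  delta <- rep(NA_real_, length(valid))
  dz <- valid & denom == 0           # n_minus == n_plus, flat counts
  delta[dz] <- 0
  dv <- valid & denom != 0
  delta[dv] <- (L / 4) * diff_[dv] / denom[dv]
  reason <- rep(NA_character_, length(valid))
  reason[too_few] <- "too_few_photons"
  reason[excess] <- "excess_correction"
  list(valid = valid, delta = delta, reason = reason)
}

#' Online MINFLUX position update for one triplet
#'
#' Applies \code{\link{minflux_correction}} to a single photon triplet and
#' updates the position estimate.
#'
#' @param x_old current position estimate (nm), also the beam centre.
#' @param L probing-pattern size (nm).
#' @param triplet integer vector \code{c(n_minus, n_0, n_plus)}.
#' @return A list with \code{valid}; if valid, \code{x_new} (satisfying
#'   \code{|x_new - x_old| <= L/2}); otherwise \code{failure_reason}.
#' @examples
#' update_position(0, 50, c(10, 0, 10))$x_new   # 0: symmetric counts
#' update_position(0, 50, c(0, 0, 20))$x_new    # -12.5
#' update_position(0, 50, c(2, 1, 1))$failure_reason   # too few photons
#' @export
update_position <- function(x_old, L, triplet) {
  stopifnot(length(triplet) == 3L)
  r <- minflux_correction(triplet[1L], triplet[2L], triplet[3L], L)
  if (r$valid) list(valid = TRUE, x_new = x_old + r$delta)
  else list(valid = FALSE, failure_reason = r$reason)
}

#' Photon-rate trigger for starting a tracking run
#'
#' @param rate detected photon rate (kHz).
#' @param threshold trigger threshold (kHz); instrument thresholds typically
#'   range from 6 to 10 kHz depending on sample background.
#' @return \code{TRUE} iff \code{rate > threshold} (strict).
#' @export
trigger_check <- function(rate, threshold = 6) {
  rate > threshold
}

#' Simulate MINFLUX acquisition along a motor path
#'
#' Runs the tracking routine on a simulated \code{\link{simulate_motor_path}}
#' emitter: the zoom-in schedule is executed once (each L centred on the
#' latest estimate), after which the routine loops at the final L = 50 nm.
#' Per 2D cycle the x and y axes are localized alternately with line-minimum
#' triplets; time advances by \code{\link{cycle_time_us}} per cycle.  A
#' failed localization repeats at the same L so a single failure does not
#' lose the motor; a run of \code{max_fail_run} consecutive failed cycles
#' terminates the trace.
#'
#' @param path a \code{"motor_path"}.
#' @param config a \code{\link{beam_config}}.
#' @param seed optional integer seed for the photon noise.
#' @param start_estimate optional length-2 start estimate (nm); defaults to
#'   the true emitter position at t = 0.  If the emitter is farther than
#'   \code{L_schedule[1]/2} from it, the trace aborts with a diagnostic.
#' @return An object of class \code{"raw_trace"}: a data frame with one row
#'   per 2D cycle (\code{t} in s; per-axis counts, beam centres, estimates
#'   and validity; \code{L}; \code{valid}) with metadata attributes,
#'   including the ground-truth path as \code{attr(, "motor_path")}.
#' @export
run_acquisition <- function(path, config = beam_config(), seed = NULL,
                            start_estimate = NULL) {
  stopifnot(inherits(path, "motor_path"), inherits(config, "beam_config"))
  if (nrow(path$events) < 1L) stop("path is empty")
  if (!is.null(seed)) set.seed(seed)
  e0 <- emitter_position(path, 0)
  if (is.null(start_estimate)) start_estimate <- c(e0[1L, 1L], e0[1L, 2L])
  if (any(abs(c(e0) - start_estimate) > config$L_schedule[1L] / 2))
    stop("emitter is farther than L_schedule[1]/2 = ",
         config$L_schedule[1L] / 2,
         " nm from the start estimate; tracking cannot lock on")

  dt_s <- cycle_time_us(config) * 1e-6
  ty_off <- 3 * (config$exposure_us + config$switch_dead_us) * 1e-6
  n_max <- ceiling(path$duration / dt_s) + length(config$L_schedule) *
    max(config$repeats_per_step) + 1L
  out <- matrix(NA_real_, nrow = n_max, ncol = 15L)
  colnames(out) <- c("t", "L",
                     "center_x", "n_minus_x", "n_0_x", "n_plus_x", "est_x", "valid_x",
                     "center_y", "n_minus_y", "n_0_y", "n_plus_y", "est_y", "valid_y",
                     "valid")
  est <- c(start_estimate[1L], start_estimate[2L])
  sched_i <- 1L; sched_done <- 0L
  t <- 0; k <- 0L; fail_run <- 0L
  while (t <= path$duration) {
    L <- config$L_schedule[sched_i]
    k <- k + 1L
    ex <- emitter_position(path, min(t, path$duration))
    lam_x <- expected_counts(ex[1L, 1L], est[1L], L,
                             config$brightness, config$background)
    nx <- stats::rpois(3L, lam_x)
    rx <- minflux_correction(nx[1L], nx[2L], nx[3L], L)
    cx <- est[1L]
    if (rx$valid) est[1L] <- est[1L] + rx$delta

    ey <- emitter_position(path, min(t + ty_off, path$duration))
    lam_y <- expected_counts(ey[1L, 2L], est[2L], L,
                             config$brightness, config$background)
    ny <- stats::rpois(3L, lam_y)
    ry <- minflux_correction(ny[1L], ny[2L], ny[3L], L)
    cy <- est[2L]
    if (ry$valid) est[2L] <- est[2L] + ry$delta

    ok <- rx$valid && ry$valid
    out[k, ] <- c(t, L, cx, nx, est[1L], rx$valid,
                  cy, ny, est[2L], ry$valid, ok)
    if (ok) {
      fail_run <- 0L
      if (sched_i < length(config$L_schedule)) {
        sched_done <- sched_done + 1L
        if (sched_done >= config$repeats_per_step[sched_i]) {
          sched_i <- sched_i + 1L
          sched_done <- 0L
        }
      }
    } else {
      fail_run <- fail_run + 1L
      if (fail_run >= config$max_fail_run) break
    }
    t <- t + dt_s
  }
  df <- as.data.frame(out[seq_len(k), , drop = FALSE])
  for (col in c("n_minus_x", "n_0_x", "n_plus_x",
                "n_minus_y", "n_0_y", "n_plus_y"))
    df[[col]] <- as.integer(df[[col]])
  df$valid_x <- as.logical(df$valid_x)
  df$valid_y <- as.logical(df$valid_y)
  df$valid <- as.logical(df$valid)
  structure(df,
            class = c("raw_trace", "data.frame"),
            beam_config = config,
            motor_path = path,
            metadata = list(seed = seed,
                            cycle_time_us = cycle_time_us(config)))
}
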