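#' Kinetic and geometric parameters of a simulated kinesin motor
#'
#' Bundles the stepping kinetics and geometry used by
#' \code{\link{simulate_motor_path}}.  Dwells in both mechanochemical states
#' are exponential: \code{tau_2HB} is the mean two-head-bound dwell and
#' \code{tau_1HB} the mean one-head-bound dwell between the paired substeps
#' (ATP binding takes place in the 1HB state, so \code{tau_1HB} shortens with
#' increasing ATP).  The two on-axis substeps must sum to the 16 nm
#' binding-site periodicity.
#'
#' @param tau_2HB mean 2HB (bound) dwell in ms; must be > 0.
#' @param tau_1HB mean 1HB (unbound) dwell in ms; must be > 0.
#' @param substep1_mean,substep2_mean on-axis sizes (nm) of the paired
#'   substeps entering and leaving the 1HB state; must sum to 16 nm.
#' @param substep_sd standard deviation (nm) of individual substep sizes;
#'   draws are truncated to (0, 16) nm.
#' @param offaxis_shift_sd standard deviation (nm) of the lateral (off-axis)
#'   displacement entering and leaving the 1HB state.
#' @param offaxis_corr correlation in [-1, 1] between the paired off-axis
#'   displacements (entering vs. leaving the 1HB state).
#' @param switch_rate rate (events/s) of the Poisson microtubule-switching
#'   process.
#' @param switch_offaxis_range length-2 interval (nm); the magnitude of the
#'   off-axis jump at a switch is drawn uniformly from it (random sign).
#' @param reversal_prob probability that a microtubule switch reverses the
#'   walking direction.
#' @param detach_rate rate (events/s) of motor detachment, ending the path.
#' @param seed optional integer seed; when set,
#'   \code{\link{simulate_motor_path}} is bit-reproducible.
#' @return An object of class \code{"kinetic_params"} (a validated list).
#' @seealso \code{\link{make_preset}} for construct/ATP presets.
#' @export
kinetic_params <- function(tau_2HB, tau_1HB,
                           substep1_mean = 8, substep2_mean = 8,
                           substep_sd = 1,
                           offaxis_shift_sd = 3, offaxis_corr = 0,
                           switch_rate = 0, switch_offaxis_range = c(30, 80),
                           reversal_prob = 0.25, detach_rate = 0,
                           seed = NULL) {
  p <- list(tau_2HB = tau_2HB, tau_1HB = tau_1HB,
            substep1_mean = substep1_mean, substep2_mean = substep2_mean,
            substep_sd = substep_sd,
            offaxis_shift_sd = offaxis_shift_sd, offaxis_corr = offaxis_corr,
            switch_rate = switch_rate,
            switch_offaxis_range = switch_offaxis_range,
            reversal_prob = reversal_prob, detach_rate = detach_rate,
            seed = seed)
  num <- p[setdiff(names(p), "seed")]
  if (!all(vapply(num, function(v) all(is.finite(v)), logical(1L))))
    stop("all kinetic parameters must be finite")
  if (tau_2HB <= 0 || tau_1HB <= 0)
    stop("dwell means tau_2HB and tau_1HB must be strictly positive")
  if (abs(substep1_mean + substep2_mean - 16) > 1e-9)
    stop("substep1_mean + substep2_mean must equal the 16 nm binding-site periodicity")
  if (substep_sd < 0 || offaxis_shift_sd < 0)
    stop("standard deviations must be non-negative")
  if (offaxis_corr < -1 || offaxis_corr > 1)
    stop("offaxis_corr must lie in [-1, 1]")
  if (switch_rate < 0 || detach_rate < 0)
    stop("switch_rate and detach_rate must be non-negative")
  if (length(switch_offaxis_range) != 2L ||
      any(switch_offaxis_range < 0) || diff(switch_offaxis_range) < 0)
    stop("switch_offaxis_range must be a non-decreasing non-negative length-2 interval")
  if (reversal_prob < 0 || reversal_prob > 1)
    stop("reversal_prob must lie in [0, 1]")
  structure(p, class = "kinetic_params")
}

# ATP-level preset dwell means (ms).  tau_1HB varies with ATP (ATP binds in
# the 1HB state); tau_2HB is held near-constant.  Values are chosen so that
# the renewal velocities 16/(tau_1HB + tau_2HB) bracket typical measured
# kinesin velocities (~230-550 nm/s) without claiming to reproduce them.
.preset_tau <- list(low  = c(tau_1HB = 60, tau_2HB = 9),
                    mid  = c(tau_1HB = 20, tau_2HB = 9),
                    high = c(tau_1HB = 45, tau_2HB = 9))

#' Preset kinetic parameters for a labeling construct and ATP level
#'
#' \code{K28C} (label at the back of the head) takes symmetric ~8 + 8 nm
#' substeps with a small negative correlation between the paired off-axis
#' displacements; \code{T324C} (label near the neck linker) takes asymmetric
#' 6 + 10 nm substeps with uncorrelated off-axis displacements.  The ATP
#' level (\code{low}/\code{mid}/\code{high}, i.e. 50 uM / 500 uM / 5 mM)
#' sets the mean 1HB dwell, which shortens at higher ATP.
#'
#' @param construct one of \code{"K28C"}, \code{"T324C"}.
#' @param atp_level one of \code{"low"}, \code{"mid"}, \code{"high"}.
#' @return A \code{\link{kinetic_params}} object.
#' @examples
#' make_preset("K28C", "low")$substep1_mean   # 8 nm
#' make_preset("T324C", "low")$substep2_mean  # 10 nm
#' @export
make_preset <- function(construct = c("K28C", "T324C"),
                        atp_level = c("low", "mid", "high")) {
  if (!is.character(construct) || !construct[1L] %in% c("K28C", "T324C"))
    stop("unknown construct '", construct[1L], "'; valid options: K28C, T324C")
  if (!is.character(atp_level) || !atp_level[1L] %in% c("low", "mid", "high"))
    stop("unknown atp_level '", atp_level[1L],
         "'; valid options: low, mid, high")
  construct <- construct[1L]
  atp_level <- atp_level[1L]
  tau <- .preset_tau[[atp_level]]
  if (construct == "K28C") {
    p <- kinetic_params(tau_2HB = tau[["tau_2HB"]], tau_1HB = tau[["tau_1HB"]],
                        substep1_mean = 8, substep2_mean = 8,
                        offaxis_corr = -0.3, detach_rate = 0.5)
  } else {
    p <- kinetic_params(tau_2HB = tau[["tau_2HB"]], tau_1HB = tau[["tau_1HB"]],
                        substep1_mean = 6, substep2_mean = 10,
                        offaxis_corr = 0, detach_rate = 0.5)
  }
  attr(p, "construct") <- construct
  attr(p, "atp_level") <- atp_level
  p
}

# Substep size draw, Gaussian truncated to (0, 16) nm by rejection.
.rsubstep <- function(mean, sd) {
  if (sd == 0) return(mean)
  repeat {
    s <- stats::rnorm(1L, mean, sd)
    if (s > 0 && s < 16) return(s)
  }
}

#' Simulate a ground-truth kinesin walking path
#'
#' Generates the event timeline of the labeled head as an alternating renewal
#' process: exponential 2HB dwells, then a substep into the 1HB state, an
#' exponential 1HB dwell, and a substep back to the 2HB state, the pair
#' summing to 16 nm in expectation.  Each substep carries a lateral
#' (off-axis) displacement; the displacements entering and leaving the 1HB
#' state are bivariate Gaussian with correlation \code{offaxis_corr}.
#' Microtubule switches arrive as an independent Poisson process, add a
#' uniform off-axis jump from \code{switch_offaxis_range} (random sign),
#' increment the microtubule id and, with probability \code{reversal_prob},
#' reverse the walking direction.  The path ends at \code{duration} or at an
#' exponential detachment time, whichever comes first.
#'
#' Positions are piecewise constant and right-continuous at event times.
#'
#' @param params a \code{\link{kinetic_params}} object.
#' @param duration requested duration in s; must be > 0.
#' @return An object of class \code{"motor_path"}: a list with
#'   \code{events} (data frame with columns \code{time}, \code{x_on},
#'   \code{x_off}, \code{state}, \code{mt_id}), \code{duration} (s, possibly
#'   shortened by detachment) and \code{params}.
#' @export
simulate_motor_path <- function(params, duration) {
  if (!inherits(params, "kinetic_params"))
    params <- do.call(kinetic_params, params)
  if (!is.finite(duration) || duration <= 0)
    stop("duration must be a positive finite time in s")
  if (!is.null(params$seed)) set.seed(params$seed)

  t_end <- duration
  if (params$detach_rate > 0)
    t_end <- min(duration, stats::rexp(1L, params$detach_rate))
  switch_times <- numeric(0)
  if (params$switch_rate > 0) {
    n_sw <- stats::rpois(1L, params$switch_rate * t_end)
    if (n_sw > 0) switch_times <- sort(stats::runif(n_sw, 0, t_end))
  }

  rho <- params$offaxis_corr
  # Pre-allocate generously; grown if needed.
  cap <- max(64L, ceiling(4 * t_end * 1000 / (params$tau_1HB + params$tau_2HB)) + length(switch_times) + 8L)
  time <- x_on <- x_off <- numeric(cap)
  state <- character(cap); mt_id <- integer(cap)
  k <- 1L
  time[1L] <- 0; x_on[1L] <- 0; x_off[1L] <- 0
  state[1L] <- "2HB"; mt_id[1L] <- 1L

  push <- function(tt, xo, yo, st, mt) {
    k <<- k + 1L
    if (k > length(time)) {
      grow <- function(v) c(v, vector(mode(v), length(v)))
      time <<- grow(time); x_on <<- grow(x_on); x_off <<- grow(x_off)
      state <<- grow(state); mt_id <<- grow(mt_id)
    }
    time[k] <<- tt; x_on[k] <<- xo; x_off[k] <<- yo
    state[k] <<- st; mt_id[k] <<- mt
  }

  t <- 0; x <- 0; y <- 0; dir <- 1; mt <- 1L; st <- "2HB"
  sw_i <- 1L
  pend_s2 <- NA_real_; pend_d2 <- NA_real_  # second half of a substep pair
  repeat {
    rate_ms <- if (st == "2HB") params$tau_2HB else params$tau_1HB
    t_next <- t + stats::rexp(1L, 1000 / rate_ms)  # dwell means are in ms
    # process any microtubule switches before the next stepping transition
    while (sw_i <= length(switch_times) && switch_times[sw_i] < min(t_next, t_end)) {
      jump <- sample(c(-1, 1), 1L) *
        stats::runif(1L, params$switch_offaxis_range[1L], params$switch_offaxis_range[2L])
      y <- y + jump
      mt <- mt + 1L
      if (stats::runif(1L) < params$reversal_prob) dir <- -dir
      push(switch_times[sw_i], x, y, st, mt)
      sw_i <- sw_i + 1L
    }
    if (t_next >= t_end) break
    if (st == "2HB") {
      s1 <- .rsubstep(params$substep1_mean, params$substep_sd)
      pend_s2 <- 16 - s1  # pair sums to 16 nm
      z1 <- stats::rnorm(1L); z2 <- stats::rnorm(1L)
      d1 <- params$offaxis_shift_sd * z1
      pend_d2 <- params$offaxis_shift_sd * (rho * z1 + sqrt(1 - rho^2) * z2)
      x <- x + dir * s1; y <- y + d1; st <- "1HB"
    } else {
      x <- x + dir * pend_s2; y <- y + pend_d2; st <- "2HB"
    }
    t <- t_next
    push(t, x, y, st, mt)
  }

  structure(list(events = data.frame(time = time[seq_len(k)],
                                     x_on = x_on[seq_len(k)],
                                     x_off = x_off[seq_len(k)],
                                     state = state[seq_len(k)],
                                     mt_id = mt_id[seq_len(k)]),
                 duration = t_end, params = params),
            class = "motor_path")
}

#' @export
print.motor_path <- function(x, ...) {
  ev <- x$events
  cat(sprintf("<motor_path> %d events over %.3f s, %d microtubule(s), run %.1f nm\n",
              nrow(ev), x$duration, max(ev$mt_id),
              ev$x_on[nrow(ev)] - ev$x_on[1L]))
  invisible(x)
}

#' Position of the labeled head at given times
#'
#' Piecewise-constant lookup into a \code{\link{simulate_motor_path}} event
#' timeline, right-continuous at event times (the position \emph{after} an
#' event applies at the event time itself).
#'
#' @param path a \code{"motor_path"}.
#' @param t time(s) in s; all values must lie in \code{[0, path$duration]}.
#' @return A two-column matrix (\code{x}, \code{y}) in nm, one row per time.
#' @export
emitter_position <- function(path, t) {
  stopifnot(inherits(path, "motor_path"))
  if (any(!is.finite(t)) || any(t < 0) || any(t > path$duration))
    stop("t must lie within [0, duration] = [0, ", format(path$duration), "]")
  i <- findInterval(t, path$events$time)  # largest event time <= t
  i[i < 1L] <- 1L
  cbind(x = path$events$x_on[i], y = path$events$x_off[i])
}

#' Ground-truth step fit of a simulated path
#'
#' Converts a \code{"motor_path"} event timeline into the same plateau/step
#' representation that \code{\link{fit_steps}} produces from measured data,
#' with every stepping (and switching) event as an exact change point.  Used
#' as a noise-free reference for the analysis stages.
#'
#' @param path a \code{"motor_path"}.
#' @return A \code{"step_fit"} object (see \code{\link{fit_steps}}).
#' @export
path_step_fit <- function(path) {
  stopifnot(inherits(path, "motor_path"))
  ev <- path$events
  K <- nrow(ev)
  t_start <- ev$time
  t_end <- c(ev$time[-1L], path$duration)
  new_step_fit(change_points = if (K > 1L) seq_len(K - 1L) else integer(0),
               t_change = ev$time[-1L],
               change_dt = rep(0, max(K - 1L, 0L)),
               levels_on = ev$x_on, levels_off = ev$x_off,
               t_start = t_start, t_end = t_end,
               n = K, sigma = 0, source = "ground_truth")
}
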