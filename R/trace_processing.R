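# Internal constructor shared by fit_steps / fit_trace_steps / path_step_fit.
# A step_fit holds K plateaus and K-1 change points; steps and dwells are
# derived here so the invariants (steps = level diffs, one more plateau than
# change point) hold by construction.
new_step_fit <- function(change_points, t_change, change_dt,
                         levels_on, levels_off = NULL,
                         t_start, t_end, n, sigma, source = "fit") {
  K <- length(levels_on)
  stopifnot(length(change_points) == K - 1L, length(t_start) == K,
            length(t_end) == K)
  structure(list(change_points = as.integer(change_points),
                 t_change = t_change,
                 change_dt = change_dt,
                 levels_on = levels_on,
                 levels_off = levels_off,
                 steps_on = if (K > 1L) diff(levels_on) else numeric(0),
                 steps_off = if (!is.null(levels_off) && K > 1L)
                   diff(levels_off) else NULL,
                 t_start = t_start, t_end = t_end,
                 dwells = t_end - t_start,
                 n = n, sigma = sigma, source = source),
            class = "step_fit")
}

#' @export
print.step_fit <- function(x, ...) {
  cat(sprintf("<step_fit> %d plateaus, %d change points over %.3f s (sigma = %.2f nm)\n",
              length(x$levels_on), length(x$change_points),
              x$t_end[length(x$t_end)] - x$t_start[1L], x$sigma))
  if (length(x$steps_on))
    cat("  on-axis steps (nm): ",
        paste(sprintf("%.1f", x$steps_on), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Refine MINFLUX positions with the sliding curvature estimator
#'
#' Per cycle and axis the raw position offset is
#' \code{(L/4) * (n_minus - n_plus) / d} with pattern curvature
#' \code{d = n_plus + n_minus - 2*n_0}.  The refinement replaces the noisy
#' per-cycle denominator by its mean over a centred sliding time window of
#' width \code{T_ms}: the emitter barely moves within ~20 ms, so the
#' curvature is effectively constant and averaging it reduces localization
#' noise without losing temporal resolution.  Windows truncate at the trace
#' boundaries, and only cycles probed with the same L enter a window (the
#' curvature scales with L^2).  Offsets are taken relative to each cycle's
#' beam centre.  Cycles whose window-mean curvature is not positive are
#' marked invalid and excluded.
#'
#' @param raw a \code{"raw_trace"} from \code{\link{run_acquisition}} or
#'   \code{\link{read_trace}}.
#' @param T_ms sliding window width in ms (default 20).
#' @return An object of class \code{"refined_trace"}: a data frame with
#'   columns \code{t} (s), \code{x}, \code{y} (nm), carrying the rotation
#'   angle (0 until aligned) and source metadata as attributes.
#' @export
sliding_curvature_estimate <- function(raw, T_ms = 20) {
  stopifnot(inherits(raw, "raw_trace"))
  if (T_ms <= 0) stop("T_ms must be > 0")
  keep <- raw$valid
  if (!any(keep)) stop("raw trace has no valid cycles")
  d <- raw[keep, , drop = FALSE]
  half <- T_ms / 2000  # s
  refine_axis <- function(nm, n0, np, center, L, t) {
    num <- (L / 4) * (nm - np)
    den <- np + nm - 2 * n0
    denbar <- numeric(length(t))
    for (Lval in unique(L)) {
      sel <- which(L == Lval)
      ts <- t[sel]; ds <- den[sel]
      cs <- c(0, cumsum(ds))
      lo <- findInterval(ts - half, ts, left.open = TRUE) + 1L
      hi <- findInterval(ts + half, ts)
      denbar[sel] <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
    }
    ok <- denbar > 0
    list(x = center + num / denbar, ok = ok)
  }
  rx <- refine_axis(d$n_minus_x, d$n_0_x, d$n_plus_x, d$center_x, d$L, d$t)
  ry <- refine_axis(d$n_minus_y, d$n_0_y, d$n_plus_y, d$center_y, d$L, d$t)
  ok <- rx$ok & ry$ok
  out <- data.frame(t = d$t[ok], x = rx$x[ok], y = ry$x[ok])
  structure(out, class = c("refined_trace", "data.frame"),
            rotation_angle = 0,
            metadata = attr(raw, "metadata"),
            motor_path = attr(raw, "motor_path"),
            T_ms = T_ms)
}

#' Align the walking direction with the x-axis
#'
#' Rotates the 2D positions so that the direction of maximal displacement
#' variance (the dominant eigenvector of the position covariance) lies along
#' x, with the net movement pointing in +x.  The rotation is an isometry, so
#' step sizes are unchanged; the applied angle is recorded in the
#' \code{rotation_angle} attribute.
#'
#' @param trace a \code{"refined_trace"} (or any data frame with \code{x},
#'   \code{y}).
#' @return The trace with rotated coordinates (on-axis x, off-axis y).
#' @export
align_principal_axis <- function(trace) {
  x <- trace$x; y <- trace$y
  if (length(x) < 2L) stop("need at least 2 positions to align")
  if (stats::sd(x) == 0 && stats::sd(y) == 0)
    stop("degenerate trace: all positions identical")
  cv <- stats::cov(cbind(x, y))
  v <- eigen(cv, symmetric = TRUE)$vectors[, 1L]
  ang <- atan2(v[2L], v[1L])
  rot <- function(a) {
    ca <- cos(a); sa <- sin(a)
    cbind(ca * x + sa * y, -sa * x + ca * y)
  }
  xy <- rot(ang)
  if (xy[length(x), 1L] - xy[1L, 1L] < 0) {  # net movement must be +x
    ang <- ang + pi
    xy <- rot(ang)
  }
  out <- trace
  out$x <- xy[, 1L]; out$y <- xy[, 2L]
  attr(out, "rotation_angle") <- -ang  # angle applied to the data
  out
}

# Recursive binary segmentation on squared-error cost.  Candidate splits
# keep both sides >= min_seg samples; a split is accepted if it lowers the
# summed within-segment SSE by more than `penalty`.
.binseg <- function(x, penalty, min_seg) {
  n <- length(x)
  s1 <- cumsum(x); s2 <- cumsum(x^2)
  seg_sum <- function(a, b) s1[b] - if (a > 1L) s1[a - 1L] else 0
  seg_sse <- function(a, b) {
    s <- seg_sum(a, b)
    (s2[b] - if (a > 1L) s2[a - 1L] else 0) - s^2 / (b - a + 1L)
  }
  cps <- integer(0)
  stack <- list(c(1L, n))
  while (length(stack)) {
    ab <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    a <- ab[1L]; b <- ab[2L]
    if (b - a + 1L < 2L * min_seg) next
    ss <- (a + min_seg - 1L):(b - min_seg)
    nl <- ss - a + 1L; nr <- b - ss
    suml <- s1[ss] - if (a > 1L) s1[a - 1L] else 0
    tot <- seg_sum(a, b)
    # gain = SSE(a,b) - SSE(a,s) - SSE(s+1,b), expanded via segment sums
    gain <- suml^2 / nl + (tot - suml)^2 / nr - tot^2 / (b - a + 1L)
    j <- which.max(gain)
    if (gain[j] > penalty) {
      s <- ss[j]
      cps <- c(cps, s)
      stack[[length(stack) + 1L]] <- c(a, s)
      stack[[length(stack) + 1L]] <- c(s + 1L, b)
    }
  }
  sort(cps)
}

# Piecewise-constant fit given change points (split after each index).
.pc_fit <- function(x, cps) {
  bounds <- c(0L, cps, length(x))
  lv <- numeric(length(bounds) - 1L)
  fitted <- numeric(length(x))
  for (k in seq_along(lv)) {
    idx <- (bounds[k] + 1L):bounds[k + 1L]
    lv[k] <- mean(x[idx])
    fitted[idx] <- lv[k]
  }
  list(levels = lv, fitted = fitted)
}

#' Fit steps by iterative change-point detection
#'
#' Three stages, matching standard processing of MINFLUX stepping traces:
#' \enumerate{
#'   \item recursive binary change-point search on squared-error cost.  At
#'     each iteration the split minimizing the summed within-segment squared
#'     residuals is accepted if it reduces a penalized cost; the BIC-style
#'     penalty \code{penalty_mult * sigma^2 * log(n)} is calibrated so a flat
#'     noise-only series yields zero change points at the configured sigma
#'     (estimated robustly from first differences when not supplied);
#'   \item a moving median of width \code{median_width} applied to the fitted
#'     step function, removing steps caused by isolated spikes; change points
#'     are re-derived from the filtered function and plateau levels refit as
#'     segment means;
#'   \item a single round removing steps with \code{|size| < min_step} by
#'     merging adjacent plateaus (levels refit as segment means).  Steps that
#'     fall below \code{min_step} only as a result of the merging are
#'     deliberately \emph{not} re-removed.
#' }
#'
#' @param x on-axis position series (nm).
#' @param t optional timestamps (s); if omitted, sample index is used and
#'   dwells are in samples.
#' @param min_step minimum retained step size (nm), default 2.
#' @param median_width moving-median width (odd), default 9.
#' @param sigma noise standard deviation (nm); default estimated as
#'   \code{mad(diff(x))/sqrt(2)}.
#' @param penalty_mult multiplier of the \code{sigma^2 * log(n)} penalty.
#' @param min_seg minimum segment length (samples) for split candidates;
#'   prevents single-sample plateaus that the median filter would erase.
#' @return An object of class \code{"step_fit"} with change-point indices,
#'   plateau levels, step sizes and plateau dwell durations.  Off-axis
#'   levels are filled in by \code{\link{offaxis_plateaus}} or
#'   \code{\link{fit_trace_steps}}.
#' @export
fit_steps <- function(x, t = NULL, min_step = 2, median_width = 9,
                      sigma = NULL, penalty_mult = 2, min_seg = 3L) {
  n <- length(x)
  if (n < 2L * min_seg) stop("series too short for step fitting")
  if (median_width %% 2L != 1L) stop("median_width must be odd")
  if (is.null(t)) t <- seq_len(n) else stopifnot(length(t) == n)
  if (is.null(sigma)) sigma <- stats::mad(diff(x)) / sqrt(2)
  penalty <- penalty_mult * sigma^2 * log(n)

  cps <- .binseg(x, penalty, as.integer(min_seg))
  fitted <- .pc_fit(x, cps)$fitted
  if (n >= median_width)
    fitted <- stats::runmed(fitted, median_width, endrule = "keep")
  cps <- which(diff(fitted) != 0)
  # plateau levels of the filtered step function itself: spike plateaus the
  # median erased must not leak back in through data segment means
  lv_f <- fitted[c(cps, n)]

  if (length(cps)) {  # single-round small-step removal
    small <- abs(diff(lv_f)) < min_step
    cps <- cps[!small]
  }
  levels <- .pc_fit(x, cps)$levels

  K <- length(levels)
  tc <- if (K > 1L) (t[cps] + t[cps + 1L]) / 2 else numeric(0)
  new_step_fit(change_points = cps, t_change = tc,
               change_dt = if (K > 1L) t[cps + 1L] - t[cps] else numeric(0),
               levels_on = levels,
               t_start = c(t[1L], tc), t_end = c(tc, t[n]),
               n = n, sigma = sigma)
}

#' Fitted piecewise-constant step function of a step fit
#'
#' @param fit a \code{"step_fit"} with sample-index change points.
#' @param axis \code{"on"} or \code{"off"}.
#' @return The fitted level at every sample (length \code{fit$n}).
#' @export
step_function <- function(fit, axis = c("on", "off")) {
  axis <- match.arg(axis)
  lv <- if (axis == "on") fit$levels_on else fit$levels_off
  if (is.null(lv)) stop("fit has no ", axis, "-axis levels")
  rep(lv, times = diff(c(0L, fit$change_points, fit$n)))
}

#' Off-axis plateau levels at the on-axis change points
#'
#' The off-axis coordinate is not searched for its own change points: the
#' change points of the on-axis step fit delimit its plateaus, and each
#' off-axis level is the arithmetic mean of its segment.
#'
#' @param y off-axis position series (nm), same length as the fitted series.
#' @param change_points strictly increasing change-point indices (split
#'   after each index), e.g. \code{fit$change_points}.
#' @return A list with \code{levels} (per plateau) and \code{steps}
#'   (successive level differences).
#' @export
offaxis_plateaus <- function(y, change_points) {
  n <- length(y)
  cps <- as.integer(change_points)
  if (length(cps) && (any(diff(cps) <= 0) || cps[1L] < 1L || cps[length(cps)] >= n))
    stop("change_points must be strictly increasing indices within the series")
  lv <- .pc_fit(y, cps)$levels
  list(levels = lv, steps = if (length(lv) > 1L) diff(lv) else numeric(0))
}

#' Fit on- and off-axis steps of a refined trace
#'
#' Convenience wrapper: \code{\link{fit_steps}} on the on-axis coordinate,
#' then \code{\link{offaxis_plateaus}} on the off-axis coordinate.
#'
#' @param trace an aligned \code{"refined_trace"}.
#' @inheritParams fit_steps
#' @return A \code{"step_fit"} with both on- and off-axis levels and steps.
#' @export
fit_trace_steps <- function(trace, min_step = 2, median_width = 9,
                            sigma = NULL, penalty_mult = 2, min_seg = 3L) {
  fit <- fit_steps(trace$x, t = trace$t, min_step = min_step,
                   median_width = median_width, sigma = sigma,
                   penalty_mult = penalty_mult, min_seg = min_seg)
  off <- offaxis_plateaus(trace$y, fit$change_points)
  fit$levels_off <- off$levels
  fit$steps_off <- off$steps
  fit
}

#' Quality thresholds for automated trace screening
#'
#' @param min_photons minimum mean photons per 1D localization.
#' @param min_sbr minimum mean signal-to-background ratio.
#' @param min_run_nm minimum run length (nm).
#' @param min_run_s minimum run time (s).
#' @param max_precision_nm maximum mean within-plateau localization
#'   standard deviation (nm).
#' @return A named list of thresholds.
#' @export
qc_thresholds <- function(min_photons = 0, min_sbr = 0, min_run_nm = 0,
                          min_run_s = 0, max_precision_nm = Inf) {
  list(min_photons = min_photons, min_sbr = min_sbr, min_run_nm = min_run_nm,
       min_run_s = min_run_s, max_precision_nm = max_precision_nm)
}

#' Automated trace quality control
#'
#' Replaces manual screening with reproducible metrics: mean photons per
#' localization, mean signal-to-background ratio (side counts over centre
#' counts; at the line minimum the centre counts are essentially
#' background), mean within-plateau localization precision, run length and
#' run time.  The trace passes iff all metrics clear the configured
#' thresholds.
#'
#' @param raw the \code{"raw_trace"} the fit derives from.
#' @param trace the refined, aligned trace used for the fit.
#' @param fit the \code{"step_fit"} of the trace.
#' @param thresholds a \code{\link{qc_thresholds}} list.
#' @return A list with \code{pass} and a \code{metrics} list.
#' @export
trace_qc <- function(raw, trace, fit, thresholds = qc_thresholds()) {
  d <- raw[raw$valid, , drop = FALSE]
  photons <- mean(c(d$n_minus_x + d$n_0_x + d$n_plus_x,
                    d$n_minus_y + d$n_0_y + d$n_plus_y))
  side <- mean(c(d$n_minus_x + d$n_plus_x, d$n_minus_y + d$n_plus_y)) / 2
  ctr <- mean(c(d$n_0_x, d$n_0_y))
  sbr <- if (ctr > 0) side / ctr else Inf
  bounds <- c(0L, fit$change_points, fit$n)
  prec <- vapply(seq_len(length(bounds) - 1L), function(k) {
    idx <- (bounds[k] + 1L):bounds[k + 1L]
    if (length(idx) > 1L) stats::sd(trace$x[idx]) else NA_real_
  }, numeric(1L))
  precision <- mean(prec, na.rm = TRUE)
  run_nm <- abs(fit$levels_on[length(fit$levels_on)] - fit$levels_on[1L])
  run_s <- fit$t_end[length(fit$t_end)] - fit$t_start[1L]
  metrics <- list(mean_photons = photons, mean_sbr = sbr,
                  mean_precision_nm = precision,
                  run_length_nm = run_nm, run_time_s = run_s)
  pass <- photons >= thresholds$min_photons &&
    sbr >= thresholds$min_sbr &&
    (is.na(precision) || precision <= thresholds$max_precision_nm) &&
    run_nm >= thresholds$min_run_nm &&
    run_s >= thresholds$min_run_s
  list(pass = pass, metrics = metrics)
}
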