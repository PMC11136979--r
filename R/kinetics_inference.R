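#' Dwell-time densities of the two-state stepping model
#'
#' The unbound (1HB) dwell is a pure exponential with mean \code{tau1}.
#' The bound dwell between two detected full steps spans the labeled head's
#' own ATP wait plus the partner head's complete cycle (equal kinetics of
#' both heads), i.e. the sum of two exponential 2HB waits and one
#' exponential 1HB wait; its density is
#' \deqn{p_B(t) = \frac{1}{\tau_2(\tau_2-\tau_1)}\left(t e^{-t/\tau_2}
#'   - \frac{\tau_1\tau_2}{\tau_2-\tau_1}\left(e^{-t/\tau_2}
#'   - e^{-t/\tau_1}\right)\right),}
#' which integrates to 1 and has mean \code{2*tau2 + tau1}.
#' \code{dwell_bound_density} evaluates it through a numerically stable
#' convolution form (a series expansion takes over near
#' \code{tau1 = tau2}, where the closed form cancels catastrophically).
#'
#' @param t dwell time(s), same unit as the taus (ms throughout the
#'   package); non-positive values have density 0.
#' @param tau1 mean 1HB dwell (> 0).
#' @param tau2 mean 2HB dwell (> 0).
#' @return Density values (or their log with \code{log = TRUE}).
#' @param log if \code{TRUE}, return log-density.
#' @export
dwell_bound_density <- function(t, tau1, tau2, log = FALSE) {
  if (tau1 <= 0 || tau2 <= 0) stop("taus must be > 0")
  f <- numeric(length(t))
  pos <- is.finite(t) & t > 0
  tp <- t[pos]
  if (abs(tau2 - tau1) > 1e-3 * max(tau1, tau2)) {
    # closed form: only decaying exponentials, safe away from tau1 = tau2
    f[pos] <- pmax(
      tp * exp(-tp / tau2) / (tau2 * (tau2 - tau1)) -
        tau1 / (tau2 - tau1)^2 * (exp(-tp / tau2) - exp(-tp / tau1)),
      0)
  } else {
    # near-degenerate: convolution form with h(x) = (1-(1+x)e^{-x})/x^2
    # expanded in series; |x| = |(1/tau2 - 1/tau1) t| stays small wherever
    # the density is non-negligible
    x <- (1 / tau2 - 1 / tau1) * tp
    h <- ifelse(abs(x) < 1e-2,
                1 / 2 - x / 3 + x^2 / 8 - x^3 / 30 + x^4 / 144,
                (1 - (1 + x) * exp(-x)) / x^2)
    f[pos] <- exp(-tp / tau1) / (tau1 * tau2^2) * tp^2 * h
  }
  f[!pos & !is.na(t)] <- 0
  if (log) base::log(pmax(f, .Machine$double.xmin)) else f
}

#' @rdname dwell_bound_density
#' @export
dwell_unbound_density <- function(t, tau1, log = FALSE) {
  if (tau1 <= 0) stop("tau1 must be > 0")
  stats::dexp(t, rate = 1 / tau1, log = log)
}

#' Sample dwells from the stepping model
#'
#' Generative counterparts of the densities: unbound dwells are exponential
#' with mean \code{tau1}; bound dwells are the sum of two exponential waits
#' of mean \code{tau2} and one of mean \code{tau1}.
#'
#' @param n number of dwells.
#' @param tau1,tau2 mean dwells (ms).
#' @return Numeric vector of dwell times (ms).
#' @export
rdwell_unbound <- function(n, tau1) stats::rexp(n, rate = 1 / tau1)

#' @rdname rdwell_unbound
#' @export
rdwell_bound <- function(n, tau1, tau2) {
  stats::rexp(n, rate = 1 / tau2) + stats::rexp(n, rate = 1 / tau2) +
    stats::rexp(n, rate = 1 / tau1)
}

#' Joint maximum-likelihood fit of the dwell-time model
#'
#' Fits (tau_1HB, tau_2HB) simultaneously to the pooled unbound and bound
#' dwell times: unbound dwells contribute through the exponential density
#' and bound dwells through \code{\link{dwell_bound_density}}.  Optimization
#' starts from moment estimates (\code{tau1 = mean(unbound)};
#' \code{tau2 = (mean(bound) - tau1)/2}) on the log scale; standard errors
#' come from the observed information at the optimum.
#'
#' With \code{bound = NULL} the fit reduces to the exponential-only model,
#' whose MLE is the sample mean in closed form.
#'
#' @param unbound unbound (1HB) dwell times in ms; all > 0, at least 5 when
#'   fitting jointly.
#' @param bound bound (2HB-flanked) dwell times in ms, or \code{NULL} for
#'   the unbound-only fit.
#' @return An object of class \code{"dwell_fit"}: \code{tau_1HB},
#'   \code{tau_2HB}, \code{se_tau_1HB}, \code{se_tau_2HB}, \code{loglik},
#'   \code{n_unbound}, \code{n_bound}.
#' @export
fit_dwell_model <- function(unbound, bound = NULL) {
  unbound <- as.numeric(unbound)
  if (length(unbound) < 1L || any(!is.finite(unbound)) || any(unbound <= 0))
    stop("unbound dwells must be positive and non-empty")
  if (is.null(bound) || length(bound) == 0L) {
    tau1 <- mean(unbound)
    return(structure(list(tau_1HB = tau1, tau_2HB = NA_real_,
                          se_tau_1HB = tau1 / sqrt(length(unbound)),
                          se_tau_2HB = NA_real_,
                          loglik = sum(stats::dexp(unbound, 1 / tau1, log = TRUE)),
                          n_unbound = length(unbound), n_bound = 0L),
                     class = "dwell_fit"))
  }
  bound <- as.numeric(bound)
  if (any(!is.finite(bound)) || any(bound <= 0))
    stop("bound dwells must be positive")
  if (length(unbound) < 5L || length(bound) < 5L)
    stop("need at least 5 dwells in each state for a joint fit")

  nll <- function(par) {
    tau1 <- exp(par[1L]); tau2 <- exp(par[2L])
    -sum(stats::dexp(unbound, 1 / tau1, log = TRUE)) -
      sum(dwell_bound_density(bound, tau1, tau2, log = TRUE))
  }
  tau1_0 <- mean(unbound)
  tau2_0 <- (mean(bound) - tau1_0) / 2
  if (!is.finite(tau2_0) || tau2_0 <= 0) tau2_0 <- mean(bound) / 3
  opt <- stats::optim(log(c(tau1_0, tau2_0)), nll, method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 2000L))
  H <- stats::optimHess(opt$par, nll)
  se_log <- tryCatch(sqrt(diag(solve(H))), error = function(e) c(NA_real_, NA_real_))
  taus <- exp(opt$par)
  structure(list(tau_1HB = taus[1L], tau_2HB = taus[2L],
                 se_tau_1HB = taus[1L] * se_log[1L],
                 se_tau_2HB = taus[2L] * se_log[2L],
                 loglik = -opt$value,
                 n_unbound = length(unbound), n_bound = length(bound),
                 convergence = opt$convergence),
            class = "dwell_fit")
}

#' @export
print.dwell_fit <- function(x, ...) {
  cat(sprintf("<dwell_fit> tau_1HB = %.2f +/- %.2f ms, tau_2HB = %s ms (n = %d U, %d B; loglik %.1f)\n",
              x$tau_1HB, x$se_tau_1HB,
              if (is.na(x$tau_2HB)) "NA"
              else sprintf("%.2f +/- %.2f", x$tau_2HB, x$se_tau_2HB),
              x$n_unbound, x$n_bound, x$loglik))
  invisible(x)
}

#' Fit the 1HB-duration versus velocity relation
#'
#' The renewal identity v = dx / (t_1HB + t_2HB) inverts to the rational
#' form \code{t_1HB(v) = 1000 * dx / v - t_2HB} (t in ms, v in nm/s, dx in
#' nm), which is linear in 1/v and is fitted by (optionally weighted) least
#' squares.
#'
#' @param velocity mean velocities (nm/s), at least two distinct values.
#' @param t_1HB corresponding mean 1HB durations (ms).
#' @param weights optional least-squares weights.
#' @return An object of class \code{"velocity_relation_fit"}: \code{dx_nm},
#'   \code{t_2HB_ms}, standard errors, \code{residuals} and the underlying
#'   \code{lm} fit.
#' @export
fit_velocity_relation <- function(velocity, t_1HB, weights = NULL) {
  if (length(velocity) < 2L || length(velocity) != length(t_1HB))
    stop("need >= 2 (velocity, t_1HB) points of equal length")
  if (length(unique(velocity)) < 2L)
    stop("velocities are identical: the system is singular")
  inv_v <- 1000 / velocity
  fit <- if (is.null(weights)) stats::lm(t_1HB ~ inv_v)
         else stats::lm(t_1HB ~ inv_v, weights = weights)
  cf <- stats::coef(fit)
  # an exact interpolation (zero residual) is legitimate here; summary.lm
  # would warn about its degenerate variance estimate
  se <- suppressWarnings(sqrt(diag(stats::vcov(fit))))
  structure(list(dx_nm = unname(cf[2L]), t_2HB_ms = unname(-cf[1L]),
                 se_dx_nm = unname(se[2L]), se_t_2HB_ms = unname(se[1L]),
                 residuals = unname(stats::residuals(fit)), lm = fit),
            class = "velocity_relation_fit")
}

#' @export
print.velocity_relation_fit <- function(x, ...) {
  cat(sprintf("<velocity_relation_fit> dx = %.2f +/- %.2f nm, t_2HB = %.2f +/- %.2f ms\n",
              x$dx_nm, x$se_dx_nm, x$t_2HB_ms, x$se_t_2HB_ms))
  invisible(x)
}

#' Mean velocity of a fitted trace
#'
#' Net on-axis displacement (last minus first plateau level) over the trace
#' duration.
#'
#' @param fit a \code{"step_fit"}; a stationary single-plateau trace has
#'   velocity 0.
#' @return Velocity in nm/s (nm per time unit of the fit).
#' @export
trace_velocity <- function(fit) {
  stopifnot(inherits(fit, "step_fit"))
  K <- length(fit$levels_on)
  if (K < 1L) stop("empty step fit")
  dur <- fit$t_end[K] - fit$t_start[1L]
  if (dur <= 0) stop("trace duration is zero")
  (fit$levels_on[K] - fit$levels_on[1L]) / dur
}

#' Collect paired off-axis substep displacements
#'
#' For every resolved substep pair (a B-U step immediately followed by a
#' U-B step) the off-axis sizes of the two steps form one pair.
#'
#' @param states a \code{"state_sequence"}.
#' @param fit the corresponding \code{"step_fit"} with off-axis steps.
#' @return A two-column matrix (\code{bu}, \code{ub}) of off-axis step
#'   sizes in nm, one row per pair.
#' @export
substep_offaxis_pairs <- function(states, fit) {
  stopifnot(inherits(states, "state_sequence"))
  off <- if (inherits(fit, "step_fit")) fit$steps_off else as.numeric(fit)
  lab <- states$labels
  if (is.null(off) || length(off) != length(lab) - 1L)
    stop("off-axis steps are missing or inconsistent with the state labels")
  i <- which(lab[-length(lab)] == "B" & lab[-1L] == "U")
  i <- i[i + 1L <= length(off)]  # need the following U->B step
  cbind(bu = off[i], ub = off[i + 1L])
}

#' Covariance and correlation of paired off-axis substep displacements
#'
#' Summarizes the lateral excursion of the head during the unbound state:
#' covariance matrix of the (B-U, U-B) off-axis pairs, the covariance
#' ellipse (semi-axes and orientation from its eigen-decomposition) and the
#' Pearson correlation.
#'
#' @param pairs a two-column matrix or data frame of paired off-axis step
#'   sizes (nm), e.g. from \code{\link{substep_offaxis_pairs}} (rows from
#'   several traces may be concatenated); at least 3 pairs.
#' @return An object of class \code{"offaxis_correlation"}:
#'   \code{covariance} (2x2, nm^2), \code{semi_axes} (nm),
#'   \code{orientation} (radians of the major axis), \code{correlation},
#'   \code{n}.
#' @export
offaxis_correlation <- function(pairs) {
  pairs <- as.matrix(pairs)
  if (ncol(pairs) != 2L) stop("pairs must have two columns")
  if (nrow(pairs) < 3L) stop("need at least 3 substep pairs")
  cv <- stats::cov(pairs)
  eg <- eigen(cv, symmetric = TRUE)
  r <- stats::cor(pairs[, 1L], pairs[, 2L])
  structure(list(covariance = cv,
                 semi_axes = sqrt(pmax(eg$values, 0)),
                 orientation = atan2(eg$vectors[2L, 1L], eg$vectors[1L, 1L]),
                 correlation = r, n = nrow(pairs)),
            class = "offaxis_correlation")
}

#' @export
print.offaxis_correlation <- function(x, ...) {
  cat(sprintf("<offaxis_correlation> r = %.3f (n = %d), ellipse %.1f x %.1f nm at %.0f deg\n",
              x$correlation, x$n, x$semi_axes[1L], x$semi_axes[2L],
              x$orientation * 180 / pi))
  invisible(x)
}

#' Detect microtubule switches and direction reversals
#'
#' A motor transferring to another microtubule mid-walk shows an off-axis
#' jump exceeding the ~25 nm microtubule diameter and/or a reversal of its
#' walking direction (kinesin itself is strictly plus-end directed).  An
#' event is emitted for every off-axis step larger than
#' \code{offaxis_threshold} in magnitude, and for every change of the
#' on-axis direction sustained for at least \code{min_run} consecutive
#' steps (single back-steps are not flagged).
#'
#' @param fit a \code{"step_fit"} with on- and off-axis steps.
#' @param offaxis_threshold off-axis jump threshold (nm), default 25.
#' @param min_run steps the new direction must persist, default 3.
#' @return A data frame with one row per event: \code{time} (s),
#'   \code{offaxis_jump} (nm), \code{duration} (s, time resolution of the
#'   jump), \code{direction_reversed}.
#' @export
detect_switches <- function(fit, offaxis_threshold = 25, min_run = 3L) {
  stopifnot(inherits(fit, "step_fit"))
  n <- length(fit$steps_on)
  off <- if (is.null(fit$steps_off)) rep(0, n) else fit$steps_off
  dt <- if (length(fit$change_dt) == n) fit$change_dt else rep(0, n)
  jump_idx <- which(abs(off) > offaxis_threshold)

  rev_idx <- integer(0)
  s <- sign(fit$steps_on)
  nz <- which(s != 0)
  if (length(nz)) {
    dir <- s[nz[1L]]
    j <- 1L
    while (j <= length(nz)) {
      i <- nz[j]
      if (s[i] != dir) {
        run <- nz[j:min(length(nz), j + min_run - 1L)]
        sustained <- length(run) >= min_run &&
          all(s[run] == s[i]) &&
          all(diff(run) == 1L)  # consecutive steps in the new direction
        if (sustained) {
          rev_idx <- c(rev_idx, i)
          dir <- s[i]
        }
      }
      j <- j + 1L
    }
  }
  idx <- sort(union(jump_idx, rev_idx))
  data.frame(time = fit$t_change[idx],
             offaxis_jump = off[idx],
             duration = dt[idx],
             direction_reversed = idx %in% rev_idx)
}
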