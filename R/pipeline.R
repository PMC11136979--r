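#' Simulate a complete MINFLUX tracking measurement
#'
#' Convenience wrapper: builds (or accepts) kinetic parameters, simulates a
#' motor path and runs the MINFLUX acquisition on it.  A single seed drives
#' both the kinetics and the photon noise.
#'
#' @param construct,atp_level preset labels, see \code{\link{make_preset}}.
#' @param duration requested duration (s).
#' @param seed integer seed; the run is bit-reproducible given it.
#' @param config a \code{\link{beam_config}}.
#' @param params optional \code{\link{kinetic_params}} overriding the
#'   preset.
#' @return A \code{"raw_trace"} with the ground-truth path attached as
#'   \code{attr(, "motor_path")}.
#' @export
simulate_trace <- function(construct = "K28C", atp_level = "low",
                           duration = 2, seed = NULL,
                           config = beam_config(), params = NULL) {
  if (is.null(params)) params <- make_preset(construct, atp_level)
  if (!is.null(seed)) set.seed(seed)
  params$seed <- NULL  # one RNG stream for path and photons
  path <- simulate_motor_path(params, duration)
  raw <- run_acquisition(path, config)
  meta <- attr(raw, "metadata")
  meta$construct <- attr(params, "construct")
  meta$atp_level <- attr(params, "atp_level")
  meta$seed <- seed
  attr(raw, "metadata") <- meta
  raw
}

#' Run the full analysis pipeline on a raw trace
#'
#' Chains position refinement (\code{\link{sliding_curvature_estimate}}),
#' principal-axis alignment, step fitting, HMM state annotation and dwell
#' extraction.
#'
#' @param raw a \code{"raw_trace"}.
#' @param T_ms sliding-curvature window (ms).
#' @param min_step,median_width step-fit filters, see \code{\link{fit_steps}}.
#' @param hmm an \code{\link{hmm_spec}}.
#' @return A list with \code{trace} (refined, aligned), \code{fit},
#'   \code{states}, \code{dwells} (ms, censored edges excluded),
#'   \code{velocity} (nm/s, \code{NA} if fewer than 2 plateaus) and
#'   \code{qc} metrics.
#' @export
analyze_trace <- function(raw, T_ms = 20, min_step = 2, median_width = 9,
                          hmm = hmm_spec()) {
  refined <- sliding_curvature_estimate(raw, T_ms = T_ms)
  aligned <- align_principal_axis(refined)
  fit <- fit_trace_steps(aligned, min_step = min_step,
                         median_width = median_width)
  if (length(fit$steps_on) >= 1L) {
    states <- annotate_states(fit, hmm)
    dwells <- extract_dwells(states, fit)
    velocity <- trace_velocity(fit)
  } else {
    states <- NULL
    dwells <- list(unbound = numeric(0), bound = numeric(0))
    velocity <- NA_real_
  }
  qc <- trace_qc(raw, aligned, fit)
  list(trace = aligned, fit = fit, states = states, dwells = dwells,
       velocity = velocity, qc = qc)
}

# ---- command-line interface --------------------------------------------

.cli_args <- function(args) {
  # parse --key value / --key=value pairs into a named character list
  out <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("unexpected argument '", a, "'")
    a <- sub("^--", "", a)
    if (grepl("=", a)) {
      kv <- strsplit(a, "=", fixed = TRUE)[[1L]]
      out[[gsub("-", "_", kv[1L])]] <- paste(kv[-1L], collapse = "=")
    } else {
      if (i == length(args)) stop("missing value for --", a)
      out[[gsub("-", "_", a)]] <- args[i + 1L]
      i <- i + 1L
    }
    i <- i + 1L
  }
  out
}

.cli_get <- function(opts, key, default = NULL, required = FALSE) {
  if (!is.null(opts[[key]])) return(opts[[key]])
  if (required) stop("missing required option --", gsub("_", "-", key))
  default
}

.cli_simulate <- function(opts) {
  seed <- as.integer(.cli_get(opts, "seed", "1"))
  raw <- simulate_trace(construct = .cli_get(opts, "construct", "K28C"),
                        atp_level = .cli_get(opts, "atp", "low"),
                        duration = as.numeric(.cli_get(opts, "duration", "2")),
                        seed = seed)
  write_trace(raw, .cli_get(opts, "out", required = TRUE))
  0L
}

.cli_analyze <- function(opts) {
  raw <- read_trace(.cli_get(opts, "in", required = TRUE))
  res <- analyze_trace(raw,
                       T_ms = as.numeric(.cli_get(opts, "T_ms", "20")),
                       min_step = as.numeric(.cli_get(opts, "min_step", "2")),
                       median_width = as.integer(.cli_get(opts, "median_width", "9")))
  write_steps(res$fit, .cli_get(opts, "out", required = TRUE),
              states = res$states)
  0L
}

.cli_fit <- function(opts) {
  files <- strsplit(.cli_get(opts, "in", required = TRUE), ",")[[1L]]
  unb <- bnd <- numeric(0)
  velocities <- numeric(0)
  pairs <- NULL
  switches <- 0L
  for (f in files) {
    fit <- read_steps(f)
    st <- attr(fit, "states")
    if (!is.null(st)) {
      dw <- extract_dwells(st, fit)
      unb <- c(unb, dw$unbound); bnd <- c(bnd, dw$bound)
      if (!is.null(fit$steps_off))
        pairs <- rbind(pairs, substep_offaxis_pairs(st, fit))
    }
    if (length(fit$levels_on) >= 2L)
      velocities <- c(velocities, trace_velocity(fit))
    switches <- switches + nrow(detect_switches(fit))
  }
  res <- list(n_traces = length(files),
              velocity_nm_s = velocities,
              n_unbound_dwells = length(unb), n_bound_dwells = length(bnd),
              n_switch_events = switches)
  if (length(unb) >= 5L && length(bnd) >= 5L) {
    df <- fit_dwell_model(unb, bnd)
    res$tau_1HB_ms <- df$tau_1HB; res$tau_2HB_ms <- df$tau_2HB
    res$se_tau_1HB_ms <- df$se_tau_1HB; res$se_tau_2HB_ms <- df$se_tau_2HB
  } else if (length(unb) >= 1L) {
    res$tau_1HB_ms <- fit_dwell_model(unb)$tau_1HB
  }
  if (!is.null(pairs) && nrow(pairs) >= 3L)
    res$offaxis_correlation <- offaxis_correlation(pairs)$correlation
  write_results(res, .cli_get(opts, "out", required = TRUE))
  0L
}

.cli_report <- function(opts) {
  fit <- read_steps(.cli_get(opts, "in", required = TRUE))
  edges <- seq(-40, 40, by = 1)
  h <- population_histogram(fit$steps_on, edges)
  out <- .cli_get(opts, "out", required = TRUE)
  con <- file(out, "w")
  on.exit(close(con))
  writeLines("bin_left_nm\tbin_right_nm\theight", con)
  writeLines(sprintf("%s\t%s\t%s", .fmt(edges[-length(edges)]),
                     .fmt(edges[-1L]), .fmt(h$heights)), con)
  0L
}

#' Command-line entry point
#'
#' Dispatches the \code{simulate}, \code{analyze}, \code{fit} and
#' \code{report} subcommands used by the \code{inst/scripts/kinestep-cli.R}
#' wrapper script.  Options are \code{--key value} pairs; see the script
#' for usage.  Exit status: 0 ok, 1 bad input/usage, 2 internal error.
#'
#' @param args character vector of command-line arguments (subcommand
#'   first).
#' @return Integer exit status, invisibly.
#' @export
kinestep_cli <- function(args) {
  if (length(args) < 1L ||
      !args[1L] %in% c("simulate", "analyze", "fit", "report")) {
    message("usage: kinestep <simulate|analyze|fit|report> [--options]")
    return(invisible(1L))
  }
  status <- tryCatch({
    opts <- .cli_args(args[-1L])
    switch(args[1L],
           simulate = .cli_simulate(opts),
           analyze = .cli_analyze(opts),
           fit = .cli_fit(opts),
           report = .cli_report(opts))
  },
  error = function(e) {
    message("kinestep: ", conditionMessage(e))
    if (grepl("missing required option|unexpected argument|missing value|unknown",
              conditionMessage(e))) 1L else 2L
  })
  invisible(as.integer(status))
}
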