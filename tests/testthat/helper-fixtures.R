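# Fixture builders and independent oracles used across the test files.

# Noisy staircase with known change points.
make_staircase <- function(sizes, samples_per_plateau = 30L, noise_sd = 0,
                           level0 = 0) {
  levels <- cumsum(c(level0, sizes))
  x <- rep(levels, each = samples_per_plateau)
  if (noise_sd > 0) x <- x + rnorm(length(x), 0, noise_sd)
  list(x = x, levels = levels,
       change_points = seq(samples_per_plateau, by = samples_per_plateau,
                           length.out = length(sizes)))
}

# Motor path that never steps (static emitter for localization tests).
static_path <- function(duration = 5) {
  simulate_motor_path(kinetic_params(tau_2HB = 1e9, tau_1HB = 1e9), duration)
}

# Minimal raw_trace wrapper around hand-built per-cycle columns, so the
# refinement stage can be tested on exactly controlled photon counts.
fake_raw_trace <- function(t, L, nx, ny, center_x = 0, center_y = 0) {
  n <- length(t)
  df <- data.frame(t = t, L = L,
                   center_x = rep_len(center_x, n),
                   n_minus_x = nx[, 1L], n_0_x = nx[, 2L], n_plus_x = nx[, 3L],
                   est_x = 0, valid_x = TRUE,
                   center_y = rep_len(center_y, n),
                   n_minus_y = ny[, 1L], n_0_y = ny[, 2L], n_plus_y = ny[, 3L],
                   est_y = 0, valid_y = TRUE,
                   valid = TRUE)
  structure(df, class = c("raw_trace", "data.frame"),
            metadata = list(), beam_config = NULL)
}

# Build a step_fit directly from plateau levels and dwell durations (s);
# used to feed the inference stages with exactly known step sequences.
make_step_fit <- function(levels_on, levels_off = NULL, dwells = NULL) {
  K <- length(levels_on)
  if (is.null(dwells)) dwells <- rep(0.01, K)
  t_start <- cumsum(c(0, dwells[-K]))
  t_end <- t_start + dwells
  kinestep:::new_step_fit(change_points = seq_len(K - 1L),
                          t_change = t_end[-K],
                          change_dt = rep(0, K - 1L),
                          levels_on = levels_on, levels_off = levels_off,
                          t_start = t_start, t_end = t_end,
                          n = K, sigma = 0, source = "test")
}

# ---- independent HMM oracle --------------------------------------------
# Exhaustive maximization over all legal label paths (no U->U), written
# directly from the model definition and independent of the Viterbi code.
# Applies the same documented tie-break bonuses so ties are deterministic.

legal_paths <- function(n_plat) {
  paths <- list(1L, 2L)  # 1 = B, 2 = U
  for (i in seq_len(n_plat - 1L)) {
    nxt <- list()
    for (p in paths) {
      last <- p[length(p)]
      nxt[[length(nxt) + 1L]] <- c(p, 1L)
      if (last == 1L) nxt[[length(nxt) + 1L]] <- c(p, 2L)
    }
    paths <- nxt
  }
  paths
}

oracle_path_score <- function(path, sizes, spec) {
  np <- length(path)
  bonus <- function(i) 1e-6 + 1e-9 * (np - i + 1) / np
  sc <- log(spec$init[path[1L]]) + if (path[1L] == 1L) bonus(1L) else 0
  for (i in seq_along(sizes)) {
    s <- path[i]; s2 <- path[i + 1L]
    sc <- sc + if (s == 1L && s2 == 1L) {
      log(1 - spec$p_sub) + dnorm(sizes[i], spec$mu_full, spec$sigma_step, log = TRUE)
    } else if (s == 1L && s2 == 2L) {
      log(spec$p_sub) + dnorm(sizes[i], spec$mu_sub_bu, spec$sigma_step, log = TRUE)
    } else if (s == 2L && s2 == 1L) {
      dnorm(sizes[i], spec$mu_sub_ub, spec$sigma_step, log = TRUE)
    } else -Inf
    if (s2 == 1L) sc <- sc + bonus(i + 1L)
  }
  sc
}

oracle_decode <- function(sizes, spec) {
  paths <- legal_paths(length(sizes) + 1L)
  scores <- vapply(paths, oracle_path_score, numeric(1L),
                   sizes = sizes, spec = spec)
  c("B", "U")[paths[[which.max(scores)]]]
}
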