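#' Hidden Markov specification for bound/unbound annotation
#'
#' Structural model of a kinesin step sequence: plateaus are either bound
#' (B, labeled head on the microtubule) or unbound (U, between paired
#' substeps).  Regular steps (B to B transitions) are 16 nm; substeps come
#' in pairs of around 8 nm, a B to U step followed by a U to B step, so a
#' U plateau can never be followed by another U plateau.  Emissions are
#' Gaussian around the transition means with common standard deviation
#' \code{sigma_step}.
#'
#' For constructs with asymmetric substeps (label near the neck linker) the
#' two substep means can be set per direction: \code{mu_sub_bu} for the
#' bound-to-unbound substep and \code{mu_sub_ub} for the unbound-to-bound
#' substep.
#'
#' @param mu_full emission mean (nm) of regular B-B steps, default 16.
#' @param mu_sub common substep emission mean (nm), default 8.
#' @param sigma_step emission standard deviation (nm), > 0.  Default 3 nm:
#'   per-localization precision of 4-5 nm, averaged over plateau samples.
#' @param p_sub prior probability that a cycle resolves its substeps
#'   (weight of the B-to-U transition), in [0, 1].
#' @param init initial distribution over (bound, unbound).  The default
#'   weights the unbound start by \code{p_sub}: a trace that begins in the
#'   unbound state implies an unobserved bound-to-unbound substep just
#'   before it, which carries the same resolution probability.  (A uniform
#'   start would let a fully alternating substep sequence of odd length
#'   flip its phase wholesale, because the unbound-first reading saves one
#'   transition cost.)
#' @param mu_sub_bu,mu_sub_ub optional per-direction substep means (nm);
#'   both default to \code{mu_sub}.
#' @return An object of class \code{"hmm_spec"}.
#' @export
hmm_spec <- function(mu_full = 16, mu_sub = 8, sigma_step = 3, p_sub = 0.5,
                     init = NULL,
                     mu_sub_bu = mu_sub, mu_sub_ub = mu_sub) {
  if (sigma_step <= 0) stop("sigma_step must be > 0")
  if (p_sub < 0 || p_sub > 1) stop("p_sub must lie in [0, 1]")
  if (is.null(init)) init <- c(bound = 1, unbound = p_sub)
  if (length(init) != 2L || any(init < 0) || sum(init) <= 0)
    stop("init must be two non-negative weights over (bound, unbound)")
  structure(list(mu_full = mu_full, mu_sub_bu = mu_sub_bu,
                 mu_sub_ub = mu_sub_ub, sigma_step = sigma_step,
                 p_sub = p_sub, init = init / sum(init)),
            class = "hmm_spec")
}

# Additive tie-break bonuses: likelihood ties (e.g. a lone 8 nm step read as
# B->U vs U->B) are broken toward bound plateaus, and among those toward
# binding earlier.  The bonuses are additive per plateau, so Viterbi with
# the augmented score still maximizes it exactly; they are far below any
# likelihood difference between genuinely distinct paths.
.state_bonus <- function(i, n_plat) {
  1e-6 + 1e-9 * (n_plat - i + 1) / n_plat
}

# log score of transition from state s (1=B, 2=U) to state s2 given step
# size, including the destination plateau's tie-break bonus.
.trans_score <- function(size, s, s2, spec, i2, n_plat) {
  lp <- if (s == 1L && s2 == 1L) {
    log1p(-spec$p_sub) + stats::dnorm(size, spec$mu_full, spec$sigma_step, log = TRUE)
  } else if (s == 1L && s2 == 2L) {
    log(spec$p_sub) + stats::dnorm(size, spec$mu_sub_bu, spec$sigma_step, log = TRUE)
  } else if (s == 2L && s2 == 1L) {
    stats::dnorm(size, spec$mu_sub_ub, spec$sigma_step, log = TRUE)
  } else -Inf
  lp + if (s2 == 1L) .state_bonus(i2, n_plat) else 0
}

#' Annotate plateaus as bound or unbound (Viterbi decoding)
#'
#' Finds the most likely bound/unbound label sequence for the plateaus of a
#' step fit under the \code{\link{hmm_spec}} structure: emissions are
#' Gaussian around 16 nm for B-B transitions and around the substep means
#' for B-U and U-B transitions; U-U transitions are forbidden (substeps come
#' in pairs).  Exact likelihood ties are broken toward the path with more
#' bound plateaus (conservative: fewer claimed substeps), then toward
#' binding earlier.
#'
#' @param steps a \code{"step_fit"} or a numeric vector of on-axis step
#'   sizes (nm); n steps imply n + 1 plateaus.
#' @param spec an \code{\link{hmm_spec}}.
#' @return An object of class \code{"state_sequence"}: list with
#'   \code{labels} (\code{"B"}/\code{"U"} per plateau) and \code{loglik}
#'   (log-likelihood of the decoded path, without tie-break bonuses).
#' @examples
#' annotate_states(c(16, 8, 8, 16))$labels  # B B U B B
#' @export
annotate_states <- function(steps, spec = hmm_spec()) {
  sizes <- if (inherits(steps, "step_fit")) steps$steps_on else as.numeric(steps)
  n <- length(sizes)
  if (n < 1L) stop("need at least one step")
  if (!inherits(spec, "hmm_spec")) stop("spec must be an hmm_spec")
  np <- n + 1L
  V <- matrix(-Inf, nrow = np, ncol = 2L)
  bp <- matrix(0L, nrow = np, ncol = 2L)
  ini <- log(spec$init)
  V[1L, 1L] <- ini[1L] + .state_bonus(1L, np)
  V[1L, 2L] <- ini[2L]
  for (i in seq_len(n)) {
    for (s2 in 1:2) {
      best <- -Inf; arg <- 0L
      for (s in 1:2) {
        sc <- V[i, s] + .trans_score(sizes[i], s, s2, spec, i + 1L, np)
        if (sc > best) { best <- sc; arg <- s }
      }
      V[i + 1L, s2] <- best
      bp[i + 1L, s2] <- arg
    }
  }
  lab <- integer(np)
  lab[np] <- if (V[np, 1L] >= V[np, 2L]) 1L else 2L
  for (i in rev(seq_len(n))) lab[i] <- bp[i + 1L, lab[i + 1L]]
  labels <- c("B", "U")[lab]
  # plain log-likelihood of the decoded path (no tie-break bonuses)
  ll <- ini[lab[1L]]
  for (i in seq_len(n))
    ll <- ll + .trans_score(sizes[i], lab[i], lab[i + 1L], spec, i + 1L, np) -
      if (lab[i + 1L] == 1L) .state_bonus(i + 1L, np) else 0
  structure(list(labels = labels, loglik = ll), class = "state_sequence")
}

#' @export
print.state_sequence <- function(x, ...) {
  cat("<state_sequence> ", paste(x$labels, collapse = " "),
      sprintf("  (loglik %.3f)\n", x$loglik), sep = "")
  invisible(x)
}

#' Extract bound and unbound dwell times
#'
#' Unbound dwells are the durations of U plateaus (the 1HB interval between
#' paired substeps); bound dwells are the durations of B plateaus (the
#' labeled head microtubule-bound between detected steps).  The first and
#' last plateaus are excluded: their durations are censored by the trace
#' start and stop.
#'
#' @param states a \code{"state_sequence"} from \code{\link{annotate_states}}.
#' @param steps the \code{"step_fit"} the states were decoded from (its
#'   \code{dwells} are in s).
#' @return A list with \code{unbound} and \code{bound} dwell vectors in ms.
#' @export
extract_dwells <- function(states, steps) {
  stopifnot(inherits(states, "state_sequence"))
  dw <- if (inherits(steps, "step_fit")) steps$dwells else as.numeric(steps)
  K <- length(states$labels)
  if (length(dw) != K)
    stop("labels and plateau durations are inconsistent in length")
  if (K <= 2L) return(list(unbound = numeric(0), bound = numeric(0)))
  interior <- 2L:(K - 1L)
  lab <- states$labels[interior]
  list(unbound = dw[interior][lab == "U"] * 1000,
       bound = dw[interior][lab == "B"] * 1000)
}
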