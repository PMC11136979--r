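---
title: "Models and methods behind kinestep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind kinestep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

kinestep simulates MINFLUX tracking of a fluorophore on one kinesin-1 head
and analyses the resulting traces: position refinement, change-point step
fitting, hidden-Markov annotation of bound/unbound states, and kinetic
model fits.  This vignette records the models, the tunable parameters, the
numerical choices, and what the synthetic data can and cannot tell you
about real measurements.

## The stepping model

Kinesin-1 walks along a microtubule protofilament; the labeled head
advances 16 nm per step, the spacing of free binding sites, and each such
step resolves into two substeps of roughly 8 nm separated by a
one-head-bound (1HB) interval.  The two-head-bound (2HB) interval
separates full steps.  `simulate_motor_path()` renders this as an
alternating renewal process:

* 2HB dwell, exponential with mean `tau_2HB` (ms);
* substep 1 (mean `substep1_mean`), entering the 1HB state;
* 1HB dwell, exponential with mean `tau_1HB`;
* substep 2 (mean `substep2_mean = 16 - substep1_mean`), re-binding.

ATP is taken up during the 1HB state, so the ATP-level presets
(`make_preset()`) vary `tau_1HB` and keep `tau_2HB` near-constant at 9 ms:
`tau_1HB` = 60, 20 and 45 ms for low (50 µM), mid (500 µM) and high (5 mM)
ATP.  These values were chosen once so that the renewal velocities
`16/(tau_1HB + tau_2HB)` — about 232, 552 and 296 nm/s — bracket the range
of typical kinesin-1 velocities in cells; they are working points, not
fitted constants.  The non-monotonic ordering (5 mM slower than 500 µM)
mirrors the observed lack of velocity saturation at high ATP; this package
offers no mechanistic model for it, it is simply part of the preset
conditions.

Two modelling assumptions deserve emphasis:

* **Both dwells are single-exponential.**  For the 1HB state this is
  forced by the dwell-time model below, whose unbound density is a pure
  exponential.  For the 2HB state a single exponential is the simplest
  choice consistent with the weak velocity dependence of the bound-state
  duration; nothing in the package depends on it being exactly right, but
  parameter-recovery results should be read with this assumption in mind.
* **Substeps pair to exactly 16 nm.**  Substep 1 is Gaussian
  (`substep_sd`, truncated to (0, 16) nm); substep 2 is its complement to
  16 nm, because the head re-binds on the discrete binding-site lattice.
  Construct `K28C` uses symmetric 8 + 8 nm substeps, `T324C` asymmetric
  6 + 10 nm, reflecting how the label position changes the apparent
  substep partition.

Each substep also carries a lateral (off-axis) displacement: the pair of
shifts entering and leaving the 1HB state is bivariate Gaussian with
standard deviation `offaxis_shift_sd` (3 nm) and correlation
`offaxis_corr`.  For `K28C` the preset correlation is −0.3 — the lateral
excursion is partially reversed on re-binding, as expected if the tethered
head swings to one side and returns to the protofilament axis; the sign
and size are a package choice, since only the existence of a small
correlation is established.  `T324C` uses 0.

Microtubule switches are a Poisson process (`switch_rate`) independent of
the stepping cycle: each switch adds a uniform off-axis jump from
`switch_offaxis_range` (default 30–80 nm, random sign), increments the
microtubule id and reverses the walking direction with probability
`reversal_prob`.  Detachment ends the path at an exponential time
(`detach_rate`).  There is no force model, no load dependence, no 3D
lattice geometry and no tethered-head diffusion.

## The acquisition model

MINFLUX localizes by probing an excitation line minimum at three positions
`[-L/2, 0, +L/2]` around the current estimate and updating

```
x_new = x_old + (L/4) (n_minus - n_plus) / (n_plus + n_minus - 2 n_0)
```

A localization fails if fewer than five photons were collected or if
`2 (n_plus + n_minus - 2 n_0) < |n_minus - n_plus|`, which caps valid
corrections at L/2.  A triplet with equal side counts and zero curvature
term carries no position information; `update_position()` then applies a
zero correction, the safest interpretation.

The intensity around the minimum is modelled as a clean quadratic —
`lambda = brightness * offset^2 + background` per exposure — because the
update rule above is exactly the quadratic-minimum estimator; no
donut-beam profile is introduced.  The zoom-in schedule defaults to
L = 150, 100, 75, 50 nm with one successful localization per stage and an
open-ended loop at the final L = 50 nm; failed localizations repeat at the
same L, and a run of 50 consecutive failures ends the trace.  Timing per
2D cycle is `6 × 200 µs` exposures plus `6 × 5 µs` switching plus
`2 × 0.5 ns` recalculation = 1230.001 µs.  (The sum of these printed
components is what the package uses; a rounded figure of 1231 µs is
sometimes quoted, consistent with a 500 ns rather than 500 ps
recalculation time. The discrepancy is below one part in 10^3 and
irrelevant downstream.)

The default photon budget (`brightness = 0.007` photons/(nm²·exposure),
`background = 0.1` photons/exposure, about 11 photons per triplet) was
calibrated once so that the single-localization standard deviation at
L = 50 nm is ~4.5 nm, the middle of the 4–5 nm regime of MINFLUX motor
tracking; with it, roughly 10% of cycles fail and are repeated.

## Position refinement and step fitting

The sliding curvature estimator replaces the noisy per-cycle denominator
(the pattern curvature) with its mean over a centred window of `T_ms` =
20 ms: the motor barely moves within 20 ms, so the curvature is constant
over the window and averaging it reduces localization noise without
temporal smoothing of the numerator.  The window is time-defined (not
sample-count-defined), truncates at the trace ends, and only mixes cycles
probed with the same L, since the curvature scales with L².  Cycles whose
window-mean curvature is not positive are dropped.

After aligning the dominant displacement direction with +x (principal
component of the 2D position covariance, sign fixed by the net movement),
steps are fitted in three stages:

1. **Recursive binary segmentation** on squared-error cost.  A split is
   accepted when it lowers the cost by more than
   `penalty_mult * sigma² * log(n)` (default multiplier 2), with `sigma`
   estimated robustly as `mad(diff(x))/sqrt(2)`.  The exact penalty and
   termination rule of the original step-fitting literature are not
   published; this BIC-style rule is a standard, deterministic choice and
   is calibrated so a flat noise-only series yields zero change points.
   Candidate segments keep at least 3 samples per side, which avoids
   single-sample plateaus the median filter would erase anyway.
2. **Moving median of width 9** applied to the fitted step function,
   removing plateaus created by isolated spikes.  Change points and
   plateau levels are re-derived from the filtered function itself —
   re-fitting levels from the raw data at this stage would leak erased
   spikes back into segment means.
3. **A single round of small-step removal**: steps below `min_step` = 2 nm
   merge their plateaus, and final levels are re-fit as segment means of
   the data.  Removal can push neighbouring steps below 2 nm; these are
   deliberately not re-removed (single round).

The off-axis coordinate gets no change-point search of its own: the
on-axis change points delimit its plateaus and each level is the segment
mean.  A consequence worth knowing: an off-axis jump that falls inside an
on-axis plateau is split between the two flanking plateau means, so
detected switch jumps can read 10–30% low; the detection threshold (25 nm,
the microtubule diameter) is far enough below the simulated 60 nm jumps
that detection is unaffected.

## State annotation and dwell extraction

The hidden Markov model (`hmm_spec()`, `annotate_states()`) encodes
exactly two structural assumptions: regular steps are 16 nm, and substeps
come in pairs of about 8 nm — so a bound plateau is followed by bound
(emission N(16, sigma)) or unbound (N(8, sigma)), and an unbound plateau
is always followed by bound (N(8, sigma)); unbound-to-unbound is
forbidden.  The emission/transition parameterization is not published;
this Gaussian-emission minimal structure is the package's choice.
Emission sigma defaults to 3 nm (4–5 nm localizations averaged over
plateau samples).  For `T324C` the two substep means can be set per
direction (6 nm entering, 10 nm leaving the unbound state).

Two decoding details:

* The initial distribution weights an unbound start by `p_sub`.  A trace
  that begins unbound implies an unobserved bound-to-unbound substep just
  before its start, which carries the same resolution probability; with a
  uniform start, a fully alternating substep sequence of odd length would
  flip its phase wholesale because the unbound-first reading saves one
  transition cost.
* Exact likelihood ties (e.g. a lone 8 nm step read as B→U versus U→B)
  are broken toward bound plateaus — the conservative reading that claims
  fewer substeps — then toward binding earlier, via additive score bonuses
  (10⁻⁶ per bound plateau, position-weighted 10⁻⁹) that are orders of
  magnitude below any genuine likelihood difference.  The exhaustive-path
  oracle in the test suite applies the same documented rule, so
  equivalence checks are exact.

Dwells are plateau durations: unbound plateaus give 1HB dwells, bound
plateaus 2HB-state dwells.  The first and last plateaus are censored by
the trace boundaries and excluded.  Substeps erased by the 2 nm filter are
invisible to the HMM — there is no missing-step imputation; a missed pair
simply appears as a 16 nm bound-to-bound transition, which is exactly what
the bound-dwell model absorbs (next section).

## Dwell-time and velocity models

The unbound dwell density is a pure exponential,
`p_U(t) = exp(-t/tau_1HB)/tau_1HB`.  The bound dwell between two detected
full steps is modelled as

```
p_B(t) = 1/(tau2 (tau2 - tau1)) * ( t exp(-t/tau2)
         - tau1 tau2/(tau2 - tau1) * (exp(-t/tau2) - exp(-t/tau1)) )
```

This expression integrates to one and is identical to the hypoexponential
density of the sum of two exponential tau2 waits and one exponential tau1
wait (mean `2 tau2 + tau1`) — the labeled head stays bound through its own
ATP wait plus the partner head's complete cycle, assuming equal kinetics
of both heads.  `fit_dwell_model()` maximizes the joint likelihood of both
pools over `(tau_1HB, tau_2HB)` on the log scale from moment-based starts
(`tau1 = mean(unbound)`, `tau2 = (mean(bound) - tau1)/2`), with standard
errors from the observed information.

Numerics: the closed form above cancels catastrophically as
`tau1 → tau2`; within 0.1% of the degeneracy the density is evaluated
through the convolution form `exp(-t/tau1)/(tau1 tau2²) t² h(x)` with
`h(x) = (1-(1+x)e^{-x})/x²` expanded in series for small
`x = (1/tau2 - 1/tau1) t`.  The two branches agree to ~10⁻⁵ across the
switch, so the likelihood stays smooth through the equal-rate line that
the recovery grid crosses.

Because the simulator's observable bound plateau in a fully resolved trace
is a single exponential (the alternating renewal above), parameter
recovery of the *fitting machinery* is assessed on dwells drawn from the
model's own generative form (`rdwell_unbound()`, `rdwell_bound()`),
while pipeline-extracted dwells are checked against the simulator's means.
On pipeline output, where short 2HB plateaus are frequently merged, the
joint fit is the right tool precisely because `p_B` models the merged
interval; raw means of detected unbound dwells are biased low by the
resolution limit, which also shows up as the detected-substep fraction
rising with `tau_1HB`.

The 1HB-duration/velocity relation is the rational form
`t_1HB(v) = 1000 dx / v - t_2HB` (t in ms, v in nm/s, dx in nm): the
renewal identity `v = dx/(t_1HB + t_2HB)` inverted, linear in `1/v` and
fitted by (optionally weighted) least squares; the fit is unweighted by
default since no weighting scheme is established for these points.

## Summary representations

Histograms are normalized to the population size (`population_histogram`),
bivariate step-size scatters are colored by the number of neighbours
within a 4 nm radius (`density_scatter`), and violins are Gaussian kernel
densities; passing a `shared_bandwidth()` (Silverman's rule on the pooled
values) makes densities of several datasets comparable — the common-
bandwidth rule is the package's documented choice where none is published.
Covariance ellipses of paired off-axis substeps come from the
eigen-decomposition of the 2×2 covariance matrix
(`offaxis_correlation`).

Files are tab-separated with `# key=value` metadata headers; numbers are
written with 17 significant digits so doubles round-trip exactly and
writer output is byte-deterministic.

## What the synthetic data does and does not show

The generator reproduces the kinetic and geometric structure the analysis
assumes: exponential dwells, paired substeps on a 16 nm lattice, lateral
substep shifts, Poisson photon counts from a quadratic line minimum with
background, 4–5 nm localizations, rare large off-axis switch jumps.  It
does **not** emulate fluorophore photophysics (blinking, bleaching),
drift, roadblock-induced pausing or detours, variable SBR along a neurite,
the 3D projection of motion on curved microtubule bundles, or
trace-selection bias by a human screener.  Passing tests therefore
establish that the analysis recovers the truth *under the stated model* —
they quantify method behaviour (bias from the resolution limit, split
switch jumps, phase anchoring of the HMM), not biological conclusions
about real neurites.

## Problem sizes

The test suite and the acceptance script use sizes chosen to make
Monte-Carlo conclusions stable at interactive run times: 10⁵ triplets per
estimator offset; 100 staircases of ~10 plateaus for step-fit recovery;
all 87,380 step sequences up to length 8 for the Viterbi/enumeration
equivalence; 20 replicates × 2,000 dwells per cell of the 3×3 dwell-model
grid; 10 traces of 2 s per ATP condition (roughly 400–800 detected steps
each) for the end-to-end velocity, substep-fraction and switch analyses;
2,000 substep pairs for the off-axis correlation.  These are the package's
reference settings; all are parameters of ordinary exported functions and
scale up directly.

## Known limitations

* Step-fit accuracy degrades sharply when plateaus are shorter than ~8
  samples at the default noise level; with `tau_2HB` = 9 ms and a 1.23 ms
  cycle this regime is genuinely hard, so detected dwell pools
  under-represent short intervals.  The joint dwell model compensates for
  merged full steps but not for fragmented long plateaus.
* The sliding curvature estimator only averages the denominator; its
  variance reduction over the per-cycle estimator is modest (~10%) at the
  default photon budget, growing with window length and signal rate.
* Off-axis plateau levels inherit on-axis change points, so lateral jumps
  inside an on-axis plateau are split across two steps (see above).
* `detect_switches()` requires three consecutive steps in the new
  direction before declaring a reversal; reversals within the last two
  steps of a trace are undetectable by design (single back-steps are more
  often fit artefacts than switches).
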