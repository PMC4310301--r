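#' Continuous relaxation of the Tsodyks-Markram synaptic variables
#'
#' Between spikes the depression variable r recovers toward 1 with time
#' constant tau_rec and the facilitation variable u relaxes toward the
#' utilization U with time constant tau_facil. The exact exponential
#' relaxation over one step dt is used (stabler than Euler for small time
#' constants; tau_facil can be as small as 1 ms = dt).
#'
#' @param r,u Matrices (or vectors) of synaptic depression / facilitation
#'   state.
#' @param U,tau_rec,tau_facil STP parameters, same shape as `r` (times in
#'   ms).
#' @param dt Step (ms).
#' @return List with updated `r` and `u`.
#' @export
stp_decay_step <- function(r, u, U, tau_rec, tau_facil, dt = 1) {
  r <- r + (1 - r) * (1 - exp(-dt / tau_rec))
  u <- u + (U - u) * (1 - exp(-dt / tau_facil))
  list(r = r, u = u)
}

#' Spike-triggered STP update and release
#'
#' On a presynaptic spike the facilitation variable is incremented,
#' u <- u + U (1 - u), the synapse releases r * u of its resources, and the
#' depression variable is depleted by the released amount. Under the
#' standard Tsodyks-Markram convention (`facil_first = TRUE`) the release
#' is evaluated with the post-increment u, so a first spike from rest
#' (r = 1, u = U) releases U(2 - U); with `facil_first = FALSE` release
#' uses the pre-increment u and the first amplitude from rest is U. The
#' released amount multiplied by the maximum strength A gives the
#' effective efficacy w = r u A.
#'
#' @inheritParams stp_decay_step
#' @param facil_first Apply the facilitation increment before computing the
#'   release (default, the convention used throughout).
#' @return List with updated `r`, `u` and the `release` amounts (r*u per
#'   synapse).
#' @export
stp_on_spike <- function(r, u, U, facil_first = TRUE) {
  if (facil_first) {
    u <- u + U * (1 - u)
    release <- r * u
    r <- r - release
  } else {
    release <- r * u
    r <- r - release
    u <- u + U * (1 - u)
  }
  list(r = r, u = u, release = release)
}

#' Periodic-stimulation fixed point of the TM spike-to-spike map
#'
#' For a single synapse driven at a fixed rate, the spike-to-spike map of
#' the depression/facilitation dynamics has a unique fixed point
#' (r_ss, u_ss): the state seen by each spike once transients have died
#' out. Closed forms follow from composing the exponential inter-spike
#' relaxation with the spike update; `u_ss` is the post-facilitation value
#' used for release.
#'
#' @param U,tau_rec,tau_facil Scalar STP parameters (times in ms).
#' @param rate Stimulation rate (Hz); 0 returns the rest state (1, U).
#' @param facil_first Release convention, see [stp_on_spike()].
#' @return List with `r_ss`, `u_ss` and `release_ss = r_ss * u_ss`.
#' @export
stp_steady_state <- function(U, tau_rec, tau_facil, rate, facil_first = TRUE) {
  if (rate < 0) stop("rate must be >= 0")
  if (rate == 0) return(list(r_ss = 1, u_ss = U, release_ss = U))
  isi <- 1000 / rate                     # ms between spikes
  ef <- exp(-isi / tau_facil)
  er <- exp(-isi / tau_rec)
  # u just before a spike: u- = U + (u+ - U) ef, with u+ = u- + U (1 - u-),
  # so u+ - U = u- (1 - U)  =>  u- = U / (1 - (1 - U) ef)
  um <- U / (1 - (1 - U) * ef)
  up <- um + U * (1 - um)
  u_rel <- if (facil_first) up else um
  # r just before a spike: r- = 1 - (1 - r+) er, with r+ = r- (1 - u_rel)
  # => r- = (1 - er) / (1 - (1 - u_rel) er)
  rm <- (1 - er) / (1 - (1 - u_rel) * er)
  list(r_ss = rm, u_ss = u_rel, release_ss = rm * u_rel)
}

#' Single-synapse release train
#'
#' Drives one synapse from full rest with `n_spikes` spikes at a fixed
#' rate and returns the sequence of release amplitudes r_k u_k, the
#' postsynaptic-response profile used to classify a synapse as facilitating
#' (amplitudes initially rise) or depressing (monotone decay). Following
#' the standard measurement convention for paired-pulse protocols the
#' facilitation variable of the rested synapse starts at `u0 = 0`, so the
#' first amplitude is exactly U and any rise over subsequent spikes
#' reflects facilitation (inside the network, where synapses are never
#' fully rested, u relaxes to U instead).
#'
#' @inheritParams stp_steady_state
#' @param n_spikes Number of stimulation spikes (>= 1).
#' @param u0 Initial facilitation state (0 = fully rested measurement
#'   convention).
#' @return Numeric vector of `n_spikes` release amplitudes.
#' @export
synapse_trace <- function(U, tau_rec, tau_facil, rate, n_spikes = 10,
                          facil_first = TRUE, u0 = 0) {
  stopifnot(n_spikes >= 1, rate > 0)
  isi <- 1000 / rate
  r <- 1; u <- u0
  amps <- numeric(n_spikes)
  for (k in seq_len(n_spikes)) {
    if (k > 1) {
      r <- r + (1 - r) * (1 - exp(-isi / tau_rec))
      u <- u + (U - u) * (1 - exp(-isi / tau_facil))
    }
    s <- stp_on_spike(r, u, U, facil_first)
    r <- s$r; u <- s$u
    amps[k] <- s$release
  }
  amps
}

#' Classify a release train as facilitating or depressing
#'
#' A trace is facilitating when its amplitudes initially rise (the second
#' amplitude exceeds the first), depressing when they decrease from the
#' first spike on.
#'
#' @param amps Release amplitudes from [synapse_trace()].
#' @return `"facilitating"` or `"depressing"`.
#' @export
classify_trace <- function(amps) {
  if (length(amps) < 2) return("depressing")
  if (amps[2] > amps[1]) "facilitating" else "depressing"
}
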