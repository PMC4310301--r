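#' Initialize the four STDP spike-history traces
#'
#' Each neuron carries two presynaptic indicators (m1, fast; m2, slow) and
#' two postsynaptic indicators (o1 fast, o2 slow). All decay exponentially
#' toward zero and jump by 1 at that neuron's own spikes.
#'
#' @param n Number of neurons.
#' @return List of four zero vectors `m1`, `m2`, `o1`, `o2`.
#' @export
triplet_traces <- function(n) {
  z <- numeric(n)
  list(m1 = z, m2 = z, o1 = z, o2 = z)
}

#' Decay and increment the STDP traces over one step
#'
#' @param traces List from [triplet_traces()].
#' @param spikes Logical vector of this step's spikes.
#' @param const Constants (uses `dt` and the four trace time constants).
#' @return Updated traces list.
#' @export
traces_step <- function(traces, spikes, const = default_params()) {
  dt <- const$dt
  traces$m1 <- traces$m1 * exp(-dt / const$tau_m1)
  traces$m2 <- traces$m2 * exp(-dt / const$tau_m2)
  traces$o1 <- traces$o1 * exp(-dt / const$tau_o1)
  traces$o2 <- traces$o2 * exp(-dt / const$tau_o2)
  if (any(spikes)) {
    traces$m1[spikes] <- traces$m1[spikes] + 1
    traces$m2[spikes] <- traces$m2[spikes] + 1
    traces$o1[spikes] <- traces$o1[spikes] + 1
    traces$o2[spikes] <- traces$o2[spikes] + 1
  }
  traces
}

#' Triplet-STDP weight changes triggered by this step's spikes
#'
#' For every spiking neuron i the rule potentiates i's incoming synapses
#' j -> i in proportion to the presynaptic fast trace m1_j,
#' \deqn{\Delta A_{ij} = +\gamma m^1_j (A_2^+ + A_3^+ o^2_i),}
#' and depresses i's outgoing synapses i -> k in proportion to the target's
#' fast postsynaptic trace o1_k,
#' \deqn{\Delta A_{ki} = -\gamma o^1_k (A_2^- + A_3^- m^2_i).}
#' The slow traces o2_i and m2_i are read at their values just before the
#' triggering spike's own +1 increment (the epsilon convention); all traces
#' passed in must therefore be the pre-increment values for this step.
#'
#' @param traces Pre-increment traces for this step.
#' @param spikes Logical vector of this step's spikes.
#' @param mask Logical matrix of existing synapses (entry (i, j): j -> i).
#' @param gamma STDP learning rate.
#' @param const Constants (STDP amplitudes).
#' @return Matrix of weight changes Delta A (same shape as `mask`), zero on
#'   non-synapses.
#' @export
stdp_deltas <- function(traces, spikes, mask, gamma, const = default_params()) {
  n <- length(spikes)
  dA <- matrix(0, n, n)
  for (i in which(spikes)) {
    # potentiation of incoming j -> i (row i)
    pot <- gamma * traces$m1 * (const$A2_plus + const$A3_plus * traces$o2[i])
    dA[i, ] <- dA[i, ] + pot * mask[i, ]
    # depression of outgoing i -> k (column i)
    dep <- gamma * traces$o1 * (const$A2_minus + const$A3_minus * traces$m2[i])
    dA[, i] <- dA[, i] - dep * mask[, i]
  }
  dA
}

#' Combine STDP and STP-driven weight changes with hard bounds
#'
#' Applies A <- A + Delta A^STDP + Delta A^STP and clips each existing
#' synapse once to the hard interval [A_min, A_max]; masked entries (absent
#' synapses, diagonal) stay exactly 0.
#'
#' @param A Maximum-strength matrix.
#' @param dA_stdp,dA_stp Weight-change matrices (either may be 0).
#' @param mask Logical matrix of existing synapses.
#' @param const Constants (`A_min`, `A_max`).
#' @return Updated weight matrix.
#' @export
total_weight_update <- function(A, dA_stdp, dA_stp, mask,
                                const = default_params()) {
  A <- A + dA_stdp + dA_stp
  A <- pmin(pmax(A, const$A_min), const$A_max)
  A[!mask] <- 0
  A
}
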