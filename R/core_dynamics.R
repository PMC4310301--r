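#' Euler step of the membrane equation
#'
#' Advances the sub-threshold membrane potential of every non-refractory
#' neuron by one explicit-Euler step of
#' \deqn{dV_i/dt = -g_L V_i + \sum_{j \ne i} g_{ij} (E_{rev} - V_i),}
#' where the conductances are treated numerically as rates (1/ms).
#' Refractory neurons are held clamped at V = 0.
#'
#' @param V Numeric vector of membrane potentials (mV).
#' @param refractory Logical vector, `TRUE` for neurons inside their
#'   refractory period at this step.
#' @param g Conductance matrix; entry (i, j) is the conductance of the
#'   synapse j -> i (diagonal must be 0).
#' @param const Constants from [default_params()] (uses `g_L`, `E_rev`,
#'   `dt`).
#' @return Updated potential vector.
#' @export
step_membrane <- function(V, refractory, g, const = default_params()) {
  if (!all(is.finite(V))) stop("non-finite membrane potential (diverging input)")
  gin <- rowSums(g)
  Vn <- V + const$dt * (-const$g_L * V + gin * (const$E_rev - V))
  Vn[refractory] <- 0
  if (!all(is.finite(Vn))) stop("membrane step produced non-finite potential")
  Vn
}

#' Threshold crossing and refractory bookkeeping
#'
#' Neurons with V >= V_thr (1 mV) emit a spike; their potential is reset to
#' 0 and they are refractory for the next t_ref = 10 ms, which caps the
#' sustainable firing rate at 1/t_ref = 100 Hz.
#'
#' @param V Membrane potentials after [step_membrane()].
#' @param ref_until Per-neuron time (ms) until which the neuron is
#'   refractory.
#' @param t Current time (ms).
#' @inheritParams step_membrane
#' @return List with `spikes` (logical), `V` (reset), `ref_until`.
#' @export
detect_spikes <- function(V, ref_until, t, const = default_params()) {
  spikes <- (t >= ref_until) & (V >= const$V_thr)
  V[spikes] <- 0
  ref_until[spikes] <- t + const$t_ref
  list(spikes = spikes, V = V, ref_until = ref_until)
}

#' Conductance decay and spike-triggered injection
#'
#' Conductances decay toward zero with the exact per-step exponential
#' factor exp(-dt/tau_g); each presynaptic spike of neuron j then adds the
#' effective efficacy w_ij = r_ij u_ij A_ij to every g_ij.
#'
#' @param g Conductance matrix (entry (i, j): synapse j -> i).
#' @param presyn_spikes Logical vector over presynaptic neurons.
#' @param w Effective efficacy matrix for this step (only columns of
#'   spiking neurons are read).
#' @inheritParams step_membrane
#' @return Updated conductance matrix.
#' @export
conductance_step <- function(g, presyn_spikes, w, const = default_params()) {
  if (any(w[, presyn_spikes] < 0)) stop("negative effective efficacy")
  g <- g * exp(-const$dt / const$tau_g)
  if (any(presyn_spikes)) {
    idx <- which(presyn_spikes)
    g[, idx] <- g[, idx] + w[, idx, drop = FALSE]
  }
  g
}
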