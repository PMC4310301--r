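#' Exponential-moving-average firing-rate update
#'
#' Each neuron's rate estimate decays with time constant tau_nu (1 s) and
#' receives a unit impulse (+1 Hz) per spike, so that steady firing at
#' f Hz yields an estimate of f Hz. Estimates are capped at the refractory
#' limit nu_lim = 100 Hz.
#'
#' @param nu Numeric vector of rate estimates (Hz).
#' @param spikes Logical vector of this step's spikes.
#' @param const Constants (`dt`, `tau_nu`, `nu_lim`).
#' @return Updated rate vector.
#' @export
rate_ema_step <- function(nu, spikes, const = default_params()) {
  nu <- nu * exp(-const$dt / const$tau_nu)
  nu[spikes] <- nu[spikes] + 1
  pmin(nu, const$nu_lim)
}

#' Population task error
#'
#' The squared normalized rate error E = ((nu_targ - <nu>) / nu_lim)^2
#' minimized by the error-driven STP rules.
#'
#' @param nu_targ Target rate (Hz).
#' @param nu_mean Population mean rate estimate (Hz).
#' @param nu_lim Maximum rate (Hz), 1/t_ref.
#' @return Scalar error.
#' @export
compute_error <- function(nu_targ, nu_mean, nu_lim = 100) {
  ((nu_targ - nu_mean) / nu_lim)^2
}

#' Error-dependent learning rate for the STP parameters
#'
#' The three STP parameters share the rate
#' eta = eta_bar (1 + (nu_targ - <nu>) / nu_lim)^2, which accelerates
#' learning when the population fires below target and damps it when
#' above. The learning rate for the maximum strength A stays fixed at the
#' STDP rate gamma.
#'
#' @inheritParams compute_error
#' @param eta_bar Base rate (0.1).
#' @return Scalar learning rate.
#' @export
adaptive_learning_rate <- function(nu_targ, nu_mean, eta_bar = 0.1,
                                   nu_lim = 100) {
  eta_bar * (1 + (nu_targ - nu_mean) / nu_lim)^2
}

#' Per-spike error-driven updates of the incoming synapses of one neuron
#'
#' When neuron i spikes it backwards-regulates its incoming synapses j -> i
#' using the gradient of the population error through the mean-field
#' surrogate relations (<nu> bounded by A/tau_rec + I_ext and its U- and
#' tau_facil-analogues):
#' \deqn{\Delta\tau_{rec} = -2\eta (\nu_t - \langle\nu\rangle) A /
#'   (\nu_{lim}^2 \tau_{rec}^2)}
#' \deqn{\Delta U = -2\eta (\nu_t - \langle\nu\rangle) A /
#'   (\nu_{lim}^2 U^2)}
#' \deqn{\Delta\tau_{facil} = +2\eta (\nu_t - \langle\nu\rangle) A /
#'   \nu_{lim}^2}
#' \deqn{\Delta A^{STP} = 2\gamma (\nu_t - \langle\nu\rangle) /
#'   (\nu_{lim}^2 \tau_{rec})}
#' with rates in Hz and time constants in seconds. Inputs and outputs here
#' carry time constants in ms (the state convention); the conversion is
#' internal. Deltas for parameters excluded from the scheme are exactly 0.
#' `<nu>` is the mean of i's population, not nu_i: the task is defined at
#' population level.
#'
#' @param U,tau_rec,tau_facil,A Numeric vectors: the incoming-synapse row
#'   of neuron i (tau in ms).
#' @param nu_targ,nu_mean Target and population-mean rate (Hz).
#' @param config [learning_config()] (scheme flags, eta_bar, gamma,
#'   learn_scale).
#' @param const Constants (`nu_lim`, bounds are applied by the caller).
#' @return List of deltas `dU`, `dtau_rec` (ms), `dtau_facil` (ms),
#'   `dA_stp`.
#' @export
stp_learning_deltas <- function(U, tau_rec, tau_facil, A, nu_targ, nu_mean,
                                config, const = default_params()) {
  err <- nu_targ - nu_mean                       # Hz
  eta <- adaptive_learning_rate(nu_targ, nu_mean, config$eta_bar,
                                const$nu_lim) * config$learn_scale
  nl2 <- const$nu_lim^2
  trec_s <- tau_rec / 1000                       # seconds in the rules
  dtrec <- if (config$learn[["taurec"]])
    -2 * eta * err * A / (nl2 * trec_s^2) * 1000 else 0 * tau_rec
  dU <- if (config$learn[["U"]])
    -2 * eta * err * A / (nl2 * U^2) else 0 * U
  dtf <- if (config$learn[["taufacil"]])
    2 * eta * err * A / nl2 * 1000 else 0 * tau_facil
  dA <- if (config$learn[["A"]])
    2 * config$gamma * config$learn_scale * err / (nl2 * trec_s) else 0 * A
  list(dU = dU, dtau_rec = dtrec, dtau_facil = dtf, dA_stp = dA)
}

#' Clip STP parameters to their hard bounds
#'
#' @param U,tau_rec,tau_facil Parameter arrays (tau in ms).
#' @param const Constants holding the bounds.
#' @return List of clipped arrays.
#' @export
clip_stp_params <- function(U, tau_rec, tau_facil, const = default_params()) {
  list(U = pmin(pmax(U, const$U_min), const$U_max),
       tau_rec = pmin(pmax(tau_rec, const$tau_rec_min), const$tau_rec_max),
       tau_facil = pmin(pmax(tau_facil, const$tau_facil_min),
                        const$tau_facil_max))
}
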