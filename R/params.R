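#' Default model constants
#'
#' Returns the full set of constants used by the neuron, synapse and
#' plasticity models: membrane and conductance constants, spike threshold
#' and refractory period, STP parameter bounds, triplet-STDP amplitudes and
#' trace time constants, hard bounds on the maximum synaptic strength, the
#' base STP learning rate and the discretization step. All times are in ms,
#' rates in Hz, conductances in uS (treated numerically as 1/ms rates in
#' the membrane equation).
#'
#' @return Named list of constants (class `stp_constants`).
#' @export
default_params <- function() {
  structure(list(
    E_rev = 30,          # reversal potential (mV)
    g_L = 0.1,           # leak conductance (uS)
    tau_g = 10,          # conductance decay (ms)
    V_thr = 1,           # spike threshold (mV)
    t_ref = 10,          # refractory period (ms)
    dt = 1,              # integration step (ms)
    nu_lim = 100,        # 1/t_ref, maximum sustainable rate (Hz)
    tau_nu = 1000,       # rate-EMA time constant (ms)
    nu_in = 10,          # per-neuron wave-stimulus rate (Hz)
    stim_amp = 2,        # stimulus pulse amplitude (mV), suprathreshold
    U_min = 0.05, U_max = 0.95,
    tau_rec_min = 100, tau_rec_max = 900,     # ms
    tau_facil_min = 1, tau_facil_max = 900,   # ms
    A_min = 1e-3, A_max = 1,
    eta_bar = 0.1,       # base STP learning rate
    coupling = 0.27,     # dimensionless synaptic coupling; the per-spike
                         # conductance increment is w_ij * coupling / N
                         # (size-normalized, see the methods vignette)
    A2_plus = 4.6e-3, A3_plus = 9.1e-3,   # triplet LTP amplitudes
    A2_minus = 3.0e-3, A3_minus = 7.5e-9, # triplet LTD amplitudes
    tau_m1 = 16.8, tau_m2 = 575,          # presynaptic trace decays (ms)
    tau_o1 = 33.7, tau_o2 = 47            # postsynaptic trace decays (ms)
  ), class = "stp_constants")
}

#' Learning-scheme configuration
#'
#' Selects which synaptic parameters are adapted by the error-driven STP
#' rules. All schemes run the triplet STDP rule; the scheme decides which of
#' U, tau_rec, tau_facil receive per-spike gradient updates and whether the
#' STP-dependent rule for the maximum strength A is active.
#'
#' @param scheme One of `"U_taurec"` (U and tau_rec only), `"U_taurec_A"`,
#'   `"full"` (U, tau_rec, tau_facil and A), `"minimal_taurec_A"` (tau_rec
#'   and A only) or `"U_A"` (U and A only; the combination that fails to
#'   reach high rate targets).
#' @param eta_bar Base learning rate for the STP parameters (error-dependent
#'   scaling is applied on top, see [adaptive_learning_rate()]).
#' @param gamma STDP learning rate, also the fixed learning rate of the
#'   STP-dependent A rule.
#' @param learn_scale Global calibration factor multiplying every
#'   error-driven update (1 = bare rules in Hz/seconds units; the default 5
#'   is the calibrated value used for the network experiments, see the
#'   methods vignette).
#' @param facil_first If `TRUE` (the standard Tsodyks-Markram convention)
#'   the facilitation increment is applied before release on a presynaptic
#'   spike; `FALSE` releases with the pre-increment u.
#' @param g_scale Optional direct override for the per-spike conductance
#'   scale; by default [run_simulation()] uses `coupling / N` from the
#'   model constants.
#' @param refrac_gate Sensitivity switch: if `TRUE`, conductance
#'   injections onto a refractory target are dropped instead of
#'   accumulated. Default `FALSE` (conductances accumulate during
#'   refractoriness; only the membrane is clamped).
#' @return List of class `learning_config`.
#' @export
learning_config <- function(scheme = c("full", "U_taurec", "U_taurec_A",
                                       "minimal_taurec_A", "U_A"),
                            eta_bar = 0.1, gamma = 2, learn_scale = 5,
                            facil_first = TRUE, g_scale = NULL,
                            refrac_gate = FALSE) {
  scheme <- match.arg(scheme)
  flags <- switch(scheme,
    U_taurec         = c(U = TRUE,  taurec = TRUE,  taufacil = FALSE, A = FALSE),
    U_taurec_A       = c(U = TRUE,  taurec = TRUE,  taufacil = FALSE, A = TRUE),
    full             = c(U = TRUE,  taurec = TRUE,  taufacil = TRUE,  A = TRUE),
    minimal_taurec_A = c(U = FALSE, taurec = TRUE,  taufacil = FALSE, A = TRUE),
    U_A              = c(U = TRUE,  taurec = FALSE, taufacil = FALSE, A = TRUE))
  stopifnot(eta_bar >= 0, gamma >= 0, learn_scale >= 0)
  structure(list(scheme = scheme, learn = flags, eta_bar = eta_bar,
                 gamma = gamma, learn_scale = learn_scale,
                 facil_first = isTRUE(facil_first), g_scale = g_scale,
                 refrac_gate = isTRUE(refrac_gate)),
            class = "learning_config")
}

#' @export
print.learning_config <- function(x, ...) {
  on <- names(x$learn)[x$learn]
  cat("<learning_config> scheme:", x$scheme,
      "| adapted:", paste(on, collapse = ", "),
      "| eta_bar:", x$eta_bar, "| gamma:", x$gamma, "\n")
  invisible(x)
}

#' Phase schedule
#'
#' An ordered list of task phases. Each phase has a duration and one target
#' firing rate per population; during a phase every neuron's error-driven
#' updates use its own population's target and mean rate.
#'
#' @param durations Numeric vector of phase durations in seconds.
#' @param targets Matrix (or vector for one phase) with one row per phase
#'   and one column per population, giving the target rate (Hz).
#' @param gamma Optional numeric vector, one STDP learning rate per phase;
#'   recycled if length 1.
#' @return List of class `phase_schedule`.
#' @export
phase_schedule <- function(durations, targets, gamma = 2) {
  durations <- as.numeric(durations)
  if (any(durations < 0)) stop("phase durations must be >= 0")
  targets <- rbind(targets)
  if (nrow(targets) != length(durations))
    targets <- matrix(targets, nrow = length(durations),
                      ncol = ncol(targets), byrow = TRUE)
  if (any(targets < 0)) stop("target rates must be >= 0")
  gamma <- rep_len(gamma, length(durations))
  structure(list(durations = durations, targets = targets, gamma = gamma),
            class = "phase_schedule")
}

#' Canonical four-phase single-population schedule
#'
#' Alternates the target of both populations through low-high-low-high
#' (5, 30, 5, 30 Hz), with the STDP rate gamma = 2 in low-target phases and
#' gamma = 1 in high-target phases.
#'
#' @param t_ph Phase duration in seconds (500 s for the canonical
#'   experiment).
#' @param low,high The two target rates (Hz).
#' @export
single_phase_schedule <- function(t_ph = 500, low = 5, high = 30) {
  tg <- matrix(c(low, low, high, high, low, low, high, high),
               nrow = 4, ncol = 2, byrow = TRUE)
  phase_schedule(rep(t_ph, 4), tg, gamma = c(2, 1, 2, 1))
}
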