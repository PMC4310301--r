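#' Sequential wave-stimulus protocol
#'
#' Input neurons are stimulated one after another in a fixed cyclic order
#' with lag t_delay = 1/(nu_in * n_in), so that each neuron receives
#' suprathreshold pulses at nu_in Hz and the stimulus sweeps the input
#' population like a traveling wave. Gaussian jitter with SD
#' 0.1 * t_delay is added to each nominal time; draws that would invert
#' the firing order of adjacent pulses are resampled so the cyclic order is
#' always preserved.
#'
#' @param n_in Number of input neurons.
#' @param horizon Protocol length (ms).
#' @param nu_in Per-neuron stimulus rate (Hz).
#' @param jitter_frac Jitter SD as a fraction of t_delay (0 disables
#'   jitter).
#' @param amplitude Pulse amplitude (mV), suprathreshold by construction.
#' @param order Permutation of `1:n_in` giving the stimulation order.
#' @return Object of class `stimulus_protocol`: a list with the event table
#'   `events` (columns `time_ms`, `neuron`) and the protocol parameters.
#' @export
build_protocol <- function(n_in, horizon, nu_in = 10, jitter_frac = 0.1,
                           amplitude = 2, order = seq_len(n_in)) {
  stopifnot(n_in >= 1, nu_in > 0)
  if (horizon <= 0) stop("horizon must be > 0")
  if (length(order) != n_in || !setequal(order, seq_len(n_in)))
    stop("order must be a permutation of 1:n_in")
  t_delay <- 1000 / (nu_in * n_in)             # ms
  sd <- jitter_frac * t_delay
  n_ev <- floor(horizon / t_delay)
  nominal <- (seq_len(n_ev) - 1) * t_delay
  neuron <- order[((seq_len(n_ev) - 1) %% n_in) + 1]
  times <- nominal
  if (sd > 0 && n_ev > 0) {
    prev <- -Inf
    for (k in seq_len(n_ev)) {
      repeat {
        tk <- nominal[k] + stats::rnorm(1, 0, sd)
        if (tk > prev && tk >= 0) break        # preserve firing order
      }
      times[k] <- tk
      prev <- tk
    }
  }
  keep <- times >= 0 & times < horizon
  structure(list(events = data.frame(time_ms = times[keep],
                                     neuron = neuron[keep]),
                 n_in = n_in, nu_in = nu_in, t_delay = t_delay,
                 jitter_sd = sd, amplitude = amplitude, order = order,
                 horizon = horizon),
            class = "stimulus_protocol")
}

#' @export
print.stimulus_protocol <- function(x, ...) {
  cat("<stimulus_protocol>", x$n_in, "input neurons at", x$nu_in,
      "Hz | t_delay", signif(x$t_delay, 4), "ms | jitter SD",
      signif(x$jitter_sd, 4), "ms |", nrow(x$events), "events over",
      x$horizon, "ms\n")
  invisible(x)
}

#' Apply due stimulus pulses to the membrane
#'
#' Adds the pulse amplitude (2 mV) to the membrane potential of each
#' stimulated neuron; a pulse arriving during the neuron's refractory
#' period is absorbed (the clamp keeps V at 0).
#'
#' @param V Membrane potentials (mV).
#' @param neurons Integer vector of neurons due a pulse this step.
#' @param refractory Logical vector of refractory neurons.
#' @param amplitude Pulse size (mV).
#' @return Updated potential vector.
#' @export
stimulus_pulse <- function(V, neurons, refractory, amplitude = 2) {
  if (length(neurons)) {
    hit <- neurons[!refractory[neurons]]
    V[hit] <- V[hit] + amplitude
  }
  V
}

#' Write / read a protocol event list as columnar text
#'
#' @param protocol A `stimulus_protocol`.
#' @param path File path (tab-separated, header `time_ms neuron`).
#' @export
write_protocol <- function(protocol, path) {
  utils::write.table(protocol$events, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_protocol
#' @export
read_protocol_events <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t")
}
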