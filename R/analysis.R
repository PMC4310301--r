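#' Symmetry index of a connectivity matrix
#'
#' Pairwise reciprocity statistic
#' \deqn{s = 1 - \frac{2}{N(N-1) - 2M} \sum_{i<j}
#'   \frac{|A_{ij} - A_{ji}|}{A_{ij} + A_{ji}},}
#' where M counts pairs with both connections absent (excluded from the
#' sum). s = 1 for a perfectly reciprocal (bidirectional) weight matrix and
#' approaches 0 when every pair is strictly one-way; iid uniform weights
#' give E[s] = 2 - 2 ln 2 (about 0.614). With weights bounded below by a
#' positive A_min, M = 0 always.
#'
#' @param A Square weight matrix with zero diagonal and nonnegative
#'   entries.
#' @return Object of class `symmetry_result` with `s`, `M` and `N`.
#' @export
symmetry_index <- function(A) {
  A <- as.matrix(A)
  if (nrow(A) != ncol(A)) stop("A must be square")
  if (any(A < 0)) stop("A must be nonnegative")
  res <- symmetry_index_cpp(A)
  if (is.na(res$s))
    warning("all pairs mutually absent: symmetry undefined")
  structure(list(s = res$s, M = res$M, N = nrow(A)),
            class = "symmetry_result")
}

#' Null distribution and p-value for the symmetry index
#'
#' Estimates the mean and SD of s on completely random networks (iid
#' uniform(0, 1) off-diagonal weights) by Monte Carlo and returns a
#' two-sided normal-approximation p-value for an observed s. The closed
#' form E[s] = 2 - 2 ln 2 (from E[|X-Y|/(X+Y)] = 2 ln 2 - 1 for iid
#' uniforms) is available as a cross-check of the sampler.
#'
#' @param s_obs Observed symmetry index.
#' @param N Matrix size the observation came from (>= 3).
#' @param n_null Number of Monte-Carlo null matrices.
#' @param seed Optional seed for the null sampler.
#' @return `symmetry_result` with `s`, `null_mean`, `null_sd`, `p_value`
#'   and the number of null samples.
#' @export
symmetry_p_value <- function(s_obs, N, n_null = 10000, seed = NULL) {
  if (N < 3) stop("N must be >= 3")
  if (!is.null(seed)) set.seed(seed)
  if (n_null < 100)
    warning("fewer than 100 null samples: variance estimate is unstable")
  null_s <- replicate(n_null, {
    A <- matrix(stats::runif(N * N), N, N)
    diag(A) <- 0
    symmetry_index_cpp(A)$s
  })
  mu <- mean(null_s); sdv <- stats::sd(null_s)
  z <- (s_obs - mu) / sdv
  structure(list(s = s_obs, N = N, null_mean = mu, null_sd = sdv,
                 n_null = n_null,
                 p_value = 2 * stats::pnorm(-abs(z))),
            class = "symmetry_result")
}

#' Closed-form null mean of the symmetry index
#'
#' @return 2 - 2 ln 2, the expected s of an iid-uniform random network.
#' @export
symmetry_null_mean <- function() 2 - 2 * log(2)

#' @export
print.symmetry_result <- function(x, ...) {
  cat("<symmetry_result> s =", signif(x$s, 4))
  if (!is.null(x$M)) cat(", M =", x$M)
  if (!is.null(x$p_value))
    cat(sprintf(" | null %.4f +/- %.4f, p = %.3g",
                x$null_mean, x$null_sd, x$p_value))
  cat("\n")
  invisible(x)
}

#' Projection-group summary of the STP parameters
#'
#' Summarizes the synaptic parameters of the synapses between the two
#' output populations of a double-scenario network, in the six groupings
#' used to map the emergent synapses onto the facilitation-dominated (E1)
#' and depression-dominated (E2) classes and their source-specific
#' subtypes: pooled onto out1 (E1), out1 -> out1 (E1a), out2 -> out1
#' (E1b), pooled onto out2 (E2), out2 -> out2 (E2a), out1 -> out2 (E2b).
#' For a single-scenario network a single row (all -> output) is returned.
#'
#' @param net An `stp_network` (typically after [run_simulation()]).
#' @return data.frame with group label, synapse count, mean and SD of
#'   tau_rec, tau_facil (ms) and U, the ratio of mean tau_rec to mean
#'   tau_facil, and the subtype label.
#' @export
group_summary <- function(net) {
  stopifnot(inherits(net, "stp_network"))
  pops <- net$spec$populations
  one <- function(label, tgt, src, subtype) {
    sel <- net$mask[tgt, src, drop = FALSE]
    if (!any(sel)) {
      warning("empty synapse group: ", label)
      return(NULL)
    }
    tr <- net$tau_rec[tgt, src, drop = FALSE][sel]
    tf <- net$tau_facil[tgt, src, drop = FALSE][sel]
    uu <- net$U[tgt, src, drop = FALSE][sel]
    data.frame(group = label, n = sum(sel),
               tau_rec_mean = mean(tr), tau_rec_sd = stats::sd(tr),
               tau_facil_mean = mean(tf), tau_facil_sd = stats::sd(tf),
               U_mean = mean(uu), U_sd = stats::sd(uu),
               ratio = mean(tr) / mean(tf), subtype = subtype)
  }
  if (net$spec$scenario == "single") {
    out <- one("all -> output", pops$output, seq_len(net$spec$N), "")
    rownames(out) <- NULL
    return(out)
  }
  both <- c(pops$out1, pops$out2)
  res <- rbind(
    one("out1+out2 -> out1", pops$out1, both, "E1"),
    one("out1 -> out1", pops$out1, pops$out1, "E1a"),
    one("out2 -> out1", pops$out1, pops$out2, "E1b"),
    one("out1+out2 -> out2", pops$out2, both, "E2"),
    one("out2 -> out2", pops$out2, pops$out2, "E2a"),
    one("out1 -> out2", pops$out2, pops$out1, "E2b"))
  rownames(res) <- NULL
  res
}
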