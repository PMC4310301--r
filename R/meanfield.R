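#' Mean-field population parameters
#'
#' Population-level description of a recurrently connected pool with
#' dynamic synapses: mean current h with decay tau, mean depression x and
#' facilitation u, synaptic parameters (A, U, tau_rec, tau_facil, all in
#' seconds here), external current I_ext, and a threshold-linear gain
#' <nu> = a * max(h - theta, 0). The gain constants a and theta are used
#' only for analytic validation, never by the network simulation.
#'
#' @param A,U,tau_rec,tau_facil Population synaptic parameters (tau in s).
#' @param tau Current decay constant (s).
#' @param I_ext Mean external current.
#' @param a,theta Gain-function constants.
#' @return List of class `meanfield_params`.
#' @export
meanfield_params <- function(A = 0.5, U = 0.5, tau_rec = 0.5,
                             tau_facil = 0.5, tau = 0.01, I_ext = 0,
                             a = 1, theta = 0) {
  stopifnot(tau > 0, tau_rec > 0, tau_facil > 0, U >= 0, U <= 1)
  structure(list(A = A, U = U, tau_rec = tau_rec, tau_facil = tau_facil,
                 tau = tau, I_ext = I_ext, a = a, theta = theta),
            class = "meanfield_params")
}

#' Right-hand side of the dynamic mean-field equations
#'
#' \deqn{\tau \dot h = -h + A u x \nu + I_{ext}}
#' \deqn{\dot x = (1 - x)/\tau_{rec} - u x \nu}
#' \deqn{\dot u = (U - u)/\tau_{facil} + U (1 - u) \nu}
#'
#' @param p [meanfield_params()].
#' @param h,x,u Current state (mean current, depression, facilitation).
#' @param nu Population rate (Hz, i.e. 1/s to match tau in s).
#' @return Named numeric vector of derivatives `(dh, dx, du)`.
#' @export
meanfield_rhs <- function(p, h, x, u, nu) {
  stopifnot(nu >= 0)
  c(dh = (-h + p$A * u * x * nu + p$I_ext) / p$tau,
    dx = (1 - x) / p$tau_rec - u * x * nu,
    du = (p$U - u) / p$tau_facil + p$U * (1 - u) * nu)
}

#' Fixed-point current F(nu)
#'
#' The equilibrium mean current as a function of the population rate,
#' obtained by setting the mean-field derivatives to zero:
#' \deqn{F(\nu) = \frac{A U (\nu^{-1} + \tau_{facil})}
#'   {\nu^{-2} + \nu^{-1} U \tau_{facil} + \nu^{-1} U \tau_{rec}
#'    + U \tau_{facil} \tau_{rec}} + I_{ext}.}
#'
#' @param p [meanfield_params()].
#' @param nu Population rate (> 0).
#' @return Equilibrium current h.
#' @export
fixed_point_F <- function(p, nu) {
  stopifnot(all(nu > 0))
  with(p, A * U * (1 / nu + tau_facil) /
         (1 / nu^2 + U * tau_facil / nu + U * tau_rec / nu +
            U * tau_facil * tau_rec) + I_ext)
}

#' Self-consistent mean-field rate
#'
#' Solves a * max(F(nu) - theta, 0) = nu for nu by bisection on a scanned
#' bracket. Reports failure (returns `NA` with a warning) when no sign
#' change exists in the bracket rather than silently defaulting.
#'
#' @param p [meanfield_params()].
#' @param lower,upper Bracket for the rate (Hz).
#' @return The self-consistent rate, or `NA_real_` if no root is
#'   bracketed.
#' @export
meanfield_rate <- function(p, lower = 1e-6, upper = 500) {
  f <- function(nu) p$a * pmax(fixed_point_F(p, nu) - p$theta, 0) - nu
  if (f(lower) * f(upper) > 0) {
    warning("no self-consistent rate bracketed in [", lower, ", ", upper, "]")
    return(NA_real_)
  }
  stats::uniroot(f, c(lower, upper), tol = 1e-10)$root
}

#' High-rate bound on the population rate
#'
#' The nu -> Inf limit of F gives the heuristic rate bound
#' <nu> = A / tau_rec + I_ext that underlies the tau_rec learning rule.
#'
#' @param p [meanfield_params()].
#' @return Bound (same units as the gain output).
#' @export
rate_bound <- function(p) {
  stopifnot(p$tau_rec > 0)
  p$A / p$tau_rec + p$I_ext
}
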