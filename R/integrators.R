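# Single-step schemes on one neuron: Heun's RK2 (explicit trapezoid) and the
# second-order exponential time differencing Runge-Kutta step (ETD2RK). The
# ETD2RK step freezes per-variable linear rates from the step-start state,
# propagates that linear part exactly, and quadratures the remainder with the
# phi1/phi2 weights; with all rates forced to zero it reduces exactly to Heun,
# which is why Heun is the RK2 flavor used throughout.

#' Exponential-integrator phi functions
#'
#' `phi1(x) = (exp(x) - 1)/x` and `phi2(x) = (exp(x) - 1 - x)/x^2`, the
#' quadrature weights of the ETD2RK scheme. Below `|x| = 1e-4` a 6-term Taylor
#' series is used to avoid cancellation.
#'
#' @param x numeric vector.
#' @return `phi1(0) = 1`, `phi2(0) = 1/2`; both strictly increasing.
#' @examples
#' phi1(log(2)) # 1/log(2)
#' @export
phi1 <- function(x) {
  out <- numeric(length(x))
  s <- abs(x) < 1e-4
  xs <- x[s]
  out[s] <- 1 + xs * (1 / 2 + xs * (1 / 6 + xs * (1 / 24 + xs * (1 / 120 + xs / 720))))
  xl <- x[!s]
  out[!s] <- expm1(xl) / xl
  out
}

#' @rdname phi1
#' @export
phi2 <- function(x) {
  out <- numeric(length(x))
  s <- abs(x) < 1e-4
  xs <- x[s]
  out[s] <- 1 / 2 + xs * (1 / 6 + xs * (1 / 24 + xs * (1 / 120 + xs * (1 / 720 + xs / 5040))))
  xl <- x[!s]
  out[!s] <- (expm1(xl) - xl) / (xl * xl)
  out
}

#' Generic Heun step
#'
#' One explicit-trapezoid step for `dz/dt = f(t, z)`:
#' predictor `z* = z + dt f(t, z)`, then
#' `z_1 = z + dt/2 (f(t, z) + f(t + dt, z*))`.
#'
#' @param f right-hand side, `f(t, z)` returning a vector like `z`.
#' @param z state vector at time `t`.
#' @param t,dt start time and step, ms.
#' @return State vector at `t + dt`.
#' @export
heun_step <- function(f, z, t, dt) {
  d0 <- f(t, z)
  d1 <- f(t + dt, z + dt * d0)
  z + dt / 2 * (d0 + d1)
}

#' Generic ETD2RK step
#'
#' One step for `dz/dt = c z + F(t, z)` with `F(t, z) = f(t, z) - c z` and the
#' per-component linear rates `c` held fixed over the step:
#' predictor `a = z exp(c dt) + F(t, z) dt phi1(c dt)`, corrector
#' `z_1 = a + (F(t + dt, a) - F(t, z)) dt phi2(c dt)`.
#' With `c = 0` this is exactly [heun_step()].
#'
#' @param f full right-hand side `f(t, z)`.
#' @param c per-component frozen linear rates (1/ms), same length as `z`.
#' @param z state vector at time `t`.
#' @param t,dt start time and step, ms.
#' @return State vector at `t + dt`.
#' @export
etd2rk_step <- function(f, c, z, t, dt) {
  x <- c * dt
  F0 <- f(t, z) - c * z
  a <- z * exp(x) + F0 * dt * phi1(x)
  F1 <- f(t + dt, a) - c * a
  a + (F1 - F0) * dt * phi2(x)
}

#' Single-neuron RK2 (Heun) step
#'
#' Advances one neuron's state over a spike-free step, with the synaptic
#' conductances supplied as a function of time (evaluated only at the two
#' stage times `t` and `t + dt`).
#'
#' @param state named state vector (see [neuron_rhs()]).
#' @param t,dt start time and step, ms.
#' @param conductance_at function of time returning `c(G_E, G_I)` on the
#'   spike-free trajectory (e.g. built from [decay_step()]).
#' @param params a [neuron_params()] object.
#' @param syn a [synapse_params()] object.
#' @return State vector at `t + dt`.
#' @export
rk2_step <- function(state, t, dt, conductance_at,
                     params = neuron_params("HH"), syn = synapse_params()) {
  f <- function(tt, z) {
    g <- conductance_at(tt)
    neuron_rhs(z, g[[1]], g[[2]], params, syn)
  }
  heun_step(f, state, t, dt)
}

#' Single-neuron ETD2 step
#'
#' The ETD2RK step applied to the neuron equations. The frozen linear rates
#' are `c_V = (-G_Na m_k^3 h_k - G_K n_k^4 - G_L)/C` for the voltage and
#' `c_z = -(alpha_z(V_k) + beta_z(V_k))` for each gate, all evaluated at the
#' step-start state.
#'
#' @inheritParams rk2_step
#' @return State vector at `t + dt`.
#' @export
etd2_step <- function(state, t, dt, conductance_at,
                      params = neuron_params("HH"), syn = synapse_params()) {
  V <- state[["V"]]
  rtm <- params$model == "RTM"
  m <- if (rtm) steady_state(V, "m", params$model) else state[["m"]]
  cV <- (-params$G_Na * m^3 * state[["h"]] - params$G_K * state[["n"]]^4 -
           params$G_L) / params$C
  crate <- function(g) {
    r <- gating_rates(V, g, params$model)
    -(r$alpha + r$beta)
  }
  cvec <- if (rtm) c(cV, crate("h"), crate("n"))
          else c(cV, crate("m"), crate("h"), crate("n"))
  f <- function(tt, z) {
    g <- conductance_at(tt)
    neuron_rhs(z, g[[1]], g[[2]], params, syn)
  }
  etd2rk_step(f, cvec, state, t, dt)
}

#' Scheme selection inside the adaptive method
#'
#' A neuron is integrated with the ETD2 branch while inside its stiff period
#' (the window following its last spike) and with the RK2 branch otherwise.
#'
#' @param stiff_until end of the neuron's current stiff period, ms
#'   (`-Inf` if it never spiked).
#' @param t_k step start time, ms.
#' @return `"ETD2"` if `t_k < stiff_until`, else `"RK2"`.
#' @export
select_scheme <- function(stiff_until, t_k) {
  ifelse(t_k < stiff_until, "ETD2", "RK2")
}
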