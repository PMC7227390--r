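# Conductance-based single-neuron models: the classical Hodgkin-Huxley (HH)
# squid-axon parameter set and the reduced Traub-Miles (RTM) pyramidal-cell
# variant whose sodium activation m is instantaneous, m = alpha_m/(alpha_m+beta_m).
# Units throughout: mV, ms, mS/cm^2, uF/cm^2, uA/cm^2.

#' Neuron model parameters
#'
#' Named parameter sets for the two supported conductance-based models.
#' `"HH"` is the classical Hodgkin-Huxley neuron (state `V, m, h, n`);
#' `"RTM"` is the reduced Traub-Miles neuron, whose sodium activation is
#' instantaneous so the state reduces to `V, h, n`.
#'
#' @param model `"HH"` or `"RTM"`.
#' @param ... named overrides of individual constants (`C`, `V_Na`, `V_K`,
#'   `V_L`, `G_Na`, `G_K`, `G_L`, `V_th`).
#'
#' @return An object of class `model_params`: a list with the membrane
#'   capacitance `C` (uF/cm^2), reversal potentials `V_Na`, `V_K`, `V_L` (mV),
#'   maximal conductances `G_Na`, `G_K`, `G_L` (mS/cm^2), firing threshold
#'   `V_th` (mV) and `model` kind.
#' @examples
#' neuron_params("HH")$V_Na
#' neuron_params("RTM", G_L = 0.2)
#' @export
neuron_params <- function(model = c("HH", "RTM"), ...) {
  model <- match.arg(model)
  p <- if (model == "HH") {
    list(C = 1, V_Na = 50, V_K = -77, V_L = -54.387,
         G_Na = 120, G_K = 36, G_L = 0.3, V_th = -50)
  } else {
    list(C = 1, V_Na = 50, V_K = -100, V_L = -67,
         G_Na = 100, G_K = 80, G_L = 0.1, V_th = 0)
  }
  over <- list(...)
  bad <- setdiff(names(over), names(p))
  if (length(bad)) stop("unknown model parameter(s): ", paste(bad, collapse = ", "))
  p[names(over)] <- over
  p$model <- model
  stopifnot(p$C > 0, p$G_Na >= 0, p$G_K >= 0, p$G_L >= 0,
            p$V_K < p$V_th, p$V_th < p$V_Na)
  structure(p, class = "model_params")
}

# y / (1 - exp(-y)) with a guarded series below |y| = 1e-6: the shared form of
# the opening rates whose numerator and 1 - exp(.) vanish together.
ratefun <- function(y) {
  out <- numeric(length(y))
  small <- abs(y) < 1e-6
  out[small] <- 1 + y[small] * (0.5 + y[small] / 12)
  ys <- y[!small]
  out[!small] <- -ys / expm1(-ys)
  out
}

#' Voltage-dependent gating rates
#'
#' Opening (`alpha`) and closing (`beta`) rates for the gating variables of the
#' HH or RTM neuron. Removable singularities (voltages where a rate's numerator
#' and `1 - exp(.)` denominator vanish together) are evaluated by their
#' analytic limits.
#'
#' @param V membrane potential(s), mV. Must be finite.
#' @param gate `"m"`, `"h"` or `"n"`.
#' @param model `"HH"` or `"RTM"`.
#' @return A list with components `alpha` and `beta` (1/ms), same length as `V`.
#' @examples
#' gating_rates(-65, "m")$beta # exactly 4
#' @export
gating_rates <- function(V, gate = c("m", "h", "n"), model = c("HH", "RTM")) {
  gate <- match.arg(gate)
  model <- match.arg(model)
  if (!all(is.finite(V))) stop("'V' must be finite")
  if (model == "HH") {
    switch(gate,
      m = list(alpha = ratefun(0.1 * V + 4), beta = 4 * exp(-(V + 65) / 18)),
      h = list(alpha = 0.07 * exp(-(V + 65) / 20),
               beta = 1 / (1 + exp(-3.5 - 0.1 * V))),
      n = list(alpha = 0.1 * ratefun(0.1 * V + 5.5),
               beta = 0.125 * exp(-(V + 65) / 80)))
  } else {
    switch(gate,
      m = list(alpha = 1.28 * ratefun((V + 54) / 4),
               beta = 1.4 * ratefun(-(V + 27) / 5)),
      h = list(alpha = 0.128 * exp(-(V + 50) / 18),
               beta = 4 / (1 + exp(-(V + 27) / 5))),
      n = list(alpha = 0.16 * ratefun((V + 52) / 5),
               beta = 0.5 * exp(-(V + 57) / 40)))
  }
}

#' Steady-state gating value
#'
#' `alpha(V) / (alpha(V) + beta(V))`, the equilibrium of a gating variable at
#' clamped voltage. Used to initialize gates and, for the RTM model, as the
#' instantaneous sodium activation at every evaluation.
#'
#' @inheritParams gating_rates
#' @return Value(s) in (0, 1).
#' @export
steady_state <- function(V, gate = c("m", "h", "n"), model = c("HH", "RTM")) {
  r <- gating_rates(V, gate, model)
  r$alpha / (r$alpha + r$beta)
}

#' Single-neuron right-hand side
#'
#' Time derivatives of the neuron state given instantaneous excitatory and
#' inhibitory synaptic conductances. The membrane equation is
#' `C dV/dt = -(V - V_Na) G_Na m^3 h - (V - V_K) G_K n^4 - (V - V_L) G_L + I_input`
#' with `I_input = -G_E (V - V_GE) - G_I (V - V_GI)`; each gate follows
#' `dz/dt = (1 - z) alpha_z(V) - z beta_z(V)`.
#'
#' @param state named numeric vector: `V`, `m`, `h`, `n` for HH, or `V`, `h`,
#'   `n` for RTM (the instantaneous `m` is recomputed from `V`).
#' @param G_E,G_I excitatory / inhibitory conductances, mS/cm^2 (>= 0).
#' @param params a [neuron_params()] object.
#' @param syn a [synapse_params()] object (for the reversal potentials).
#' @return Named vector of derivatives matching the state layout.
#' @export
neuron_rhs <- function(state, G_E = 0, G_I = 0, params = neuron_params("HH"),
                       syn = synapse_params()) {
  if (!all(is.finite(unlist(state)))) stop("non-finite state")
  if (G_E < 0 || G_I < 0) stop("conductances must be non-negative")
  V <- state[["V"]]
  rtm <- params$model == "RTM"
  m <- if (rtm) steady_state(V, "m", params$model) else state[["m"]]
  rh <- gating_rates(V, "h", params$model)
  rn <- gating_rates(V, "n", params$model)
  I_in <- -G_E * (V - syn$V_GE) - G_I * (V - syn$V_GI)
  dV <- (-(V - params$V_Na) * params$G_Na * m^3 * state[["h"]] -
           (V - params$V_K) * params$G_K * state[["n"]]^4 -
           (V - params$V_L) * params$G_L + I_in) / params$C
  dh <- (1 - state[["h"]]) * rh$alpha - state[["h"]] * rh$beta
  dn <- (1 - state[["n"]]) * rn$alpha - state[["n"]] * rn$beta
  if (rtm) return(c(V = dV, h = dh, n = dn))
  rm <- gating_rates(V, "m", params$model)
  dm <- (1 - state[["m"]]) * rm$alpha - state[["m"]] * rm$beta
  c(V = dV, m = dm, h = dh, n = dn)
}

#' State vector with gates at steady state
#'
#' @param V membrane potential, mV.
#' @param params a [neuron_params()] object.
#' @return Named state vector (`V, m, h, n` for HH; `V, h, n` for RTM) with
#'   every gate at its steady-state value for `V`.
#' @export
state_at <- function(V, params = neuron_params("HH")) {
  if (params$model == "RTM") {
    c(V = V, h = steady_state(V, "h", "RTM"), n = steady_state(V, "n", "RTM"))
  } else {
    c(V = V, m = steady_state(V, "m", "HH"), h = steady_state(V, "h", "HH"),
      n = steady_state(V, "n", "HH"))
  }
}

#' Resting state of the autonomous neuron
#'
#' Fixed point of the single-neuron system with zero synaptic input: the root
#' of `dV/dt` along the manifold where every gate sits at its steady state.
#'
#' @param params a [neuron_params()] object.
#' @param interval voltage bracket for the root search, mV.
#' @return Named state vector at the fixed point.
#' @export
resting_state <- function(params = neuron_params("HH"),
                          interval = c(-90, -40)) {
  f <- function(V) neuron_rhs(state_at(V, params), 0, 0, params)[["V"]]
  V0 <- uniroot(f, interval, tol = 1e-12)$root
  state_at(V0, params)
}
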