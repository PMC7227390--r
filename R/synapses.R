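# Double-exponential synaptic conductance dynamics. Between spikes the pair
# (G, H) obeys dG/dt = -G/sigma_r + H, dH/dt = -H/sigma_d, which is solved
# exactly; each spike at time u adds its weight to H and the closed-form
# kernel contribution to G at the end of the step ("recalibration").

#' Synaptic and feedforward-input parameters
#'
#' @param V_GE,V_GI excitatory / inhibitory synaptic reversal potentials (mV).
#' @param sigma_r_E,sigma_d_E rise / decay time constants of excitatory
#'   conductances (ms); `sigma_r_I`, `sigma_d_I` likewise for inhibitory.
#' @param f feedforward Poisson strength onto the excitatory conductance
#'   (`F_E`, mS/cm^2).
#' @param F_I feedforward strength onto the inhibitory conductance (default 0).
#' @param nu feedforward Poisson rate per neuron, Hz.
#' @return An object of class `synapse_params`.
#' @examples
#' synapse_params()$sigma_d_I # 7 ms
#' @export
synapse_params <- function(V_GE = 0, V_GI = -80,
                           sigma_r_E = 0.5, sigma_d_E = 3.0,
                           sigma_r_I = 0.5, sigma_d_I = 7.0,
                           f = 0.06, F_I = 0, nu = 300) {
  stopifnot(sigma_r_E > 0, sigma_r_I > 0,
            sigma_r_E < sigma_d_E, sigma_r_I < sigma_d_I,
            f >= 0, F_I >= 0, nu >= 0)
  structure(list(V_GE = V_GE, V_GI = V_GI,
                 sigma_r_E = sigma_r_E, sigma_d_E = sigma_d_E,
                 sigma_r_I = sigma_r_I, sigma_d_I = sigma_d_I,
                 f = f, F_I = F_I, nu = nu),
            class = "synapse_params")
}

#' Spike-induced conductance kernel
#'
#' The closed-form conductance response to a single unit spike at `t = 0`:
#' `sigma_d sigma_r / (sigma_d - sigma_r) * (exp(-t/sigma_d) - exp(-t/sigma_r))`
#' for `t > 0`, zero otherwise.
#'
#' @param sigma_d,sigma_r decay and rise time constants, ms
#'   (`0 < sigma_r < sigma_d`).
#' @param t time since the spike, ms (vectorized).
#' @return Dimensionless kernel weight(s); 0 for `t <= 0`.
#' @examples
#' syn_kernel(3, 0.5, 1) # near the kernel peak
#' @export
syn_kernel <- function(sigma_d, sigma_r, t) {
  if (!(sigma_r > 0 && sigma_r < sigma_d))
    stop("need 0 < sigma_r < sigma_d")
  out <- sigma_d * sigma_r / (sigma_d - sigma_r) *
    (exp(-t / sigma_d) - exp(-t / sigma_r))
  out[t <= 0] <- 0
  out
}

#' Exact spike-free conductance decay over one step
#'
#' Advances the synaptic state by `dt` under the homogeneous dynamics (no
#' spikes): `H' = H exp(-dt/sigma_d)` and
#' `G' = G exp(-dt/sigma_r) + H * syn_kernel(sigma_d, sigma_r, dt)`,
#' the exact solution of the linear system.
#'
#' @param state list with numeric components `G_E`, `G_I`, `H_E`, `H_I`
#'   (scalars or per-neuron vectors), mS/cm^2.
#' @param dt step length, ms (> 0).
#' @param params a [synapse_params()] object.
#' @return State list of the same shape at `t + dt`.
#' @export
decay_step <- function(state, dt, params = synapse_params()) {
  stopifnot(dt > 0)
  list(
    G_E = state$G_E * exp(-dt / params$sigma_r_E) +
      state$H_E * syn_kernel(params$sigma_d_E, params$sigma_r_E, dt),
    G_I = state$G_I * exp(-dt / params$sigma_r_I) +
      state$H_I * syn_kernel(params$sigma_d_I, params$sigma_r_I, dt),
    H_E = state$H_E * exp(-dt / params$sigma_d_E),
    H_I = state$H_I * exp(-dt / params$sigma_d_I))
}

#' End-of-step conductance recalibration for one neuron
#'
#' Folds the spikes that occurred inside a step `(t_start, t_end]` into the
#' spike-free (decayed) synaptic state at `t_end`. A spike of weight `w` at
#' time `u` adds `w * exp(-(t_end - u)/sigma_d)` to `H` and
#' `w * syn_kernel(sigma_d, sigma_r, t_end - u)` to `G` of its receptor type.
#' Feedforward events use weights `f` (excitatory) and `F_I` (inhibitory);
#' synaptic events carry their own weight and the presynaptic type.
#'
#' @param state synaptic state after [decay_step()] (components `G_E`, `G_I`,
#'   `H_E`, `H_I`; scalars for a single neuron).
#' @param ff_times feedforward spike times in `(t_start, t_end]`, ms.
#' @param syn_spikes `NULL` or a data frame with columns `time`, `weight`,
#'   `type` (`"E"` or `"I"`): the interpolated synaptic spikes of the step.
#' @param t_end end of the step, ms.
#' @param params a [synapse_params()] object.
#' @param t_start start of the step, ms (`-Inf` to skip the bound check).
#' @return Recalibrated state list.
#' @export
recalibrate <- function(state, ff_times = numeric(), syn_spikes = NULL,
                        t_end, params = synapse_params(), t_start = -Inf) {
  all_t <- c(ff_times, syn_spikes$time)
  if (length(all_t) && (any(all_t <= t_start) || any(all_t > t_end)))
    stop("spike time outside the step interval (t_start, t_end]")
  add <- function(st, u, w, type) {
    sd <- if (type == "E") params$sigma_d_E else params$sigma_d_I
    sr <- if (type == "E") params$sigma_r_E else params$sigma_r_I
    gk <- if (type == "E") "G_E" else "G_I"
    hk <- if (type == "E") "H_E" else "H_I"
    st[[hk]] <- st[[hk]] + w * exp(-(t_end - u) / sd)
    st[[gk]] <- st[[gk]] + w * syn_kernel(sd, sr, t_end - u)
    st
  }
  for (u in ff_times) {
    if (params$f > 0) state <- add(state, u, params$f, "E")
    if (params$F_I > 0) state <- add(state, u, params$F_I, "I")
  }
  if (!is.null(syn_spikes) && nrow(syn_spikes)) {
    for (r in seq_len(nrow(syn_spikes)))
      state <- add(state, syn_spikes$time[r], syn_spikes$weight[r],
                   syn_spikes$type[r])
  }
  state
}

#' Draw feedforward Poisson spike trains
#'
#' Independent homogeneous Poisson processes, one per neuron, with exact
#' (non-grid-aligned) event times on `(0, T]`.
#'
#' @param N number of neurons.
#' @param nu rate per neuron, Hz.
#' @param T train duration, ms.
#' @param seed optional integer seed (the caller's RNG state is restored).
#' @return Object of class `feedforward_train`: list with `times` (length-`N`
#'   list of strictly increasing spike-time vectors, ms), `N`, `T`.
#' @export
draw_poisson_trains <- function(N, nu, T, seed = NULL) {
  stopifnot(N >= 1, nu >= 0, T > 0)
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(set_rng_state(old))
    set.seed(seed)
  }
  rate_ms <- nu / 1000 # Hz -> events per ms
  times <- lapply(seq_len(N), function(i) {
    n <- rpois(1, rate_ms * T)
    sort(runif(n, 0, T))
  })
  structure(list(times = times, N = as.integer(N), T = T),
            class = "feedforward_train")
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

set_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}
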