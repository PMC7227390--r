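# Full-network evolution: evolve all neurons spike-free over a step, detect
# upward threshold crossings, interpolate spike times linearly, recalibrate
# conductances with the step's feedforward and synaptic spikes, and update
# the per-neuron stiff trackers that drive the adaptive scheme.

.methods <- c("naive-rk2" = 0L, "rk2" = 1L, "etd2" = 2L, "aetd2" = 3L)

#' Network simulation configuration
#'
#' @param N,N_E,N_I total, excitatory and inhibitory neuron counts
#'   (`N = N_E + N_I`; neurons `1..N_E` are excitatory).
#' @param topology `"all-to-all"` or `"random"` (directed Erdos-Renyi with
#'   connection probability `p`); every existing edge has weight `S/N`.
#' @param p connection probability for `topology = "random"`.
#' @param S recurrent coupling strength, mS/cm^2 (per-edge weight `S/N`).
#' @param f feedforward Poisson strength, mS/cm^2.
#' @param nu feedforward Poisson rate per neuron, Hz.
#' @param dt time step, ms.
#' @param T total run time, ms (the run covers `ceiling(T/dt)` full steps).
#' @param method `"rk2"`, `"etd2"`, `"aetd2"` or `"naive-rk2"` (RK2 with
#'   spikes assigned to the step end instead of interpolated).
#' @param model `"HH"` or `"RTM"`.
#' @param stiff_duration length of the post-spike stiff period, ms; also the
#'   per-neuron refractory window of spike detection.
#' @param stiff_slope_threshold RTM stiff criterion: a neuron is stiff while
#'   `|dV/dt|` exceeds this slope (mV/ms) or inside a post-spike window.
#' @param seed integer master seed; expanded into independent substreams for
#'   the feedforward trains, initial-condition jitter and random topology.
#' @param include_self include the self-edge `i -> i` in the all-to-all
#'   topology (weight `S/N`).
#' @param V0 initial membrane potential, mV (gates start at steady state,
#'   conductances at zero).
#' @param V0_jitter half-width of a seeded uniform per-neuron offset added to
#'   `V0`, mV (0 = identical initial conditions).
#' @param record neuron indices whose voltage traces are sampled.
#' @param record_every sample the trace every this many steps.
#' @param model_params,synapse_params optional pre-built parameter objects;
#'   by default built from `model`, `f` and `nu`.
#' @return An object of class `network_config`.
#' @examples
#' cfg <- network_config(T = 100, dt = 0.02, seed = 1)
#' @export
network_config <- function(N = 100, N_E = 80, N_I = 20,
                           topology = c("all-to-all", "random"), p = 0.25,
                           S = 0.2, f = 0.06, nu = 300,
                           dt = 0.01, T = 1000,
                           method = c("rk2", "etd2", "aetd2", "naive-rk2"),
                           model = c("HH", "RTM"),
                           stiff_duration = 3.5, stiff_slope_threshold = 20,
                           seed = 1, include_self = TRUE,
                           V0 = -65, V0_jitter = 0,
                           record = integer(0), record_every = 1,
                           model_params = NULL, synapse_params = NULL) {
  topology <- match.arg(topology)
  method <- match.arg(method)
  model <- match.arg(model)
  stopifnot(N == N_E + N_I, N >= 1, dt > 0, T >= dt, S >= 0, f >= 0, nu >= 0,
            stiff_duration >= 0, record_every >= 1,
            all(record >= 1 & record <= N))
  if (is.null(model_params)) model_params <- neuron_params(model)
  if (is.null(synapse_params)) synapse_params <- synapse_params(f = f, nu = nu)
  structure(list(
    N = N, N_E = N_E, N_I = N_I, topology = topology, p = p, S = S,
    f = f, nu = nu, dt = dt, T = T, method = method, model = model,
    stiff_duration = stiff_duration,
    stiff_slope_threshold = stiff_slope_threshold,
    seed = as.integer(seed), include_self = include_self,
    V0 = V0, V0_jitter = V0_jitter,
    record = as.integer(record), record_every = as.integer(record_every),
    model_params = model_params, synapse_params = synapse_params),
    class = "network_config")
}

#' @export
print.network_config <- function(x, ...) {
  cat(sprintf("<network_config> %s network, N = %d (%dE/%dI), %s\n",
              x$model, x$N, x$N_E, x$N_I, x$topology))
  cat(sprintf("  S = %g, f = %g, nu = %g Hz | method = %s, dt = %g ms, T = %g ms, seed = %d\n",
              x$S, x$f, x$nu, x$method, x$dt, x$T, x$seed))
  invisible(x)
}

# Expand the master seed into independent substreams so that changing one
# consumer (e.g. the topology draw) does not shift another's stream.
derive_seeds <- function(seed) {
  old <- get_rng_state()
  on.exit(set_rng_state(old))
  set.seed(seed)
  s <- sample.int(.Machine$integer.max - 1L, 3L)
  list(feedforward = s[1], init = s[2], topology = s[3])
}

# Connectivity matrix W[i, j] = weight of edge j -> i.
build_weights <- function(config) {
  N <- config$N
  w <- config$S / N
  if (config$topology == "all-to-all") {
    W <- matrix(w, N, N)
    if (!config$include_self) diag(W) <- 0
  } else {
    seeds <- derive_seeds(config$seed)
    old <- get_rng_state()
    on.exit(set_rng_state(old))
    set.seed(seeds$topology)
    W <- matrix(w * (runif(N * N) < config$p), N, N)
  }
  W
}

# Initial per-neuron states: V0 (optionally jittered), gates at steady state,
# conductances zero.
build_initial_state <- function(config) {
  N <- config$N
  V <- rep(config$V0, N)
  if (config$V0_jitter > 0) {
    seeds <- derive_seeds(config$seed)
    old <- get_rng_state()
    on.exit(set_rng_state(old))
    set.seed(seeds$init)
    V <- V + runif(N, -config$V0_jitter, config$V0_jitter)
  }
  mp <- config$model_params
  list(V = V,
       m = steady_state(V, "m", mp$model),
       h = steady_state(V, "h", mp$model),
       n = steady_state(V, "n", mp$model),
       G_E = numeric(N), G_I = numeric(N),
       H_E = numeric(N), H_I = numeric(N),
       stiff_until = rep(-Inf, N))
}

#' Upward threshold crossing with linear spike-time interpolation
#'
#' If the neuron was below threshold at the step start and at-or-above it at
#' the step end (and is eligible, i.e. outside its refractory window), the
#' spike time is the linear-interpolation solution of
#' `V_th = V_k + (V_k1 - V_k)/dt * (tau - t_k)`.
#'
#' @param V_k,V_k1 membrane potential at step start / end, mV.
#' @param t_k step start, ms.
#' @param dt step length, ms.
#' @param V_th firing threshold, mV.
#' @param eligible logical detection gate.
#' @return Interpolated spike time in `(t_k, t_k + dt]`, or `NA` if no spike.
#' @examples
#' detect_spike(-51, -49, 10, 0.1, -50) # 10.05
#' @export
detect_spike <- function(V_k, V_k1, t_k, dt, V_th, eligible = TRUE) {
  stopifnot(dt > 0)
  if (!eligible || !(V_k < V_th && V_k1 >= V_th)) return(NA_real_)
  if (V_k1 <= V_k) return(t_k + dt) # guarded; impossible for a true crossing
  t_k + dt * (V_th - V_k) / (V_k1 - V_k)
}

# Feedforward train -> flat layout for the C++ core (0-based slices).
flatten_train <- function(train) {
  counts <- vapply(train$times, length, integer(1))
  list(times = as.numeric(unlist(train$times, use.names = FALSE)),
       start = as.integer(cumsum(c(0L, counts[-length(counts)]))),
       count = as.integer(counts))
}

#' Advance the whole network by one step (reference R engine)
#'
#' One iteration of the network loop: spike-free advance of every neuron with
#' its scheme, exact conductance decay, threshold detection with
#' interpolation, conductance recalibration with the step's feedforward and
#' synaptic spikes, and stiff-tracker update. This pure-R path mirrors the
#' compiled engine and is intended for small problems and verification.
#'
#' @param state network state list (`V`, `m`, `h`, `n`, `G_E`, `G_I`, `H_E`,
#'   `H_I`, `stiff_until`), as built by the simulator.
#' @param t_k step start time, ms.
#' @param config a [network_config()].
#' @param W weight matrix (`W[i, j]` = weight of edge `j -> i`).
#' @param feedforward a `feedforward_train`.
#' @return List with the updated `state` and a data frame `spikes`
#'   (`time`, `neuron`) of this step's detected spikes.
#' @export
step_network <- function(state, t_k, config, W, feedforward) {
  dt <- config$dt
  t1 <- t_k + dt
  N <- config$N
  mp <- config$model_params
  sp <- config$synapse_params
  naive <- config$method == "naive-rk2"
  rtm_mode <- config$model == "RTM"
  V_old <- state$V
  new_state <- state

  for (i in seq_len(N)) {
    g0 <- c(state$G_E[i], state$G_I[i])
    g1dec <- decay_step(list(G_E = state$G_E[i], G_I = state$G_I[i],
                             H_E = state$H_E[i], H_I = state$H_I[i]), dt, sp)
    cond_at <- function(tt) {
      if (tt <= t_k) g0 else c(g1dec$G_E, g1dec$G_I)
    }
    z <- if (rtm_mode) c(V = state$V[i], h = state$h[i], n = state$n[i])
         else c(V = state$V[i], m = state$m[i], h = state$h[i], n = state$n[i])
    scheme <- if (config$method == "etd2") "ETD2"
      else if (config$method != "aetd2") "RK2"
      else if (!rtm_mode) select_scheme(state$stiff_until[i], t_k)
      else {
        dv <- neuron_rhs(z, g0[1], g0[2], mp, sp)[["V"]]
        if (abs(dv) >= config$stiff_slope_threshold ||
            t_k < state$stiff_until[i]) "ETD2" else "RK2"
      }
    z1 <- if (scheme == "ETD2") etd2_step(z, t_k, dt, cond_at, mp, sp)
          else rk2_step(z, t_k, dt, cond_at, mp, sp)
    new_state$V[i] <- z1[["V"]]
    new_state$h[i] <- z1[["h"]]
    new_state$n[i] <- z1[["n"]]
    new_state$m[i] <- if (rtm_mode) steady_state(z1[["V"]], "m", "RTM")
                      else z1[["m"]]
  }
  if (any(!is.finite(new_state$V)))
    stop(sprintf("non-finite membrane potential at t = %.6g (method %s, dt %g)",
                 t1, config$method, dt))

  dec <- decay_step(state[c("G_E", "G_I", "H_E", "H_I")], dt, sp)
  new_state[c("G_E", "G_I", "H_E", "H_I")] <- dec

  # detection (refractory-gated), then stiff-tracker update
  taus <- numeric(0); who <- integer(0)
  for (i in seq_len(N)) {
    tau <- detect_spike(V_old[i], new_state$V[i], t_k, dt, mp$V_th,
                        eligible = t_k >= state$stiff_until[i])
    if (!is.na(tau)) {
      if (naive) tau <- t1
      taus <- c(taus, tau); who <- c(who, i)
      new_state$stiff_until[i] <- tau + config$stiff_duration
    }
  }

  # recalibration: feedforward events + this step's synaptic spikes
  for (i in seq_len(N)) {
    ff <- feedforward$times[[i]]
    ff <- ff[ff > t_k & ff <= t1]
    if (naive && length(ff)) ff <- rep(t1, length(ff))
    pre <- which(W[i, ] != 0)
    pre_sp <- who %in% pre
    syn_df <- if (any(pre_sp)) {
      data.frame(time = if (naive) rep(t1, sum(pre_sp)) else taus[pre_sp],
                 weight = W[i, who[pre_sp]],
                 type = ifelse(who[pre_sp] <= config$N_E, "E", "I"))
    } else NULL
    st_i <- list(G_E = new_state$G_E[i], G_I = new_state$G_I[i],
                 H_E = new_state$H_E[i], H_I = new_state$H_I[i])
    st_i <- recalibrate(st_i, ff, syn_df, t1, sp, t_start = t_k - 1e-9)
    new_state$G_E[i] <- st_i$G_E; new_state$G_I[i] <- st_i$G_I
    new_state$H_E[i] <- st_i$H_E; new_state$H_I[i] <- st_i$H_I
  }

  list(state = new_state,
       spikes = data.frame(time = taus, neuron = who))
}

#' Simulate a pulse-coupled network
#'
#' Runs the full network loop for `ceiling(T/dt)` steps with the configured
#' integration method. The compiled engine is the default; `engine = "r"`
#' runs the pure-R reference path ([step_network()]), which is slower but
#' built from the independently testable single-neuron and synapse
#' primitives.
#'
#' @param config a [network_config()].
#' @param feedforward optional pre-drawn [draw_poisson_trains()] object (so
#'   several runs can share one input realization); by default drawn from the
#'   config's feedforward substream over the run length.
#' @param engine `"cpp"` or `"r"`.
#' @return Object of class `hh_sim`: list with `spikes` (data frame `time`,
#'   `neuron`, sorted by time), `trace` (data frame of sampled voltages, or
#'   `NULL`), `final` (final neuron/synapse state and stiff trackers),
#'   `T_end`, `n_steps`, `counters` (feedforward events applied, synaptic
#'   deliveries) and the `config`.
#' @examples
#' cfg <- network_config(N = 4, N_E = 3, N_I = 1, T = 20, dt = 0.02,
#'                       f = 0.1, seed = 2)
#' sim <- simulate_network(cfg)
#' mean_firing_rate(sim)
#' @export
simulate_network <- function(config, feedforward = NULL,
                             engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  stopifnot(inherits(config, "network_config"))
  n_steps <- as.integer(ceiling(config$T / config$dt - 1e-9))
  T_end <- n_steps * config$dt

  if (is.null(feedforward)) {
    seeds <- derive_seeds(config$seed)
    feedforward <- draw_poisson_trains(config$N, config$nu, T_end,
                                       seed = seeds$feedforward)
  } else {
    stopifnot(inherits(feedforward, "feedforward_train"),
              feedforward$N == config$N)
    if (feedforward$T < T_end - 1e-9)
      warning("feedforward train shorter than the run; late steps get no input")
  }

  W <- build_weights(config)
  init <- build_initial_state(config)
  mp <- config$model_params
  sp <- config$synapse_params

  if (engine == "cpp") {
    ff <- flatten_train(feedforward)
    res <- cpp_simulate(
      model_kind = if (config$model == "RTM") 1L else 0L,
      model_par = c(mp$C, mp$V_Na, mp$V_K, mp$V_L, mp$G_Na, mp$G_K, mp$G_L,
                    mp$V_th),
      syn_par = c(sp$V_GE, sp$V_GI, sp$sigma_r_E, sp$sigma_d_E,
                  sp$sigma_r_I, sp$sigma_d_I),
      W = W, is_exc = as.integer(seq_len(config$N) <= config$N_E),
      FE = sp$f, FI = sp$F_I,
      ff_times = ff$times, ff_start = ff$start, ff_count = ff$count,
      V0 = init$V, m0 = init$m, h0 = init$h, n0 = init$n,
      GE0 = init$G_E, GI0 = init$G_I, HE0 = init$H_E, HI0 = init$H_I,
      dt = config$dt, n_steps = n_steps, method = .methods[[config$method]],
      stiff_duration = config$stiff_duration,
      stiff_mode = if (config$model == "RTM") 1L else 0L,
      slope_thr = config$stiff_slope_threshold,
      record_idx = config$record - 1L, record_every = config$record_every)
    spikes <- data.frame(time = res$spike_time, neuron = res$spike_neuron)
    final <- list(V = res$V, m = res$m, h = res$h, n = res$n,
                  G_E = res$G_E, G_I = res$G_I, H_E = res$H_E, H_I = res$H_I,
                  stiff_until = res$stiff_until)
    trace <- if (length(config$record)) {
      tr <- as.data.frame(res$trace_V)
      names(tr) <- paste0("V", config$record)
      cbind(data.frame(t = res$trace_t), tr)
    } else NULL
    counters <- list(ff_events_applied = res$ff_events_applied,
                     deliveries = res$deliveries)
  } else {
    state <- init
    sp_t <- numeric(0); sp_n <- integer(0)
    rows <- list(); row_t <- numeric(0)
    if (length(config$record)) {
      rows[[1]] <- state$V[config$record]; row_t <- 0
    }
    n_deliv <- 0; n_ff <- 0
    for (k in seq_len(n_steps) - 1L) {
      t_k <- k * config$dt
      out <- step_network(state, t_k, config, W, feedforward)
      state <- out$state
      if (nrow(out$spikes)) {
        sp_t <- c(sp_t, out$spikes$time)
        sp_n <- c(sp_n, out$spikes$neuron)
        n_deliv <- n_deliv +
          sum(W[, out$spikes$neuron, drop = FALSE] != 0)
      }
      n_ff <- n_ff + sum(vapply(feedforward$times, function(u)
        sum(u > t_k & u <= t_k + config$dt), numeric(1)))
      if (length(config$record) && (k + 1L) %% config$record_every == 0L) {
        rows[[length(rows) + 1L]] <- state$V[config$record]
        row_t <- c(row_t, (k + 1L) * config$dt)
      }
    }
    spikes <- data.frame(time = sp_t, neuron = sp_n)
    final <- state
    trace <- if (length(config$record)) {
      tr <- as.data.frame(do.call(rbind, rows))
      names(tr) <- paste0("V", config$record)
      cbind(data.frame(t = row_t), tr)
    } else NULL
    counters <- list(ff_events_applied = n_ff, deliveries = n_deliv)
  }

  ord <- order(spikes$time, spikes$neuron)
  spikes <- spikes[ord, , drop = FALSE]
  rownames(spikes) <- NULL
  structure(list(spikes = spikes, trace = trace, final = final,
                 T_end = T_end, n_steps = n_steps, counters = counters,
                 config = config, engine = engine),
            class = "hh_sim")
}

#' @export
print.hh_sim <- function(x, ...) {
  cat(sprintf("<hh_sim> %s, method %s, dt = %g ms, T = %g ms: %d spikes (%.2f Hz mean rate)\n",
              x$config$model, x$config$method, x$config$dt, x$T_end,
              nrow(x$spikes), mean_firing_rate(x)))
  invisible(x)
}
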