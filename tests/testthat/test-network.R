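# The network loop: detection, recalibration routing, engine agreement,
# determinism, adaptive-scheme reductions and the stiff tracker.

test_that("detect_spike interpolates upward crossings only", {
  expect_equal(detect_spike(-51, -49, 10, 0.1, -50), 10.05, tolerance = 1e-14)
  expect_true(is.na(detect_spike(-49, -48, 10, 0.1, -50))) # already above
  expect_true(is.na(detect_spike(-49, -51, 10, 0.1, -50))) # downward
  expect_true(is.na(detect_spike(-51, -49, 10, 0.1, -50, eligible = FALSE)))
  expect_equal(detect_spike(-50.0001, -49.9999, 0, 0.277, -50),
               0.1385, tolerance = 1e-10)
})

test_that("a resting network with zero input stays at its fixed point", {
  rest <- resting_state()
  cfg <- network_config(N = 5, N_E = 4, N_I = 1, S = 0, f = 0, nu = 0,
                        T = 1, dt = 0.1, V0 = rest[["V"]], seed = 1)
  sim <- simulate_network(cfg)
  expect_identical(nrow(sim$spikes), 0L)
  expect_true(all(abs(sim$final$V - rest[["V"]]) < 1e-9))
})

test_that("a detected spike increments postsynaptic H_E by its kernel weight", {
  # two-neuron all-to-all without self-edges: neuron 1 (excitatory) is pushed
  # over threshold by a large excitatory conductance; neuron 2 must receive
  # (S/2) * exp(-(t_end - tau)/sigma_d_E) on H_E (hand evaluation).
  cfg <- network_config(N = 2, N_E = 2, N_I = 0, S = 0.2, f = 0, nu = 0,
                        T = 1, dt = 0.1, include_self = FALSE, seed = 1)
  W <- matrix(c(0, 0.1, 0.1, 0), 2, 2)
  sp <- cfg$synapse_params
  # neuron 1 sits just below threshold with rest-like gates (recently
  # depolarized, not yet inactivated) and a strong excitatory conductance
  state <- list(V = c(-50.05, -65), m = steady_state(c(-65, -65), "m"),
                h = steady_state(c(-65, -65), "h"),
                n = steady_state(c(-65, -65), "n"),
                G_E = c(0.6, 0), G_I = c(0, 0), H_E = c(0, 0), H_I = c(0, 0),
                stiff_until = rep(-Inf, 2))
  ff <- structure(list(times = list(numeric(0), numeric(0)), N = 2, T = 1),
                  class = "feedforward_train")
  out <- step_network(state, 0, cfg, W, ff)
  expect_identical(out$spikes$neuron, 1L)
  tau <- out$spikes$time
  expect_gt(tau, 0); expect_lte(tau, 0.1)
  expect_equal(out$state$H_E[2],
               0.1 * exp(-(0.1 - tau) / sp$sigma_d_E), tolerance = 1e-12)
  expect_equal(out$state$G_E[2],
               0.1 * syn_kernel(sp$sigma_d_E, sp$sigma_r_E, 0.1 - tau),
               tolerance = 1e-12)
  # no self-edge: neuron 1 receives nothing
  expect_equal(out$state$H_E[1], 0, tolerance = 1e-15)
})

test_that("compiled and reference R engines agree", {
  for (method in c("rk2", "etd2", "aetd2", "naive-rk2")) {
    cfg <- tiny_config(method = method)
    a <- simulate_network(cfg, engine = "cpp")
    b <- simulate_network(cfg, engine = "r")
    expect_equal(nrow(a$spikes), nrow(b$spikes), info = method)
    expect_equal(a$spikes$time, b$spikes$time, tolerance = 1e-9,
                 info = method)
    expect_equal(a$final$V, b$final$V, tolerance = 1e-8, info = method)
    expect_equal(a$final$G_E, b$final$G_E, tolerance = 1e-10, info = method)
  }
})

test_that("simulation is deterministic under a fixed seed", {
  cfg <- tiny_config(method = "aetd2")
  a <- simulate_network(cfg)
  b <- simulate_network(cfg)
  expect_identical(a$spikes, b$spikes)
  expect_identical(a$final, b$final)
  # and the raster files are byte-identical
  f1 <- tempfile(); f2 <- tempfile()
  write_raster(a, f1); write_raster(b, f2)
  expect_identical(readLines(f1), readLines(f2))
  unlink(c(f1, f2))
})

test_that("AETD2 with a zero-length stiff window is bitwise RK2", {
  cfg_a <- study_config(T = 60, dt = 0.02, method = "aetd2",
                        stiff_duration = 0)
  cfg_r <- study_config(T = 60, dt = 0.02, method = "rk2",
                        stiff_duration = 0)
  a <- simulate_network(cfg_a)
  r <- simulate_network(cfg_r)
  expect_identical(a$spikes, r$spikes)
  expect_identical(a$final$V, r$final$V)
})

test_that("AETD2 with an infinite stiff window steps with ETD2 after the first spike", {
  # single self-coupled neuron driven to fire; after its first spike every
  # aetd2 step must coincide with the etd2 step from the same state
  cfg <- network_config(N = 1, N_E = 1, N_I = 0, S = 0.1, f = 0.15, nu = 800,
                        T = 40, dt = 0.05, method = "aetd2",
                        stiff_duration = Inf, seed = 11)
  W <- matrix(0.1, 1, 1)
  ff <- draw_poisson_trains(1, cfg$nu, cfg$T, seed = 5)
  cfg_e <- cfg; cfg_e$method <- "etd2"
  state <- etdhh:::build_initial_state(cfg)
  spiked <- FALSE
  checked <- 0
  for (k in 0:(cfg$T / cfg$dt - 1)) {
    t_k <- k * cfg$dt
    out_a <- step_network(state, t_k, cfg, W, ff)
    if (spiked && checked < 20) {
      out_e <- step_network(state, t_k, cfg_e, W, ff)
      expect_identical(out_a$state$V, out_e$state$V)
      checked <- checked + 1
    }
    if (nrow(out_a$spikes)) spiked <- TRUE
    state <- out_a$state
  }
  expect_true(spiked)
  expect_gt(checked, 0)
})

test_that("all interpolating methods agree at a small step", {
  base <- study_config(T = 1000, dt = 0.005)
  seeds <- etdhh:::derive_seeds(base$seed)
  ff <- draw_poisson_trains(base$N, base$nu, base$T + 1,
                            seed = seeds$feedforward)
  rates <- vapply(c("rk2", "etd2", "aetd2"), function(m) {
    cfg <- base; cfg$method <- m
    mean_firing_rate(simulate_network(cfg, feedforward = ff))
  }, numeric(1))
  expect_lt(relative_rate_error(rates[["etd2"]], rates[["rk2"]]), 0.001)
  expect_lt(relative_rate_error(rates[["aetd2"]], rates[["rk2"]]), 0.001)
})

test_that("detection respects the per-neuron refractory window", {
  cfg <- study_config(T = 300, dt = 0.02, method = "rk2")
  sim <- simulate_network(cfg)
  expect_gt(nrow(sim$spikes), 0)
  isi <- unlist(tapply(sim$spikes$time, sim$spikes$neuron,
                       function(x) diff(sort(x))))
  if (length(isi)) expect_gte(min(isi), cfg$stiff_duration)
})

test_that("every spike yields one conductance increment per postsynaptic target", {
  cfg <- study_config(T = 200, dt = 0.02)
  sim <- simulate_network(cfg)
  # all-to-all with self-edges: out-degree N for every neuron
  expect_equal(sim$counters$deliveries, nrow(sim$spikes) * cfg$N)
  ff <- draw_poisson_trains(cfg$N, cfg$nu, sim$T_end,
                            seed = etdhh:::derive_seeds(cfg$seed)$feedforward)
  expect_equal(sim$counters$ff_events_applied, sum(lengths(ff$times)))
})

test_that("random topology is seeded, directed and excludes absent edges from delivery", {
  cfg <- network_config(N = 40, N_E = 32, N_I = 8, topology = "random",
                        p = 0.25, T = 150, dt = 0.02, seed = 9)
  W1 <- etdhh:::build_weights(cfg)
  W2 <- etdhh:::build_weights(cfg)
  expect_identical(W1, W2)
  expect_false(isSymmetric(W1 != 0))
  expect_equal(mean(W1 != 0), 0.25, tolerance = 0.1)
  sim <- simulate_network(cfg)
  deg <- colSums(W1 != 0)
  expect_equal(sim$counters$deliveries, sum(deg[sim$spikes$neuron]))
})

test_that("the RTM network runs with the slope-based stiff criterion", {
  cfg_r <- network_config(N = 20, N_E = 16, N_I = 4, model = "RTM",
                          T = 500, dt = 0.02, method = "rk2", f = 0.06,
                          nu = 300, S = 0.2, seed = 4)
  ref <- simulate_network(cfg_r)
  expect_gt(nrow(ref$spikes), 0)
  expect_true(all(is.finite(ref$final$V)))
  cfg_a <- cfg_r; cfg_a$method <- "aetd2"; cfg_a$dt <- 0.3
  seeds <- etdhh:::derive_seeds(cfg_r$seed)
  ff <- draw_poisson_trains(cfg_r$N, cfg_r$nu, cfg_r$T + 1,
                            seed = seeds$feedforward)
  ra <- simulate_network(cfg_a, feedforward = ff)
  rr <- simulate_network(cfg_r, feedforward = ff)
  expect_lt(relative_rate_error(mean_firing_rate(ra), mean_firing_rate(rr)),
            0.1)
})

test_that("instability aborts with a diagnostic naming method and step", {
  cfg <- network_config(N = 3, N_E = 3, N_I = 0, S = 0, f = 0, nu = 0,
                        T = 5, dt = 4, method = "rk2", V0 = -20, seed = 1)
  expect_error(simulate_network(cfg), "non-finite")
})
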