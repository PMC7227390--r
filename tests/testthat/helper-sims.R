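# Shared fixtures: the 100-neuron study configuration and a cache so the
# long benchmark simulations are run once per test session.

.sim_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .sim_cache)) assign(key, expr, envir = .sim_cache)
  get(key, envir = .sim_cache)
}

# The all-to-all 80E/20I network driven by 300 Hz Poisson input at f = 0.06,
# recurrent coupling S = 0.2 (all in mS/cm^2).
study_config <- function(T = 1000, dt = 0.01, seed = 1, method = "rk2", ...) {
  network_config(N = 100, N_E = 80, N_I = 20, S = 0.2, f = 0.06, nu = 300,
                 T = T, dt = dt, seed = seed, method = method, ...)
}

tiny_config <- function(...) {
  network_config(N = 6, N_E = 5, N_I = 1, T = 20, dt = 0.05, f = 0.12,
                 nu = 600, seed = 42, ...)
}

# Accuracy table on the full 10 s run, shared across acceptance tests.
accuracy_table <- function() {
  cached("accuracy_table", {
    pairs <- data.frame(
      method = c("rk2", rep(c("etd2", "aetd2"), each = 4)),
      dt = c(0.01, rep(c(0.05, 0.1, 0.2, 0.277), 2)))
    rate_table(study_config(T = 10000), methods = pairs$method,
               dts = pairs$dt, benchmark_dt = 0.005, expand = FALSE)
  })
}
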