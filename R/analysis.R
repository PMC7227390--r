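# Error metrics, convergence-order estimation, firing-rate statistics and the
# step-count efficiency ratio used to compare the integration schemes.

#' Final-time membrane-potential error
#'
#' Euclidean norm across neurons of the difference between the final-time
#' voltages of a run and of a reference (high-resolution) run.
#'
#' @param V_run,V_ref per-neuron membrane potentials at the final time, mV.
#' @return Non-negative scalar (mV).
#' @export
error_V <- function(V_run, V_ref) {
  if (length(V_run) != length(V_ref)) stop("length mismatch")
  sqrt(sum((V_run - V_ref)^2))
}

#' Last-spike-time error
#'
#' Euclidean norm across neurons of the difference between each neuron's last
#' spike time in a run and in the reference. Neurons without a spike in
#' either run are dropped pairwise (their count is reported via the
#' `"dropped"` attribute and a message).
#'
#' @param tau_run,tau_ref per-neuron last spike times, ms (`NA` = no spike).
#' @return Non-negative scalar (ms), or `NA` if no neuron spiked in both runs.
#' @export
error_tau <- function(tau_run, tau_ref) {
  if (length(tau_run) != length(tau_ref)) stop("length mismatch")
  ok <- !is.na(tau_run) & !is.na(tau_ref)
  dropped <- sum(!ok)
  if (dropped > 0)
    message(dropped, " neuron(s) without spikes in both runs dropped")
  if (!any(ok)) {
    warning("no neuron spiked in both runs; last-spike error undefined")
    return(structure(NA_real_, dropped = dropped))
  }
  structure(sqrt(sum((tau_run[ok] - tau_ref[ok])^2)), dropped = dropped)
}

#' Per-neuron last spike times
#'
#' @param x an `hh_sim` object or a spike data frame (`time`, `neuron`).
#' @param N number of neurons (taken from the config for an `hh_sim`).
#' @return Numeric vector of length `N`; `NA` for neurons that never spiked.
#' @export
last_spike_times <- function(x, N = NULL) {
  if (inherits(x, "hh_sim")) {
    if (is.null(N)) N <- x$config$N
    x <- x$spikes
  }
  out <- rep(NA_real_, N)
  if (nrow(x)) {
    agg <- tapply(x$time, x$neuron, max)
    out[as.integer(names(agg))] <- as.numeric(agg)
  }
  out
}

#' Empirical convergence order
#'
#' Least-squares slope of `log(error)` against `log(dt)`.
#'
#' @param dts step sizes, ms (>= 2 values).
#' @param errors corresponding errors (> 0; zero errors are excluded with a
#'   warning).
#' @return Fitted slope (the empirical order of the scheme).
#' @examples
#' convergence_order(c(0.1, 0.05), c(1e-2, 2.5e-3)) # 2
#' @export
convergence_order <- function(dts, errors) {
  stopifnot(length(dts) == length(errors))
  keep <- errors > 0 & is.finite(errors)
  if (any(!keep)) warning("excluding ", sum(!keep), " zero/non-finite error(s)")
  if (sum(keep) < 2) stop("need at least 2 positive (dt, error) pairs")
  unname(coef(lm(log(errors[keep]) ~ log(dts[keep])))[2])
}

#' Population mean firing rate
#'
#' Total spike count divided by neuron count and run time, in Hz.
#'
#' @param x an `hh_sim` object, a spike data frame, or a spike count.
#' @param N number of neurons (unneeded for an `hh_sim`).
#' @param T run time, ms (unneeded for an `hh_sim`).
#' @return Rate in Hz.
#' @export
mean_firing_rate <- function(x, N = NULL, T = NULL) {
  if (inherits(x, "hh_sim")) {
    N <- x$config$N; T <- x$T_end; x <- nrow(x$spikes)
  } else if (is.data.frame(x)) {
    x <- nrow(x)
  }
  stopifnot(!is.null(N), !is.null(T), T > 0)
  x / (N * T) * 1000
}

#' Relative firing-rate error
#'
#' `|rate_method - rate_benchmark| / rate_benchmark`.
#'
#' @param rate_method,rate_benchmark rates, Hz.
#' @return Non-negative fraction (multiply by 100 for percent).
#' @export
relative_rate_error <- function(rate_method, rate_benchmark) {
  abs(rate_method - rate_benchmark) / rate_benchmark
}

#' Step-count efficiency ratio
#'
#' With both schemes evaluating essentially the same work per step, the
#' speedup of the adaptive method over RK2 at a common run time is the ratio
#' of step counts, i.e. of step sizes: `dt_aetd2 / dt_rk2`.
#'
#' @param dt_aetd2,dt_rk2 step sizes, ms.
#' @return Dimensionless ratio.
#' @export
efficiency_ratio <- function(dt_aetd2, dt_rk2) {
  dt_aetd2 / dt_rk2
}

#' Convergence study against a fine-step reference
#'
#' Runs each method at each step size and one reference run, all sharing the
#' same feedforward realization, topology and initial conditions, and
#' measures the final-time voltage error and last-spike-time error against
#' the reference.
#'
#' @param config a [network_config()] (its `dt`/`method` are overridden).
#' @param dts step sizes to test, ms.
#' @param methods methods to test.
#' @param ref_dt reference step size, ms.
#' @param ref_method reference method (default `"rk2"`).
#' @param engine simulation engine.
#' @return Object of class `convergence_report`: list with `errors` (data
#'   frame `method`, `dt`, `error_V`, `error_tau`) and `slopes` (data frame
#'   `method`, `slope_V`, `slope_tau`; `NA` when fewer than 2 step sizes).
#' @export
convergence_study <- function(config, dts,
                              methods = c("naive-rk2", "rk2", "etd2", "aetd2"),
                              ref_dt = 0.005, ref_method = "rk2",
                              engine = "cpp") {
  seeds <- derive_seeds(config$seed)
  ff <- draw_poisson_trains(config$N, config$nu, config$T + max(dts) + 1,
                            seed = seeds$feedforward)
  run <- function(method, dt) {
    cfg <- config
    cfg$method <- method
    cfg$dt <- dt
    simulate_network(cfg, feedforward = ff, engine = engine)
  }
  ref <- run(ref_method, ref_dt)
  tau_ref <- last_spike_times(ref)
  grid <- expand.grid(method = methods, dt = dts, stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(r) {
    sim <- run(grid$method[r], grid$dt[r])
    data.frame(method = grid$method[r], dt = grid$dt[r],
               error_V = error_V(sim$final$V, ref$final$V),
               error_tau = suppressMessages(
                 as.numeric(error_tau(last_spike_times(sim), tau_ref))))
  })
  errors <- do.call(rbind, res)
  slopes <- do.call(rbind, lapply(unique(errors$method), function(m) {
    e <- errors[errors$method == m, ]
    sv <- if (nrow(e) >= 2) convergence_order(e$dt, e$error_V) else NA_real_
    st <- if (nrow(e) >= 2 && all(is.finite(e$error_tau)))
      convergence_order(e$dt, e$error_tau) else NA_real_
    data.frame(method = m, slope_V = sv, slope_tau = st)
  }))
  structure(list(errors = errors, slopes = slopes, ref_dt = ref_dt,
                 ref_method = ref_method, config = config),
            class = "convergence_report")
}

#' @export
print.convergence_report <- function(x, ...) {
  cat(sprintf("<convergence_report> reference %s at dt = %g ms\n",
              x$ref_method, x$ref_dt))
  print(x$errors, row.names = FALSE)
  cat("fitted log-log slopes:\n")
  print(x$slopes, row.names = FALSE)
  invisible(x)
}

#' Firing-rate accuracy table
#'
#' Runs the given (method, dt) combinations and a small-step RK2 benchmark,
#' all on one shared feedforward realization, and tabulates the population
#' mean rate and its relative error against the benchmark.
#'
#' @param config a [network_config()] (its `dt`/`method` are overridden).
#' @param methods,dts parallel vectors of methods and step sizes (recycled
#'   against each other via [expand.grid()] when `expand = TRUE`).
#' @param benchmark_dt RK2 benchmark step size, ms.
#' @param expand if `TRUE`, run every method at every dt.
#' @param engine simulation engine.
#' @return Data frame `method`, `dt`, `rate_Hz`, `relative_error` (fraction);
#'   the benchmark appears as the first row with relative error 0.
#' @export
rate_table <- function(config, methods = c("etd2", "aetd2"),
                       dts = c(0.1, 0.277), benchmark_dt = 0.005,
                       expand = TRUE, engine = "cpp") {
  seeds <- derive_seeds(config$seed)
  ff <- draw_poisson_trains(config$N, config$nu,
                            config$T + max(dts, benchmark_dt) + 1,
                            seed = seeds$feedforward)
  run_rate <- function(method, dt) {
    cfg <- config
    cfg$method <- method
    cfg$dt <- dt
    mean_firing_rate(simulate_network(cfg, feedforward = ff, engine = engine))
  }
  bench <- run_rate("rk2", benchmark_dt)
  grid <- if (expand)
    expand.grid(method = methods, dt = dts, stringsAsFactors = FALSE)
  else data.frame(method = methods, dt = dts, stringsAsFactors = FALSE)
  rates <- mapply(run_rate, grid$method, grid$dt)
  rbind(data.frame(method = "rk2", dt = benchmark_dt, rate_Hz = bench,
                   relative_error = 0),
        data.frame(method = grid$method, dt = grid$dt, rate_Hz = rates,
                   relative_error = relative_rate_error(rates, bench)))
}
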