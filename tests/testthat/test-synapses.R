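# Double-exponential conductance dynamics: kernel, exact decay, spike
# recalibration and the feedforward Poisson trains.

test_that("spike kernel is causal, positive and peaks where calculus says", {
  expect_identical(syn_kernel(3, 0.5, 0), 0)
  expect_identical(syn_kernel(3, 0.5, -1), 0)
  tt <- seq(0.001, 30, by = 0.001)
  k <- syn_kernel(3, 0.5, tt)
  expect_true(all(k > 0))
  expect_lt(k[length(k)], 1e-3)
  # argmax: d/dt = 0 at t* = sd*sr/(sd - sr) * log(sd/sr)
  t_star <- 3 * 0.5 / (3 - 0.5) * log(3 / 0.5)
  expect_equal(t_star, 0.6 * log(6), tolerance = 1e-12)
  expect_equal(tt[which.max(k)], t_star, tolerance = 1e-3)
  expect_error(syn_kernel(0.5, 3, 1), "sigma_r < sigma_d")
})

test_that("decay_step is the exact no-spike solution", {
  sp <- synapse_params()
  st <- list(G_E = 0, G_I = 0, H_E = 1, H_I = 0)
  out <- decay_step(st, 3, sp)
  expect_equal(out$H_E, exp(-1), tolerance = 1e-14)
  # closed form: G(3) = 0.6 (e^-1 - e^-6) for sd = 3, sr = 0.5
  expect_equal(out$G_E, 0.6 * (exp(-1) - exp(-6)), tolerance = 1e-14)
  expect_identical(out$G_I, 0)

  # continuity as dt -> 0+
  st2 <- list(G_E = 0.3, G_I = 0.2, H_E = 0.1, H_I = 0.4)
  out2 <- decay_step(st2, 1e-10, sp)
  expect_equal(unlist(out2), unlist(st2), tolerance = 1e-9)

  # semigroup: two half steps equal one full step to machine precision
  one <- decay_step(st2, 0.8, sp)
  two <- decay_step(decay_step(st2, 0.4, sp), 0.4, sp)
  expect_equal(unlist(two), unlist(one), tolerance = 1e-14)
})

test_that("decay_step agrees with high-resolution numerical integration", {
  skip_if_not_installed("deSolve")
  sp <- synapse_params()
  rhs <- function(t, y, parms) {
    list(c(G = -y[["G"]] / sp$sigma_r_E + y[["H"]],
           H = -y[["H"]] / sp$sigma_d_E))
  }
  y0 <- c(G = 0.25, H = 0.8)
  sol <- deSolve::lsoda(y0, c(0, 2.5), rhs, NULL, rtol = 1e-12, atol = 1e-14)
  out <- decay_step(list(G_E = 0.25, G_I = 0, H_E = 0.8, H_I = 0), 2.5, sp)
  expect_equal(out$G_E, unname(sol[2, "G"]), tolerance = 1e-8)
  expect_equal(out$H_E, unname(sol[2, "H"]), tolerance = 1e-8)
})

test_that("recalibrate folds spikes exactly and superposes", {
  sp <- synapse_params()
  st <- list(G_E = 0.1, G_I = 0.05, H_E = 0.2, H_I = 0.02)
  expect_identical(recalibrate(st, numeric(), NULL, t_end = 1, sp), st)

  # a feedforward spike exactly at t_end: H += f, G += 0
  out <- recalibrate(st, ff_times = 1, NULL, t_end = 1, sp, t_start = 0)
  expect_equal(out$H_E, st$H_E + sp$f, tolerance = 1e-14)
  expect_equal(out$G_E, st$G_E, tolerance = 1e-14)

  # superposition: both spikes folded at the step end equal the same two
  # spikes applied across two sub-steps with exact decay in between
  u <- c(0.3, 0.7)
  w <- 0.05
  direct <- decay_step(st, 1, sp)
  direct <- recalibrate(direct,
                        syn_spikes = data.frame(time = u, weight = w,
                                                type = "E"),
                        t_end = 1, params = sp, t_start = 0)
  split <- decay_step(st, 0.5, sp)
  split <- recalibrate(split,
                       syn_spikes = data.frame(time = u[1], weight = w,
                                               type = "E"),
                       t_end = 0.5, params = sp, t_start = 0)
  split <- decay_step(split, 0.5, sp)
  split <- recalibrate(split,
                       syn_spikes = data.frame(time = u[2], weight = w,
                                               type = "E"),
                       t_end = 1, params = sp, t_start = 0.5)
  expect_equal(unlist(split), unlist(direct), tolerance = 1e-14)

  # inhibitory spikes are routed to (G_I, H_I)
  outI <- recalibrate(st, syn_spikes = data.frame(time = 0.5, weight = w,
                                                  type = "I"),
                      t_end = 1, params = sp, t_start = 0)
  expect_identical(outI$G_E, st$G_E)
  expect_gt(outI$H_I, st$H_I)

  expect_error(recalibrate(st, ff_times = 2, NULL, t_end = 1, sp,
                           t_start = 0), "outside")
})

test_that("non-negativity is preserved by decay and recalibration", {
  sp <- synapse_params()
  st <- list(G_E = 0.5, G_I = 0.3, H_E = 0.2, H_I = 0.1)
  for (dt in c(0.01, 0.5, 5)) {
    st2 <- decay_step(st, dt, sp)
    expect_true(all(unlist(st2) >= 0))
  }
  st3 <- recalibrate(st, ff_times = c(0.2, 0.9),
                     syn_spikes = data.frame(time = 0.5, weight = 0.01,
                                             type = c("E")),
                     t_end = 1, params = sp, t_start = 0)
  expect_true(all(unlist(st3) >= unlist(st) - 1e-15))
})

test_that("naive end-of-step spike placement has a first-order conductance error", {
  sp <- synapse_params()
  dts <- c(0.1, 0.05, 0.025)
  errs <- vapply(dts, function(dt) {
    u <- 0.4 * dt # off-grid spike at a fixed fraction of the step
    exact <- recalibrate(list(G_E = 0, G_I = 0, H_E = 0, H_I = 0),
                         ff_times = u, NULL, t_end = dt, sp, t_start = 0)
    naive <- recalibrate(list(G_E = 0, G_I = 0, H_E = 0, H_I = 0),
                         ff_times = dt, NULL, t_end = dt, sp, t_start = 0)
    abs(exact$G_E - naive$G_E)
  }, numeric(1))
  expect_equal(convergence_order(dts, errs), 1, tolerance = 0.1)
})

test_that("Poisson trains have the right statistics and are reproducible", {
  expect_true(all(lengths(draw_poisson_trains(5, 0, 100, seed = 1)$times) == 0))

  tr <- draw_poisson_trains(1000, 300, 1000, seed = 7)
  counts <- lengths(tr$times)
  expect_lt(abs(mean(counts) - 300), 3 * sqrt(300) / sqrt(1000))
  expect_true(all(vapply(tr$times, function(x) !is.unsorted(x, strictly = TRUE),
                         logical(1))))
  expect_true(all(unlist(tr$times) > 0 & unlist(tr$times) <= 1000))

  tr2 <- draw_poisson_trains(1000, 300, 1000, seed = 7)
  expect_identical(tr, tr2)
  tr3 <- draw_poisson_trains(1000, 300, 1000, seed = 8)
  expect_false(identical(tr$times[[1]], tr3$times[[1]]))
})
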