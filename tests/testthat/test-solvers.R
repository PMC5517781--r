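test_that("exponential-Euler gating relaxes exactly toward steady state", {
  # fixed point
  expect_equal(exp_euler_gating_step(0.5, 1, 1, 0.1), 0.5, tolerance = 1e-15)
  # alpha = beta, x = 1, dt chosen so the decay factor is exactly 1/2
  dt <- log(2) / 2
  expect_equal(exp_euler_gating_step(1, 1, 1, dt), 0.75, tolerance = 1e-12)
  # asymptotic limit: large dt lands on x_inf
  expect_equal(exp_euler_gating_step(0.9, 2, 3, 1e6), 2 / 5,
               tolerance = 1e-12)
  # zero total rate: no dynamics
  expect_identical(exp_euler_gating_step(0.3, 0, 0, 0.1), 0.3)
  expect_error(exp_euler_gating_step(0.3, 1, 1, 0), "dt")
})

test_that("RK4 is exact for constants and 4th-order accurate for decay", {
  expect_identical(rk4_step(function(t, y) 0 * y, 2.5, 0, 0.1), 2.5)
  expect_lt(abs(rk4_step(function(t, y) -y, 1, 0, 0.1) - exp(-0.1)), 1e-7)
  # convergence study on [0, 1]: halving dt shrinks global error ~16x
  global_err <- function(dt) {
    y <- 1
    for (i in seq_len(round(1 / dt))) y <- rk4_step(function(t, y) -y, y, 0, dt)
    abs(y - exp(-1))
  }
  ratio <- global_err(0.1) / global_err(0.05)
  expect_gt(ratio, 12); expect_lt(ratio, 20)
  expect_error(suppressWarnings(rk4_step(function(t, y) sqrt(y), -1, 0, 0.1)),
               "non-finite")
})

test_that("lookup tables sample the grid and interpolate linearly", {
  tab <- build_table(function(v) exp(v / 10), -100, 50, 1)
  expect_identical(length(tab$samples), 151L)
  tab2 <- build_table(function(v) v^2, 0, 1, 0.5)
  expect_equal(tab2$samples, c(0, 0.25, 1))
  # grid nodes are returned exactly; linear functions are reproduced exactly
  expect_identical(table_lookup(tab2, 0.5), 0.25)
  lin <- build_table(function(v) 3 * v - 2, -5, 5, 0.7)
  probes <- seq(-5, -5 + 14 * 0.7, length.out = 57)
  expect_equal(table_lookup(lin, probes), 3 * probes - 2, tolerance = 1e-12)
  # hand-computed interpolation of exp: midpoint of [0, 0.5]
  e <- build_table(exp, 0, 1, 0.5)
  expect_equal(table_lookup(e, 0.25), (1 + exp(0.5)) / 2, tolerance = 1e-12)
  expect_equal(table_lookup(e, 1), exp(1), tolerance = 1e-12)  # last node
  expect_error(table_lookup(e, 1.5), "range")
  expect_error(build_table(exp, 1, 0, 0.1), "v_min")
  expect_error(build_table(exp, 0, 1, 0), "step")
})

test_that("max relative table error is measured and monotone in the step", {
  lin <- build_table(function(v) 2 * v + 10, 0, 1, 0.1)
  expect_equal(table_max_relative_error(lin, function(v) 2 * v + 10), 0,
               tolerance = 1e-10)
  err1 <- rate_table_errors(step = 1, n_probes = 2e4)
  err05 <- rate_table_errors(step = 0.5, n_probes = 2e4)
  expect_true(all(err05 <= err1 + 1e-12))  # halving the step never hurts
  zero_fn <- build_table(function(v) v, 0, 1, 0.5)   # fn vanishes at v = 0
  expect_error(table_max_relative_error(zero_fn, function(v) v), "zero")
})

test_that("exact LIF propagator agrees with brute-force Euler at tiny dt", {
  tau <- 10; v0 <- 0.5; dt <- 1e-4; n <- 1e5   # 10 ms, mid-subthreshold v0
  v_euler <- v0
  for (i in seq_len(n)) v_euler <- v_euler * (1 - dt / tau)
  v_exact <- v0 * exp(-n * dt / tau)
  expect_lt(abs(v_euler - v_exact), 1e-6)
  # and the package step reproduces the exact propagator
  p <- lif_params(tau = tau)
  st <- lif_state(1, v = v0)
  r <- lif_step(st, p, dt = 10, t = 10)
  expect_equal(r$state$v, v_exact, tolerance = 1e-12)
})

test_that("RK4 at dt=0.05 is converged for the HH membrane", {
  # subthreshold relaxation from a perturbed state over 20 ms
  net_for <- function(dt) single_hh_net(i_inj = 0, init = list(v = -58),
                                        duration = 20, dt = dt)
  fine <- run_network(net_for(0.005), seed = 1, record_v = 0)
  coarse <- run_network(net_for(0.05), seed = 1, record_v = 0)
  tc <- attr(coarse$traces, "time")
  tf <- attr(fine$traces, "time")
  common <- match(round(tc, 9), round(tf, 9))
  expect_true(all(!is.na(common)))
  expect_lt(max(abs(coarse$traces[, 1] - fine$traces[common, 1])), 0.1)
})

test_that("all solvers keep gating variables inside [0, 1]", {
  set.seed(5)
  for (solver in c("rk4", "exp_euler")) {
    for (rep in 1:3) {
      st <- list(v = runif(1, -90, -40), m = runif(1), h = runif(1),
                 n = runif(1))
      net <- single_hh_net(i_inj = 10, init = list(state = st),
                           duration = 500, dt = 0.05, solver = solver)
      r <- run_network(net, seed = rep, record_v = 0)
      fin <- r$state
      expect_true(all(c(fin$m, fin$h, fin$n) >= 0 &
                      c(fin$m, fin$h, fin$n) <= 1),
                  info = solver)
      expect_true(all(is.finite(r$traces)))
    }
  }
})
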