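test_that("LIF membrane decays exactly and rests at zero", {
  p <- lif_params(tau = 10, theta = 1, v_reset = 0, t_ref = 5.01)
  # fixed point at rest
  r <- lif_step(lif_state(1, v = 0), p, dt = 0.1, input_jump = 0, t = 0.1)
  expect_identical(r$state$v, 0)
  expect_false(r$spiked)
  # closed-form propagator: v(dt) = v0 * exp(-dt/tau)
  r <- lif_step(lif_state(1, v = 0.5), p, dt = 0.1, input_jump = 0, t = 0.1)
  expect_equal(r$state$v, 0.5 * exp(-0.01), tolerance = 1e-12)
  # semigroup property: two half steps equal one full step exactly
  half <- lif_step(lif_state(1, v = 0.7), p, dt = 0.05, t = 0.05)$state
  half2 <- lif_step(half, p, dt = 0.05, t = 0.1)$state
  full <- lif_step(lif_state(1, v = 0.7), p, dt = 0.1, t = 0.1)$state
  expect_equal(half2$v, full$v, tolerance = 1e-15)
  expect_error(lif_step(lif_state(1), p, dt = 0), "dt")
})

test_that("LIF threshold, reset, and refractory clamp follow the spike rule", {
  p <- lif_params(tau = 10, theta = 1, v_reset = 0, t_ref = 5.01)
  # decayed 0.999*e^-0.01 + 0.025 = 1.01406 > theta -> spike and reset
  r <- lif_step(lif_state(1, v = 0.999), p, dt = 0.1, input_jump = 0.025,
                t = 0.1)
  expect_equal(0.999 * exp(-0.01) + 0.025, 1.014060, tolerance = 1e-6)
  expect_true(r$spiked)
  expect_identical(r$state$v, 0)
  expect_equal(r$state$last_spike, 0.1)
  expect_equal(r$state$refractory_until, 0.1 + 5.01)
  # during refractoriness (clamp): inputs discarded, v held at reset
  r2 <- lif_step(r$state, p, dt = 0.1, input_jump = 5, t = 0.2)
  expect_false(r2$spiked)
  expect_identical(r2$state$v, 0)
  # integrate mode: membrane integrates but cannot spike
  r3 <- lif_step(r$state, p, dt = 0.1, input_jump = 5, t = 0.2,
                 refractory_mode = "integrate")
  expect_false(r3$spiked)
  expect_equal(r3$state$v, 5)
  # first boundary at or past last_spike + t_ref is eligible again
  st <- r$state; st$v <- 2
  r4 <- lif_step(st, p, dt = 0.1, input_jump = 0, t = 5.2)
  expect_true(r4$spiked)
})

test_that("HH rate functions match direct evaluation, including limits", {
  r <- hh_rates(-40)
  expect_identical(r$alpha_m, 1.0)   # removable singularity
  expect_identical(hh_rates(-55)$alpha_n, 0.1)
  r <- hh_rates(-65)
  expect_equal(r$beta_m, 4.0, tolerance = 1e-12)
  expect_equal(r$alpha_n, 0.1 / (exp(1) - 1), tolerance = 1e-12)  # ~0.0582
  expect_equal(r$alpha_n, 0.0582, tolerance = 1e-3)
  # all six positive and finite across the physiological range
  v <- seq(-100, 50, by = 0.37)
  rr <- hh_rates(v)
  for (k in names(rr)) {
    expect_true(all(is.finite(rr[[k]])), info = k)
    expect_true(all(rr[[k]] > 0), info = k)
  }
  expect_error(hh_rates(Inf), "finite")
  expect_error(hh_rates(NA_real_), "finite")
})

test_that("gating steady states are bounded and match frozen values", {
  ss <- gating_steady_state(-65)
  expect_equal(ss$m_inf, 0.0529, tolerance = 1e-2)
  expect_equal(ss$h_inf, 0.5961, tolerance = 1e-3)
  expect_equal(ss$n_inf, 0.3177, tolerance = 1e-3)
  expect_equal(gating_steady_state(0)$m_inf, 0.974, tolerance = 1e-3)
  v <- seq(-120, 60, by = 1.7)
  ss <- gating_steady_state(v)
  for (k in names(ss))
    expect_true(all(ss[[k]] > 0 & ss[[k]] < 1), info = k)
})

test_that("HH derivatives vanish near rest and add injected current linearly", {
  p <- hh_params()
  st <- hh_state(-65)
  d0 <- hh_derivatives(st, p)
  expect_lt(abs(d0$dv), 0.05)          # near-rest cancellation
  expect_equal(d0$dm, 0, tolerance = 1e-12)  # gating at steady state
  expect_equal(d0$dh, 0, tolerance = 1e-12)
  expect_equal(d0$dn, 0, tolerance = 1e-12)
  d10 <- hh_derivatives(st, hh_params(i_inj = 10))
  expect_equal(d10$dv - d0$dv, 10, tolerance = 1e-12)  # I/c additivity
})

test_that("synaptic conductances enter the voltage equation as densities", {
  p <- hh_params(area = 1e-4, c = 1)
  st <- hh_state(-55)
  base <- hh_derivatives(st, p)
  syn <- hh_derivatives(st, p, syn = list(g_inh = 2, e_inh = -75))
  # 2 nS over 1e-4 cm^2 = 0.02 mS/cm^2; driving force -20 mV -> -0.4 mV/ms
  expect_equal(syn$dv - base$dv, 2 * 1e-6 / 1e-4 * (-75 - (-55)),
               tolerance = 1e-12)
})

test_that("a current step elicits repetitive firing (excitability)", {
  r <- run_network(single_hh_net(i_inj = 10, duration = 200), seed = 1)
  expect_gt(nrow(r$spikes), 5)
})

test_that("release from hyperpolarization fires a rebound spike (anodal break)", {
  held <- hh_held_state(i_inj = -5, hold_ms = 100)
  expect_lt(held$v, -68)   # genuinely hyperpolarized below rest
  rel <- run_network(single_hh_net(i_inj = 0, init = list(state = held),
                                   duration = 30), seed = 1)
  expect_gte(nrow(rel$spikes), 1)
})
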