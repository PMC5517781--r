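test_that("scheduled events are delivered exactly round(d/dt) steps later", {
  q <- event_queue(n_targets = 3, max_delay = 2.1, dt = 0.1)
  schedule(q, target = 2, increment = 0.5, delay = 0.5)   # 5 steps ahead
  schedule(q, target = 2, increment = 0.25, delay = 0.5)  # same slot: sums
  schedule(q, target = 3, increment = 1, delay = 0.1)     # next step
  due <- deliver_due(q)
  expect_equal(due, c(0, 0, 1))
  for (i in 2:4) expect_equal(deliver_due(q), c(0, 0, 0))
  expect_equal(deliver_due(q), c(0, 0.75, 0))
  # nothing left
  expect_equal(deliver_due(q), c(0, 0, 0))
})

test_that("the queue rejects acausal and off-grid delays", {
  q <- event_queue(2, max_delay = 1, dt = 0.1)
  expect_error(schedule(q, 1, 1, delay = 0.05), "causality")
  expect_error(schedule(q, 1, 1, delay = 0.137), "off the dt")
  expect_error(schedule(q, 1, 1, delay = 5), "horizon")
})

test_that("Poisson trains are calibrated, seeded, and grid-aligned", {
  expect_identical(length(poisson_train(0, 1000, 0.1)), 0L)
  tr <- poisson_train(50, 1e5, 0.1, seed = 11)    # 100 s
  mu <- 50 * 100; sd <- sqrt(1e6 * 5e-3 * (1 - 5e-3))
  expect_lt(abs(length(tr) - mu), 5 * sd)
  expect_identical(tr, poisson_train(50, 1e5, 0.1, seed = 11))
  expect_true(all(abs(tr / 0.1 - round(tr / 0.1)) < 1e-9))
  expect_error(poisson_train(-1, 100, 0.1), "non-negative")
  expect_error(poisson_train(5000, 100, 0.1), "Bernoulli")
})

test_that("an unconnected resting network stays silent", {
  net <- tiny_lif_net(3, integer(), integer(), numeric(), numeric(),
                      duration = 20)
  r <- run_network(net, seed = 1)
  expect_identical(nrow(r$spikes), 0L)
  expect_error(min_isi(r$spikes), class = "spikenet_undefined_result")
})

test_that("a suprathreshold initial LIF fires once at t=0 then respects t_ref", {
  net <- tiny_lif_net(1, integer(), integer(), numeric(), numeric(),
                      init_v = 2, duration = 4)
  r <- run_network(net, seed = 1)
  expect_identical(nrow(r$spikes), 1L)
  expect_identical(r$spikes$time, 0)
})

test_that("spikes propagate with exactly their axonal delay (causality)", {
  # neuron 0 starts above threshold -> spikes at t=0; its suprathreshold
  # weight reaches neuron 1 at exactly d = 0.7 ms
  net <- tiny_lif_net(2, pre = 0L, post = 1L, weight = 2, delay = 0.7,
                      init_v = c(2, 0), duration = 5)
  r <- run_network(net, seed = 1)
  sp1 <- r$spikes[r$spikes$neuron == 1, ]
  expect_equal(sp1$time, 0.7, tolerance = 1e-9)
  expect_true(all(r$spikes$time[r$spikes$neuron == 0] == 0))
})

test_that("spike records sit on the dt grid and respect the refractory floor", {
  cs <- build_case_study_1(seed = 3, scale = 25)   # 160 E + 40 I + 500 gen
  r <- run_network(cs$network, seed = 4)
  expect_gt(nrow(r$spikes), 0)
  steps <- r$spikes$time / 0.1
  expect_true(all(abs(steps - round(steps)) < 1e-9))
  expect_gte(min_isi(r$spikes), 5.01)
})

test_that("(config, seed) -> spike record is fully deterministic", {
  cs <- build_case_study_1(seed = 5, scale = 50)
  r1 <- run_network(cs$network, seed = 6)
  cs_again <- build_case_study_1(seed = 5, scale = 50)
  r2 <- run_network(cs_again$network, seed = 6)
  expect_identical(cs$network$edges, cs_again$network$edges)
  expect_identical(r1$spikes, r2$spikes)
  r3 <- run_network(cs$network, seed = 7)
  expect_false(identical(r1$spikes, r3$spikes))
})

test_that("summary statistics match hand-built records", {
  rec <- data.frame(neuron = c(0L, 0L, 0L), time = c(1, 3, 8))
  expect_identical(min_isi(rec), 2)
  rec2 <- data.frame(neuron = c(0L, 1L), time = c(1, 2))
  expect_identical(min_isi(rec2), Inf)   # no neuron spiked twice
  pr <- population_rate(data.frame(neuron = 0L, time = c(0.2, 0.7, 1.5)),
                        duration = 3, bin = 1)
  expect_equal(pr$count, c(2, 1, 0))
  expect_equal(pr$time, c(0.5, 1.5, 2.5))
})

test_that("spectral peak detection finds bursts and rejects flat records", {
  # synthetic bursts every 25 ms -> 40 Hz
  burst_times <- rep(seq(0, 975, by = 25), each = 20) +
    rep(seq(0, 1.9, by = 0.1), times = 40)
  rec <- data.frame(neuron = rep(0:19, times = 40), time = burst_times)
  osc <- oscillation_frequency(rec, duration = 1000, bin = 1,
                               band = c(20, 100))
  expect_equal(osc$frequency, 40, tolerance = 1.01)  # +/- one spectral bin
  expect_true(osc$oscillatory)
  # homogeneous Poisson record: no significant peak
  flat <- do.call(rbind, lapply(0:3, function(i)
    data.frame(neuron = i, time = poisson_train(500, 1000, 0.1,
                                                seed = 2 + i))))
  osc2 <- oscillation_frequency(flat, duration = 1000, bin = 1)
  expect_false(osc2$oscillatory)
  expect_error(oscillation_frequency(rec, 1000, bin = 1, band = c(20, 900)),
               "Nyquist")
})

test_that("PIR network fires a rebound volley only under heterogeneous init", {
  cs <- build_case_study_2(seed = 2, n = 100, out_degree = 10)
  r <- run_network(cs$network, duration = 60, seed = 3)
  # release from scattered hyperpolarized potentials -> synchronized volley
  expect_gt(nrow(r$spikes), 10)
  expect_lt(diff(range(r$spikes$time)), 20)
  # identical resting initial conditions, no drive -> silence
  net_rest <- cs$network
  net_rest$init <- list(v = -65)
  r0 <- run_network(net_rest, duration = 60, seed = 3)
  expect_identical(nrow(r0$spikes), 0L)
})
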