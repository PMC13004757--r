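test_that("depression update matches closed form and dense integration", {
  p <- depression_params(pv = 0.5, tau_D = 200)
  # fixed point of recovery
  expect_equal(update_depression(1, p, numeric(), t_eval = 123), 1)
  # single multiplicative decrement just after a spike
  expect_equal(update_depression(1, p, 0, t_eval = 1e-9), 0.5,
               tolerance = 1e-6)
  # closed form after one spike and one recovery interval
  expect_equal(update_depression(1, p, 0, t_eval = 200),
               1 - 0.5 * exp(-1), tolerance = 1e-9)
  # dense-dt numeric oracle on irregular trains
  for (seed in 1:3) {
    set.seed(seed)
    spikes <- round(sort(runif(5, 0, 40)), 1)
    got <- update_depression(1, depression_params(0.6, 30), spikes,
                             t_eval = 50)
    ref <- depression_dense(0.6, 30, spikes, t_eval = 50)
    expect_equal(got, ref, tolerance = 1e-6)
    expect_gt(got, 0)
    expect_lte(got, 1)
  }
  expect_error(depression_params(pv = 0), "pv")
  expect_error(depression_params(tau_D = -1), "tau_D")
  expect_error(update_depression(1, p, c(5, 3), t_eval = 10), "sorted")
})

test_that("single LIF neuron reproduces analytic behaviour", {
  net <- one_neuron_net()
  # resting fixed point: no input, V stays at E_leak, no spikes
  r0 <- simulate_network(net, duration = 500, seed = 1,
                         record_v = list(population = "A", neurons = 1),
                         details = TRUE)
  expect_identical(nrow(r0$record), 0L)
  expect_true(all(abs(r0$v_trace[, 1] + 70) < 1e-9))
  # subthreshold current: steady state E_leak + I / g_leak
  r1 <- simulate_network(net, list(pulse_input("A", 0, 800, 0.15)),
                         duration = 800, seed = 1,
                         record_v = list(population = "A", neurons = 1),
                         details = TRUE)
  expect_identical(nrow(r1$record), 0L)
  expect_equal(tail(r1$v_trace[, 1], 1), -70 + 15, tolerance = 1e-3)
  # suprathreshold: interspike interval matches the analytic formula
  r2 <- simulate_network(net, list(pulse_input("A", 0, 3000, 0.4)),
                         duration = 3000, seed = 1)
  isi <- diff(r2$time_ms)
  analytic <- 3 + 20 * log((40 - (-65 + 70)) / (40 - 20))
  expect_true(all(abs(isi - analytic) <= 2 * 0.1))
  # halving dt moves spike times by less than dt
  r3 <- simulate_network(net, list(pulse_input("A", 0, 3000, 0.4)),
                         duration = 3000, dt = 0.05, seed = 1)
  n <- min(nrow(r2), nrow(r3))
  expect_lt(max(abs(r2$time_ms[1:n] - r3$time_ms[1:n])), 0.1 + 1e-9)
})

test_that("simulation is reproducible and seed-sensitive", {
  net <- one_neuron_net(noise_sd = 0.3)
  inp <- list(pulse_input("A", 0, 2000, 0.3))
  a <- simulate_network(net, inp, duration = 2000, seed = 42)
  b <- simulate_network(net, inp, duration = 2000, seed = 42)
  c <- simulate_network(net, inp, duration = 2000, seed = 43)
  expect_identical(a$time_ms, b$time_ms)
  expect_false(identical(a$time_ms, c$time_ms))
})

test_that("bernoulli connectivity has the right statistics and determinism", {
  expect_identical(nrow(bernoulli_connect(10, 10, 0, seed = 1)), 0L)
  expect_identical(nrow(bernoulli_connect(7, 9, 1, seed = 1)), 63L)
  e1 <- bernoulli_connect(40, 40, 0.5, seed = 5)
  e2 <- bernoulli_connect(40, 40, 0.5, seed = 5)
  expect_identical(e1, e2)
  # edge count within the central 99.9% binomial interval
  n <- 40 * 40
  expect_true(abs(nrow(e1) - n / 2) < 3.29 * sqrt(n * 0.25))
  expect_error(bernoulli_connect(-1, 5, 0.5), "non-negative")
})

test_that("heterogeneous sampling hits mean, spread and positivity", {
  expect_identical(sample_heterogeneous(3, 0, 5, seed = 1), rep(3, 5))
  x <- sample_heterogeneous(200, 0.3, 1e4, seed = 2)
  expect_true(all(x > 0))
  expect_equal(mean(x), 200, tolerance = 0.02)
  expect_true(sd(x) / mean(x) > 0.27 && sd(x) / mean(x) < 0.33)
  expect_identical(x, sample_heterogeneous(200, 0.3, 1e4, seed = 2))
})

test_that("spike record round-trips through delimited text", {
  net <- one_neuron_net(noise_sd = 0.5)
  rec <- simulate_network(net, list(pulse_input("A", 0, 1000, 0.35)),
                          duration = 1000, seed = 9)
  expect_gt(nrow(rec), 0)
  path <- file.path(withr::local_tempdir(), "spikes.tsv")
  write_spike_record(rec, path)
  back <- read_spike_record(path)
  expect_equal(nrow(back), nrow(rec))
  expect_equal(back$time_ms, rec$time_ms)
  expect_identical(back$neuron_index, rec$neuron_index)
  expect_equal(attr(back, "t_end"), attr(rec, "t_end"))
})

test_that("disabled depression leaves repeated responses identical", {
  # two neurons, driver -> follower without depression: the follower's
  # response to identical pulses is identical each trial
  pops <- list(
    population_spec("A", n = 1, neuron = neuron_params(), cm_rel_sd = 0),
    population_spec("B", n = 1, neuron = neuron_params(), cm_rel_sd = 0))
  proj <- projection_spec("A", "B", p_connect = 1,
                          kinetics = synapse_kinetics("AMPA", g_max = 40))
  net <- network_spec(pops, list(proj), seed = 1)
  inp <- lapply(seq(0, 4) * 500, function(t0)
    pulse_input("A", t0, t0 + 50, 0.4))
  rec <- simulate_network(net, inp, duration = 2500, seed = 1)
  bcounts <- vapply(seq(0, 4) * 500, function(t0)
    sum(rec$population == "B" & rec$time_ms >= t0 & rec$time_ms < t0 + 100),
    0)
  expect_true(all(bcounts == bcounts[1]))
  expect_gt(bcounts[1], 0)
})

test_that("unstable parameters raise a simulation error naming the neuron", {
  bad <- one_neuron_net()
  expect_error(
    simulate_network(bad, list(pulse_input("A", 0, 100, Inf)),
                     duration = 100, seed = 1),
    "non-finite membrane potential for neuron")
})
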