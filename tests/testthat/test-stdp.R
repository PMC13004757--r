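test_that("stdp_update reproduces the closed-form pair effects", {
  p <- stdp_params(A_plus = 0.029, A_minus = -0.0348, w_init = 1)
  s <- stdp_state(p)
  expect_equal(s$w, 1)
  # no events: weight unchanged by pure decay
  expect_equal(stdp_update(stdp_update(s, "pre", 0), "pre", 1e6)$w, 1)
  # pre at 0, post at 10 ms: potentiation by A_plus * exp(-10/20)
  s1 <- stdp_update(stdp_state(p), "pre", 0)
  s1 <- stdp_update(s1, "post", 10)
  expect_equal(s1$w - 1, 0.029 * exp(-0.5), tolerance = 1e-12)
  # post at 0, pre at 10 ms: depression by A_minus * exp(-0.5)
  s2 <- stdp_update(stdp_state(p), "post", 0)
  s2 <- stdp_update(s2, "pre", 10)
  expect_equal(s2$w - 1, -0.0348 * exp(-0.5), tolerance = 1e-12)
  # clipping at the lower bound
  s3 <- stdp_state(stdp_params(A_plus = 0.029, A_minus = -0.5,
                               w_init = 0.01))
  s3 <- stdp_update(s3, "post", 0)
  s3 <- stdp_update(s3, "pre", 1)
  expect_equal(s3$w, 0)
  expect_error(stdp_update(s1, "pre", 5), "precedes")
})

test_that("event-driven STDP equals dense-time integration on random trains", {
  p <- stdp_params(A_plus = 0.029, alpha = -1.2, w_init = 1)
  for (seed in 1:4) {
    set.seed(seed)
    pre <- round(sort(runif(12, 0, 150)), 2)
    post <- round(sort(runif(12, 0, 150)), 2)
    post <- post[!post %in% pre]
    ev <- rbind(data.frame(t = pre, kind = "pre"),
                data.frame(t = post, kind = "post"))
    ev <- ev[order(ev$t), ]
    s <- stdp_state(p)
    for (i in seq_len(nrow(ev))) s <- stdp_update(s, ev$kind[i], ev$t[i])
    ref <- stdp_dense(pre, post, p, t_end = 160, dt = 0.01)
    expect_equal(s$w, ref, tolerance = 1e-9)
  }
})

test_that("engine STDP matches the event-driven reference on a driven pair", {
  # one presynaptic and one postsynaptic neuron, each driven by its own
  # suprathreshold pulses; the plastic synapse is too weak to influence
  # spiking, so the R-level reference applied to the recorded spike
  # times must reproduce the engine's final weight.
  p <- stdp_params(A_plus = 0.05, alpha = -1.2, w_init = 1,
                   w_max = 10)
  pops <- list(
    population_spec("PRE", n = 1, neuron = neuron_params(), cm_rel_sd = 0),
    population_spec("POST", n = 1, neuron = neuron_params(), cm_rel_sd = 0))
  proj <- projection_spec("PRE", "POST", p_connect = 1,
                          kinetics = synapse_kinetics("AMPA", g_max = p$w_init),
                          delay = 1, plasticity = p)
  net <- network_spec(pops, list(proj), seed = 1)
  inputs <- c(
    lapply(seq(0, 900, by = 120), function(t0)
      pulse_input("PRE", t0, t0 + 12, 0.6)),
    lapply(seq(37, 900, by = 95), function(t0)
      pulse_input("POST", t0, t0 + 12, 0.6)))
  sim <- simulate_network(net, inputs, duration = 1000, seed = 1,
                          details = TRUE)
  rec <- sim$record
  w_engine <- sim$final_w[[which(!vapply(sim$final_w, is.null, TRUE))[1]]]
  pre_t <- rec$time_ms[rec$population == "PRE"]
  post_t <- rec$time_ms[rec$population == "POST"]
  expect_gt(length(pre_t), 3)
  expect_gt(length(post_t), 3)
  ev <- rbind(data.frame(t = pre_t, kind = "pre"),
              data.frame(t = post_t, kind = "post"))
  ev <- ev[order(ev$t, ev$kind == "post"), ]  # pre before post on ties
  s <- stdp_state(p)
  for (i in seq_len(nrow(ev))) s <- stdp_update(s, ev$kind[i], ev$t[i])
  expect_equal(w_engine, s$w, tolerance = 1e-9)
})

test_that("stdp parameter validation", {
  expect_error(stdp_params(A_plus = -1), "A_plus")
  expect_error(stdp_params(alpha = 2), "alpha")
  sp <- stdp_params(A_plus = 0.029, alpha = -1.2)
  expect_equal(sp$A_minus, -0.0348)
  expect_equal(sp$w_init, 0.029)
  expect_equal(sp$w_max, 2.4)
})
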