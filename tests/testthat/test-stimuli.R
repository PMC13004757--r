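test_that("rhythmic protocols sit on the exact onset grid", {
  for (rate in c(1.5, 2, 2.5)) {
    p <- make_stimulus_sequence("frequency_deviant", rate = rate,
                                n_burn_in = 0)
    expect_equal(diff(p$events$onset), rep(1000 / rate, nrow(p$events) - 1))
    expect_equal(p$events$onset[1:10],
                 1000 / rate * (1:10))
  }
  # 10 trials at 2 Hz: onsets one period apart
  p <- make_stimulus_sequence("frequency_deviant", n_pre_standards = 9,
                              n_cycles = 1, n_burn_in = 0)
  expect_equal(p$events$onset, 500 * (1:10))
})

test_that("deviant placement and omission slots are correct", {
  p <- make_stimulus_sequence("omission", n_pre_standards = 4,
                              n_cycles = 3, n_burn_in = 2)
  ev <- p$events
  expect_identical(sum(ev$is_burn_in), 2L)
  expect_identical(sum(ev$is_deviant_trial), 3L)
  expect_true(all(ev$is_omission[ev$is_deviant_trial]))
  expect_true(all(is.na(ev$frequency_label[ev$is_omission])))
  # deviants come after runs of n_pre_standards standards
  dv <- which(ev$is_deviant_trial)
  expect_equal(diff(dv), rep(5L, 2))
  # inverse protocol: long standards, short deviant
  pi <- make_stimulus_sequence("inverse_duration_deviant", n_burn_in = 0)
  expect_true(all(pi$events$duration[!pi$events$is_deviant_trial] == 100))
  expect_true(all(pi$events$duration[pi$events$is_deviant_trial] == 50))
})

test_that("long tones start 50 ms before the co-scheduled short onset", {
  net <- build_mmn_network(mmn_params(), n = 4, seed = 1)
  p <- make_stimulus_sequence("duration_deviant", n_burn_in = 0)
  inputs <- mmnsim:::tone_inputs(net, p)
  dev_onset <- p$events$onset[p$events$is_deviant_trial][1]
  starts <- vapply(inputs, `[[`, 0, "start")
  ends <- vapply(inputs, `[[`, 0, "end")
  dev_in <- which(abs(ends - (dev_onset + 50)) < 1e-9 &
                    starts < dev_onset)
  expect_true(length(dev_in) > 0)
  expect_true(all(abs(starts[dev_in] - (dev_onset - 50)) < 1e-9))
})

test_that("roving sequence covers all 12 transitions plus 4 omissions", {
  p <- make_stimulus_sequence("roving")
  ev <- p$events
  expect_identical(sum(ev$is_omission), 4L)
  key <- paste(ev$frequency_label, ev$duration)
  trans <- character()
  for (i in 2:nrow(ev)) {
    if (ev$is_omission[i] || ev$is_omission[i - 1]) next
    if (key[i] != key[i - 1]) trans <- c(trans, paste(key[i - 1], "->", key[i]))
  }
  expect_identical(length(trans), 12L)
  expect_identical(anyDuplicated(trans), 0L)
  # runs of five identical tones between transitions
  expect_true(all(table(rle(key[!ev$is_omission])$lengths) > 0))
  expect_identical(sum(ev$is_deviant_trial), 16L)  # 12 transitions + 4 omissions
})

test_that("random control draws identities per slot reproducibly", {
  a <- make_stimulus_sequence("random_control", seed = 3)
  b <- make_stimulus_sequence("random_control", seed = 3)
  c <- make_stimulus_sequence("random_control", seed = 4)
  expect_identical(a$events, b$events)
  expect_false(identical(a$events$duration, c$events$duration) &&
                 identical(a$events$frequency_label, c$events$frequency_label))
})

test_that("phase-locked pulse schedules obey the jitter bounds", {
  s0 <- phase_locked_spec(rate = 2, jitter_theta = 0, amplitude = 0.3)
  sched <- phase_locked_pulse_times(s0, duration = 3000, n_neurons = 5)
  for (tt in sched$times)
    expect_equal(tt, seq(0, 2500, by = 500))
  s1 <- phase_locked_spec(rate = 2, jitter_theta = 20, seed = 7,
                          amplitude = 0.3)
  sc1 <- phase_locked_pulse_times(s1, duration = 3000, n_neurons = 200)
  expect_true(all(abs(sc1$t0) <= 20))
  # offsets roughly uniform: both halves populated
  expect_gt(mean(sc1$t0 > 0), 0.35)
  expect_gt(mean(sc1$t0 < 0), 0.35)
  # per-neuron phase fixed across pulses
  gaps <- unlist(lapply(sc1$times, diff))
  expect_true(all(abs(gaps - 500) < 1e-9))
})

test_that("protocols serialize to JSON and back", {
  p <- make_stimulus_sequence("duration_deviant", n_cycles = 2)
  path <- file.path(withr::local_tempdir(), "prot.json")
  write_protocol(p, path)
  q <- read_protocol(path)
  expect_equal(q$events$onset, p$events$onset)
  expect_identical(q$kind, p$kind)
  expect_equal(q$expected_onsets, p$expected_onsets)
})

test_that("unknown protocol kind errors", {
  expect_error(make_stimulus_sequence("nonsense"))
})
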