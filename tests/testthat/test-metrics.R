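simple_protocol <- function() {
  # 4 standards then a deviant, all onsets >= 650 ms, no burn-in
  make_stimulus_sequence("frequency_deviant", n_pre_standards = 4,
                         n_cycles = 1, n_burn_in = 1)
}

record_with_counts <- function(protocol, dev_n, std_n, pop = "EO",
                               pop_size = 40) {
  ev <- protocol$events[!protocol$events$is_burn_in, ]
  times <- numeric()
  for (i in seq_len(nrow(ev))) {
    k <- if (ev$is_deviant_trial[i]) dev_n else std_n
    if (k > 0) times <- c(times, ev$onset[i] + seq_len(k) * 10)
  }
  spike_record(times, rep(pop, length(times)),
               rep(1L, length(times)), t_end = max(times) + 1000,
               pop_sizes = setNames(pop_size, pop))
}

test_that("deviance index implements the window-count definition", {
  p <- simple_protocol()
  # hand count: 12 spikes in the deviant window, 3 per standard window
  rec <- record_with_counts(p, dev_n = 12, std_n = 3)
  di <- deviance_index(rec, p)
  expect_equal(di$f_deviant, 24)
  expect_equal(di$f_standard, 6)
  expect_equal(di$f_dd, 18)
  # identical counts give zero index
  di0 <- deviance_index(record_with_counts(p, 5, 5), p)
  expect_equal(di0$f_dd, 0)
  # empty record gives all-zero rates
  emp <- spike_record(numeric(), character(), integer(), t_end = 5000,
                      pop_sizes = c(EO = 40L))
  die <- deviance_index(emp, p)
  expect_equal(c(die$f_deviant, die$f_standard, die$f_dd), c(0, 0, 0))
})

test_that("deviance index antisymmetry under class-label swap", {
  p <- make_stimulus_sequence("frequency_deviant", n_cycles = 1,
                              n_burn_in = 0)
  rec <- record_with_counts(p, dev_n = 9, std_n = 2)
  di <- deviance_index(rec, p, standard_selection = "all")
  q <- p
  q$events$is_deviant_trial <- !q$events$is_deviant_trial
  dj <- deviance_index(rec, q, standard_selection = "all")
  expect_equal(dj$f_dd, -di$f_dd)
})

test_that("windows reaching before the record are excluded with a warning", {
  p <- make_stimulus_sequence("frequency_deviant", n_cycles = 1,
                              n_burn_in = 0)
  p$events$onset <- p$events$onset - 500  # first onset at 0
  rec <- record_with_counts(p, 4, 4)
  expect_warning(deviance_index(rec, p), "excluded")
})

test_that("acceptance test applies inclusive 80% and 6x thresholds", {
  p <- simple_protocol()
  ev <- p$events[!p$events$is_burn_in, ]
  don <- ev$onset[ev$is_deviant_trial]
  std <- ev$onset[!ev$is_deviant_trial]
  # 32 of 40 neurons fire once for the deviant; standards average exactly
  # deviant/6 spikes
  dev_times <- don + seq_len(32) * 5
  dev_idx <- 1:32
  std_times <- unlist(lapply(std, function(o) o + seq_len(8) * 5))
  std_idx <- rep(1:8, length(std))
  rec <- spike_record(c(dev_times, std_times),
                      rep("EO", length(dev_times) + length(std_times)),
                      c(dev_idx, std_idx), t_end = 10000,
                      pop_sizes = c(EO = 40L))
  # deviant 32 spikes, standards 8 each: ratio 4 -> rejected
  a1 <- acceptance_test(rec, p)
  expect_false(a1$accepted)
  expect_equal(a1$frac_firing, 0.8)
  # boundary case: 36 deviant spikes over 32 neurons (80% exactly) and
  # 6 spikes per standard, so the ratio is exactly 6
  dev_times3 <- don + seq_len(36) * 5
  dev_idx3 <- c(1:32, 1:4)
  std_times3 <- unlist(lapply(std, function(o) o + seq_len(6) * 5))
  rec3 <- spike_record(c(dev_times3, std_times3),
                       rep("EO", length(dev_times3) + length(std_times3)),
                       c(dev_idx3, rep(1:6, length(std))), t_end = 10000,
                       pop_sizes = c(EO = 40L))
  a3 <- acceptance_test(rec3, p)
  expect_true(a3$accepted)          # exactly 80% and exactly 6x
  expect_equal(a3$ratio, 6)
  # 31 of 40 neurons (77.5%) fails even with a huge ratio
  dev_times4 <- don + seq_len(31) * 5
  rec4 <- spike_record(dev_times4, rep("EO", 31), 1:31, t_end = 10000,
                       pop_sizes = c(EO = 40L))
  a4 <- acceptance_test(rec4, p)
  expect_false(a4$accepted)
  expect_equal(a4$frac_firing, 31 / 40)
  expect_true(is.infinite(a4$ratio))
  # zero output spikes -> rejected
  emp <- spike_record(numeric(), character(), integer(), t_end = 10000,
                      pop_sizes = c(EO = 40L))
  expect_false(acceptance_test(emp, p)$accepted)
})

test_that("rate curve integrates to the spike count", {
  expect_true(all(rate_curve(numeric(), sigma = 25)$rate == 0))
  rc <- rate_curve(c(100), sigma = 25)
  expect_equal(sum(rc$rate) * 1 / 1000, 1, tolerance = 1e-3)
  set.seed(1)
  spikes <- sort(runif(37, 200, 800))
  rc2 <- rate_curve(spikes, sigma = 25)
  expect_equal(sum(rc2$rate) / 1000, 37, tolerance = 1e-2)
})

test_that("burst detection matches examples and a brute-force oracle", {
  expect_equal(nrow(detect_bursts(numeric())), 0L)
  b1 <- detect_bursts(5)
  expect_equal(b1$n_spikes, 1L)
  b2 <- detect_bursts(c(0, 10, 20, 100), max_isi = 50)
  expect_equal(b2$start, c(0, 100))
  expect_equal(b2$end, c(20, 100))
  expect_equal(b2$n_spikes, c(3L, 1L))
  # gaps exactly at the threshold stay inside one burst
  b3 <- detect_bursts(c(0, 49, 98), max_isi = 50)
  expect_identical(nrow(b3), 1L)
  # O(n^2) union-find oracle: transitive closure of the pairwise
  # "within max_isi" relation
  brute <- function(x, iso) {
    n <- length(x)
    parent <- seq_len(n)
    find <- function(i) {
      while (parent[i] != i) i <- parent[i]
      i
    }
    for (i in seq_len(n)) for (j in seq_len(n))
      if (abs(x[i] - x[j]) <= iso) parent[find(j)] <- find(i)
    comp <- vapply(seq_len(n), find, 1L)
    split(x, comp)
  }
  for (seed in 1:5) {
    set.seed(seed)
    x <- sort(round(cumsum(rexp(50, 1 / 30))))
    got <- detect_bursts(x, max_isi = 50)
    ref <- unname(brute(x, 50))
    ref <- ref[order(vapply(ref, min, 0))]
    expect_identical(nrow(got), length(ref))
    expect_equal(got$n_spikes, lengths(ref))
    expect_equal(got$start, vapply(ref, min, 0))
    expect_equal(got$end, vapply(ref, max, 0))
  }
})

test_that("entrainment scorer handles constructed rhythms", {
  # no post-cessation spikes
  s0 <- score_entrainment(c(100, 600, 1100), cessation_time = 1200,
                          rate = 2)
  expect_identical(s0$n_good_cycles, 0L)
  # synthetic 20-ms bursts of 10 spikes at exact 500-ms gaps
  mk_burst <- function(t0) t0 + seq(0, 20, length.out = 10)
  spikes <- unlist(lapply(seq(0, 3000, by = 500), mk_burst))
  sa <- score_entrainment(spikes, cessation_time = 1000, rate = 2,
                          mode = "absolute")
  expect_identical(sum(sa$expected_hits), 4L)
  expect_identical(sum(sa$unexpected_active), 0L)
  sr <- score_entrainment(spikes, cessation_time = 1020, rate = 2,
                          mode = "relative")
  expect_gte(sr$n_good_cycles, 3L)
  expect_false(sr$long_burst)
  # a burst longer than 75 ms terminates the run
  long_spikes <- c(mk_burst(0), mk_burst(500), 1000 + seq(0, 100, by = 10))
  sl <- score_entrainment(long_spikes, cessation_time = 520, rate = 2,
                          mode = "relative")
  expect_true(sl$long_burst)
})

test_that("rank-sum comparison matches exact enumeration for small n", {
  g <- group_compare(1:5, 1:5)
  expect_false(g$significant)
  expect_equal(group_compare(rep(1, 4), rep(1, 6))$p_value, 1)
  # fully separated groups of 16: significant under Bonferroni/4
  gs <- group_compare(1:16, 17:32, n_tests = 4)
  expect_lt(gs$p_value, 0.05 / 4)
  expect_true(gs$significant)
  expect_equal(gs$threshold, 0.0125)
  # normal approximation vs exact distribution, n <= 8, no ties: the
  # continuity-corrected approximation stays within 0.025 of the exact
  # p-value (the discrete exact distribution makes a tighter uniform
  # bound unattainable at these group sizes) and the Bonferroni
  # significance decision agrees except within 0.005 of the threshold
  for (seed in 1:50) {
    set.seed(seed)
    a <- rnorm(sample(4:8, 1))
    b <- rnorm(sample(4:8, 1), mean = runif(1, -1.5, 1.5))
    p_exact <- stats::wilcox.test(a, b, exact = TRUE)$p.value
    g <- group_compare(a, b)
    expect_lt(abs(p_exact - g$p_value), 0.025)
    if (abs(p_exact - g$threshold) > 0.005)
      expect_identical(g$significant, p_exact < g$threshold)
  }
})
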