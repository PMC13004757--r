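#' Deviance-detection index
#'
#' For every trial of a protocol, counts the spikes of the output
#' population inside a fixed 0.5-s peristimulus window and converts them
#' to rates by dividing by the window length. The index is the
#' difference between the mean deviant-trial rate and the mean
#' standard-trial rate, `f_dd = f_deviant - f_standard`. Trials whose
#' window starts before the recording are excluded with a warning.
#'
#' Two window conventions are in use: the index window `c(-150, 350)`
#' (default) and the response-total window `c(-50, 450)`; both are
#' half-open `[onset + w1, onset + w2)`.
#'
#' @param record a [spike_record()].
#' @param protocol the [make_stimulus_sequence()] protocol that produced
#'   it.
#' @param population which population to score (default `"EO"`).
#' @param window length-2 offset (ms) around each nominal onset.
#' @param per `"population"` (rates are summed over neurons, spikes/s)
#'   or `"neuron"` (divided by the population size).
#' @param standard_selection `"pre_deviant"` (standard trials occurring
#'   before the last deviant; default) or `"all"`.
#' @return An object of class `"deviance_result"`: list with
#'   `f_deviant`, `f_standard`, `f_dd` (spikes/s), `n_deviant_trials`,
#'   `n_standard_trials`, and the per-trial counts.
#' @export
deviance_index <- function(record, protocol, population = "EO",
                           window = c(-150, 350),
                           per = c("population", "neuron"),
                           standard_selection = c("pre_deviant", "all")) {
  per <- match.arg(per)
  standard_selection <- match.arg(standard_selection)
  stopifnot(length(window) == 2, diff(window) > 0)
  spk <- record[record$population == population, , drop = FALSE]
  ev <- protocol$events
  w_len_s <- diff(window) / 1000
  n_neurons <- attr(record, "pop_sizes")[[population]]
  if (per == "neuron" && is.null(n_neurons))
    stop("record carries no population sizes; cannot rate per neuron",
         call. = FALSE)

  count_in <- function(onset)
    sum(spk$time_ms >= onset + window[1] & spk$time_ms < onset + window[2])
  complete <- ev$onset + window[1] >= 0
  if (any(!complete))
    warning(sum(!complete), " trial(s) excluded: window extends before t=0")

  burn <- if (is.null(ev$is_burn_in)) rep(FALSE, nrow(ev)) else ev$is_burn_in
  dev_idx <- which(ev$is_deviant_trial & complete)
  std_idx <- which(!ev$is_deviant_trial & !ev$is_omission & !burn & complete)
  if (standard_selection == "pre_deviant" && length(dev_idx))
    std_idx <- std_idx[ev$onset[std_idx] < max(ev$onset[dev_idx])]

  dev_counts <- vapply(ev$onset[dev_idx], count_in, 0)
  std_counts <- vapply(ev$onset[std_idx], count_in, 0)
  denom <- w_len_s * if (per == "neuron") n_neurons else 1
  f_dev <- if (length(dev_counts)) mean(dev_counts) / denom else 0
  f_std <- if (length(std_counts)) mean(std_counts) / denom else 0
  structure(list(f_deviant = f_dev, f_standard = f_std,
                 f_dd = f_dev - f_std,
                 n_deviant_trials = length(dev_counts),
                 n_standard_trials = length(std_counts),
                 deviant_counts = dev_counts, standard_counts = std_counts,
                 per = per, window = window, population = population),
            class = "deviance_result")
}

#' @export
print.deviance_result <- function(x, ...) {
  cat(sprintf(
    "<deviance_result> f_deviant = %.2f, f_standard = %.2f, f_dd = %.2f spikes/s (%s, %d/%d trials)\n",
    x$f_deviant, x$f_standard, x$f_dd, x$per, x$n_deviant_trials,
    x$n_standard_trials))
  invisible(x)
}

#' Acceptance criterion for a fitted model
#'
#' A parameter set is accepted for a protocol when (1) at least 80
#' percent of the output neurons fire once or more for the deviant
#' (averaged over deviant trials) and (2) the number of output spikes
#' following the deviant is at least six times the average number
#' following a standard. Both thresholds are inclusive.
#'
#' @inheritParams deviance_index
#' @param n_output_neurons output population size; taken from the
#'   record's metadata when omitted.
#' @param frac_threshold,ratio_threshold the 80 percent and six-fold
#'   thresholds.
#' @return A list with `accepted` (logical) plus diagnostics
#'   (`frac_firing`, `ratio`, per-trial counts).
#' @export
acceptance_test <- function(record, protocol, population = "EO",
                            n_output_neurons = NULL,
                            window = c(-150, 350),
                            frac_threshold = 0.8, ratio_threshold = 6,
                            standard_selection = c("pre_deviant", "all")) {
  standard_selection <- match.arg(standard_selection)
  if (is.null(n_output_neurons))
    n_output_neurons <- attr(record, "pop_sizes")[[population]]
  if (is.null(n_output_neurons))
    stop("n_output_neurons must be supplied", call. = FALSE)
  spk <- record[record$population == population, , drop = FALSE]
  ev <- protocol$events
  complete <- ev$onset + window[1] >= 0
  dev_idx <- which(ev$is_deviant_trial & complete)
  frac <- vapply(ev$onset[dev_idx], function(onset) {
    inw <- spk$time_ms >= onset + window[1] & spk$time_ms < onset + window[2]
    length(unique(spk$neuron_index[inw])) / n_output_neurons
  }, 0)
  di <- suppressWarnings(deviance_index(
    record, protocol, population = population, window = window,
    standard_selection = standard_selection))
  mean_dev <- if (length(di$deviant_counts)) mean(di$deviant_counts) else 0
  mean_std <- if (length(di$standard_counts)) mean(di$standard_counts) else 0
  ratio <- if (mean_std > 0) mean_dev / mean_std
           else if (mean_dev > 0) Inf else 0
  frac_firing <- if (length(frac)) mean(frac) else 0
  list(accepted = frac_firing >= frac_threshold && ratio >= ratio_threshold,
       frac_firing = frac_firing, ratio = ratio,
       mean_deviant_spikes = mean_dev, mean_standard_spikes = mean_std,
       deviance = di)
}

#' Gaussian-smoothed firing-rate curve
#'
#' Convolves a spike train with a normalized Gaussian kernel (default
#' SD 25 ms). The time integral of the curve equals the spike count.
#'
#' @param record a [spike_record()], or a numeric vector of spike times
#'   (ms).
#' @param sigma kernel SD (ms), > 0.
#' @param population population to smooth when `record` is a
#'   [spike_record()] (default: all spikes).
#' @param t_grid evaluation grid (ms); default every 1 ms over the
#'   recording (or over the spikes, padded by 4 sigma).
#' @return Data frame with `time_ms` and `rate` (spikes/s).
#' @export
rate_curve <- function(record, sigma = 25, population = NULL,
                       t_grid = NULL) {
  stopifnot(sigma > 0)
  if (inherits(record, "spike_record")) {
    spk <- if (is.null(population)) record$time_ms
           else record$time_ms[record$population == population]
    if (is.null(t_grid)) t_grid <- seq(0, attr(record, "t_end"), by = 1)
  } else {
    spk <- as.numeric(record)
    if (is.null(t_grid)) {
      lo <- if (length(spk)) min(spk) - 4 * sigma else 0
      hi <- if (length(spk)) max(spk) + 4 * sigma else 1
      t_grid <- seq(lo, hi, by = 1)
    }
  }
  rate <- numeric(length(t_grid))
  for (ts in spk) rate <- rate + stats::dnorm(t_grid, ts, sigma)
  data.frame(time_ms = t_grid, rate = rate * 1000)
}

#' Detect bursts by interspike-interval threshold
#'
#' Splits a sorted spike train into bursts wherever the gap between two
#' consecutive spikes exceeds `max_isi` (gaps exactly equal to the
#' threshold stay within a burst).
#'
#' @param spike_times sorted spike times (ms).
#' @param max_isi maximal intra-burst interspike interval (ms),
#'   default 50.
#' @return Data frame with one row per burst: `start`, `end`,
#'   `n_spikes`.
#' @export
detect_bursts <- function(spike_times, max_isi = 50) {
  if (is.unsorted(spike_times)) stop("spike_times must be sorted", call. = FALSE)
  n <- length(spike_times)
  if (n == 0)
    return(data.frame(start = numeric(), end = numeric(),
                      n_spikes = integer()))
  brk <- which(diff(spike_times) > max_isi)
  first <- c(1L, brk + 1L)
  last <- c(brk, n)
  data.frame(start = spike_times[first], end = spike_times[last],
             n_spikes = last - first + 1L)
}

#' Score rhythmic entrainment after stimulus cessation
#'
#' Two scoring modes for post-cessation activity of the base population
#' of the synfire chain.
#'
#' `mode = "relative"` applies burst-timing criteria: starting from the
#' last population burst initiated before `cessation_time`, successive
#' bursts count as appropriately timed cycles when their first spike
#' occurs no earlier than `0.9 * period` and their last spike no later
#' than `1.1 * period` after the last spike of the previous burst
#' (450-550 ms at 2 Hz). Counting stops at the first mistimed cycle or
#' when any burst in the run lasts longer than `max_burst_ms`.
#'
#' `mode = "absolute"` checks fixed windows: for cycles `i = 0..3`,
#' "expected" windows `cessation + i * period +/- 60` ms count as hits
#' when at least `min_spikes` spikes fall inside, and "unexpected"
#' intervals `(cessation + i * period + 60, + 440]` are flagged when at
#' least `min_spikes` spikes fall inside.
#'
#' @param record a [spike_record()] or numeric spike times (ms) of the
#'   base population.
#' @param cessation_time time (ms) at which the rhythmic stimulus
#'   stopped.
#' @param rate stimulation rate (Hz).
#' @param mode `"relative"` or `"absolute"`.
#' @param population population name when `record` is a
#'   [spike_record()], default `"BASE"`.
#' @param max_isi burst-splitting interval (ms).
#' @param max_burst_ms maximal allowed burst duration (ms).
#' @param min_spikes minimum spikes per window (absolute mode).
#' @param n_cycles number of post-cessation cycles checked in absolute
#'   mode.
#' @return For `"relative"`: list with `n_good_cycles`, `long_burst`,
#'   and the burst table. For `"absolute"`: list with logical vectors
#'   `expected_hits` and `unexpected_active`.
#' @export
score_entrainment <- function(record, cessation_time, rate = 2,
                              mode = c("relative", "absolute"),
                              population = "BASE", max_isi = 50,
                              max_burst_ms = 75, min_spikes = 5,
                              n_cycles = 4) {
  mode <- match.arg(mode)
  times <- if (inherits(record, "spike_record"))
    record$time_ms[record$population == population] else as.numeric(record)
  times <- sort(times)
  period <- 1000 / rate
  if (mode == "absolute") {
    i <- seq_len(n_cycles) - 1
    centers <- cessation_time + i * period
    expected <- vapply(centers, function(ct)
      sum(times > ct - 60 & times <= ct + 60) >= min_spikes, NA)
    unexpected <- vapply(centers, function(ct)
      sum(times > ct + 60 & times <= ct + 440) >= min_spikes, NA)
    return(list(expected_hits = expected, unexpected_active = unexpected))
  }
  bursts <- detect_bursts(times, max_isi = max_isi)
  ref <- which(bursts$start <= cessation_time)
  if (!length(ref) || nrow(bursts) == length(ref))
    return(list(n_good_cycles = 0L, long_burst = FALSE, bursts = bursts))
  prev_end <- bursts$end[max(ref)]
  good <- 0L
  long_burst <- FALSE
  for (b in seq(max(ref) + 1L, nrow(bursts))) {
    if (bursts$end[b] - bursts$start[b] > max_burst_ms) {
      long_burst <- TRUE
      break
    }
    gap_first <- bursts$start[b] - prev_end
    gap_last <- bursts$end[b] - prev_end
    if (gap_first >= 0.9 * period && gap_last <= 1.1 * period) {
      good <- good + 1L
      prev_end <- bursts$end[b]
    } else break
  }
  list(n_good_cycles = good, long_burst = long_burst, bursts = bursts)
}

#' Rank-sum group comparison with Bonferroni correction
#'
#' Two-sided Wilcoxon rank-sum test (Mann-Whitney U) using the normal
#' approximation with tie correction and continuity correction;
#' significance is declared at `0.05 / n_tests` (Bonferroni over the
#' four protocols by default).
#'
#' @param values_a,values_b numeric vectors, both non-empty.
#' @param n_tests number of comparisons corrected for (default 4).
#' @return List with `p_value`, `significant`, `threshold` and the
#'   U statistic.
#' @export
group_compare <- function(values_a, values_b, n_tests = 4) {
  stopifnot(length(values_a) > 0, length(values_b) > 0)
  n1 <- length(values_a); n2 <- length(values_b)
  pooled <- c(values_a, values_b)
  r <- rank(pooled)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(pooled)
  n <- n1 + n2
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) {
    p <- 1
  } else {
    z <- (abs(U - mu) - 0.5) / sqrt(sigma2)  # continuity correction
    z <- max(z, 0)
    p <- 2 * stats::pnorm(-z)
    p <- min(p, 1)
  }
  thr <- 0.05 / n_tests
  list(p_value = p, significant = p < thr, threshold = thr, U = U)
}
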