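#' Configuration of the synfire-chain network
#'
#' A base population plus `n_chain_pops` chain populations connected
#' feedforward (Bernoulli `p_ff`, transmission delay `ff_delay`); every
#' excitatory population has a same-size inhibitory partner population,
#' bidirectionally connected, that terminates its burst and prevents
#' runaway excitation. Feedback synapses from every chain population to
#' the base population are plastic (STDP) and start weak.
#'
#' @param n_chain_pops number of chain populations (default 70; longer
#'   chains span slower stimulus rates).
#' @param n_per_pop neurons per population (default 50).
#' @param p_ff feedforward connection probability (0.5).
#' @param ff_delay feedforward transmission delay (ms, default 5).
#' @param g_ff static feedforward AMPA conductance per synapse (nS);
#'   the default is calibrated (see [calibrate_synfire()]) so that one
#'   stimulus sweeps all 70 populations in about 600 ms.
#' @param p_fb,fb_delay feedback (chain to base) connectivity and
#'   delay. The feedback is sparser than the feedforward chain (0.45):
#'   denser feedback lets weakly potentiated early populations trigger
#'   the base too early, accelerating the post-cessation cycle
#'   shortening until the rhythm collapses.
#' @param g_ei,g_ie excitatory-to-inhibitory AMPA and
#'   inhibitory-to-excitatory GABA conductances per synapse (nS). The
#'   inhibitory partners must be strong enough to cap population bursts
#'   well below 75 ms yet weak enough that reverberation-evoked base
#'   bursts carry enough spikes to re-trigger the chain; `g_ei = 1`
#'   sits in the reliable basin.
#' @param stim_amplitude,stim_width square-pulse stimulus to the base
#'   population (nA, ms).
#' @param noise_sd membrane noise current SD (nA) for all neurons.
#' @param cm_rel_sd relative SD of per-neuron capacitance (the chain
#'   needs higher spike-time precision than the novelty network, hence
#'   the smaller default).
#' @param tau_ampa AMPA decay constant (ms) of this network's
#'   excitatory synapses. The default 5 ms sets the per-hop integration
#'   latency that, together with the 5-ms transmission delay, makes one
#'   stimulus sweep the 70-population chain in about 600 ms (the 2-ms
#'   kinetics of the novelty network would pin the hop latency near
#'   7 ms however weak the conductance).
#' @param neuron a [neuron_params()] object for all populations.
#' @return An object of class `"synfire_config"`.
#' @export
synfire_config <- function(n_chain_pops = 70, n_per_pop = 50, p_ff = 0.5,
                           ff_delay = 5, g_ff = 1.25, p_fb = 0.45,
                           fb_delay = 1, g_ei = 1.0, g_ie = 2,
                           stim_amplitude = 1, stim_width = 10,
                           noise_sd = 0.1, cm_rel_sd = 0.1,
                           tau_ampa = 6, neuron = neuron_params()) {
  stopifnot(n_chain_pops >= 1, n_per_pop >= 1, ff_delay >= 0, g_ff >= 0)
  structure(as.list(environment()), class = "synfire_config")
}

chain_pop_names <- function(n) sprintf("C%02d", seq_len(n))

#' Build the synfire-chain network
#'
#' @param cfg a [synfire_config()].
#' @param stdp an [stdp_params()] object for the feedback synapses, or
#'   `NULL` for a plasticity-free chain (feedback synapses are then
#'   static at their initial weight, which is too weak to matter).
#' @param seed integer seed (connectivity and heterogeneity).
#' @return A [network_spec()]; populations are `BASE`, `C01..Cnn` and
#'   their inhibitory partners `IB`, `IC01..ICnn`.
#' @export
build_synfire_network <- function(cfg = synfire_config(), stdp = NULL,
                                  seed = 1) {
  stopifnot(inherits(cfg, "synfire_config"))
  cn <- chain_pop_names(cfg$n_chain_pops)
  exc <- c("BASE", cn)
  inh <- c("IB", sprintf("I%s", cn))
  pops <- c(
    lapply(exc, function(nm)
      population_spec(nm, n = cfg$n_per_pop, neuron = cfg$neuron,
                      excitatory = TRUE, cm_rel_sd = cfg$cm_rel_sd,
                      noise_sd = cfg$noise_sd)),
    lapply(inh, function(nm)
      population_spec(nm, n = cfg$n_per_pop, neuron = cfg$neuron,
                      excitatory = FALSE, cm_rel_sd = cfg$cm_rel_sd,
                      noise_sd = cfg$noise_sd)))

  projs <- list()
  add <- function(p) projs[[length(projs) + 1L]] <<- p
  # feedforward chain
  ff_kin <- synapse_kinetics("AMPA", g_max = cfg$g_ff,
                             tau_decay = cfg$tau_ampa)
  chain <- c("BASE", cn)
  for (i in seq_len(length(chain) - 1))
    add(projection_spec(chain[i], chain[i + 1], p_connect = cfg$p_ff,
                        kinetics = ff_kin, delay = cfg$ff_delay))
  # inhibitory partners
  for (i in seq_along(exc)) {
    add(projection_spec(exc[i], inh[i], p_connect = 0.5,
                        kinetics = synapse_kinetics(
                          "AMPA", g_max = cfg$g_ei,
                          tau_decay = cfg$tau_ampa)))
    add(projection_spec(inh[i], exc[i], p_connect = 0.5,
                        kinetics = synapse_kinetics("GABA", g_max = cfg$g_ie)))
  }
  # plastic feedback, one projection per chain population (weight
  # trajectories are recorded per projection, i.e. per population)
  fb_w0 <- if (is.null(stdp)) stdp_params()$w_init else stdp$w_init
  for (nm in cn)
    add(projection_spec(nm, "BASE", p_connect = cfg$p_fb,
                        kinetics = synapse_kinetics(
                          "AMPA", g_max = fb_w0, tau_decay = cfg$tau_ampa),
                        delay = cfg$fb_delay, plasticity = stdp))
  net <- network_spec(pops, projs, seed = seed,
                      kinetics = kinetics_config(tau_ampa = cfg$tau_ampa))
  net$synfire <- list(cfg = cfg, stdp = stdp)
  net
}

#' Run a rhythmic-entrainment experiment
#'
#' Stimulates the base population with square pulses at `stim_rate` for
#' `stim_duration` seconds, then continues without stimulation for
#' `post_duration` seconds while the plastic feedback synapses either
#' sustain the rhythm or not. With `poisson = TRUE` the stimulus times
#' follow a Poisson process of the same mean rate (a control that must
#' not produce entrainment).
#'
#' @param cfg a [synfire_config()].
#' @param stdp an [stdp_params()] object (or `NULL` to disable
#'   plasticity).
#' @param stim_rate stimulation rate (Hz).
#' @param stim_duration,post_duration entrainment and post-cessation
#'   intervals (s).
#' @param seed integer seed (drives connectivity, noise and Poisson
#'   times).
#' @param poisson use Poisson-timed stimulation.
#' @param record_weights_every snapshot interval (ms) for mean feedback
#'   weights per chain population.
#' @param dt integration step (ms).
#' @return A list: `record` ([spike_record()]), `cessation_time` (ms),
#'   `stim_times`, `w_times` and `w_means` (snapshots x populations),
#'   `final_w` (per-projection weight vectors), `runaway` flag (any
#'   500-ms bin with a population-average rate above 100 spikes/s).
#' @export
run_entrainment <- function(cfg = synfire_config(), stdp = stdp_params(),
                            stim_rate = 2, stim_duration = 12,
                            post_duration = 2.5, seed = 1,
                            poisson = FALSE, record_weights_every = 250,
                            dt = 0.1) {
  net <- build_synfire_network(cfg, stdp = stdp, seed = seed)
  period <- 1000 / stim_rate
  t_stim_end <- stim_duration * 1000
  duration <- t_stim_end + post_duration * 1000
  stim_times <- if (poisson) {
    gaps <- with_seed(seed + 7L, rexp(ceiling(4 * stim_rate * stim_duration),
                                      rate = stim_rate / 1000))
    tt <- cumsum(gaps)
    tt[tt < t_stim_end - cfg$stim_width]
  } else {
    seq(0, t_stim_end - period, by = period)
  }
  inputs <- lapply(stim_times, function(tt)
    pulse_input("BASE", tt, tt + cfg$stim_width, cfg$stim_amplitude))
  sim <- simulate_network(net, inputs, duration = duration, dt = dt,
                          seed = seed,
                          record_weights_every = record_weights_every,
                          details = TRUE)
  n_total <- sum(vapply(net$populations, `[[`, 1L, "n"))
  runaway <- any(sim$bin_counts / n_total / (sim$bin_ms / 1000) > 100)
  fw <- Filter(Negate(is.null), sim$final_w)
  names(fw) <- chain_pop_names(cfg$n_chain_pops)
  wm <- sim$w_means
  if (ncol(wm)) colnames(wm) <- chain_pop_names(cfg$n_chain_pops)
  list(record = sim$record, cessation_time = t_stim_end,
       stim_times = stim_times, w_times = sim$w_times,
       w_means = wm, final_w = fw, runaway = runaway,
       net = net)
}

#' Measure the single-stimulus propagation sweep
#'
#' Runs the chain without plasticity, delivers one stimulus to the base
#' population, and measures the activation sequence duration: the time
#' from stimulus onset to the last spike of the final population's
#' burst (the calibrated 70-population chain sweeps in about 600 ms).
#'
#' @param cfg a [synfire_config()].
#' @param seed integer seed.
#' @param dt integration step (ms).
#' @return A list with `sweep_ms`, `reached` (did the final population
#'   fire) and the [spike_record()].
#' @export
measure_sweep <- function(cfg = synfire_config(), seed = 1, dt = 0.1) {
  net <- build_synfire_network(cfg, stdp = NULL, seed = seed)
  duration <- max(1500, cfg$n_chain_pops * 15)
  rec <- simulate_network(
    net, list(pulse_input("BASE", 0, cfg$stim_width, cfg$stim_amplitude)),
    duration = duration, dt = dt, seed = seed)
  last_pop <- chain_pop_names(cfg$n_chain_pops)[cfg$n_chain_pops]
  tt <- rec$time_ms[rec$population == last_pop]
  if (!length(tt))
    return(list(sweep_ms = NA_real_, reached = FALSE, record = rec))
  # last spike of the population's (first) burst
  b <- detect_bursts(sort(tt), max_isi = 50)
  list(sweep_ms = b$end[1], reached = TRUE, record = rec)
}

#' Calibrate the feedforward conductance of the chain
#'
#' Bisects `g_ff` so that a single stimulus sweeps the whole chain in
#' approximately `target_ms`. Larger conductances advance each hop
#' (shorter sweep); below a critical conductance propagation fails.
#'
#' @param cfg a [synfire_config()] (its `g_ff` is ignored).
#' @param target_ms target sweep duration (ms).
#' @param lo,hi conductance bracket (nS).
#' @param tol_ms acceptable deviation from target (ms).
#' @param max_iter bisection iterations.
#' @param seed integer seed.
#' @return The calibrated `synfire_config`.
#' @export
calibrate_synfire <- function(cfg = synfire_config(), target_ms = 600,
                              lo = 0.8, hi = 4, tol_ms = 10,
                              max_iter = 12, seed = 1) {
  eval_g <- function(g) {
    cfg$g_ff <- g
    measure_sweep(cfg, seed = seed)
  }
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    m <- eval_g(mid)
    if (!m$reached || m$sweep_ms > target_ms) lo <- mid else hi <- mid
    if (m$reached && abs(m$sweep_ms - target_ms) <= tol_ms) break
  }
  cfg$g_ff <- hi
  cfg
}

#' Grid search over the STDP learning-rate parameters
#'
#' For every combination of `A_plus` and `alpha` runs `reps`
#' entrainment experiments with different seeds and scores
#' post-cessation activity with the absolute scorer
#' ([score_entrainment()] mode `"absolute"`): the fraction of
#' repetitions with spiking at the expected post-cessation times and
#' the fraction with activity at unexpected (inter-cycle) times.
#'
#' @param A_plus_values,alpha_values grid axes (nS, dimensionless).
#' @param reps repetitions per cell (default 20).
#' @param cfg a [synfire_config()].
#' @param stim_rate,stim_duration,post_duration as
#'   [run_entrainment()].
#' @param seed master seed; repetition seeds derive from it.
#' @param min_cycles expected-time hits required in a repetition for it
#'   to count (default 3 of the 4 scored cycles).
#' @return A data frame with one row per grid cell: `A_plus`, `alpha`,
#'   `frac_expected`, `frac_unexpected`.
#' @export
entrainment_grid <- function(A_plus_values, alpha_values, reps = 20,
                             cfg = synfire_config(), stim_rate = 2,
                             stim_duration = 12, post_duration = 2.5,
                             seed = 1, min_cycles = 3) {
  stopifnot(reps >= 1)
  grid <- expand.grid(A_plus = A_plus_values, alpha = alpha_values)
  seeds <- derive_seeds(seed, reps, salt = 5L)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    hits <- logical(reps); unexp <- logical(reps)
    for (r in seq_len(reps)) {
      ent <- run_entrainment(
        cfg, stdp_params(A_plus = grid$A_plus[i], alpha = grid$alpha[i]),
        stim_rate = stim_rate, stim_duration = stim_duration,
        post_duration = post_duration, seed = seeds[r])
      sc <- score_entrainment(ent$record, ent$cessation_time,
                              rate = stim_rate, mode = "absolute")
      hits[r] <- sum(sc$expected_hits) >= min_cycles
      unexp[r] <- any(sc$unexpected_active)
    }
    c(frac_expected = mean(hits), frac_unexpected = mean(unexp))
  })
  cbind(grid, do.call(rbind, res))
}
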