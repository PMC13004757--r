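# Shared fixtures: all built in code, sized for speed.

one_neuron_net <- function(Cm = 200, g_leak = 10, noise_sd = 0) {
  network_spec(list(population_spec(
    "A", n = 1, neuron = neuron_params(Cm = Cm, g_leak = g_leak),
    cm_rel_sd = 0, noise_sd = noise_sd)), seed = 1)
}

# short oddball protocol used where full length is not needed
quick_protocol <- function(kind, ...) {
  make_stimulus_sequence(kind, n_cycles = 2, n_burn_in = 3, ...)
}

# Dense-timestep numeric integration (midpoint rule) of the depression
# ODE between spikes (independent oracle for the event-driven closed
# form). Spike times must lie on the dt grid.
depression_dense <- function(pv, tau_D, spike_times, t_eval, dt = 1e-4) {
  D <- 1
  n <- round(t_eval / dt)
  spike_steps <- round(spike_times / dt)
  for (s in seq_len(n)) {
    if (any(spike_steps == s - 1)) D <- D - pv * D
    half <- D + dt / 2 * (1 - D) / tau_D
    D <- D + dt * (1 - half) / tau_D
  }
  D
}

# Dense-time integration of the STDP trace equations on a fine grid with
# per-step exponential decay (exact for the linear trace dynamics, so the
# only difference from the event-driven path is the bookkeeping), used as
# the brute-force oracle. Event times must lie on the dt grid.
stdp_dense <- function(pre, post, params, t_end, dt = 0.01) {
  w <- params$w_init
  Apre <- 0
  Apost <- 0
  dec <- exp(-dt / params$tau_A)
  pre_steps <- round(pre / dt)
  post_steps <- round(post / dt)
  for (s in 0:round(t_end / dt)) {
    if (any(pre_steps == s)) {
      w <- min(max(w + Apost, params$w_min), params$w_max)
      Apre <- Apre + params$A_plus
    }
    if (any(post_steps == s)) {
      w <- min(max(w + Apre, params$w_min), params$w_max)
      Apost <- Apost + params$A_minus
    }
    Apre <- Apre * dec
    Apost <- Apost * dec
  }
  w
}
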