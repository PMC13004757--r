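#' Global receptor-channel kinetics of a network
#'
#' The engine aggregates synaptic conductances per neuron into one AMPA,
#' one NMDA and one GABA channel, so decay constants and reversal
#' potentials are network-global. Individual projections choose their
#' receptor and per-synapse conductance via [synapse_kinetics()].
#'
#' @param tau_ampa,tau_nmda,tau_gaba decay time constants (ms).
#' @param E_exc,E_inh excitatory / inhibitory reversal potentials (mV).
#' @param mg_block apply the sigmoidal magnesium voltage block to the
#'   NMDA channel.
#' @param mg_mM magnesium concentration (mM) of the block factor.
#' @return An object of class `"kinetics_config"`.
#' @export
kinetics_config <- function(tau_ampa = 2, tau_nmda = 100, tau_gaba = 10,
                            E_exc = 0, E_inh = -80, mg_block = TRUE,
                            mg_mM = 1) {
  stopifnot(tau_ampa > 0, tau_nmda > 0, tau_gaba > 0)
  structure(list(tau_ampa = tau_ampa, tau_nmda = tau_nmda,
                 tau_gaba = tau_gaba, E_exc = E_exc, E_inh = E_inh,
                 mg_block = isTRUE(mg_block), mg_mM = mg_mM),
            class = "kinetics_config")
}

#' Specify one neuron population
#'
#' @param name population label (e.g. `"ES"`, `"EO"`).
#' @param n number of neurons, >= 1.
#' @param neuron a [neuron_params()] object (population mean values).
#' @param excitatory logical; informational flag.
#' @param cm_rel_sd relative standard deviation of per-neuron membrane
#'   capacitance (heterogeneity); default 0.3.
#' @param noise_sd per-neuron white-noise current SD (nA), quoted as the
#'   per-step SD at the 0.1-ms reference step (rescaled by
#'   `sqrt(0.1 / dt)` for other step sizes so that membrane-voltage
#'   statistics stay comparable across `dt`).
#' @return An object of class `"population_spec"`.
#' @export
population_spec <- function(name, n = 40, neuron = neuron_params(),
                            excitatory = TRUE, cm_rel_sd = 0.3,
                            noise_sd = 0) {
  stopifnot(is.character(name), length(name) == 1, n >= 1,
            inherits(neuron, "neuron_params"), cm_rel_sd >= 0,
            noise_sd >= 0)
  structure(list(name = name, n = as.integer(n), neuron = neuron,
                 excitatory = isTRUE(excitatory), cm_rel_sd = cm_rel_sd,
                 noise_sd = noise_sd),
            class = "population_spec")
}

#' Specify one projection between two populations
#'
#' Connectivity is Bernoulli with probability `p_connect`, sampled from
#' `seed` (the same seed always reproduces the same adjacency). A
#' projection may carry several receptor components (e.g. AMPA plus an
#' NMDA component scaled by an NMDA/AMPA ratio) sharing one adjacency.
#'
#' @param source,target population names.
#' @param p_connect connection probability; the network default is 0.5.
#' @param kinetics a [synapse_kinetics()] object or a list of them.
#' @param depression optional [depression_params()]; applies short-term
#'   depression to all components (the released fraction multiplies the
#'   transmitted conductance, `w * D`).
#' @param delay transmission delay (ms), >= 0.
#' @param plasticity optional [stdp_params()]; makes the (single,
#'   AMPA-kinetics) component plastic.
#' @param seed integer adjacency seed; if `NULL`, derived from the
#'   network seed when the network is built.
#' @return An object of class `"projection_spec"`.
#' @export
projection_spec <- function(source, target, p_connect = 0.5, kinetics,
                            depression = NULL, delay = 0,
                            plasticity = NULL, seed = NULL) {
  if (inherits(kinetics, "synapse_kinetics")) kinetics <- list(kinetics)
  stopifnot(all(vapply(kinetics, inherits, TRUE, "synapse_kinetics")),
            p_connect >= 0, p_connect <= 1, delay >= 0)
  if (!is.null(depression) && !inherits(depression, "depression_params"))
    stop("depression must be a depression_params object", call. = FALSE)
  if (!is.null(plasticity)) {
    if (!inherits(plasticity, "stdp_params"))
      stop("plasticity must be an stdp_params object", call. = FALSE)
    if (length(kinetics) != 1)
      stop("a plastic projection must have a single receptor component",
           call. = FALSE)
  }
  structure(list(source = source, target = target, p_connect = p_connect,
                 kinetics = kinetics, depression = depression,
                 delay = delay, plasticity = plasticity, seed = seed),
            class = "projection_spec")
}

#' Square-pulse current input
#'
#' @param population target population name.
#' @param start,end pulse window (ms); a negative `start` is truncated
#'   at 0.
#' @param amplitude current amplitude (nA).
#' @param neurons optional integer vector of neuron indices within the
#'   population (default: all neurons).
#' @return An object of class `"pulse_input"`.
#' @export
pulse_input <- function(population, start, end, amplitude, neurons = NULL) {
  stopifnot(end > start)
  structure(list(population = population, start = start, end = end,
                 amplitude = amplitude, neurons = neurons),
            class = "pulse_input")
}

#' Assemble a network specification
#'
#' @param populations list of [population_spec()] objects; their order
#'   fixes the global neuron index blocks.
#' @param projections list of [projection_spec()] objects.
#' @param inputs list of [pulse_input()] objects delivered on every run
#'   of this network (additional run-specific inputs can be passed to
#'   [simulate_network()]).
#' @param kinetics a [kinetics_config()].
#' @param seed integer network seed governing structure: per-neuron
#'   capacitance heterogeneity and any projection adjacency without its
#'   own seed.
#' @return An object of class `"network_spec"`.
#' @export
network_spec <- function(populations, projections = list(),
                         inputs = list(), kinetics = kinetics_config(),
                         seed = 1) {
  stopifnot(all(vapply(populations, inherits, TRUE, "population_spec")),
            all(vapply(projections, inherits, TRUE, "projection_spec")),
            all(vapply(inputs, inherits, TRUE, "pulse_input")),
            inherits(kinetics, "kinetics_config"))
  nm <- vapply(populations, `[[`, "", "name")
  if (anyDuplicated(nm)) stop("duplicated population names", call. = FALSE)
  names(populations) <- nm
  for (pr in projections)
    for (fld in c("source", "target"))
      if (!pr[[fld]] %in% nm)
        stop(sprintf("projection references unknown population '%s'",
                     pr[[fld]]), call. = FALSE)
  for (ii in inputs)
    if (!ii$population %in% nm)
      stop(sprintf("input references unknown population '%s'",
                   ii$population), call. = FALSE)
  structure(list(populations = populations, projections = projections,
                 inputs = inputs, kinetics = kinetics,
                 seed = as.integer(seed)),
            class = "network_spec")
}

#' @export
print.network_spec <- function(x, ...) {
  ns <- vapply(x$populations, `[[`, 1L, "n")
  cat("<network_spec> ", length(ns), " populations, ", sum(ns),
      " neurons, ", length(x$projections), " projections\n", sep = "")
  cat("  populations:", paste0(names(ns), "(", ns, ")", collapse = " "), "\n")
  invisible(x)
}

population_offsets <- function(spec) {
  ns <- vapply(spec$populations, `[[`, 1L, "n")
  off <- c(0L, cumsum(ns))
  list(n = ns, offset = setNames(off[-length(off)], names(ns)),
       total = sum(ns))
}

# Per-neuron membrane capacitances, sampled once from the network seed so
# the same spec always yields the same heterogeneity realization.
population_cm_values <- function(spec) {
  offs <- population_offsets(spec)
  seeds <- derive_seeds(spec$seed, length(spec$populations), salt = 11L)
  out <- vector("list", length(spec$populations))
  for (i in seq_along(spec$populations)) {
    p <- spec$populations[[i]]
    out[[i]] <- sample_heterogeneous(p$neuron$Cm, p$cm_rel_sd, p$n,
                                     seed = seeds[i])
  }
  names(out) <- names(spec$populations)
  out
}

check_kinetics <- function(spec) {
  k <- spec$kinetics
  ref <- list(AMPA = c(k$tau_ampa, k$E_exc), NMDA = c(k$tau_nmda, k$E_exc),
              GABA = c(k$tau_gaba, k$E_inh))
  for (pr in spec$projections)
    for (comp in pr$kinetics) {
      r <- ref[[comp$receptor]]
      if (abs(comp$tau_decay - r[1]) > 1e-9 || abs(comp$E_rev - r[2]) > 1e-9)
        stop(sprintf(
          "projection %s->%s: %s kinetics (tau %g, E %g) differ from the network receptor channel (tau %g, E %g)",
          pr$source, pr$target, comp$receptor, comp$tau_decay, comp$E_rev,
          r[1], r[2]), call. = FALSE)
    }
  invisible(TRUE)
}

# Flatten a network_spec + inputs into the plain-vector structure the C++
# engine consumes.
build_engine_input <- function(spec, inputs, duration, dt, seed,
                               record_v = NULL, w_every = 0) {
  check_kinetics(spec)
  offs <- population_offsets(spec)
  n_steps <- as.integer(round(duration / dt))
  cmv <- population_cm_values(spec)

  Cm <- numeric(offs$total); gL <- EL <- Vth <- Vrs <- nsd <- Cm
  trf <- integer(offs$total)
  for (nm in names(spec$populations)) {
    p <- spec$populations[[nm]]
    idx <- offs$offset[[nm]] + seq_len(p$n)
    Cm[idx] <- cmv[[nm]]
    gL[idx] <- p$neuron$g_leak
    EL[idx] <- p$neuron$E_leak
    Vth[idx] <- p$neuron$V_thresh
    Vrs[idx] <- p$neuron$V_reset
    trf[idx] <- as.integer(round(p$neuron$t_ref / dt))
    nsd[idx] <- p$noise_sd * 1000 * sqrt(0.1 / dt)  # nA -> pA, dt-rescaled
  }

  proj_seeds <- derive_seeds(spec$seed, max(1L, length(spec$projections)),
                             salt = 23L)
  eng_projs <- list()
  for (i in seq_along(spec$projections)) {
    pr <- spec$projections[[i]]
    n_src <- spec$populations[[pr$source]]$n
    n_tgt <- spec$populations[[pr$target]]$n
    aseed <- if (is.null(pr$seed)) proj_seeds[i] else pr$seed
    edges <- bernoulli_connect(n_src, n_tgt, pr$p_connect, seed = aseed)
    ord <- order(edges[, 1], edges[, 2])
    edges <- edges[ord, , drop = FALSE]
    row_ptr <- c(0L, cumsum(tabulate(edges[, 1], nbins = n_src)))
    tgt_glob <- offs$offset[[pr$target]] + edges[, 2] - 1L
    for (comp in pr$kinetics) {
      ep <- list(
        src0 = unname(offs$offset[[pr$source]]), n_src = n_src,
        row_ptr = as.integer(row_ptr), tgt = as.integer(tgt_glob),
        w = rep(comp$g_max, nrow(edges)),
        receptor = match(comp$receptor, c("AMPA", "NMDA", "GABA")) - 1L,
        delay_steps = as.integer(round(pr$delay / dt)),
        pv = if (is.null(pr$depression)) 0 else pr$depression$pv,
        tau_D = if (is.null(pr$depression)) 1 else pr$depression$tau_D,
        plastic = FALSE)
      if (!is.null(pr$plasticity)) {
        sp <- pr$plasticity
        ep$plastic <- TRUE
        ep$A_plus <- sp$A_plus; ep$A_minus <- sp$A_minus
        ep$tau_A <- sp$tau_A; ep$w_min <- sp$w_min; ep$w_max <- sp$w_max
        ep$w <- rep(sp$w_init, nrow(edges))
        ep$tgt0 <- unname(offs$offset[[pr$target]]); ep$n_tgt <- n_tgt
        co <- order(edges[, 2], edges[, 1])
        ep$in_ptr <- as.integer(c(0L, cumsum(tabulate(edges[, 2], nbins = n_tgt))))
        ep$in_edge <- as.integer(co - 1L)
        ep$in_src <- as.integer(edges[co, 1] - 1L)
        if (w_every > 0) {
          ep$w_group <- integer(nrow(edges))
          ep$n_groups <- 1L
        }
      }
      eng_projs[[length(eng_projs) + 1L]] <- ep
    }
  }

  # pulse schedule -> sorted step diffs
  all_inputs <- c(spec$inputs, inputs)
  ev_step <- integer(); ev_neuron <- integer(); ev_damp <- numeric()
  for (ii in all_inputs) {
    s0 <- max(0L, as.integer(round(ii$start / dt)))
    s1 <- as.integer(round(ii$end / dt))
    if (s1 <= s0 || s0 >= n_steps) next
    idx <- if (is.null(ii$neurons)) seq_len(spec$populations[[ii$population]]$n)
           else ii$neurons
    glob <- offs$offset[[ii$population]] + idx - 1L
    amp_pA <- ii$amplitude * 1000
    ev_step <- c(ev_step, rep(s0, length(glob)))
    ev_neuron <- c(ev_neuron, glob)
    ev_damp <- c(ev_damp, rep(amp_pA, length(glob)))
    if (s1 < n_steps) {
      ev_step <- c(ev_step, rep(s1, length(glob)))
      ev_neuron <- c(ev_neuron, glob)
      ev_damp <- c(ev_damp, rep(-amp_pA, length(glob)))
    }
  }
  ord <- order(ev_step)

  rv <- integer()
  if (!is.null(record_v))
    rv <- as.integer(offs$offset[[record_v$population]] +
                       record_v$neurons - 1L)

  list(dt = dt, n_steps = n_steps, seed = as.double(seed),
       neuron = list(Cm = Cm, gL = gL, EL = EL, Vth = Vth, Vreset = Vrs,
                     tref_steps = trf, noise_sd = nsd, V0 = EL),
       kin = list(tau_ampa = spec$kinetics$tau_ampa,
                  tau_nmda = spec$kinetics$tau_nmda,
                  tau_gaba = spec$kinetics$tau_gaba,
                  E_exc = spec$kinetics$E_exc, E_inh = spec$kinetics$E_inh,
                  mg_block = spec$kinetics$mg_block,
                  mg_mM = spec$kinetics$mg_mM),
       pulses = list(step = ev_step[ord], neuron = ev_neuron[ord],
                     d_amp = ev_damp[ord]),
       projections = eng_projs,
       record_v = rv,
       w_every_steps = as.integer(w_every),
       offsets = offs)
}

#' Simulate a network
#'
#' Integrates the network with exponential-Euler updates at fixed step
#' `dt`. Identical `(spec, inputs, duration, dt, seed)` yield an
#' identical [spike_record()]: structural randomness (connectivity,
#' heterogeneity) is governed by the network seed inside `spec`, while
#' `seed` here only drives the noise currents.
#'
#' @param spec a [network_spec()].
#' @param inputs additional [pulse_input()] list for this run.
#' @param duration simulated time (ms).
#' @param dt integration step (ms), default 0.1.
#' @param seed integer noise seed.
#' @param record_v optional `list(population =, neurons =)` to record
#'   membrane voltages.
#' @param record_weights_every optional interval (ms) at which mean
#'   plastic weights per projection are snapshotted.
#' @param details if `TRUE`, return a list with the record plus voltage
#'   traces, weight trajectories, final plastic weights and diagnostics;
#'   otherwise just the [spike_record()].
#' @return A [spike_record()] (or a detailed list, see `details`).
#' @export
simulate_network <- function(spec, inputs = list(), duration, dt = 0.1,
                             seed = 1, record_v = NULL,
                             record_weights_every = NULL,
                             details = FALSE) {
  stopifnot(inherits(spec, "network_spec"), duration > 0, dt > 0)
  if (inherits(inputs, "pulse_input")) inputs <- list(inputs)
  w_every <- if (is.null(record_weights_every)) 0L
             else as.integer(round(record_weights_every / dt))
  eng <- build_engine_input(spec, inputs, duration, dt, seed,
                            record_v = record_v, w_every = w_every)
  out <- .simulate_engine(eng)
  offs <- eng$offsets
  pop_of <- rep(names(offs$n), offs$n)
  rec <- spike_record(
    time_ms = out$spike_step * dt,
    population = pop_of[out$spike_neuron + 1L],
    neuron_index = out$spike_neuron + 1L - unname(offs$offset[
      pop_of[out$spike_neuron + 1L]]),
    t_end = eng$n_steps * dt, dt = dt, seed = seed,
    pop_sizes = offs$n)
  if (!details) return(rec)
  list(record = rec,
       v_trace = out$v_trace,
       w_times = out$w_times,
       w_means = out$w_means,
       final_w = out$final_w,
       bin_counts = out$bin_counts,
       bin_ms = out$bin_ms)
}
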