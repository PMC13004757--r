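#' Build an oddball stimulus protocol
#'
#' Generates the tone-event sequence for one protocol. Events sit on a
#' rhythmic grid with inter-onset interval `1000 / rate` ms starting at
#' one full period (so that every peristimulus analysis window and the
#' alternative-phase pacemaker pulse fit into simulated time). Short
#' tones last 50 ms from their nominal onset; long tones last 100 ms and
#' start 50 ms *before* the nominal onset, so both tone types end
#' together.
#'
#' Protocol kinds:
#' * `frequency_deviant` — short standard-frequency tones with a short
#'   deviant-frequency tone as deviant.
#' * `omission` — short standards; the deviant slot is silent.
#' * `duration_deviant` — short standards; the deviant is a long tone of
#'   the standard frequency.
#' * `inverse_duration_deviant` — long standards; the deviant is a short
#'   tone of the standard frequency.
#' * `double_deviant` — short standards; the deviant is a long tone of
#'   the deviant frequency.
#' * `roving` — runs of five identical tones covering all 12 ordered
#'   transitions between the four tone types (an Eulerian circuit of the
#'   complete digraph on short/long x standard/deviant), followed by one
#'   omission after a run of each tone type.
#' * `random_control` — tone identity drawn uniformly at random per slot
#'   (seeded); deviant flags keep the cyclic positions of the rhythmic
#'   protocols so that the acceptance criterion can be evaluated (and
#'   should fail).
#'
#' @param kind protocol kind, see above.
#' @param n_pre_standards standards before each deviant (default 4).
#' @param n_cycles number of (standards + deviant) cycles (default 4).
#' @param n_burn_in initial standard tones flagged `is_burn_in`
#'   (default 4): they settle the short-term depression to its
#'   steady state and are excluded from standard-trial averaging by the
#'   metrics, like the discarded initial trials of a recording session.
#'   Ignored by `roving`.
#' @param rate presentation rate (Hz), default 2.
#' @param seed integer seed (used by `random_control` only).
#' @param short_ms,long_ms tone durations (ms).
#' @return An object of class `"stimulus_protocol"`: a list with `kind`,
#'   `rate`, `events` (data frame with `onset`, `duration`,
#'   `frequency_label`, `is_omission`, `is_deviant_trial`) and
#'   `expected_onsets` (the full rhythmic grid).
#' @export
make_stimulus_sequence <- function(kind = c("frequency_deviant", "omission",
                                            "duration_deviant",
                                            "inverse_duration_deviant",
                                            "double_deviant", "roving",
                                            "random_control"),
                                   n_pre_standards = 4, n_cycles = 4,
                                   n_burn_in = 4, rate = 2, seed = 1,
                                   short_ms = 50, long_ms = 100) {
  kind <- match.arg(kind)
  stopifnot(n_pre_standards >= 1, n_cycles >= 1, n_burn_in >= 0, rate > 0)
  period <- 1000 / rate

  tone_types <- data.frame(
    label = c("SS", "SD", "LS", "LD"),
    frequency_label = c("standard", "deviant", "standard", "deviant"),
    duration = c(short_ms, short_ms, long_ms, long_ms),
    stringsAsFactors = FALSE)

  mk_events <- function(type_idx, omission, deviant) {
    n <- length(type_idx)
    data.frame(
      onset = period * seq_len(n),
      duration = ifelse(omission, 0, tone_types$duration[type_idx]),
      frequency_label = ifelse(omission, NA_character_,
                               tone_types$frequency_label[type_idx]),
      is_omission = omission,
      is_deviant_trial = deviant,
      stringsAsFactors = FALSE)
  }

  cyc <- n_pre_standards + 1L
  n_ev <- n_cycles * cyc
  pos_dev <- seq_len(n_ev) %% cyc == 0

  ev <- switch(kind,
    frequency_deviant = mk_events(ifelse(pos_dev, 2L, 1L),
                                  rep(FALSE, n_ev), pos_dev),
    omission = {
      e <- mk_events(rep(1L, n_ev), pos_dev, pos_dev)
      e$frequency_label[pos_dev] <- NA
      e
    },
    duration_deviant = mk_events(ifelse(pos_dev, 3L, 1L),
                                 rep(FALSE, n_ev), pos_dev),
    inverse_duration_deviant = mk_events(ifelse(pos_dev, 1L, 3L),
                                         rep(FALSE, n_ev), pos_dev),
    double_deviant = mk_events(ifelse(pos_dev, 4L, 1L),
                               rep(FALSE, n_ev), pos_dev),
    random_control = {
      ids <- with_seed(seed, sample.int(4L, n_ev, replace = TRUE))
      mk_events(ids, rep(FALSE, n_ev), pos_dev)
    },
    roving = {
      circuit <- eulerian_circuit_k4()
      runs <- c(circuit, circuit[length(circuit)])  # resume last type once
      type_seq <- integer(0)
      omis <- logical(0)
      devi <- logical(0)
      run_len <- 5L
      for (j in seq_along(circuit)) {
        type_seq <- c(type_seq, rep(circuit[j], run_len))
        omis <- c(omis, rep(FALSE, run_len))
        devi <- c(devi, j > 1, rep(FALSE, run_len - 1))
      }
      # one omission after a run of each tone type; the first appended
      # run repeats the circuit's final type so no extra pair transition
      # is introduced.
      last <- circuit[length(circuit)]
      order4 <- c(last, setdiff(1:4, last))
      for (tt in order4) {
        type_seq <- c(type_seq, rep(tt, run_len), tt)
        omis <- c(omis, rep(FALSE, run_len), TRUE)
        devi <- c(devi, rep(FALSE, run_len), TRUE)
      }
      e <- mk_events(type_seq, omis, devi)
      e$frequency_label[omis] <- NA
      e$duration[omis] <- 0
      e
    })

  ev$is_burn_in <- FALSE
  if (kind != "roving" && n_burn_in > 0) {
    std_type <- if (kind == "inverse_duration_deviant") 3L else 1L
    burn <- mk_events(rep(std_type, n_burn_in),
                      rep(FALSE, n_burn_in), rep(FALSE, n_burn_in))
    burn$is_burn_in <- TRUE
    ev$onset <- ev$onset + n_burn_in * period
    ev <- rbind(burn, ev)
  }
  structure(list(kind = kind, rate = rate, events = ev,
                 expected_onsets = period * seq_len(nrow(ev)),
                 short_ms = short_ms, long_ms = long_ms, seed = seed),
            class = "stimulus_protocol")
}

# Deterministic Eulerian circuit of the complete digraph on 4 vertices
# (each ordered pair appears exactly once as a consecutive transition).
eulerian_circuit_k4 <- function() {
  unused <- matrix(TRUE, 4, 4); diag(unused) <- FALSE
  path <- integer(0)
  stack <- 1L
  while (length(stack)) {
    v <- stack[length(stack)]
    nxt <- which(unused[v, ])
    if (length(nxt)) {
      u <- nxt[1]
      unused[v, u] <- FALSE
      stack <- c(stack, u)
    } else {
      path <- c(v, path)
      stack <- stack[-length(stack)]
    }
  }
  path  # 13 vertices, 12 transitions
}

#' @export
print.stimulus_protocol <- function(x, ...) {
  cat("<stimulus_protocol> ", x$kind, ", ", nrow(x$events), " events at ",
      x$rate, " Hz (", sum(x$events$is_deviant_trial), " deviant trials)\n",
      sep = "")
  invisible(x)
}

#' Phase-locked (pacemaker) input specification
#'
#' Describes rhythmic square-pulse currents delivered to a population at
#' the stimulus presentation rate. Each neuron draws a fixed phase
#' offset from `U[phase_offset - jitter_theta, phase_offset +
#' jitter_theta]` once (per seed) and then pulses strictly periodically.
#'
#' @param rate pulse rate (Hz).
#' @param phase_offset pulse onset relative to the nominal stimulus
#'   onset grid (ms); 0 for the standard-phase population, -50 for the
#'   alternative-phase population aligned with the first half of long
#'   tones.
#' @param jitter_theta half-width of the per-neuron uniform phase jitter
#'   (ms), >= 0.
#' @param pulse_width pulse duration (ms).
#' @param amplitude pulse current (nA).
#' @param seed integer seed for the per-neuron phases.
#' @return An object of class `"phase_locked_spec"`.
#' @export
phase_locked_spec <- function(rate = 2, phase_offset = 0, jitter_theta = 0,
                              pulse_width = 50, amplitude = 0.3, seed = 1) {
  stopifnot(rate > 0, jitter_theta >= 0, pulse_width > 0)
  structure(list(rate = rate, phase_offset = phase_offset,
                 jitter_theta = jitter_theta, pulse_width = pulse_width,
                 amplitude = amplitude, seed = seed),
            class = "phase_locked_spec")
}

#' Per-neuron pulse schedule of a phase-locked input
#'
#' @param spec a [phase_locked_spec()].
#' @param duration schedule horizon (ms).
#' @param n_neurons number of neurons.
#' @return A list with `t0` (per-neuron first-pulse offsets, ms) and
#'   `times` (list of per-neuron pulse onset vectors covering
#'   `[0, duration)`).
#' @export
phase_locked_pulse_times <- function(spec, duration, n_neurons) {
  stopifnot(inherits(spec, "phase_locked_spec"), duration > 0,
            n_neurons >= 1)
  period <- 1000 / spec$rate
  t0 <- spec$phase_offset +
    if (spec$jitter_theta > 0)
      with_seed(spec$seed, runif(n_neurons, -spec$jitter_theta,
                                 spec$jitter_theta))
    else rep(0, n_neurons)
  times <- lapply(t0, function(off) {
    k <- seq.int(0, ceiling(duration / period) + 1)
    tt <- off + k * period
    tt[tt > -spec$pulse_width & tt < duration]
  })
  list(t0 = t0, times = times)
}

# Expand a phase-locked spec into pulse_input objects for one population.
phase_locked_inputs <- function(spec, population, duration, n_neurons) {
  sched <- phase_locked_pulse_times(spec, duration, n_neurons)
  out <- vector("list", 0)
  for (i in seq_len(n_neurons)) {
    for (tt in sched$times[[i]]) {
      out[[length(out) + 1L]] <-
        pulse_input(population, tt, tt + spec$pulse_width, spec$amplitude,
                    neurons = i)
    }
  }
  out
}

#' Serialize / deserialize a stimulus protocol as JSON
#'
#' @param protocol a [make_stimulus_sequence()] result.
#' @param path file path.
#' @return `write_protocol` returns `path` invisibly; `read_protocol`
#'   the reconstructed protocol.
#' @export
write_protocol <- function(protocol, path) {
  jsonlite::write_json(unclass(protocol), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_protocol
#' @export
read_protocol <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$events <- as.data.frame(x$events, stringsAsFactors = FALSE)
  structure(x, class = "stimulus_protocol")
}
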