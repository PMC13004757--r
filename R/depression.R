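#' Event-driven update of the short-term depression variable
#'
#' Evolves the fraction of releasable vesicles `D` under the
#' release-fraction model of presynaptic depression: at each presynaptic
#' spike `D` drops multiplicatively, `D <- D - pv * D`, and between spikes
#' it recovers exponentially towards 1 with time constant `tau_D`, i.e.
#' `D(t) = 1 - (1 - D0) * exp(-(t - t0) / tau_D)`. The closed form between
#' events makes the update exact for any spike train; the simulation
#' engine uses the same event-driven scheme.
#'
#' @param state current value of `D`, in (0, 1].
#' @param params a [depression_params()] object.
#' @param spike_times sorted presynaptic spike times (ms), all strictly
#'   before `t_eval`. The decrement applies at (i.e. just after) each
#'   spike time.
#' @param t_eval time (ms) at which to evaluate `D`; must be at or after
#'   the reference time `t0`.
#' @param t0 time (ms) at which `state` holds; default 0.
#' @return `D(t_eval)`, a value in (0, 1].
#' @examples
#' p <- depression_params(pv = 0.5, tau_D = 200)
#' update_depression(1, p, spike_times = 0, t_eval = 200)  # 1 - 0.5 * exp(-1)
#' @export
update_depression <- function(state, params, spike_times = numeric(),
                              t_eval, t0 = 0) {
  if (!inherits(params, "depression_params"))
    params <- do.call(depression_params, as.list(params))
  if (!is.numeric(state) || length(state) != 1 || state <= 0 || state > 1)
    stop("state must be a single value in (0, 1]", call. = FALSE)
  if (t_eval < t0) stop("t_eval must be >= t0", call. = FALSE)
  if (length(spike_times)) {
    if (is.unsorted(spike_times)) stop("spike_times must be sorted", call. = FALSE)
    if (any(spike_times < t0) || any(spike_times >= t_eval))
      stop("spike_times must lie in [t0, t_eval)", call. = FALSE)
  }
  D <- state
  t <- t0
  for (ts in spike_times) {
    D <- 1 - (1 - D) * exp(-(ts - t) / params$tau_D)  # recover to spike time
    D <- D * (1 - params$pv)                          # release
    t <- ts
  }
  1 - (1 - D) * exp(-(t_eval - t) / params$tau_D)
}
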