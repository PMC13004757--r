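#' Leaky integrate-and-fire neuron parameters
#'
#' Single-compartment LIF membrane parameters. The membrane time constant
#' is `Cm / g_leak` (pF / nS = ms), which is what distinguishes the
#' delayed-activating populations (larger `Cm`, hence slower charging and
#' a response only to long tones) from the rest of the network.
#'
#' @param Cm membrane capacitance (pF), > 0.
#' @param g_leak leak conductance (nS), > 0.
#' @param E_leak leak reversal / resting potential (mV).
#' @param V_thresh spike threshold (mV).
#' @param V_reset post-spike reset potential (mV), below `V_thresh`.
#' @param t_ref absolute refractory period (ms), >= 0. The membrane is
#'   clamped at `V_reset` for this long after a spike.
#' @return An object of class `"neuron_params"`.
#' @examples
#' neuron_params(Cm = 200)
#' @export
neuron_params <- function(Cm = 200, g_leak = 10, E_leak = -70,
                          V_thresh = -50, V_reset = -65, t_ref = 3) {
  stopifnot(is.numeric(Cm), Cm > 0, is.numeric(g_leak), g_leak > 0,
            is.numeric(t_ref), t_ref >= 0)
  if (V_reset >= V_thresh)
    stop("V_reset must be below V_thresh", call. = FALSE)
  structure(list(Cm = Cm, g_leak = g_leak, E_leak = E_leak,
                 V_thresh = V_thresh, V_reset = V_reset, t_ref = t_ref),
            class = "neuron_params")
}

#' Short-term synaptic depression parameters
#'
#' Release-fraction model of presynaptic depression: the fraction of
#' releasable vesicles `D` is decremented multiplicatively by `pv * D` at
#' each presynaptic spike and recovers exponentially towards 1 with time
#' constant `tau_D` between spikes. See [update_depression()].
#'
#' @param pv release fraction per spike, in (0, 1].
#' @param tau_D recovery time constant (ms), > 0.
#' @return An object of class `"depression_params"`.
#' @export
depression_params <- function(pv = 0.5, tau_D = 1000) {
  if (!is.numeric(pv) || length(pv) != 1 || pv <= 0 || pv > 1)
    stop("pv must be a single value in (0, 1]", call. = FALSE)
  if (!is.numeric(tau_D) || length(tau_D) != 1 || tau_D <= 0)
    stop("tau_D must be a single positive value (ms)", call. = FALSE)
  structure(list(pv = pv, tau_D = tau_D), class = "depression_params")
}

#' Synaptic kinetics of one receptor component
#'
#' One receptor component of a projection. `g_max` is the per-synapse
#' conductance increment on arrival of a (delayed) presynaptic spike;
#' decay is single-exponential. All projections sharing a receptor type
#' must also share `tau_decay` and `E_rev` within one simulated network
#' (the engine aggregates per-neuron conductances per receptor channel);
#' [network_spec()] enforces this.
#'
#' @param receptor one of `"AMPA"`, `"NMDA"`, `"GABA"`.
#' @param g_max peak conductance per synapse (nS), >= 0.
#' @param E_rev reversal potential (mV); defaults to 0 for AMPA/NMDA and
#'   -80 for GABA.
#' @param tau_decay decay time constant (ms); defaults 2 (AMPA),
#'   100 (NMDA), 10 (GABA).
#' @param mg_block for NMDA only: apply the sigmoidal magnesium
#'   voltage-block factor `1 / (1 + [Mg]/3.57 * exp(-0.062 V))`.
#' @return An object of class `"synapse_kinetics"`.
#' @export
synapse_kinetics <- function(receptor = c("AMPA", "NMDA", "GABA"),
                             g_max, E_rev = NULL, tau_decay = NULL,
                             mg_block = NULL) {
  receptor <- match.arg(receptor)
  defaults <- list(AMPA = list(E_rev = 0, tau_decay = 2),
                   NMDA = list(E_rev = 0, tau_decay = 100),
                   GABA = list(E_rev = -80, tau_decay = 10))[[receptor]]
  if (is.null(E_rev)) E_rev <- defaults$E_rev
  if (is.null(tau_decay)) tau_decay <- defaults$tau_decay
  if (is.null(mg_block)) mg_block <- receptor == "NMDA"
  stopifnot(is.numeric(g_max), g_max >= 0, tau_decay > 0)
  if (receptor == "GABA" && E_rev >= -50)
    stop("GABA reversal potential must be below threshold", call. = FALSE)
  structure(list(receptor = receptor, g_max = g_max, E_rev = E_rev,
                 tau_decay = tau_decay, mg_block = mg_block),
            class = "synapse_kinetics")
}

#' Pair-based STDP parameters
#'
#' Trace-based spike-timing-dependent plasticity. A presynaptic spike adds
#' `A_plus` to the presynaptic trace and adds the (negative) postsynaptic
#' trace to the weight; a postsynaptic spike adds `A_minus` (< 0) to the
#' postsynaptic trace and adds the presynaptic trace to the weight. Both
#' traces decay with time constant `tau_A`; weights are clipped to
#' `[w_min, w_max]` after every update.
#'
#' @param A_plus presynaptic trace increment (nS), > 0.
#' @param alpha ratio defining `A_minus = alpha * A_plus`; must be < 0.
#'   Ignored when `A_minus` is given directly.
#' @param A_minus postsynaptic trace increment (nS), < 0.
#' @param tau_A trace decay time constant (ms), default 20.
#' @param w_min,w_max weight bounds (nS); default 0 to 2.4 nS (2400 pS).
#' @param w_init initial weight (nS); defaults to `A_plus`, i.e. synapses
#'   start weak enough not to affect signal propagation.
#' @return An object of class `"stdp_params"`.
#' @export
stdp_params <- function(A_plus = 0.029, alpha = -1.2, A_minus = NULL,
                        tau_A = 20, w_min = 0, w_max = 2.4,
                        w_init = NULL) {
  stopifnot(is.numeric(A_plus), A_plus > 0, tau_A > 0)
  if (is.null(A_minus)) {
    stopifnot(is.numeric(alpha), alpha < 0)
    A_minus <- alpha * A_plus
  }
  if (A_minus >= 0) stop("A_minus must be negative", call. = FALSE)
  if (is.null(w_init)) w_init <- A_plus
  if (w_min > w_init || w_init > w_max)
    stop("w_init must lie within [w_min, w_max]", call. = FALSE)
  structure(list(A_plus = A_plus, A_minus = A_minus, tau_A = tau_A,
                 w_min = w_min, w_max = w_max, w_init = w_init),
            class = "stdp_params")
}
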