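#' Create the state of a single plastic synapse
#'
#' @param params an [stdp_params()] object.
#' @param w initial weight (nS); defaults to `params$w_init`.
#' @param t time (ms) at which the state holds.
#' @return An object of class `"stdp_state"` with fields `w`, `A_pre`
#'   (>= 0), `A_post` (<= 0) and `t`.
#' @export
stdp_state <- function(params, w = params$w_init, t = 0) {
  structure(list(w = w, A_pre = 0, A_post = 0, t = t, params = params),
            class = "stdp_state")
}

#' Event-driven pair-based STDP update
#'
#' Applies one pre- or postsynaptic spike to a plastic synapse. Traces
#' first decay exponentially (`exp(-dt / tau_A)`) from the last update
#' time to the event time; then, for a presynaptic spike, the weight is
#' incremented by the (negative) postsynaptic trace and the presynaptic
#' trace jumps by `A_plus`; for a postsynaptic spike, the weight is
#' incremented by the presynaptic trace and the postsynaptic trace jumps
#' by `A_minus`. The weight is clipped to `[w_min, w_max]` after every
#' update. Events at identical timestamps must be supplied pre before
#' post (the convention used by the simulation engine).
#'
#' @param state an [stdp_state()] object.
#' @param event `"pre"` or `"post"`.
#' @param t event time (ms), not before `state$t`.
#' @return The updated `"stdp_state"`.
#' @examples
#' s <- stdp_state(stdp_params(A_plus = 0.029, alpha = -1.2), w = 1)
#' s <- stdp_update(s, "pre", 0)
#' s <- stdp_update(s, "post", 10)  # w increased by 0.029 * exp(-10/20)
#' @export
stdp_update <- function(state, event = c("pre", "post"), t) {
  event <- match.arg(event)
  p <- state$params
  if (t < state$t) stop("event time precedes synapse state time", call. = FALSE)
  decay <- exp(-(t - state$t) / p$tau_A)
  state$A_pre <- state$A_pre * decay
  state$A_post <- state$A_post * decay
  state$t <- t
  if (event == "pre") {
    state$w <- min(max(state$w + state$A_post, p$w_min), p$w_max)
    state$A_pre <- state$A_pre + p$A_plus
  } else {
    state$w <- min(max(state$w + state$A_pre, p$w_min), p$w_max)
    state$A_post <- state$A_post + p$A_minus
  }
  state
}
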