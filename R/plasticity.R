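#' Two-threshold calcium rule: weight derivative
#'
#' Implements the calcium hypothesis of synaptic plasticity as a
#' threshold-based rule: spine calcium above the potentiation threshold
#' `theta_p` drives the weight towards 1 at rate `gamma_p`, and calcium above
#' the depression threshold `theta_d` drives it towards 0 at rate `gamma_d`:
#' \deqn{dw/dt = (1-w)\gamma_p \Theta[C_s-\theta_p] - w\gamma_d \Theta[C_s-\theta_d].}
#' Since `theta_p > theta_d`, both terms are active above `theta_p` and the
#' weight then relaxes towards the fixed point `gamma_p/(gamma_p+gamma_d)`;
#' between the thresholds the weight decays exponentially at rate `gamma_d`.
#' The Heaviside function is taken strict at equality (`Theta(0) = 0`).
#'
#' @param w synaptic weight(s) in `[0, 1]`.
#' @param C_s spine calcium concentration(s) (uM).
#' @param params a `ca_parameters` carrying `theta_p`, `theta_d`, `gamma_p`,
#'   `gamma_d`.
#' @return Weight rate of change (1/s), vectorized over `w`/`C_s`.
#' @export
weight_derivative <- function(w, C_s, params) {
  if (any(w < 0 | w > 1)) stop("weights must lie in [0, 1]")
  (1 - w) * params$gamma_p * (C_s > params$theta_p) -
    w * params$gamma_d * (C_s > params$theta_d)
}

#' Explicit Euler update of the synaptic weights
#'
#' Advances the weight rule by one step of the same `dt` used for the
#' calcium solver and clamps to `[0, 1]`. Under the stability precondition
#' `dt * (gamma_p + gamma_d) < 1` the unclamped update cannot leave the unit
#' interval, so the clamp is a no-op safeguard.
#'
#' @param weights weight vector in `[0, 1]`.
#' @param C_s per-spine calcium (uM).
#' @param dt time step (s).
#' @param params a `ca_parameters`.
#' @return Updated weight vector.
#' @export
update_weights <- function(weights, C_s, dt, params) {
  if (dt * (params$gamma_p + params$gamma_d) >= 1)
    stop("configuration error: dt * (gamma_p + gamma_d) must be < 1")
  w <- weights + dt * weight_derivative(weights, C_s, params)
  pmin(1, pmax(0, w))
}
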