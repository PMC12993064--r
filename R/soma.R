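#' Somatic integrator parameters
#'
#' The soma is a single leaky integrative unit attached to the terminal
#' dendritic compartment through an axial resistance; there is no feedback
#' from the soma to the dendrite:
#' \deqn{du_{soma}/dt = (1/\tau)[(u_{rest}-u_{soma}) +
#'       R_{ratio}(u_{dend}(x_0)-u_{soma})].}
#' Defaults: resting potential -70 mV, membrane time constant
#' `tau = R_soma C_soma = 22` ms, resistance ratio
#' `R_soma/R_{s,axial} = 5`. The numeric spike threshold is a package choice
#' (a threshold line, no reset or refractory dynamics).
#'
#' @param u_rest resting potential (mV).
#' @param tau membrane time constant (s).
#' @param R_ratio `R_soma / R_{s,axial}` (dimensionless, > 0).
#' @param spike_threshold somatic firing threshold (mV).
#' @return An object of class `ca_soma_params`.
#' @export
soma_params <- function(u_rest = -70, tau = 0.022, R_ratio = 5,
                        spike_threshold = -56.9) {
  if (tau <= 0) stop("`tau` must be positive")
  if (R_ratio <= 0) stop("`R_ratio` must be positive")
  structure(list(u_rest = u_rest, tau = tau, R_ratio = R_ratio,
                 spike_threshold = spike_threshold),
            class = "ca_soma_params")
}

#' Passive dendritic cable parameters
#'
#' The dendritic voltage is a passive compartmental cable: each segment
#' leaks towards `u_rest` with membrane time constant `tau_m` (matching the
#' soma) and couples to its neighbours with an axial diffusion coefficient
#' `D_v = lambda^2 / tau_m` set by the steady-state space constant `lambda`.
#' Weight-scaled synaptic current enters at spine segments with gain
#' `c_syn` (mV/s per pA of weight-scaled current). All voltage-cable numbers
#' are package defaults tuned only to keep dynamics subthreshold and
#' sequence-selective; the calcium influx remains weight-independent.
#'
#' @param tau_m membrane time constant (s).
#' @param space_constant steady-state voltage space constant (um).
#' @param c_syn synaptic voltage gain (mV/s per pA).
#' @param u_rest resting potential (mV).
#' @return An object of class `ca_cable_params`.
#' @export
cable_params <- function(tau_m = 0.022, space_constant = 50,
                         c_syn = 2.5e7, u_rest = -70) {
  if (tau_m <= 0 || space_constant <= 0) stop("cable parameters must be positive")
  structure(list(tau_m = tau_m, space_constant = space_constant,
                 D_v = space_constant^2 / tau_m, c_syn = c_syn,
                 u_rest = u_rest),
            class = "ca_cable_params")
}

#' Dendritic/somatic voltage state
#'
#' @param u_dend per-segment membrane potential (mV).
#' @param u_soma somatic potential (mV).
#' @param t time (s).
#' @return An object of class `ca_cable_state`.
#' @export
cable_state <- function(u_dend, u_soma, t = 0) {
  if (anyNA(u_dend) || any(!is.finite(u_dend)) || !is.finite(u_soma))
    stop("voltages must be finite")
  structure(list(u_dend = as.numeric(u_dend), u_soma = u_soma, t = t),
            class = "ca_cable_state")
}

#' One backward-Euler step of the somatic integrator
#'
#' @param u_soma somatic potential (mV).
#' @param u_dend_terminal potential of the dendritic compartment attached to
#'   the soma (mV), taken at the end of the step.
#' @param dt time step (s), `dt < tau`.
#' @param params a [soma_params()].
#' @return Updated somatic potential (mV).
#' @examples
#' p <- soma_params()
#' step_soma(-70, -70, 1e-4, p)  # fixed point: stays at rest
#' @export
step_soma <- function(u_soma, u_dend_terminal, dt, params) {
  stopifnot(dt > 0, dt < params$tau)
  a <- dt / params$tau
  (u_soma + a * (params$u_rest + params$R_ratio * u_dend_terminal)) /
    (1 + a * (1 + params$R_ratio))
}

#' One backward-Euler step of the passive voltage cable
#'
#' Advances the dendritic voltage (leak towards rest, nearest-neighbour
#' axial coupling, weight-scaled synaptic current at spine segments) and
#' then the soma, which reads the terminal compartment. The soma does not
#' feed back into the cable.
#'
#' @param state a [cable_state()] matching the arrangement's geometry.
#' @param inputs per-spine synaptic current already scaled by the synaptic
#'   weight (pA), held at its step-start value.
#' @param arrangement a `ca_arrangement`.
#' @param dt time step (s).
#' @param cable a [cable_params()].
#' @param soma a [soma_params()]; the soma attaches to segment `soma_seg`.
#' @param soma_seg segment index the soma reads (default 1: left end).
#' @return Updated `ca_cable_state`.
#' @export
step_cable <- function(state, inputs, arrangement, dt,
                       cable = cable_params(), soma = soma_params(),
                       soma_seg = 1L) {
  geom <- arrangement$geometry
  n <- geom$n_segments
  if (length(state$u_dend) != n)
    stop("state length does not match the geometry")
  if (length(inputs) != n_spines(arrangement))
    stop("one input per spine required")
  lam <- cable$D_v / geom$dx^2
  nb <- c(1, rep(2, n - 2), 1)
  diag_v <- 1 + dt / cable$tau_m + dt * lam * nb
  A <- diag(diag_v)
  for (i in seq_len(n - 1)) {
    A[i, i + 1] <- -dt * lam
    A[i + 1, i] <- -dt * lam
  }
  rhs <- state$u_dend + dt * cable$u_rest / cable$tau_m
  rhs[arrangement$spine_segments] <-
    rhs[arrangement$spine_segments] + dt * cable$c_syn * inputs
  u_new <- solve(A, rhs)
  if (any(!is.finite(u_new)))
    stop("configuration error: divergent voltage")
  u_soma <- step_soma(state$u_soma, u_new[soma_seg], dt, soma)
  cable_state(u_new, u_soma, state$t + dt)
}

#' Simulate a protocol with the voltage cable and somatic readout
#'
#' Co-integrates the calcium system, the weight rule and the passive voltage
#' cable; the soma integrates the terminal dendritic compartment (segment 1,
#' the left cable end). Synaptic electrical current into the cable is scaled
#' by the spine's instantaneous weight, while calcium influx is
#' weight-independent.
#'
#' @inheritParams simulate_calcium
#' @param soma a [soma_params()].
#' @param cable a [cable_params()].
#' @return A `ca_simulation` with additional elements `u_soma` (trace) and
#'   `peak_u_soma`.
#' @export
simulate_with_soma <- function(prot, arrangement, params, T,
                               cfg = solver_config(), plasticity = TRUE,
                               soma = soma_params(), cable = cable_params()) {
  check_dt(cfg, params)
  n_sp <- n_spines(arrangement)
  spikes <- expand_protocol(prot, n_sp)
  if (protocol_duration(prot) > T)
    stop("protocol spike times must lie within [0, T]")
  geom <- arrangement$geometry
  n_steps <- as.integer(ceiling(T / cfg$dt))
  store_every <- cfg$store_every
  if (is.null(store_every)) store_every <- max(1L, ceiling(n_steps / 2000))
  ca <- core_args(arrangement, params, cfg)
  res <- ca_core(
    n_seg = geom$n_segments, dx = geom$dx, dt = cfg$dt, n_steps = n_steps,
    t0 = 0, D = params$D, tau_decay = params$tau_decay,
    spine_seg = arrangement$spine_segments - 1L,
    k_d = ca$k_d, k_s = ca$k_s, flux_scale = ca$flux_scale,
    Cd0 = rep(0, geom$n_segments), Cs0 = rep(0, n_sp),
    Isyn0 = rep(0, n_sp), spikes = spikes,
    I0 = params$I0, tau_syn = params$tau_d, jsyn_coef = ca$jsyn_coef,
    plasticity = plasticity, w0 = arrangement$initial_weights,
    theta_p = params$theta_p, theta_d = params$theta_d,
    gamma_p = params$gamma_p, gamma_d = params$gamma_d,
    voltage = TRUE, u_rest = cable$u_rest, v_tau = cable$tau_m,
    v_lambda = cable$D_v / geom$dx^2, v_csyn = cable$c_syn,
    soma_tau = soma$tau, R_ratio = soma$R_ratio, soma_seg = 0L,
    ud0 = rep(cable$u_rest, geom$n_segments), usoma0 = soma$u_rest,
    store_every = as.integer(store_every), store_field = cfg$store_field)
  structure(list(
    t = res$t, C_d = if (cfg$store_field) res$C_d else NULL,
    C_s = res$C_s, w = res$w, u_soma = res$u_soma,
    peak_u_soma = max(res$u_soma),
    final_state = calcium_state(res$final$C_d, res$final$C_s, res$final$t),
    final_weights = res$final$w,
    dw = res$final$w - arrangement$initial_weights,
    arrangement = arrangement, params = params, cfg = cfg, protocol = prot,
    soma = soma, cable = cable),
    class = c("ca_soma_simulation", "ca_simulation"))
}

#' Two proximal spines for the sequence-selectivity setup
#'
#' Builds the standard layout: an 80 um cable with the soma attached at the
#' left end and two spines 1 um apart located proximally (about 5 um from
#' the soma; positions snap to segment centres).
#'
#' @param distance inter-spine distance (um).
#' @param proximal_um position of the proximal spine (um from the soma end).
#' @param dx segment length (um).
#' @param length cable length (um).
#' @param initial_weights weights for (proximal, distal) spines.
#' @return A `ca_arrangement`; spine 1 is proximal, spine 2 distal.
#' @export
sequence_arrangement <- function(distance = 1, proximal_um = 5, dx = 0.5,
                                 length = 80, initial_weights = c(0.5, 0.5)) {
  s1 <- round(proximal_um / dx) + 1L
  s2 <- s1 + round(distance / dx)
  spine_arrangement(geometry(length, dx), c(s1, s2),
                    groups = "plain", initial_weights = initial_weights)
}

#' Input-sequence learning and selectivity at the soma
#'
#' Runs the sequence-selectivity experiment: two proximal spines receive one
#' spike each, ordered either *inward* (distal spine first, activation
#' running towards the soma) or *outward* (proximal first). During the
#' learning phase the given order is presented `learn_reps` times with
#' plasticity on; in the test phase plasticity is frozen and each order is
#' presented once, recording the peak somatic potential.
#'
#' The reported ratio is the peak somatic depolarization (peak minus rest)
#' for the learned order divided by that for the non-learned order; if both
#' depolarizations are zero the ratio is 1.
#'
#' @param order sequence presented during learning: `"inward"` or
#'   `"outward"`.
#' @param learn_reps number of learning presentations.
#' @param arrangement a two-spine arrangement from [sequence_arrangement()].
#' @param params a `ca_parameters` (plasticity preset).
#' @param delta_t inter-input interval within a sequence (s).
#' @param cfg a [solver_config()].
#' @param soma a [soma_params()].
#' @param cable a [cable_params()].
#' @param plasticity if `FALSE`, the learning phase is skipped and the test
#'   runs on the initial weights (the passive baseline).
#' @return An object of class `ca_sequence_report`: learned order, weights
#'   after learning, test peak somatic potentials for both orders, the
#'   learned/non-learned depolarization ratio, and threshold crossings.
#' @export
sequence_experiment <- function(order = c("inward", "outward"),
                                learn_reps = 5,
                                arrangement = sequence_arrangement(),
                                params = default_parameters("fig2"),
                                delta_t = 0.04,
                                cfg = solver_config(store_field = FALSE),
                                soma = soma_params(), cable = cable_params(),
                                plasticity = TRUE) {
  order <- match.arg(order)
  if (n_spines(arrangement) != 2)
    stop("sequence experiment needs a two-spine arrangement")
  seq_prot <- function(ord, reps, interval = 1) {
    # spine 1 proximal, spine 2 distal; inward = distal first (t2 < t1)
    if (ord == "inward") paired_timing(2, 1, delta_t, reps, interval)
    else paired_timing(1, 2, delta_t, reps, interval)
  }
  w_learned <- arrangement$initial_weights
  if (plasticity && learn_reps > 0) {
    learn <- simulate_with_soma(
      seq_prot(order, learn_reps), arrangement, params,
      T = (learn_reps - 1) * 1 + delta_t + 0.5,
      cfg = cfg, plasticity = TRUE, soma = soma, cable = cable)
    w_learned <- learn$final_weights
  }
  arr_test <- arrangement
  arr_test$initial_weights <- w_learned
  test_one <- function(ord) {
    simulate_with_soma(seq_prot(ord, 1), arr_test, params,
                       T = delta_t + 0.3, cfg = cfg, plasticity = FALSE,
                       soma = soma, cable = cable)
  }
  test_in <- test_one("inward")
  test_out <- test_one("outward")
  peaks <- c(inward = test_in$peak_u_soma, outward = test_out$peak_u_soma)
  dep <- peaks - soma$u_rest
  learned_dep <- dep[[order]]
  other_dep <- dep[[setdiff(c("inward", "outward"), order)]]
  ratio <- if (learned_dep == 0 && other_dep == 0) 1 else learned_dep / other_dep
  structure(list(
    learned_order = order, learn_reps = learn_reps,
    weights_after_learning = w_learned,
    test_peaks = peaks,
    ratio = ratio,
    crosses_threshold = peaks > soma$spike_threshold,
    spike_threshold = soma$spike_threshold,
    u_soma = list(inward = test_in$u_soma, outward = test_out$u_soma),
    t = test_in$t),
    class = "ca_sequence_report")
}

#' @export
print.ca_sequence_report <- function(x, ...) {
  cat(sprintf("Sequence-selectivity report (learned: %s, %d presentations)\n",
              x$learned_order, x$learn_reps))
  cat(sprintf("  weights after learning: proximal %.3f, distal %.3f\n",
              x$weights_after_learning[1], x$weights_after_learning[2]))
  cat(sprintf("  test peaks: inward %.3f mV, outward %.3f mV\n",
              x$test_peaks["inward"], x$test_peaks["outward"]))
  cat(sprintf("  learned/non-learned depolarization ratio: %.3f\n", x$ratio))
  cat(sprintf("  crosses threshold (%g mV): inward %s, outward %s\n",
              x$spike_threshold, x$crosses_threshold["inward"],
              x$crosses_threshold["outward"]))
  invisible(x)
}

#' Serialize a sequence report to JSON
#'
#' @param report a `ca_sequence_report`.
#' @param path output file.
#' @param traces if `TRUE`, include the somatic voltage traces.
#' @return `path`, invisibly.
#' @export
write_sequence_report <- function(report, path, traces = FALSE) {
  obj <- report[c("learned_order", "learn_reps", "weights_after_learning",
                  "test_peaks", "ratio", "crosses_threshold",
                  "spike_threshold")]
  obj$test_peaks <- as.list(obj$test_peaks)
  obj$crosses_threshold <- as.list(obj$crosses_threshold)
  if (traces) obj$u_soma <- report$u_soma
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
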