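#' Solver configuration
#'
#' The coupled dendrite/spine calcium system is integrated with an implicit
#' (backward Euler) scheme: diffusion, leak and both spine-neck fluxes are
#' treated implicitly, while the synaptic influx is evaluated at the start of
#' each step (semi-implicit), keeping the linear system constant over a run.
#'
#' Defaults `dx = 0.5` um and `dt = 0.05` ms resolve 1 um inter-spine
#' distances and the 1 ms synaptic current transient. `dt` must satisfy
#' `dt <= tau_d / 5` so the transient is sampled.
#'
#' @param dt time step (s).
#' @param scheme integration scheme tag; only `"backward-euler"`.
#' @param boundary boundary tag; only `"no-flux"`.
#' @param store_every output decimation in steps; `NULL` picks a value that
#'   keeps at most ~2000 stored frames.
#' @param store_field if `TRUE` (default) the full dendritic calcium field is
#'   stored at each output frame, otherwise only per-spine series.
#' @param flux_mode `"paper"` applies the spine-neck fluxes with identical
#'   magnitude (concentration units) in both compartments as the model
#'   equations are printed; `"volume-corrected"` scales the dendrite-side
#'   terms by `V_s/V_d` so that transferred moles balance across the neck.
#' @return An object of class `ca_solver_config`.
#' @export
solver_config <- function(dt = 5e-5, scheme = "backward-euler",
                          boundary = "no-flux", store_every = NULL,
                          store_field = TRUE,
                          flux_mode = c("paper", "volume-corrected")) {
  if (!is.numeric(dt) || dt <= 0) stop("`dt` must be positive")
  scheme <- match.arg(scheme, "backward-euler")
  boundary <- match.arg(boundary, "no-flux")
  flux_mode <- match.arg(flux_mode)
  structure(list(dt = dt, scheme = scheme, boundary = boundary,
                 store_every = store_every, store_field = store_field,
                 flux_mode = flux_mode),
            class = "ca_solver_config")
}

#' Synaptic current from a presynaptic spike train
#'
#' Each presynaptic spike at time `t_i` contributes an exponentially decaying
#' current `I0 * exp(-(t - t_i)/tau_d)` for `t >= t_i`.
#'
#' @param t evaluation time(s) (s); vectorized.
#' @param spike_times sorted presynaptic spike times (s).
#' @param I0 current amplitude (pA).
#' @param tau_d current decay time constant (s).
#' @return Current in pA, same length as `t`.
#' @examples
#' synaptic_current(1e-3, spike_times = 0, I0 = 0.1, tau_d = 1e-3) # I0/e
#' @export
synaptic_current <- function(t, spike_times, I0 = 0.1, tau_d = 1e-3) {
  if (length(spike_times) == 0) return(rep(0, length(t)))
  if (is.unsorted(spike_times)) stop("`spike_times` must be sorted ascending")
  vapply(t, function(tt) {
    active <- spike_times <= tt
    sum(I0 * exp(-(tt - spike_times[active]) / tau_d))
  }, numeric(1))
}

#' Calcium influx into the spine head from a synaptic current
#'
#' Converts a synaptic electrical current into a rate of change of the spine
#' calcium concentration, `J_syn = gamma * I / (z * F * V_s)`, with the unit
#' conversion (pA, um^3 to uM/s) handled by [current_to_flux_coef()].
#'
#' @param I synaptic current (pA), non-negative; vectorized.
#' @param params a `ca_parameters` object.
#' @return Influx in uM/s.
#' @examples
#' synaptic_calcium_flux(0.1, default_parameters())  # ~346 uM/s
#' @export
synaptic_calcium_flux <- function(I, params) {
  if (any(I < 0)) stop("current must be non-negative")
  current_to_flux_coef(params) * I
}

#' Instantaneous calcium state
#'
#' @param C_d per-segment dendritic calcium (uM).
#' @param C_s per-spine calcium (uM).
#' @param t time (s).
#' @return An object of class `ca_state`.
#' @export
calcium_state <- function(C_d, C_s, t = 0) {
  if (any(C_d < 0) || any(C_s < 0)) stop("concentrations must be >= 0")
  structure(list(C_d = as.numeric(C_d), C_s = as.numeric(C_s), t = t),
            class = "ca_state")
}

check_dt <- function(cfg, params) {
  if (cfg$dt > params$tau_d / 5)
    stop("`dt` must satisfy dt <= tau_d/5 to resolve the synaptic transient")
}

core_args <- function(arrangement, params, cfg) {
  geom <- arrangement$geometry
  rates <- coupling_rates(params, geom$dx)
  vol <- compartment_volumes(params, geom$dx)
  list(k_d = rates$k_d, k_s = rates$k_s,
       flux_scale = if (cfg$flux_mode == "volume-corrected")
         vol$V_s / vol$V_d else 1,
       jsyn_coef = current_to_flux_coef(params))
}

#' Advance the coupled calcium system by one implicit step
#'
#' Performs a single backward-Euler step of the dendritic diffusion/leak
#' equation coupled to the spine pools, with the given per-spine synaptic
#' currents held at their step-start values.
#'
#' @param state a [calcium_state()] matching the arrangement.
#' @param inputs per-spine synaptic current (pA) at the start of the step.
#' @param arrangement a `ca_arrangement`.
#' @param params a `ca_parameters`.
#' @param cfg a [solver_config()].
#' @return The updated `ca_state` at `t + dt`.
#' @export
step_calcium <- function(state, inputs, arrangement, params,
                         cfg = solver_config()) {
  check_dt(cfg, params)
  n_sp <- n_spines(arrangement)
  if (length(state$C_d) != arrangement$geometry$n_segments ||
      length(state$C_s) != n_sp || length(inputs) != n_sp)
    stop("state/input lengths do not match the arrangement")
  ca <- core_args(arrangement, params, cfg)
  res <- ca_core(
    n_seg = arrangement$geometry$n_segments, dx = arrangement$geometry$dx,
    dt = cfg$dt, n_steps = 1L, t0 = state$t,
    D = params$D, tau_decay = params$tau_decay,
    spine_seg = arrangement$spine_segments - 1L,
    k_d = ca$k_d, k_s = ca$k_s, flux_scale = ca$flux_scale,
    Cd0 = state$C_d, Cs0 = state$C_s, Isyn0 = as.numeric(inputs),
    spikes = rep(list(numeric(0)), n_sp),
    I0 = params$I0, tau_syn = params$tau_d, jsyn_coef = ca$jsyn_coef,
    plasticity = FALSE, w0 = rep(0.5, n_sp),
    theta_p = params$theta_p, theta_d = params$theta_d,
    gamma_p = params$gamma_p, gamma_d = params$gamma_d,
    voltage = FALSE, u_rest = -70, v_tau = 1, v_lambda = 0, v_csyn = 0,
    soma_tau = 1, R_ratio = 1, soma_seg = 0L,
    ud0 = numeric(0), usoma0 = 0,
    store_every = 1L, store_field = TRUE)
  calcium_state(res$final$C_d, res$final$C_s, res$final$t)
}

# lexicographic orientation test: TRUE if the mirrored segment set sorts
# strictly before the original one
should_flip <- function(arr) {
  seg <- arr$spine_segments
  segf <- arr$geometry$n_segments + 1L - rev(seg)
  d <- which(segf != seg)
  length(d) > 0 && segf[d[1]] < seg[d[1]]
}

#' Simulate a stimulation protocol
#'
#' Integrates the coupled dendrite/spine calcium system and (optionally) the
#' two-threshold weight dynamics over `[0, T]`, driving each spine with the
#' synaptic current of its spike train.
#'
#' To make mirror symmetry exact, the cable orientation is canonicalized
#' internally: a mirrored arrangement (with a correspondingly mirrored
#' protocol) is flipped back to the canonical orientation before stepping, so
#' simulating a reflected system returns the bitwise reflection of the
#' original result. Set `canonicalize = FALSE` to integrate in the given
#' orientation.
#'
#' @param prot a `ca_protocol`.
#' @param arrangement a `ca_arrangement`.
#' @param params a `ca_parameters`.
#' @param T total simulated time (s); must cover the protocol.
#' @param cfg a [solver_config()].
#' @param plasticity if `TRUE`, weights evolve during the simulation.
#' @param initial_state optional [calcium_state()] to start from.
#' @param canonicalize see above.
#' @return An object of class `ca_simulation` with elements `t` (output
#'   times), `C_s` and `w` (frames x spines matrices), `C_d` (frames x
#'   segments, if stored), `final_weights`, `dw` (final minus initial
#'   weights), and the inputs used.
#' @export
simulate_calcium <- function(prot, arrangement, params, T,
                             cfg = solver_config(), plasticity = TRUE,
                             initial_state = NULL, canonicalize = TRUE) {
  check_dt(cfg, params)
  n_sp <- n_spines(arrangement)
  spikes <- expand_protocol(prot, n_sp)
  if (protocol_duration(prot) > T)
    stop("protocol spike times must lie within [0, T]")

  flip <- canonicalize && should_flip(arrangement)
  arr_run <- arrangement
  spikes_run <- spikes
  if (flip) {
    map <- rev(seq_len(n_sp))  # sorted-by-segment order reverses under mirror
    arr_run <- mirror_arrangement(arrangement)
    spikes_run <- spikes[map]
  }

  n_steps <- as.integer(ceiling(T / cfg$dt))
  store_every <- cfg$store_every
  if (is.null(store_every)) store_every <- max(1L, ceiling(n_steps / 2000))
  if (is.null(initial_state)) {
    initial_state <- calcium_state(
      rep(0, arrangement$geometry$n_segments), rep(0, n_sp))
  }
  st <- initial_state
  if (flip) st <- calcium_state(rev(st$C_d), st$C_s[rev(seq_len(n_sp))], st$t)

  ca <- core_args(arr_run, params, cfg)
  res <- ca_core(
    n_seg = arr_run$geometry$n_segments, dx = arr_run$geometry$dx,
    dt = cfg$dt, n_steps = n_steps, t0 = st$t,
    D = params$D, tau_decay = params$tau_decay,
    spine_seg = arr_run$spine_segments - 1L,
    k_d = ca$k_d, k_s = ca$k_s, flux_scale = ca$flux_scale,
    Cd0 = st$C_d, Cs0 = st$C_s, Isyn0 = rep(0, n_sp),
    spikes = spikes_run,
    I0 = params$I0, tau_syn = params$tau_d, jsyn_coef = ca$jsyn_coef,
    plasticity = plasticity, w0 = arr_run$initial_weights,
    theta_p = params$theta_p, theta_d = params$theta_d,
    gamma_p = params$gamma_p, gamma_d = params$gamma_d,
    voltage = FALSE, u_rest = -70, v_tau = 1, v_lambda = 0, v_csyn = 0,
    soma_tau = 1, R_ratio = 1, soma_seg = 0L,
    ud0 = numeric(0), usoma0 = 0,
    store_every = as.integer(store_every), store_field = cfg$store_field)

  C_s <- res$C_s; w <- res$w
  C_d <- if (cfg$store_field) res$C_d else NULL
  final_w <- res$final$w
  final_Cd <- res$final$C_d
  final_Cs <- res$final$C_s
  if (flip) {
    map <- rev(seq_len(n_sp))
    C_s <- C_s[, map, drop = FALSE]
    w <- w[, map, drop = FALSE]
    final_w <- final_w[map]
    final_Cs <- final_Cs[map]
    final_Cd <- rev(final_Cd)
    if (!is.null(C_d)) C_d <- C_d[, rev(seq_len(ncol(C_d))), drop = FALSE]
  }
  structure(list(
    t = res$t, C_d = C_d, C_s = C_s, w = w,
    final_state = calcium_state(final_Cd, final_Cs, res$final$t),
    final_weights = final_w,
    dw = final_w - arrangement$initial_weights,
    arrangement = arrangement, params = params, cfg = cfg, protocol = prot),
    class = "ca_simulation")
}

#' @export
print.ca_simulation <- function(x, ...) {
  cat(sprintf("Calcium simulation: %d frames, %d spines, t in [%g, %g] s\n",
              length(x$t), ncol(x$C_s), x$t[1], x$t[length(x$t)]))
  cat("  final weight change per spine:\n")
  print(round(setNames(x$dw, x$arrangement$groups), 4))
  invisible(x)
}

#' Export a simulation as tidy long-format CSV
#'
#' Writes rows `time, compartment, variable, value` where `compartment` is
#' `seg<i>` for dendritic segments and `spine<j>` for spines, and `variable`
#' is one of `C_d`, `C_s`, `w`.
#'
#' @param sim a `ca_simulation`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_simulation_csv <- function(sim, path) {
  n_sp <- ncol(sim$C_s)
  blocks <- list(
    data.frame(time = rep(sim$t, n_sp),
               compartment = rep(paste0("spine", seq_len(n_sp)),
                                 each = length(sim$t)),
               variable = "C_s", value = as.vector(sim$C_s)),
    data.frame(time = rep(sim$t, n_sp),
               compartment = rep(paste0("spine", seq_len(n_sp)),
                                 each = length(sim$t)),
               variable = "w", value = as.vector(sim$w)))
  if (!is.null(sim$C_d)) {
    n_seg <- ncol(sim$C_d)
    blocks <- c(blocks, list(
      data.frame(time = rep(sim$t, n_seg),
                 compartment = rep(paste0("seg", seq_len(n_seg)),
                                   each = length(sim$t)),
                 variable = "C_d", value = as.vector(sim$C_d))))
  }
  write.csv(do.call(rbind, blocks), path, row.names = FALSE)
  invisible(path)
}
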