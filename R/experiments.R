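#' Two spines centred on the cable
#'
#' Helper layout for the two-spine protocols: spines a given distance apart,
#' centred on an 80 um cable.
#'
#' @param distance inter-spine distance (um); must be a multiple of `dx`.
#' @param length cable length (um).
#' @param dx segment length (um).
#' @param initial_weights weights for the two spines.
#' @return A `ca_arrangement`; spine 1 is the left spine.
#' @export
two_spine_arrangement <- function(distance = 1, length = 80, dx = 0.5,
                                  initial_weights = c(0.5, 0.5)) {
  geom <- geometry(length, dx)
  k <- round(distance / dx)
  if (k < 1) stop("`distance` must be at least one segment")
  s1 <- as.integer(floor((geom$n_segments - k) / 2)) + 1L
  spine_arrangement(geom, c(s1, s1 + k), groups = "plain",
                    initial_weights = initial_weights)
}

#' Input-timing plasticity window of a two-spine system
#'
#' For each inter-input time difference on the grid, runs a fresh simulation
#' of the two-spine system (paired or triplet stimulation, 5 presentations)
#' and records the final weight change of both spines.
#'
#' @param delta_t_grid time differences (s), within +/-100 ms, sorted.
#' @param protocol_kind `"paired"` (one spike per spine) or `"triplet"` (two
#'   spikes at spine 1, one at spine 2).
#' @param params a `ca_parameters`.
#' @param distance inter-spine distance (um).
#' @param inter_input interval between the two spine-1 spikes for the
#'   triplet protocol (s).
#' @param repetitions protocol presentations.
#' @param cfg a [solver_config()].
#' @param initial_weights starting weights.
#' @return An object of class `ca_timing_curve`: `delta_t` (s), `dw`
#'   (grid x 2 matrix of final weight changes), and the inputs used.
#' @export
timing_sweep <- function(delta_t_grid, protocol_kind = c("paired", "triplet"),
                         params = default_parameters("fig4-grid"), distance = 1,
                         inter_input = 0.02, repetitions = 5,
                         cfg = solver_config(store_field = FALSE),
                         initial_weights = c(0.5, 0.5)) {
  protocol_kind <- match.arg(protocol_kind)
  if (any(abs(delta_t_grid) > 0.1 + 1e-12))
    stop("`delta_t_grid` must lie within +/-100 ms")
  if (is.unsorted(delta_t_grid)) stop("`delta_t_grid` must be sorted")
  arr <- two_spine_arrangement(distance, initial_weights = initial_weights)
  dw <- matrix(NA_real_, length(delta_t_grid), 2,
               dimnames = list(NULL, c("spine1", "spine2")))
  for (i in seq_along(delta_t_grid)) {
    dt_i <- delta_t_grid[i]
    prot <- if (protocol_kind == "paired")
      paired_timing(1, 2, dt_i, repetitions)
    else triplet(1, 2, dt_i, inter_input, repetitions)
    T_end <- protocol_duration(prot) + 0.5
    sim <- simulate_calcium(prot, arr, params, T = T_end, cfg = cfg)
    dw[i, ] <- sim$dw
  }
  structure(list(delta_t = delta_t_grid, dw = dw,
                 protocol_kind = protocol_kind, distance = distance,
                 inter_input = inter_input, params = params),
            class = "ca_timing_curve")
}

#' @export
print.ca_timing_curve <- function(x, ...) {
  cat(sprintf("Timing window (%s protocol, %g um spacing): %d time differences\n",
              x$protocol_kind, x$distance, length(x$delta_t)))
  cat(sprintf("  spine 1 pattern: %s; spine 2 pattern: %s\n",
              classify_window(x)[1], classify_window(x)[2]))
  invisible(x)
}

# run-length classification of a weight-change curve into an ordered
# potentiation/depression pattern
classify_dw <- function(dw, epsilon) {
  s <- ifelse(dw > epsilon, "P", ifelse(dw < -epsilon, "D", "0"))
  runs <- rle(s)$values
  runs <- runs[runs != "0"]
  if (length(runs) == 0) return("none")
  paste(runs, collapse = "")
}

#' Classify a timing window into an ordered P/D pattern
#'
#' Thresholds the weight-change curve at `+/-epsilon` into potentiation (P),
#' depression (D) or no change, compresses consecutive runs, drops the
#' no-change runs and returns the ordered letter string (e.g. `"DPD"`). A
#' curve with no significant change anywhere classifies as `"none"`.
#'
#' @param curve a `ca_timing_curve`, or a numeric vector of weight changes
#'   ordered along the time-difference grid.
#' @param epsilon no-change dead band on the weight change (> 0).
#' @return Character pattern per spine (for a curve) or a single string (for
#'   a vector).
#' @export
classify_window <- function(curve, epsilon = 0.01) {
  if (epsilon <= 0) stop("`epsilon` must be positive")
  if (is.numeric(curve)) return(classify_dw(curve, epsilon))
  apply(curve$dw, 2, classify_dw, epsilon = epsilon)
}

#' Heterosynaptic magnitude of a timing window
#'
#' Measures how strongly the neighbouring spine shapes the outcome at a
#' spine: the maximum absolute deviation of its weight-change curve from the
#' isolated outcome (the same single-input stimulation of that spine alone).
#'
#' @param curve a `ca_timing_curve`.
#' @param spine which spine's curve to evaluate (1 or 2).
#' @param isolated_dw optional precomputed isolated weight change; computed
#'   from a single-spine simulation when missing.
#' @param cfg a [solver_config()] for the isolated run.
#' @return Maximum absolute deviation from the isolated weight change.
#' @export
heterosynaptic_magnitude <- function(curve, spine = 1, isolated_dw = NULL,
                                     cfg = solver_config(store_field = FALSE)) {
  if (is.null(isolated_dw)) {
    arr <- two_spine_arrangement(curve$distance)
    prot <- if (curve$protocol_kind == "triplet" && spine == 1)
      burst(spine, n_spikes = 2, isi = curve$inter_input)
    else single_spike(spine)
    sim <- simulate_calcium(prot, arr, curve$params,
                            T = protocol_duration(prot) + 0.5, cfg = cfg)
    isolated_dw <- sim$dw[spine]
  }
  max(abs(curve$dw[, spine] - isolated_dw))
}

#' Group-level outcome of the multi-spine frequency experiment
#'
#' For each of `n_configs` random spine arrangements, applies a synchronous
#' frequency protocol to the stimulated (`Stim`) spines and aggregates the
#' final weight changes by group. Per-configuration seeds are derived from
#' the master seed by a counter (`seed + 1, seed + 2, ...`), so increasing
#' `n_configs` extends, and never changes, earlier configurations.
#'
#' @param frequency a preset name (`"low"`, `"medium"`, `"high"`; see
#'   [frequency_presets()]) or a numeric rate in Hz.
#' @param D diffusion coefficient (um^2/s) overriding `params$D`.
#' @param n_configs number of random arrangements.
#' @param seed master seed.
#' @param params a `ca_parameters` (multi-spine preset by default).
#' @param n_pulses pulses per spine in the frequency protocol; `NULL` uses
#'   the preset's train length (15 for a numeric rate).
#' @param config an [arrangement_config()].
#' @param cfg a [solver_config()].
#' @return An object of class `ca_group_outcome`: matrix `per_config`
#'   (configs x groups) of per-configuration group means of the weight
#'   change, plus group `mean` and `sd` across configurations.
#' @export
multi_spine_experiment <- function(frequency, D = NULL, n_configs = 20,
                                   seed = 1,
                                   params = default_parameters("fig3"),
                                   n_pulses = NULL,
                                   config = arrangement_config(),
                                   cfg = solver_config(store_field = FALSE)) {
  if (is.character(frequency)) {
    fp <- frequency_presets()
    if (!frequency %in% names(fp)) stop("unknown frequency preset: ", frequency)
    rate <- fp[[frequency]]$rate
    if (is.null(n_pulses)) n_pulses <- fp[[frequency]]$n_pulses
  } else {
    rate <- as.numeric(frequency)
    if (is.null(n_pulses)) n_pulses <- 15
  }
  if (!is.null(D)) params$D <- D
  if (n_configs < 1) stop("`n_configs` must be >= 1")
  groups <- c("Stim", "Un_in", "Un_out")
  per_config <- matrix(NA_real_, n_configs, length(groups),
                       dimnames = list(NULL, groups))
  for (i in seq_len(n_configs)) {
    arr <- generate_arrangement(seed + i, config)
    stim_ids <- which(arr$groups == "Stim")
    prot <- frequency_protocol(stim_ids, rate, n_pulses)
    T_end <- protocol_duration(prot) + 0.5
    sim <- simulate_calcium(prot, arr, params, T = T_end, cfg = cfg)
    for (g in groups)
      per_config[i, g] <- mean(sim$dw[arr$groups == g])
  }
  structure(list(per_config = per_config,
                 mean = colMeans(per_config),
                 sd = apply(per_config, 2, stats::sd),
                 n_configs = n_configs, frequency = frequency, rate = rate,
                 D = params$D, seed = seed),
            class = "ca_group_outcome")
}

#' @export
print.ca_group_outcome <- function(x, ...) {
  cat(sprintf("Multi-spine outcome: %s stimulation (%g Hz), D = %g um^2/s, %d configurations\n",
              if (is.character(x$frequency)) x$frequency else "custom",
              x$rate, x$D, x$n_configs))
  m <- rbind(mean = x$mean, sd = x$sd)
  print(round(m, 4))
  invisible(x)
}

#' Expected qualitative sign patterns per frequency regime
#'
#' The experimental plasticity patterns the multi-spine simulations are
#' matched against, encoded as weight-change signs per group: low-frequency
#' stimulation depresses stimulated spines and leaves the others unchanged;
#' medium-frequency potentiates stimulated spines and depresses unstimulated
#' neighbours inside the cluster; high-frequency potentiates both in-cluster
#' groups while the outer spines shrink.
#'
#' @return Named list (per frequency) of named sign vectors in
#'   `{"+", "-", "0"}`.
#' @export
expected_sign_patterns <- function() {
  list(low = c(Stim = "-", Un_in = "0", Un_out = "0"),
       medium = c(Stim = "+", Un_in = "-", Un_out = "0"),
       high = c(Stim = "+", Un_in = "+", Un_out = "-"))
}

dw_sign <- function(x, dead_band) {
  ifelse(x > dead_band, "+", ifelse(x < -dead_band, "-", "0"))
}

#' Matching error against expected sign patterns
#'
#' Counts, over every (configuration x frequency x group) instance, whether
#' the sign of the per-configuration group-mean weight change (with a
#' no-change dead band) matches the expected sign, and returns the mismatch
#' fraction in `[0, 1]`.
#'
#' @param outcomes named list of `ca_group_outcome` objects, one per
#'   frequency; names must match `expected_signs`.
#' @param expected_signs named list of sign vectors, as from
#'   [expected_sign_patterns()].
#' @param dead_band absolute weight change below which an outcome counts as
#'   "no change".
#' @return List with `error` (mismatch fraction), `per_config` (error per
#'   configuration across frequencies and groups) and `n_instances`.
#' @export
matching_error <- function(outcomes, expected_signs = expected_sign_patterns(),
                           dead_band = 0.01) {
  freqs <- names(outcomes)
  if (is.null(freqs) || !all(freqs %in% names(expected_signs)))
    stop("`outcomes` and `expected_signs` must cover the same frequencies")
  n_cfg <- unique(vapply(outcomes, function(o) o$n_configs, numeric(1)))
  if (length(n_cfg) != 1)
    stop("all outcomes must use the same number of configurations")
  mism <- matrix(0, n_cfg, length(freqs))
  n_group <- 0
  for (k in seq_along(freqs)) {
    o <- outcomes[[freqs[k]]]
    exp_sig <- expected_signs[[freqs[k]]]
    groups <- names(exp_sig)
    if (!all(groups %in% colnames(o$per_config)))
      stop("outcome for \"", freqs[k], "\" lacks group(s): ",
           paste(setdiff(groups, colnames(o$per_config)), collapse = ", "))
    n_group <- length(groups)
    got <- dw_sign(o$per_config[, groups, drop = FALSE], dead_band)
    mism[, k] <- rowSums(got != matrix(exp_sig, n_cfg, n_group, byrow = TRUE))
  }
  per_config <- rowSums(mism) / (length(freqs) * n_group)
  list(error = mean(per_config), per_config = per_config,
       n_instances = n_cfg * length(freqs) * n_group)
}

#' Matching error across diffusion constants
#'
#' Repeats the full multi-spine frequency experiment for each diffusion
#' constant and reports the matching error against the expected sign
#' patterns, with its standard deviation across configurations. The same
#' per-configuration seeds are reused for every `D`, so rows differ only in
#' the diffusion constant.
#'
#' @param D_list diffusion coefficients (um^2/s).
#' @param frequencies frequency preset names to include.
#' @param n_configs configurations per (D, frequency) cell.
#' @param seed master seed.
#' @param params,n_pulses,config,cfg passed to [multi_spine_experiment()].
#' @param dead_band passed to [matching_error()].
#' @return A `data.frame` with columns `D`, `error`, `sd` (across
#'   configurations) and `n_configs`, one row per diffusion constant, plus
#'   attribute `outcomes` holding the per-D outcome lists.
#' @export
diffusion_sweep <- function(D_list,
                            frequencies = c("low", "medium", "high"),
                            n_configs = 20, seed = 1,
                            params = default_parameters("fig3"),
                            n_pulses = NULL, config = arrangement_config(),
                            cfg = solver_config(store_field = FALSE),
                            dead_band = 0.01) {
  if (length(D_list) == 0) stop("`D_list` must be non-empty")
  rows <- vector("list", length(D_list))
  all_outcomes <- vector("list", length(D_list))
  for (d in seq_along(D_list)) {
    outcomes <- lapply(setNames(frequencies, frequencies), function(f)
      multi_spine_experiment(f, D = D_list[d], n_configs = n_configs,
                             seed = seed, params = params,
                             n_pulses = n_pulses, config = config, cfg = cfg))
    err <- matching_error(outcomes, dead_band = dead_band)
    rows[[d]] <- data.frame(D = D_list[d], error = err$error,
                            sd = stats::sd(err$per_config),
                            n_configs = n_configs)
    all_outcomes[[d]] <- outcomes
  }
  out <- do.call(rbind, rows)
  attr(out, "outcomes") <- setNames(all_outcomes, as.character(D_list))
  out
}
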