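#' Run configuration for the command-line drivers
#'
#' A run configuration bundles everything needed to reproduce a run: the
#' plasticity preset (or explicit parameter overrides), solver settings, an
#' arrangement (a JSON file, generator constraints, or a two-spine layout),
#' a protocol (a JSON file or a named generator with parameters), the master
#' seed and the output directory. The resolved configuration is written
#' alongside every run's outputs.
#'
#' @param config a named list or a path to a YAML/JSON file.
#' @return A validated list of class `ca_run_config`.
#' @export
run_config <- function(config = list()) {
  if (is.character(config)) {
    path <- config
    if (!file.exists(path)) stop("config file not found: ", path)
    config <- if (grepl("\\.json$", path, ignore.case = TRUE))
      jsonlite::read_json(path, simplifyVector = TRUE)
    else yaml::read_yaml(path)
  }
  defaults <- list(preset = "fig2", seed = 1L, out = "calplast-run",
                   solver = list(), parameters = list(),
                   arrangement = list(two_spine = list(distance = 1)),
                   protocol = list(kind = "single_spike", spine = 1),
                   duration = NULL, verbosity = 1L)
  cfg <- modifyList(defaults, config)
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "ca_run_config")
}

resolve_params <- function(cfg) {
  do.call(default_parameters, c(list(preset = cfg$preset), cfg$parameters))
}

resolve_solver <- function(cfg) do.call(solver_config, cfg$solver)

resolve_arrangement <- function(cfg) {
  a <- cfg$arrangement
  if (!is.null(a$file)) return(read_arrangement(a$file))
  if (!is.null(a$two_spine))
    return(do.call(two_spine_arrangement, as.list(a$two_spine)))
  gen <- a[setdiff(names(a), "generate")]
  generate_arrangement(cfg$seed, do.call(arrangement_config, gen))
}

resolve_protocol <- function(cfg, arrangement = NULL) {
  p <- cfg$protocol
  if (!is.null(p$file)) {
    if (!file.exists(p$file)) stop("protocol file not found: ", p$file)
    return(read_protocol(p$file))
  }
  kind <- p$kind
  args <- p[setdiff(names(p), "kind")]
  if (identical(kind, "frequency") && is.null(args$spines) &&
      !is.null(arrangement))
    args$spines <- which(arrangement$groups == "Stim")
  fn <- switch(kind,
               single_spike = single_spike, burst = burst,
               paired = paired_timing, triplet = triplet,
               frequency = frequency_protocol,
               stop("unknown protocol kind: ", kind))
  do.call(fn, args)
}

write_resolved <- function(cfg, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(unclass(cfg), file.path(out_dir, "resolved_config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
}

#' Command drivers: run an experiment from a configuration
#'
#' Each driver resolves the configuration, runs the corresponding package
#' function, and writes its outputs (tidy CSV time series / result tables, a
#' JSON summary and the resolved configuration) into the configured output
#' directory. These are the functions behind the `inst/cli/calplast.R`
#' command-line script.
#'
#' @param config a [run_config()], a named list, or a YAML/JSON file path.
#' @return Invisibly, a named list of written file paths.
#' @name cmd_drivers
NULL

#' @rdname cmd_drivers
#' @export
cmd_simulate <- function(config) {
  cfg <- run_config(if (inherits(config, "ca_run_config")) unclass(config)
                    else config)
  params <- resolve_params(cfg)
  scfg <- resolve_solver(cfg)
  arr <- resolve_arrangement(cfg)
  prot <- resolve_protocol(cfg, arr)
  T_end <- if (is.null(cfg$duration)) protocol_duration(prot) + 0.5
           else cfg$duration
  sim <- simulate_calcium(prot, arr, params, T = T_end, cfg = scfg)
  write_resolved(cfg, cfg$out)
  ts_file <- file.path(cfg$out, "timeseries.csv")
  write_simulation_csv(sim, ts_file)
  summary_file <- file.path(cfg$out, "summary.json")
  jsonlite::write_json(
    list(preset = cfg$preset, seed = cfg$seed, dt = scfg$dt,
         dx = arr$geometry$dx, duration = T_end,
         groups = arr$groups, final_weights = sim$final_weights,
         dw = sim$dw),
    summary_file, auto_unbox = TRUE, digits = NA)
  if (cfg$verbosity > 0)
    message(sprintf("simulate: preset=%s seed=%d dt=%g dx=%g -> %s",
                    cfg$preset, cfg$seed, scfg$dt, arr$geometry$dx, cfg$out))
  invisible(list(timeseries = ts_file, summary = summary_file))
}

#' @rdname cmd_drivers
#' @export
cmd_timing_sweep <- function(config) {
  cfg <- run_config(if (inherits(config, "ca_run_config")) unclass(config)
                    else config)
  tw <- modifyList(list(grid_ms = seq(-100, 100, by = 10), kind = "paired",
                        distance = 1, inter_input = 0.02),
                   if (is.null(cfg$timing)) list() else cfg$timing)
  curve <- timing_sweep(sort(tw$grid_ms) / 1e3, protocol_kind = tw$kind,
                        params = resolve_params(cfg),
                        distance = tw$distance,
                        inter_input = tw$inter_input,
                        cfg = resolve_solver(cfg))
  write_resolved(cfg, cfg$out)
  curve_file <- file.path(cfg$out, "timing_curve.csv")
  write.csv(data.frame(delta_t_ms = rep(curve$delta_t * 1e3, 2),
                       spine = rep(c(1L, 2L), each = length(curve$delta_t)),
                       dw = c(curve$dw[, 1], curve$dw[, 2])),
            curve_file, row.names = FALSE)
  summary_file <- file.path(cfg$out, "summary.json")
  jsonlite::write_json(
    list(pattern = as.list(classify_window(curve)),
         distance = tw$distance, kind = tw$kind),
    summary_file, auto_unbox = TRUE, digits = NA)
  invisible(list(curve = curve_file, summary = summary_file))
}

#' @rdname cmd_drivers
#' @export
cmd_multi_spine <- function(config) {
  cfg <- run_config(if (inherits(config, "ca_run_config")) unclass(config)
                    else config)
  ms <- modifyList(list(frequency = "high", D = NULL, n_configs = 5,
                        n_pulses = NULL),
                   if (is.null(cfg$multi_spine)) list() else cfg$multi_spine)
  if (is.null(cfg$preset) || identical(cfg$preset, "fig2"))
    cfg$preset <- "fig3"
  out <- multi_spine_experiment(ms$frequency, D = ms$D,
                                n_configs = ms$n_configs, seed = cfg$seed,
                                params = resolve_params(cfg),
                                n_pulses = ms$n_pulses,
                                cfg = resolve_solver(cfg))
  write_resolved(cfg, cfg$out)
  table_file <- file.path(cfg$out, "group_outcomes.csv")
  write.csv(data.frame(config = seq_len(out$n_configs), out$per_config),
            table_file, row.names = FALSE)
  summary_file <- file.path(cfg$out, "summary.json")
  jsonlite::write_json(
    list(frequency = ms$frequency, rate_hz = out$rate, D = out$D,
         n_configs = out$n_configs, mean = as.list(out$mean),
         sd = as.list(out$sd)),
    summary_file, auto_unbox = TRUE, digits = NA)
  invisible(list(table = table_file, summary = summary_file))
}

#' @rdname cmd_drivers
#' @export
cmd_diffusion_sweep <- function(config) {
  cfg <- run_config(if (inherits(config, "ca_run_config")) unclass(config)
                    else config)
  ds <- modifyList(list(D_list = c(1, 220, 440), n_configs = 5,
                        n_pulses = NULL,
                        frequencies = c("low", "medium", "high")),
                   if (is.null(cfg$diffusion)) list() else cfg$diffusion)
  if (is.null(cfg$preset) || identical(cfg$preset, "fig2"))
    cfg$preset <- "fig3"
  tab <- diffusion_sweep(ds$D_list, frequencies = ds$frequencies,
                         n_configs = ds$n_configs, seed = cfg$seed,
                         params = resolve_params(cfg),
                         n_pulses = ds$n_pulses, cfg = resolve_solver(cfg))
  write_resolved(cfg, cfg$out)
  table_file <- file.path(cfg$out, "matching_error.csv")
  write.csv(tab, table_file, row.names = FALSE)
  summary_file <- file.path(cfg$out, "summary.json")
  jsonlite::write_json(
    list(D = tab$D, error = tab$error, sd = tab$sd,
         n_configs = ds$n_configs),
    summary_file, digits = NA)
  invisible(list(table = table_file, summary = summary_file))
}

#' @rdname cmd_drivers
#' @export
cmd_sequence <- function(config) {
  cfg <- run_config(if (inherits(config, "ca_run_config")) unclass(config)
                    else config)
  sq <- modifyList(list(order = "inward", learn_reps = 5, delta_t = 0.015),
                   if (is.null(cfg$sequence)) list() else cfg$sequence)
  report <- sequence_experiment(order = sq$order, learn_reps = sq$learn_reps,
                                params = resolve_params(cfg),
                                delta_t = sq$delta_t,
                                cfg = resolve_solver(cfg))
  write_resolved(cfg, cfg$out)
  report_file <- file.path(cfg$out, "sequence_report.json")
  write_sequence_report(report, report_file)
  invisible(list(report = report_file))
}
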