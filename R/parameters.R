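#' Construct a validated set of model parameters
#'
#' Collects the physical constants of the calcium model (diffusion, geometry,
#' synaptic influx) together with the two-threshold plasticity parameters into
#' a single validated object. All internal units are seconds, micrometres and
#' micromolar; currents are in pA.
#'
#' @param D diffusion coefficient of free calcium (um^2/s).
#' @param tau_decay time constant of calcium leakage/buffering loss (s).
#' @param l_n spine neck length (um).
#' @param a_s spine neck radius (um).
#' @param r_s spine head radius (um).
#' @param r_d dendrite radius (um).
#' @param gamma fraction of the synaptic electrical current carried as
#'   calcium current (dimensionless, in (0, 1]).
#' @param z calcium valence (dimensionless).
#' @param F Faraday constant (C/mol).
#' @param I0 synaptic current amplitude per presynaptic spike (pA).
#' @param tau_d synaptic current decay time constant (s).
#' @param theta_p,theta_d calcium thresholds for potentiation and depression
#'   (uM); must satisfy `0 < theta_d < theta_p`.
#' @param gamma_p,gamma_d potentiation and depression rate constants (1/s).
#' @param preset optional name recorded for provenance.
#' @return An object of class `ca_parameters` (a named list).
#' @seealso [default_parameters()] for the standard parameter set.
#' @export
model_parameters <- function(D = 220, tau_decay = 0.08, l_n = 0.5, a_s = 0.1,
                             r_s = 0.34, r_d = 1, gamma = 0.11, z = 2,
                             F = 96485, I0 = 0.1, tau_d = 1e-3,
                             theta_p = 4e-3, theta_d = 2e-3,
                             gamma_p = 1, gamma_d = 0.3, preset = NULL) {
  p <- list(D = D, tau_decay = tau_decay, l_n = l_n, a_s = a_s, r_s = r_s,
            r_d = r_d, gamma = gamma, z = z, F = F, I0 = I0, tau_d = tau_d,
            theta_p = theta_p, theta_d = theta_d,
            gamma_p = gamma_p, gamma_d = gamma_d,
            preset = if (is.null(preset)) NA_character_ else preset)
  validate_parameters(p)
  structure(p, class = "ca_parameters")
}

validate_parameters <- function(p) {
  num <- c("tau_decay", "l_n", "a_s", "r_s", "r_d", "z", "F", "I0", "tau_d",
           "gamma_p", "gamma_d")
  for (nm in num) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1 || is.na(p[[nm]]) ||
        p[[nm]] < 0)
      stop("invalid parameter: `", nm, "` must be a non-negative number",
           call. = FALSE)
  }
  for (nm in c("tau_decay", "l_n", "a_s", "r_s", "r_d", "z", "F", "tau_d"))
    if (p[[nm]] <= 0)
      stop("invalid parameter: `", nm, "` must be strictly positive",
           call. = FALSE)
  if (!is.numeric(p$D) || length(p$D) != 1 || is.na(p$D) || p$D < 0)
    stop("invalid parameter: `D` must be a non-negative number", call. = FALSE)
  if (p$gamma <= 0 || p$gamma > 1)
    stop("invalid parameter: `gamma` must lie in (0, 1]", call. = FALSE)
  if (!(p$theta_d > 0 && p$theta_p > p$theta_d))
    stop("invalid parameter: thresholds must satisfy 0 < theta_d < theta_p",
         call. = FALSE)
  invisible(TRUE)
}

#' Default model parameters with a named plasticity preset
#'
#' Returns the standard parameter set: physiological calcium diffusion
#' constant `D = 220` um^2/s, leak time constant 0.08 s, a 0.5 um x 0.1 um
#' spine neck, 0.34 um spine head on a 1 um-radius dendrite, 11% of the
#' synaptic current carried as calcium, and a 0.1 pA / 1 ms exponential
#' synaptic current.
#'
#' The plasticity thresholds and rate constants come from a named preset:
#' \describe{
#'   \item{`"fig2"`}{`theta_d = 2e-3`, `theta_p = 4e-3` uM -- deliberately low
#'     thresholds that make subtle timing-dependent heterosynaptic changes
#'     visible in a two-spine system. Rates are calibrated, not measured.}
#'   \item{`"fig3"`}{higher, calibrated thresholds used for the multi-spine
#'     frequency-regime experiments. The whole preset is calibrated so that
#'     low/medium/high-frequency stimulation of a spine cluster reproduces the
#'     qualitative sign patterns reported across uncaging experiments.}
#'   \item{`"fig4-grid"`}{the two-spine thresholds of `"fig2"` with
#'     intermediate rate constants, a convenient starting point for sweeping
#'     `gamma_p`/`gamma_d` over timing-window grids.}
#' }
#' Preset values are stored in `inst/extdata/presets.yaml`; rate constants are
#' calibrated quantities (they are not experimentally constrained) and are
#' documented as such.
#'
#' @param preset one of `"fig2"`, `"fig3"`, `"fig4-grid"`.
#' @param ... overrides passed on to [model_parameters()].
#' @return A `ca_parameters` object.
#' @examples
#' p <- default_parameters()
#' p$D          # 220 um^2/s
#' p$theta_d    # 2e-3 uM under the "fig2" preset
#' @export
default_parameters <- function(preset = c("fig2", "fig3", "fig4-grid"), ...) {
  preset <- match.arg(preset)
  ps <- plasticity_presets()[[preset]]
  args <- modifyList(c(ps, list(preset = preset)), list(...))
  do.call(model_parameters, args)
}

#' Plasticity presets shipped with the package
#'
#' Reads the preset table (thresholds in uM, rates in 1/s) from the packaged
#' YAML file. Rate constants and the `"fig3"` thresholds are calibrated
#' values.
#'
#' @param file optional path to an alternative preset YAML file.
#' @return Named list of preset parameter lists.
#' @export
plasticity_presets <- function(file = NULL) {
  if (is.null(file))
    file <- system.file("extdata", "presets.yaml", package = "calplast",
                        mustWork = TRUE)
  yaml::read_yaml(file)
}

#' @export
print.ca_parameters <- function(x, ...) {
  cat("Calcium/plasticity model parameters",
      if (!is.na(x$preset)) sprintf("(preset \"%s\")", x$preset), "\n")
  cat(sprintf("  D = %g um^2/s, tau_decay = %g s\n", x$D, x$tau_decay))
  cat(sprintf("  spine: r_s = %g um, neck %g x %g um; dendrite r_d = %g um\n",
              x$r_s, x$l_n, x$a_s, x$r_d))
  cat(sprintf("  influx: gamma = %g, I0 = %g pA, tau_d = %g s\n",
              x$gamma, x$I0, x$tau_d))
  cat(sprintf("  plasticity: theta_d = %g, theta_p = %g uM; gamma_p = %g, gamma_d = %g 1/s\n",
              x$theta_d, x$theta_p, x$gamma_p, x$gamma_d))
  invisible(x)
}
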