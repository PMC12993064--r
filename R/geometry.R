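#' Discretized cable geometry
#'
#' Describes the unbranched dendritic cable as `n_segments` segments of
#' length `dx` with no-flux (reflecting) boundaries at both ends.
#'
#' @param length cable length (um).
#' @param dx segment length (um).
#' @param boundary boundary condition tag; only `"no-flux"` is supported.
#' @return An object of class `ca_geometry`.
#' @export
geometry <- function(length = 80, dx = 0.5, boundary = "no-flux") {
  if (!is.numeric(length) || length <= 0) stop("`length` must be positive")
  if (!is.numeric(dx) || dx <= 0) stop("`dx` must be positive")
  boundary <- match.arg(boundary, "no-flux")
  n <- round(length / dx)
  if (n < 2) stop("geometry must have at least 2 segments")
  if (abs(n * dx - length) > 1e-9 * length)
    stop("`length` must be an integer multiple of `dx`")
  structure(list(length = length, dx = dx, n_segments = as.integer(n),
                 boundary = boundary),
            class = "ca_geometry")
}

#' @export
print.ca_geometry <- function(x, ...) {
  cat(sprintf("Cable geometry: %g um, %d segments of %g um, %s boundaries\n",
              x$length, x$n_segments, x$dx, x$boundary))
  invisible(x)
}

#' Segment centre positions (um) of a geometry
#' @param geom a `ca_geometry`.
#' @return Numeric vector of length `n_segments`.
#' @export
segment_centers <- function(geom) {
  (seq_len(geom$n_segments) - 0.5) * geom$dx
}

#' Compartment volumes of a dendritic segment and a spine head
#'
#' The dendritic segment is a cylinder of radius `r_d` and length `dx`
#' (`V_d = pi r_d^2 dx`); the spine head is a sphere of radius `r_s`
#' (`V_s = 4/3 pi r_s^3`).
#'
#' @param params a `ca_parameters` object.
#' @param dx dendritic segment length (um).
#' @return Named list with `V_d` and `V_s` (um^3).
#' @examples
#' compartment_volumes(default_parameters(), dx = 1)
#' @export
compartment_volumes <- function(params, dx) {
  if (!is.numeric(dx) || length(dx) != 1 || is.na(dx) || dx <= 0)
    stop("invalid parameter: `dx` must be strictly positive")
  if (params$r_d <= 0 || params$r_s <= 0)
    stop("invalid parameter: radii must be strictly positive")
  list(V_d = pi * params$r_d^2 * dx,
       V_s = 4 / 3 * pi * params$r_s^3)
}

#' Spine--dendrite calcium exchange rates
#'
#' The exchange of calcium between a spine head and its dendritic segment is
#' modelled as two first-order rates given by inverse mean first passage
#' times across the spine neck:
#' \deqn{k_d = 4 D a_s / V_d, \qquad
#'       k_s = 1/\tau', \ \tau' = V_s/(4 D a_s) + l_n^2/(2 D).}
#' `k_d` multiplies the dendritic concentration to give the flux into the
#' spine; `k_s` multiplies the spine concentration to give the flux back into
#' the dendrite.
#'
#' For `D = 0` both rates vanish (the spine is isolated); in this degenerate
#' case `k_s` is returned as 0 with attribute `isolated = TRUE`.
#'
#' @param params a `ca_parameters` object.
#' @param dx dendritic segment length (um).
#' @return Named list with rates `k_d` and `k_s` (1/s).
#' @examples
#' coupling_rates(default_parameters(), dx = 1)  # k_d = 88/pi, k_s ~ 410/s
#' @export
coupling_rates <- function(params, dx) {
  vol <- compartment_volumes(params, dx)
  if (params$D == 0) {
    out <- list(k_d = 0, k_s = 0)
    attr(out, "isolated") <- TRUE
    return(out)
  }
  k_d <- 4 * params$D * params$a_s / vol$V_d
  tau_prime <- vol$V_s / (4 * params$D * params$a_s) +
    params$l_n^2 / (2 * params$D)
  list(k_d = k_d, k_s = 1 / tau_prime)
}

#' Conversion factor from synaptic current to spine calcium influx
#'
#' Isolates the unit conversion behind the influx relation
#' `J_syn = gamma * I / (z * F * V_s)`: with `I` in pA (1e-12 C/s), `V_s` in
#' um^3 (1e-15 L) and the result wanted in uM/s (1e-6 mol/L/s), the conversion
#' multiplies the ratio by 1e9.
#'
#' @param params a `ca_parameters` object.
#' @return Scalar coefficient `c` such that `J_syn [uM/s] = c * I [pA]`.
#' @export
current_to_flux_coef <- function(params) {
  V_s <- compartment_volumes(params, dx = 1)$V_s
  if (V_s <= 0) stop("invalid parameter: V_s must be positive")
  params$gamma * 1e9 / (params$z * params$F * V_s)
}
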