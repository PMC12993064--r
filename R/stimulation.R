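#' Stimulation protocol
#'
#' A protocol assigns each target spine a sorted list of presynaptic spike
#' times (s) within one presentation, plus a repetition structure: the whole
#' pattern is presented `repetitions` times, `repetition_interval` seconds
#' apart. The default 5 presentations 1 s apart keep presentations
#' independent (the 1 s gap is much longer than the 0.08 s calcium leak time
#' constant); the interval is a package choice, configurable per protocol.
#'
#' @param spikes named list mapping spine id (as character) to a sorted
#'   numeric vector of spike times (s) within one presentation.
#' @param repetitions number of presentations.
#' @param repetition_interval time between presentation onsets (s).
#' @param label protocol name.
#' @return An object of class `ca_protocol`.
#' @export
protocol <- function(spikes, repetitions = 5, repetition_interval = 1,
                     label = "custom") {
  stopifnot(is.list(spikes))
  if (length(spikes) > 0 && is.null(names(spikes)))
    stop("`spikes` must be named by spine id")
  for (nm in names(spikes)) {
    tt <- spikes[[nm]]
    if (length(tt) > 0 && (anyNA(tt) || any(tt < 0) || is.unsorted(tt)))
      stop("spike times for spine ", nm,
           " must be non-negative and sorted ascending")
    spikes[[nm]] <- as.numeric(tt)
  }
  if (repetitions < 1) stop("`repetitions` must be >= 1")
  if (repetitions > 1 && repetition_interval <= 0)
    stop("`repetition_interval` must be positive")
  structure(list(spikes = spikes, repetitions = as.integer(repetitions),
                 repetition_interval = repetition_interval, label = label),
            class = "ca_protocol")
}

#' @export
print.ca_protocol <- function(x, ...) {
  n_total <- sum(lengths(x$spikes)) * x$repetitions
  cat(sprintf("Stimulation protocol \"%s\": %d target spine(s), %d x %d spikes (interval %g s)\n",
              x$label, length(x$spikes), x$repetitions,
              sum(lengths(x$spikes)), x$repetition_interval))
  invisible(x)
}

#' Single-spike stimulation of one spine
#'
#' One presynaptic spike per presentation at the target spine; all other
#' spines stay silent.
#'
#' @param spine spine id (index into the arrangement).
#' @param repetitions,repetition_interval see [protocol()].
#' @return A `ca_protocol`.
#' @export
single_spike <- function(spine, repetitions = 5, repetition_interval = 1) {
  protocol(setNames(list(0), as.character(spine)),
           repetitions, repetition_interval, label = "single_spike")
}

#' Burst stimulation of one spine
#'
#' `n_spikes` equally spaced spikes per presentation at one spine. The
#' default burst shape (a 2-spike, 40 Hz pair) is a calibrated choice; the
#' source experiments state only "burst".
#'
#' @param spine spine id.
#' @param n_spikes spikes per burst (>= 1).
#' @param isi intra-burst inter-spike interval (s).
#' @param repetitions,repetition_interval see [protocol()].
#' @return A `ca_protocol`.
#' @export
burst <- function(spine, n_spikes = 2, isi = 0.025, repetitions = 5,
                  repetition_interval = 1) {
  if (n_spikes < 1) stop("`n_spikes` must be >= 1")
  if (n_spikes > 1 && isi <= 0) stop("`isi` must be positive")
  protocol(setNames(list((seq_len(n_spikes) - 1) * isi), as.character(spine)),
           repetitions, repetition_interval, label = "burst")
}

#' Paired stimulation of two spines with a time difference
#'
#' Per presentation, spine `spine_a` fires once and spine `spine_b` fires
#' `delta_t` seconds later; a negative `delta_t` reverses the order (both
#' times are shifted so the first spike is at 0).
#'
#' @param spine_a,spine_b distinct spine ids.
#' @param delta_t time difference (s), may be negative.
#' @param repetitions,repetition_interval see [protocol()].
#' @return A `ca_protocol`.
#' @export
paired_timing <- function(spine_a, spine_b, delta_t, repetitions = 5,
                          repetition_interval = 1) {
  if (identical(spine_a, spine_b))
    stop("`spine_a` and `spine_b` must be distinct")
  ta <- max(0, -delta_t)
  protocol(setNames(list(ta, ta + delta_t),
                    as.character(c(spine_a, spine_b))),
           repetitions, repetition_interval, label = "paired_timing")
}

#' Triplet stimulation: two spikes at one spine, one at another
#'
#' Spine `spine_a` fires at 0 and `inter_input` seconds later; spine
#' `spine_b` fires at `delta_t`, referenced to the first spike of `spine_a`.
#' Times are shifted so the earliest spike is at 0.
#'
#' @param spine_a,spine_b distinct spine ids.
#' @param delta_t timing of the `spine_b` spike relative to the first
#'   `spine_a` spike (s), may be negative.
#' @param inter_input interval between the two `spine_a` spikes (s).
#' @param repetitions,repetition_interval see [protocol()].
#' @return A `ca_protocol`.
#' @export
triplet <- function(spine_a, spine_b, delta_t, inter_input = 0.02,
                    repetitions = 5, repetition_interval = 1) {
  if (identical(spine_a, spine_b))
    stop("`spine_a` and `spine_b` must be distinct")
  if (inter_input <= 0) stop("`inter_input` must be positive")
  shift <- max(0, -delta_t)
  protocol(setNames(list(shift + c(0, inter_input), shift + delta_t),
                    as.character(c(spine_a, spine_b))),
           repetitions, repetition_interval, label = "triplet")
}

#' Synchronous frequency stimulation of a set of spines
#'
#' Each listed spine receives `n_pulses` spikes at the given rate; trains are
#' synchronous across spines. Used for the multi-spine frequency-regime
#' experiments.
#'
#' @param spines non-empty vector of spine ids.
#' @param rate stimulation rate (Hz).
#' @param n_pulses spikes per spine.
#' @param repetitions,repetition_interval see [protocol()]; the default is a
#'   single presentation because the train itself carries the repetition.
#' @return A `ca_protocol`.
#' @export
frequency_protocol <- function(spines, rate, n_pulses = 15, repetitions = 1,
                               repetition_interval = 1) {
  if (length(spines) == 0) stop("`spines` must be non-empty")
  if (rate <= 0) stop("`rate` must be positive")
  times <- (seq_len(n_pulses) - 1) / rate
  protocol(setNames(rep(list(times), length(spines)), as.character(spines)),
           repetitions, repetition_interval, label = "frequency")
}

#' Named frequency presets for the multi-spine experiments
#'
#' The source experiments are described only as low/medium/high-frequency
#' stimulation; the rates and train lengths here are calibrated stand-ins
#' chosen relative to the 0.08 s calcium leak time constant: at 0.5 Hz
#' dendritic calcium resets completely between pulses, at 40 Hz it
#' accumulates into a moderate standing level, and the 250 Hz train drives a
#' strong standing dendritic calcium plateau that spreads beyond the
#' stimulated cluster.
#'
#' @return Named list with elements `rate` (Hz) and `n_pulses` per preset.
#' @export
frequency_presets <- function() {
  list(low = list(rate = 0.5, n_pulses = 15),
       medium = list(rate = 40, n_pulses = 15),
       high = list(rate = 250, n_pulses = 100))
}

#' Expand a protocol to explicit per-spine spike-time vectors
#'
#' Applies the repetition structure and returns, for each of the `n` spines
#' of an arrangement, the full sorted vector of spike times.
#'
#' @param prot a `ca_protocol`.
#' @param n number of spines in the arrangement.
#' @return List of `n` numeric vectors (empty for silent spines).
#' @export
expand_protocol <- function(prot, n) {
  ids <- as.integer(names(prot$spikes))
  if (anyNA(ids) || any(ids < 1) || any(ids > n))
    stop("protocol targets unknown spine id(s); arrangement has ", n,
         " spines")
  offsets <- (seq_len(prot$repetitions) - 1) * prot$repetition_interval
  out <- rep(list(numeric(0)), n)
  for (k in seq_along(ids)) {
    base <- prot$spikes[[k]]
    if (length(base) > 0)
      out[[ids[k]]] <- sort(as.vector(outer(base, offsets, `+`)))
  }
  out
}

#' Total time span of a protocol (s)
#' @param prot a `ca_protocol`.
#' @return Time of the last spike.
#' @export
protocol_duration <- function(prot) {
  last <- suppressWarnings(max(unlist(prot$spikes), 0))
  last + (prot$repetitions - 1) * prot$repetition_interval
}

#' Relabel protocol spine ids (e.g. for a mirrored arrangement)
#'
#' @param prot a `ca_protocol`.
#' @param map integer vector: spine id `j` becomes `map[j]`.
#' @return A `ca_protocol` with remapped ids.
#' @export
remap_protocol <- function(prot, map) {
  ids <- as.integer(names(prot$spikes))
  names(prot$spikes) <- as.character(map[ids])
  prot
}

#' Write / read a protocol as JSON (times in ms)
#'
#' @param prot a `ca_protocol`.
#' @param path file path.
#' @return `write_protocol` returns `path` invisibly; `read_protocol`
#'   returns a `ca_protocol`.
#' @export
write_protocol <- function(prot, path) {
  obj <- list(spikes_ms = lapply(prot$spikes, function(t) t * 1e3),
              repetitions = prot$repetitions,
              repetition_interval_s = prot$repetition_interval,
              label = prot$label)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_protocol
#' @export
read_protocol <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  spikes <- lapply(obj$spikes_ms, function(t) as.numeric(t) / 1e3)
  if (length(spikes) > 0 && is.null(names(spikes)))
    stop("protocol file has no spine ids")
  protocol(spikes, obj$repetitions, obj$repetition_interval_s, obj$label)
}
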