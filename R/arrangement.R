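# run expr with a private, seeded RNG stream, restoring the caller's state
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Spine arrangement along the cable
#'
#' Ties a set of spines (one per dendritic segment, snapped to segment
#' centres) to a [geometry()], with a group label and an initial synaptic
#' weight per spine. Group labels follow the multi-spine experiments:
#' `"Stim"` (stimulated), `"Un_in"` (unstimulated inside the stimulated
#' cluster), `"Un_out"` (unstimulated outside it) and `"plain"` for
#' unlabelled spines.
#'
#' @param geom a `ca_geometry`.
#' @param spine_segments integer segment indices (1-based), unique.
#' @param groups character vector of group labels (recycled if length 1).
#' @param initial_weights numeric weights in `[0, 1]` (recycled if length 1).
#' @param seed optional integer recorded for provenance.
#' @param cluster optional list with `start_um` and `length_um` marking the
#'   stimulated cluster section (set by [generate_arrangement()]).
#' @return An object of class `ca_arrangement`. Spines are stored sorted by
#'   segment index.
#' @export
spine_arrangement <- function(geom, spine_segments, groups = "plain",
                              initial_weights = 0.5, seed = NA_integer_,
                              cluster = NULL) {
  stopifnot(inherits(geom, "ca_geometry"))
  seg <- as.integer(spine_segments)
  n <- length(seg)
  if (n > 0 && (any(seg < 1) || any(seg > geom$n_segments)))
    stop("spine segment indices must lie within the geometry")
  if (anyDuplicated(seg))
    stop("at most one spine per segment")
  groups <- rep_len(as.character(groups), n)
  bad <- setdiff(unique(groups), c("Stim", "Un_in", "Un_out", "plain"))
  if (length(bad) > 0)
    stop("unknown group label(s): ", paste(bad, collapse = ", "))
  w <- rep_len(as.numeric(initial_weights), n)
  if (n > 0 && (any(w < 0) || any(w > 1) || anyNA(w)))
    stop("initial weights must lie in [0, 1]")
  ord <- order(seg)
  structure(list(geometry = geom,
                 spine_segments = seg[ord],
                 groups = groups[ord],
                 initial_weights = w[ord],
                 seed = seed,
                 cluster = cluster),
            class = "ca_arrangement")
}

#' @export
print.ca_arrangement <- function(x, ...) {
  cat(sprintf("Spine arrangement: %d spines on a %g um cable (dx = %g um)\n",
              length(x$spine_segments), x$geometry$length, x$geometry$dx))
  tab <- table(factor(x$groups, c("Stim", "Un_in", "Un_out", "plain")))
  cat("  groups:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  if (!is.null(x$cluster))
    cat(sprintf("  cluster section: %g um starting at %g um\n",
                x$cluster$length_um, x$cluster$start_um))
  invisible(x)
}

#' Number of spines in an arrangement
#' @param arr a `ca_arrangement`.
#' @return Integer count.
#' @export
n_spines <- function(arr) length(arr$spine_segments)

#' Spine positions (um, segment centres)
#' @param arr a `ca_arrangement`.
#' @return Numeric vector of positions.
#' @export
spine_positions <- function(arr) {
  (arr$spine_segments - 0.5) * arr$geometry$dx
}

#' Constraints for the random arrangement generator
#'
#' Defaults emulate the multi-spine study setup: an 80 um dendrite carrying
#' 16 spines, of which 10 (7 stimulated + 3 unstimulated) are confined to a
#' 7 um cluster section (about 1.4 spines/um), with at least 3 unstimulated
#' spines on each flank outside the cluster.
#'
#' @param length dendrite length (um).
#' @param dx segment length (um).
#' @param n_spines total number of spines.
#' @param n_stim number of stimulated spines inside the cluster.
#' @param n_un_in number of unstimulated spines inside the cluster.
#' @param cluster_length length of the cluster section (um).
#' @param min_outer_per_side minimum `Un_out` spines on each flank.
#' @param weight_range range of the uniform initial-weight distribution.
#' @param stim_contiguous if `TRUE`, the stimulated spines occupy a
#'   contiguous run of the in-cluster spines instead of a random subset.
#' @param max_retries bounded number of rejection-sampling retries.
#' @return A list of class `ca_arrangement_config`.
#' @export
arrangement_config <- function(length = 80, dx = 0.5, n_spines = 16,
                               n_stim = 7, n_un_in = 3, cluster_length = 7,
                               min_outer_per_side = 3,
                               weight_range = c(0.3, 0.7),
                               stim_contiguous = FALSE,
                               max_retries = 1000) {
  cfg <- list(length = length, dx = dx, n_spines = n_spines, n_stim = n_stim,
              n_un_in = n_un_in, cluster_length = cluster_length,
              min_outer_per_side = min_outer_per_side,
              weight_range = weight_range,
              stim_contiguous = stim_contiguous, max_retries = max_retries)
  class(cfg) <- "ca_arrangement_config"
  cfg
}

#' Generate a random spine arrangement
#'
#' Places the cluster section uniformly at random along the cable (subject to
#' flank feasibility), draws the in-cluster spine segments and the outer
#' spines at uniformly random distinct segments, labels them
#' `Stim`/`Un_in`/`Un_out`, and draws initial weights from the configured
#' uniform distribution. Deterministic given `seed`; the caller's RNG state
#' is left untouched.
#'
#' @param seed integer seed.
#' @param config a [arrangement_config()].
#' @return A `ca_arrangement` with the cluster section recorded.
#' @examples
#' arr <- generate_arrangement(seed = 1)
#' table(arr$groups)
#' @export
generate_arrangement <- function(seed, config = arrangement_config()) {
  cfg <- config
  geom <- geometry(cfg$length, cfg$dx)
  n_seg <- geom$n_segments
  win_seg <- round(cfg$cluster_length / cfg$dx)
  n_in <- cfg$n_stim + cfg$n_un_in
  n_out <- cfg$n_spines - n_in
  side <- cfg$min_outer_per_side
  if (n_out < 2 * side)
    stop("generation error: fewer outer spines (", n_out,
         ") than required by min_outer_per_side (", 2 * side, ")")
  if (win_seg < n_in)
    stop("generation error: cluster section too short for ", n_in, " spines")
  # window starts leaving at least `side` segments on each flank
  first <- side + 1
  last <- n_seg - win_seg - side + 1
  if (last < first)
    stop("generation error: dendrite too short for the cluster window ",
         "with the required flanks")
  with_local_seed(seed, {
    for (try in seq_len(cfg$max_retries)) {
      win_start <- sample(first:last, 1)
      win <- win_start:(win_start + win_seg - 1)
      in_seg <- sort(sample(win, n_in))
      if (cfg$stim_contiguous) {
        s0 <- sample(seq_len(n_in - cfg$n_stim + 1), 1)
        stim_idx <- s0:(s0 + cfg$n_stim - 1)
      } else {
        stim_idx <- sample(n_in, cfg$n_stim)
      }
      left <- seq_len(win_start - 1)
      right <- if (win_start + win_seg <= n_seg)
        (win_start + win_seg):n_seg else integer(0)
      n_left <- side + sample.int(n_out - 2 * side + 1, 1) - 1
      n_right <- n_out - n_left
      if (length(left) < n_left || length(right) < n_right) next
      out_left <- sort(sample(left, n_left))
      out_right <- sort(sample(right, n_right))
      seg <- c(out_left, in_seg, out_right)
      grp <- c(rep("Un_out", n_left),
               ifelse(seq_len(n_in) %in% stim_idx, "Stim", "Un_in"),
               rep("Un_out", n_right))
      w <- runif(cfg$n_spines, cfg$weight_range[1], cfg$weight_range[2])
      ord <- order(seg)  # weights follow arrangement's sorted order
      return(spine_arrangement(
        geom, seg[ord], grp[ord], w[ord], seed = as.integer(seed),
        cluster = list(start_um = (win_start - 1) * cfg$dx,
                       length_um = win_seg * cfg$dx)))
    }
    stop("generation error: could not satisfy flank constraints after ",
         cfg$max_retries, " retries")
  })
}

#' Spine density of the stimulated cluster section
#'
#' Counts the spines whose segments fall inside the recorded cluster section
#' and divides by the section length.
#'
#' @param arr a `ca_arrangement` produced by [generate_arrangement()].
#' @return Density in spines/um.
#' @export
cluster_density <- function(arr) {
  if (is.null(arr$cluster))
    stop("arrangement has no recorded cluster section")
  pos <- spine_positions(arr)
  inside <- pos > arr$cluster$start_um &
    pos < arr$cluster$start_um + arr$cluster$length_um
  sum(inside) / arr$cluster$length_um
}

#' Mirror an arrangement about the cable midpoint
#'
#' @param arr a `ca_arrangement`.
#' @return The reflected arrangement (spines re-sorted by segment).
#' @export
mirror_arrangement <- function(arr) {
  n_seg <- arr$geometry$n_segments
  seg <- n_seg + 1L - arr$spine_segments
  cluster <- arr$cluster
  if (!is.null(cluster))
    cluster$start_um <- arr$geometry$length -
      (cluster$start_um + cluster$length_um)
  spine_arrangement(arr$geometry, seg, arr$groups, arr$initial_weights,
                    seed = arr$seed, cluster = cluster)
}

#' Write / read an arrangement as JSON
#'
#' Positions are stored in um together with labels, weights and the seed, so
#' arrangements can be exchanged with other tools.
#'
#' @param arr a `ca_arrangement`.
#' @param path file path.
#' @return `write_arrangement` returns `path` invisibly; `read_arrangement`
#'   returns a `ca_arrangement`.
#' @export
write_arrangement <- function(arr, path) {
  obj <- list(length_um = arr$geometry$length, dx_um = arr$geometry$dx,
              position_um = spine_positions(arr), group = arr$groups,
              initial_weight = arr$initial_weights, seed = arr$seed,
              cluster = arr$cluster)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_arrangement
#' @export
read_arrangement <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  geom <- geometry(obj$length_um, obj$dx_um)
  seg <- round(obj$position_um / obj$dx_um + 0.5)
  cluster <- if (is.null(obj$cluster)) NULL else as.list(obj$cluster)
  spine_arrangement(geom, seg, obj$group, obj$initial_weight,
                    seed = if (is.null(obj$seed)) NA_integer_ else obj$seed,
                    cluster = cluster)
}
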