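#' Hexagonal coordinate assignment from synapse positions
#'
#' Neurons are tied to the retinotopic lattice in three steps: a straight
#' proto-axis is fitted per column from the synapse cloud of the cells
#' already assigned there (first principal component through the centroid);
#' synapses are assigned to the nearest axis (or pin) by point-to-polyline
#' distance; and each neuron is labelled with the mode of its synapse
#' assignments. Ties are broken deterministically (lowest `(p, q)`
#' lexicographically) and flagged as ambiguous rather than resolved by
#' manual inspection.
#'
#' @name hexgrid
NULL

#' Fit a straight proto-axis to a synapse cloud
#'
#' Origin is the centroid, direction the first principal axis, with the sign
#' chosen so the axis points from the top of the neuropil to the bottom.
#'
#' @param points Numeric matrix (n x 3) of synapse positions, n >= 3 with at
#'   least 3 distinct rows.
#' @param orient Reference vector giving the top-to-bottom sense (default
#'   +z, matching [generate_grid()] slabs).
#' @return A `proto_axis`: list with `origin`, `direction` (unit 3-vector).
#' @export
compute_proto_axis <- function(points, orient = c(0, 0, 1)) {
  points <- as.matrix(points)
  if (nrow(points) < 3 || nrow(unique(points)) < 3) {
    stop_hexpin("need at least 3 distinct points to fit a proto-axis",
                "insufficient_data")
  }
  pc <- stats::prcomp(points, center = TRUE, scale. = FALSE)
  dir <- pc$rotation[, 1]
  if (sum(dir * orient) < 0) dir <- -dir
  structure(list(origin = colMeans(points), direction = dir),
            class = "proto_axis")
}

# sample a proto-axis as a polyline spanning [lo, hi] along its direction
proto_axis_polyline <- function(axis, lo, hi, n = 41L) {
  t <- seq(lo, hi, length.out = n)
  sweep(outer(t, axis$direction), 2, axis$origin, "+")
}

# normalize heterogeneous axis input (proto_axis / pin / matrix) to a
# point matrix; proto-axes are sampled over +-span along their direction
axis_points_matrix <- function(axis, span = 40000) {
  if (inherits(axis, "proto_axis")) {
    proto_axis_polyline(axis, -span / 2, span / 2, 81L)
  } else if (inherits(axis, "pin")) {
    axis$points
  } else {
    as.matrix(axis)
  }
}

#' Assign synapses to the nearest coordinate axis
#'
#' Point-to-polyline distance is the minimum Euclidean distance from the
#' point to any sampled point of the axis (consistent with pin-point
#' assignment). Equidistant cases resolve to the lowest `(p, q)`
#' lexicographically because axes are scanned in sorted coordinate order.
#'
#' @param synapses Data frame with `x`, `y`, `z` columns (or an n x 3
#'   matrix); an empty input yields an empty result.
#' @param axes Named list (keys `"p,q"`) of proto-axes, pins, or polyline
#'   matrices.
#' @return Data frame with `p`, `q` and `distance` per synapse.
#' @export
assign_synapses_to_axes <- function(synapses, axes) {
  if (length(axes) == 0) stop_hexpin("`axes` must be non-empty", "invalid_parameter")
  pts <- if (is.data.frame(synapses)) as.matrix(synapses[, c("x", "y", "z")]) else as.matrix(synapses)
  keys <- names(axes)
  pq <- do.call(rbind, lapply(strsplit(keys, ","), as.integer))
  ord <- order(pq[, 1], pq[, 2])
  pq <- pq[ord, , drop = FALSE]
  axes <- axes[ord]
  if (nrow(pts) == 0) {
    return(data.frame(p = integer(), q = integer(), distance = numeric()))
  }
  mats <- lapply(axes, axis_points_matrix)
  ref <- do.call(rbind, mats)
  owner <- rep(seq_along(mats), vapply(mats, nrow, integer(1)))
  nn <- nearest_ref_index(pts, ref)
  ai <- owner[nn$index]
  data.frame(p = pq[ai, 1], q = pq[ai, 2], distance = nn$distance)
}

#' Label a neuron with the modal coordinate of its synapse assignments
#'
#' Returns the modal `(p, q)`; when the top two counts tie, or when distinct
#' paired-connection evidence disagrees, the lowest coordinate wins and the
#' result is flagged ambiguous.
#'
#' @param assignments Data frame with `p`, `q` columns (one row per synapse
#'   or per paired-connection vote); must be non-empty.
#' @return List with `p`, `q`, `ambiguous`, `n_votes`.
#' @export
assign_neuron_coordinate <- function(assignments) {
  if (is.null(assignments) || nrow(assignments) == 0) {
    stop_hexpin("no assignments to take a mode over", "insufficient_data")
  }
  key <- sprintf("%012d|%012d", assignments$p + 5e5, assignments$q + 5e5)
  m <- lexi_mode(key)
  parts <- as.integer(strsplit(m$value, "|", fixed = TRUE)[[1]]) - 5e5L
  list(p = parts[1], q = parts[2], ambiguous = m$tied, n_votes = m$count)
}

#' Assign every neuron of a volume to a hexagonal coordinate
#'
#' Iterative driver: assign synapses to the current axes, label neurons by
#' modal column, rebuild proto-axes from the synapses of the neurons now
#' assigned to each column, and repeat. This folds the multi-stage manual
#' bootstrap (seed types, proto-axes, prototype pins) into one reproducible
#' loop.
#'
#' @param synapses Synapse table (`neuron_id`, `x`, `y`, `z`).
#' @param axes Initial axes: named list as in [assign_synapses_to_axes()],
#'   e.g. the planted axes of a [generate_grid()] lattice or proto-axes from
#'   a seed assignment.
#' @param n_iter Number of assign-rebuild rounds (default 3).
#' @return Data frame `neuron_id`, `p`, `q`, `ambiguous`, `n_votes`.
#' @export
assign_neurons_to_columns <- function(synapses, axes, n_iter = 3L) {
  out <- NULL
  for (it in seq_len(max(1L, n_iter))) {
    syn_asg <- assign_synapses_to_axes(synapses, axes)
    by_neuron <- split(syn_asg, synapses$neuron_id)
    out <- do.call(rbind, lapply(names(by_neuron), function(id) {
      m <- assign_neuron_coordinate(by_neuron[[id]])
      data.frame(neuron_id = as.integer(id), p = m$p, q = m$q,
                 ambiguous = m$ambiguous, n_votes = m$n_votes)
    }))
    if (it == n_iter) break
    # rebuild proto-axes from the synapses of currently assigned neurons
    syn_col <- merge(synapses, out[, c("neuron_id", "p", "q")], by = "neuron_id")
    new_axes <- list()
    for (k in split(syn_col, hex_key(syn_col$p, syn_col$q))) {
      pts <- as.matrix(k[, c("x", "y", "z")])
      if (nrow(unique(pts)) < 3) next
      new_axes[[hex_key(k$p[1], k$q[1])]] <-
        compute_proto_axis(pts)
    }
    if (length(new_axes)) axes <- new_axes
  }
  out[order(out$neuron_id), , drop = FALSE]
}
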