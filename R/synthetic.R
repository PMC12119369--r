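#' Synthetic optic-lobe volumes with planted ground truth
#'
#' The generator emulates the statistical structure of a columnar neuropil:
#' a hexagonal lattice of columns, each with a (optionally curved) centre
#' axis running from the top to the bottom surface of the neuropil slab;
#' neurons of named types whose synapses cluster laterally around their home
#' column's axis with planted depth profiles; type-to-type connectivity
#' rules with Poisson count noise; and per-synapse transmitter probability
#' vectors. Every planted quantity (home coordinate, type, depth,
#' transmitter) is recorded so downstream modules can be tested against
#' ground truth.
#'
#' @name synthetic-volume
NULL

#' Specify a synthetic cell type
#'
#' @param name Type name (e.g. `"Mi1"`).
#' @param n_cells Number of cells of the type (>= 1).
#' @param columns_per_cell Number of columns each cell innervates (>= 1); the
#'   home column plus its nearest lattice neighbours.
#' @param n_pre,n_post Presynapses / postsynapses per cell.
#' @param depth_profile_pre,depth_profile_post Data frames with columns
#'   `depth` (in `[0, 1]`) and `density` (non-negative relative weights);
#'   synapse depths are drawn from these control points with a small
#'   Gaussian smear.
#' @param partner_rules Data frame with columns `partner` (type name),
#'   `direction` (`"out"` for this type presynaptic, `"in"` for
#'   postsynaptic) and `mean` (mean connections per cell); may be empty.
#' @param transmitter One of [NT_CLASSES].
#' @param depth_sd Gaussian smear (in depth units) applied around the
#'   profile control points.
#' @return An object of class `type_spec`.
#' @export
type_spec <- function(name, n_cells, columns_per_cell = 1L,
                      n_pre = 80L, n_post = 120L,
                      depth_profile_pre = data.frame(depth = 0.7, density = 1),
                      depth_profile_post = data.frame(depth = 0.3, density = 1),
                      partner_rules = NULL,
                      transmitter = "ACh",
                      depth_sd = 0.02) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(n_cells) || n_cells < 1) {
    stop_hexpin("`n_cells` must be >= 1", "invalid_spec")
  }
  if (columns_per_cell < 1) stop_hexpin("`columns_per_cell` must be >= 1", "invalid_spec")
  check_profile <- function(pr, lab) {
    if (!all(c("depth", "density") %in% names(pr))) {
      stop_hexpin(sprintf("%s must have `depth` and `density` columns", lab), "invalid_spec")
    }
    if (any(pr$density < 0) || sum(pr$density) <= 0) {
      stop_hexpin(sprintf("%s densities must be non-negative and normalizable", lab), "invalid_spec")
    }
    if (any(pr$depth < 0 | pr$depth > 1)) {
      stop_hexpin(sprintf("%s depths must lie in [0, 1]", lab), "invalid_spec")
    }
  }
  check_profile(depth_profile_pre, "depth_profile_pre")
  check_profile(depth_profile_post, "depth_profile_post")
  if (!transmitter %in% NT_CLASSES) {
    stop_hexpin("`transmitter` must be one of the seven transmitter classes", "invalid_spec")
  }
  if (is.null(partner_rules)) {
    partner_rules <- data.frame(partner = character(), direction = character(),
                                mean = numeric())
  }
  structure(list(name = name, n_cells = as.integer(n_cells),
                 columns_per_cell = as.integer(columns_per_cell),
                 n_pre = as.integer(n_pre), n_post = as.integer(n_post),
                 depth_profile_pre = depth_profile_pre,
                 depth_profile_post = depth_profile_post,
                 partner_rules = partner_rules,
                 transmitter = transmitter,
                 depth_sd = depth_sd),
            class = "type_spec")
}

#' Generate a hexagonal column grid with planted centre axes
#'
#' Builds an axial-coordinate hexagonal lattice (the retinotopic column
#' array) of all coordinates within `n_rings` of the centre, and plants a
#' centre axis per column running from the top surface of the neuropil slab
#' (z = 0) to the bottom (z = `depth`). With `curvature > 0` axes are bent
#' as circular arcs bowing in +x with sagitta `curvature * depth`, keeping
#' both endpoints on the surfaces.
#'
#' @param n_rings Number of rings around the central column (>= 1); the
#'   lattice has `1 + 3 * n_rings * (n_rings + 1)` columns.
#' @param spacing Lateral distance between neighbouring column axes, nm.
#' @param curvature Dimensionless bow of the planted axes (sagitta as a
#'   fraction of slab depth); 0 gives straight parallel axes.
#' @param depth Slab thickness, nm (top surface at z = 0).
#' @param axis_samples Number of sample points per planted axis polyline.
#' @return A `hex_grid`: data frame with columns `p`, `q`, `x`, `y` and
#'   `equator` (rows with q = 0 flagged, mirroring the darker equator rows
#'   of the eye map), with planted axes and slab surfaces as attributes.
#' @export
generate_grid <- function(n_rings, spacing = 8000, curvature = 0,
                          depth = 40000, axis_samples = 41L) {
  if (!is.numeric(n_rings) || n_rings < 1) {
    stop_hexpin("`n_rings` must be >= 1", "invalid_parameter")
  }
  assert_scalar_pos(spacing, "spacing")
  assert_scalar_pos(depth, "depth")
  n_rings <- as.integer(n_rings)
  coords <- expand.grid(p = -n_rings:n_rings, q = -n_rings:n_rings)
  keep <- hex_distance(coords$p, coords$q, 0L, 0L) <= n_rings
  coords <- coords[keep, , drop = FALSE]
  coords <- coords[order(coords$p, coords$q), , drop = FALSE]
  xy <- axial_to_cart(coords$p, coords$q, spacing)
  grid <- data.frame(p = coords$p, q = coords$q, x = xy[, "x"], y = xy[, "y"],
                     equator = coords$q == 0L, row.names = NULL)

  s <- seq(0, 1, length.out = as.integer(axis_samples))
  z <- s * depth
  # circular-arc lateral offset, zero at both endpoints
  if (curvature > 0) {
    h <- curvature * depth
    R <- (h^2 + (depth / 2)^2) / (2 * h)
    xoff <- sqrt(pmax(R^2 - (z - depth / 2)^2, 0)) - (R - h)
  } else {
    xoff <- rep(0, length(z))
  }
  axes <- vector("list", nrow(grid))
  names(axes) <- hex_key(grid$p, grid$q)
  for (i in seq_len(nrow(grid))) {
    axes[[i]] <- cbind(x = grid$x[i] + xoff, y = rep(grid$y[i], length(z)), z = z)
  }
  surfaces <- list(
    top = list(point = c(0, 0, 0), normal = c(0, 0, 1)),
    bottom = list(point = c(0, 0, depth), normal = c(0, 0, 1))
  )
  structure(grid, class = c("hex_grid", "data.frame"),
            spacing = spacing, depth = depth, curvature = curvature,
            axes = axes, surfaces = surfaces)
}

#' @export
print.hex_grid <- function(x, ...) {
  cat(sprintf("<hex_grid> %d columns, spacing %g nm, depth %g nm, curvature %g\n",
              nrow(x), attr(x, "spacing"), attr(x, "depth"), attr(x, "curvature")))
  invisible(x)
}

# interpolate a planted axis at depth fraction s in [0,1]; returns matrix
axis_point_at <- function(axis, s) {
  n <- nrow(axis)
  u <- s * (n - 1) + 1
  i0 <- pmin(pmax(floor(u), 1), n - 1)
  w <- u - i0
  axis[i0, , drop = FALSE] * (1 - w) + axis[i0 + 1, , drop = FALSE] * w
}

# unit tangent of a planted axis at depth fraction s
axis_tangent_at <- function(axis, s) {
  n <- nrow(axis)
  i0 <- pmin(pmax(floor(s * (n - 1) + 1), 1), n - 1)
  d <- axis[i0 + 1, , drop = FALSE] - axis[i0, , drop = FALSE]
  d / sqrt(rowSums(d^2))
}

# sample a synapse cloud around one axis: depths from a profile, isotropic
# Gaussian jitter in the plane orthogonal to the local tangent
sample_column_cloud <- function(axis, n, profile, jitter_sd, depth_sd) {
  probs <- profile$density / sum(profile$density)
  ctrl <- sample.int(nrow(profile), n, replace = TRUE, prob = probs)
  s <- pmin(pmax(profile$depth[ctrl] + stats::rnorm(n, 0, depth_sd), 0), 1)
  base <- axis_point_at(axis, s)
  tang <- axis_tangent_at(axis, s)
  # orthonormal basis of the plane orthogonal to the tangent
  ref <- matrix(rep(c(1, 0, 0), each = n), ncol = 3)
  swap <- abs(tang[, 1]) > 0.9
  ref[swap, ] <- matrix(rep(c(0, 1, 0), each = sum(swap)), ncol = 3)
  e1 <- ref - tang * rowSums(ref * tang)
  e1 <- e1 / sqrt(rowSums(e1^2))
  e2 <- cbind(tang[, 2] * e1[, 3] - tang[, 3] * e1[, 2],
              tang[, 3] * e1[, 1] - tang[, 1] * e1[, 3],
              tang[, 1] * e1[, 2] - tang[, 2] * e1[, 1])
  u <- stats::rnorm(n, 0, jitter_sd)
  v <- stats::rnorm(n, 0, jitter_sd)
  list(points = base + e1 * u + e2 * v, depth = s)
}

# Dirichlet-like transmitter probability vectors peaked at the true class
sample_nt_probs <- function(n, transmitter, concentration = 20) {
  alpha <- rep(0.5, length(NT_CLASSES))
  alpha[match(transmitter, NT_CLASSES)] <- concentration
  g <- matrix(stats::rgamma(n * length(alpha), shape = rep(alpha, each = n)),
              nrow = n)
  g / rowSums(g)
}

#' Generate neurons and synapses for a synthetic volume
#'
#' Each neuron receives a home column (one-to-one when `n_cells` equals the
#' number of columns, so strictly columnar types tile the lattice as a
#' mosaic) and, for multicolumnar types, its `columns_per_cell - 1` nearest
#' extra columns. Synapses are sampled around the planted column axes at
#' depths drawn from the type's depth profiles, with isotropic Gaussian
#' lateral jitter (default `spacing / 6`, small enough that nearest-axis
#' assignment recovers the planted column almost always). True labels
#' (type, home coordinate, per-synapse depth and column) are recorded.
#'
#' @param specs List of [type_spec()] objects.
#' @param grid A [generate_grid()] lattice.
#' @param seed Integer seed; regeneration with the same seed is bit-identical.
#' @param jitter_sd Lateral jitter standard deviation, nm.
#' @param neuropil Region name stamped on the synapse table.
#' @return A `synthetic_volume`: list with `grid`, `neurons`, `synapses`,
#'   `connections` (empty until [generate_connectivity()]), `specs`, `seed`.
#' @export
generate_neurons <- function(specs, grid, seed, jitter_sd = NULL,
                             neuropil = "ME") {
  if (length(specs) == 0) stop_hexpin("`specs` must be non-empty", "invalid_spec")
  if (inherits(specs, "type_spec")) specs <- list(specs)
  spec_names <- vapply(specs, `[[`, character(1), "name")
  for (sp in specs) {
    unknown <- setdiff(sp$partner_rules$partner, spec_names)
    if (length(unknown)) {
      stop_hexpin(sprintf("partner_rules of '%s' name unknown types: %s",
                          sp$name, paste(unknown, collapse = ", ")),
                  "invalid_spec")
    }
  }
  spacing <- attr(grid, "spacing")
  axes <- attr(grid, "axes")
  jitter_sd <- jitter_sd %||% (spacing / 6)

  with_seed(seed, {
    neuron_rows <- list()
    synapse_rows <- list()
    next_id <- 1L
    for (sp in specs) {
      ncol_grid <- nrow(grid)
      # home columns: a mosaic permutation when counts match the lattice
      if (sp$n_cells <= ncol_grid) {
        home_idx <- sample.int(ncol_grid, sp$n_cells)
      } else {
        home_idx <- c(rep(seq_len(ncol_grid), sp$n_cells %/% ncol_grid),
                      sample.int(ncol_grid, sp$n_cells %% ncol_grid))
      }
      for (ci in seq_len(sp$n_cells)) {
        id <- next_id
        next_id <- next_id + 1L
        hi <- home_idx[[ci]]
        # innervated columns: home plus nearest lattice neighbours
        if (sp$columns_per_cell > 1L) {
          d <- hex_distance(grid$p, grid$q, grid$p[hi], grid$q[hi])
          ord <- order(d, grid$p, grid$q)
          cols <- ord[seq_len(min(sp$columns_per_cell, ncol_grid))]
        } else {
          cols <- hi
        }
        n_cols <- length(cols)
        per_pre <- diff(round(seq(0, sp$n_pre, length.out = n_cols + 1)))
        per_post <- diff(round(seq(0, sp$n_post, length.out = n_cols + 1)))
        for (k in seq_len(n_cols)) {
          col_i <- cols[[k]]
          ax <- axes[[hex_key(grid$p[col_i], grid$q[col_i])]]
          for (pol in c("pre", "post")) {
            n_syn <- if (pol == "pre") per_pre[[k]] else per_post[[k]]
            if (n_syn == 0) next
            prof <- if (pol == "pre") sp$depth_profile_pre else sp$depth_profile_post
            cl <- sample_column_cloud(ax, n_syn, prof, jitter_sd, sp$depth_sd)
            # jitter is orthogonal to the local tangent; clamp z so curved
            # axes cannot push points outside the bounding slab
            cl$points[, 3] <- pmin(pmax(cl$points[, 3], 0), attr(grid, "depth"))
            probs <- sample_nt_probs(n_syn, sp$transmitter)
            colnames(probs) <- nt_prob_cols()
            synapse_rows[[length(synapse_rows) + 1L]] <- data.frame(
              neuron_id = id, prepost = pol,
              x = cl$points[, 1], y = cl$points[, 2], z = cl$points[, 3],
              confidence = stats::rbeta(n_syn, 8, 2),
              roi = neuropil,
              true_depth = cl$depth,
              true_p = grid$p[col_i], true_q = grid$q[col_i],
              probs
            )
          }
        }
        neuron_rows[[length(neuron_rows) + 1L]] <- data.frame(
          neuron_id = id, type = sp$name,
          instance = paste0(sp$name, "_R"),
          true_p = grid$p[hi], true_q = grid$q[hi],
          transmitter = sp$transmitter
        )
      }
    }
    neurons <- do.call(rbind, neuron_rows)
    synapses <- do.call(rbind, synapse_rows)
    synapses$synapse_id <- seq_len(nrow(synapses))
    synapses <- synapses[, c("synapse_id", setdiff(names(synapses), "synapse_id"))]
    structure(list(grid = grid, neurons = neurons, synapses = synapses,
                   connections = empty_connections(), specs = specs,
                   seed = as.integer(seed), jitter_sd = jitter_sd,
                   neuropil = neuropil),
              class = "synthetic_volume")
  })
}

empty_connections <- function() {
  data.frame(pre_id = integer(), post_id = integer(),
             weight = integer(), roi = character())
}

#' Generate type-to-type connectivity for a synthetic volume
#'
#' For each partner rule (A, B, direction, mean) every A cell draws a
#' Poisson(`mean`) total connection count, split across the `n_partners`
#' spatially nearest B cells (by home-column lattice distance), so planted
#' connectivity respects retinotopy.
#'
#' @param volume A [generate_neurons()] result.
#' @param seed Integer seed.
#' @param n_partners How many nearby partner cells share a rule's count.
#' @return The volume with its `connections` table filled (columns `pre_id`,
#'   `post_id`, `weight`, `roi`).
#' @export
generate_connectivity <- function(volume, seed, n_partners = 3L) {
  stopifnot(inherits(volume, "synthetic_volume"))
  neurons <- volume$neurons
  rows <- list()
  with_seed(seed, {
    for (sp in volume$specs) {
      rules <- sp$partner_rules
      if (nrow(rules) == 0) next
      cells <- neurons[neurons$type == sp$name, , drop = FALSE]
      for (ri in seq_len(nrow(rules))) {
        partners <- neurons[neurons$type == rules$partner[ri], , drop = FALSE]
        if (nrow(partners) == 0) next
        for (ci in seq_len(nrow(cells))) {
          total <- stats::rpois(1, rules$mean[ri])
          if (total == 0) next
          d <- hex_distance(partners$true_p, partners$true_q,
                            cells$true_p[ci], cells$true_q[ci])
          ord <- order(d, partners$true_p, partners$true_q)
          k <- min(n_partners, nrow(partners))
          tgt <- ord[seq_len(k)]
          w <- as.vector(stats::rmultinom(1, total, prob = rep(1, k)))
          keep <- w > 0
          if (!any(keep)) next
          out_dir <- rules$direction[ri] == "out"
          rows[[length(rows) + 1L]] <- data.frame(
            pre_id = if (out_dir) cells$neuron_id[ci] else partners$neuron_id[tgt[keep]],
            post_id = if (out_dir) partners$neuron_id[tgt[keep]] else cells$neuron_id[ci],
            weight = w[keep],
            roi = volume$neuropil
          )
        }
      }
    }
  })
  conn <- if (length(rows)) do.call(rbind, rows) else empty_connections()
  if (nrow(conn)) {
    # merge duplicate (pre, post, roi) pairs arising from reciprocal rules
    agg <- stats::aggregate(weight ~ pre_id + post_id + roi, data = conn, FUN = sum)
    conn <- agg[order(agg$pre_id, agg$post_id), c("pre_id", "post_id", "weight", "roi")]
    rownames(conn) <- NULL
  }
  volume$connections <- conn
  volume
}

#' @export
print.synthetic_volume <- function(x, ...) {
  cat(sprintf("<synthetic_volume> %d neurons (%d types), %d synapses, %d connections, seed %d\n",
              nrow(x$neurons), length(unique(x$neurons$type)),
              nrow(x$synapses), nrow(x$connections), x$seed))
  invisible(x)
}
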