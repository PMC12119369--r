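# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

# 19-column lattice, five planted types (three columnar mosaics, one
# five-column type, one wide-field type), disjoint partner rules, default
# jitter spacing/6 -- the study conditions of the recovery tests
fixture_volume <- function() {
  if (is.null(.fixtures$vol)) {
    grid <- generate_grid(2, spacing = 8000, curvature = 0.05)
    vol <- generate_neurons(default_type_specs(nrow(grid)), grid, seed = 101)
    .fixtures$vol <- generate_connectivity(vol, seed = 102)
  }
  .fixtures$vol
}

fixture_coords <- function() {
  if (is.null(.fixtures$coords)) {
    vol <- fixture_volume()
    .fixtures$coords <- assign_neurons_to_columns(
      vol$synapses, attr(vol$grid, "axes"), n_iter = 1)
  }
  .fixtures$coords
}

fixture_pins <- function() {
  if (is.null(.fixtures$pins)) {
    vol <- fixture_volume()
    coords <- fixture_coords()
    ids <- vol$neurons$neuron_id[vol$neurons$type %in% columnar_type_names(vol)]
    syn <- merge(vol$synapses[vol$synapses$neuron_id %in% ids, ],
                 coords[, c("neuron_id", "p", "q")], by = "neuron_id")
    built <- build_pins(syn, attr(vol$grid, "surfaces"), pin_params("medulla"))
    .fixtures$pins <- regularize_and_fill(built, vol$grid)
  }
  .fixtures$pins
}

fixture_depth_assignments <- function() {
  if (is.null(.fixtures$depth)) {
    vol <- fixture_volume()
    .fixtures$depth <- cbind(
      vol$synapses[, c("synapse_id", "neuron_id", "prepost")],
      assign_points_to_pins(vol$synapses, fixture_pins()))
  }
  .fixtures$depth
}

# straight synthetic column cloud spanning a slab; returns points + surfaces
straight_column_cloud <- function(n = 600, depth = 40000, sd_lat = 1200,
                                  seed = 1, x0 = 0, y0 = 0) {
  grid <- generate_grid(1, spacing = 8000, depth = depth)
  ax <- attr(grid, "axes")[[hex_key_chr(0, 0)]]
  vol <- generate_neurons(
    list(type_spec("T", n_cells = 1, n_pre = n / 2, n_post = n / 2,
                   depth_profile_pre = data.frame(depth = c(.1, .3, .5), density = 1),
                   depth_profile_post = data.frame(depth = c(.6, .8, .95), density = 1),
                   depth_sd = 0.05)),
    grid, seed = seed, jitter_sd = sd_lat)
  pts <- as.matrix(vol$synapses[, c("x", "y", "z")])
  pts[, 1] <- pts[, 1] + x0
  pts[, 2] <- pts[, 2] + y0
  list(points = pts, surfaces = attr(grid, "surfaces"),
       axis = cbind(ax[, 1] + x0, ax[, 2] + y0, ax[, 3]))
}

hex_key_chr <- function(p, q) paste0(p, ",", q)

# two small mutually wired types for I/O round-trip tests
io_test_specs <- function(n_columns) {
  list(
    type_spec("IoA", n_cells = n_columns, n_pre = 30, n_post = 30,
              partner_rules = data.frame(partner = "IoB", direction = "out",
                                         mean = 6)),
    type_spec("IoB", n_cells = n_columns, n_pre = 30, n_post = 30)
  )
}

# independent shortest-path oracle: minimum-hop path from the first to the
# last point in the DAG whose edges are pairs (i < j) with gap <= d_max
oracle_shortest_sublist_len <- function(l, d_max) {
  n <- nrow(l)
  edges <- c()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (sqrt(sum((l[i, ] - l[j, ])^2)) <= d_max) edges <- c(edges, i, j)
    }
  }
  if (is.null(edges)) return(NA_integer_)
  g <- igraph::make_graph(edges, n = n, directed = TRUE)
  sp <- suppressWarnings(igraph::shortest_paths(g, 1, n)$vpath[[1]])
  if (length(sp) == 0) NA_integer_ else length(sp)
}

# full enumeration oracle for small instances
oracle_enumerate_sublist_len <- function(l, d_max) {
  n <- nrow(l)
  interior <- seq_len(n)[-c(1, n)]
  best <- NA_integer_
  for (mask in 0:(2^length(interior) - 1)) {
    pick <- c(1, interior[bitwAnd(bitwShiftR(mask, seq_along(interior) - 1), 1) == 1], n)
    gaps <- sqrt(rowSums(diff(l[pick, , drop = FALSE])^2))
    if (all(gaps <= d_max) && (is.na(best) || length(pick) < best)) {
      best <- length(pick)
    }
  }
  best
}

# permutation brute force for square assignment problems
oracle_assignment_weight <- function(C) {
  n <- nrow(C)
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    }
    out
  }
  max(vapply(perms(seq_len(n)), function(p) sum(C[cbind(seq_len(n), p)]),
             numeric(1)))
}
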