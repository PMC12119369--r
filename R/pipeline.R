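#' Run the full analysis pipeline on a (synthetic) volume
#'
#' Executes the stages in order — simulate (when no volume is supplied),
#' column coordinates, pins, depth distributions, connectivity features and
#' clustering, coverage, neurotransmitter calls, inter-region matrix — and
#' writes each stage's tables plus a manifest and log to `out_dir`. All
#' randomness flows from `config$seed`; a rerun with the same seed is
#' numerically identical.
#'
#' @param config Configuration list (see [default_config()]).
#' @param out_dir Output directory.
#' @param volume Optional pre-built `synthetic_volume`; otherwise a default
#'   volume of five planted types is generated from `config`.
#' @return List of stage results, invisibly; tables and `manifest.yaml`
#'   under `out_dir`.
#' @export
run_pipeline <- function(config = default_config(), out_dir = tempfile("hexpin_run_"),
                         volume = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "pipeline.log")
  logf <- function(fmt, ...) {
    cat(sprintf(paste0(fmt, "\n"), ...), file = log_path, append = TRUE)
  }
  stage <- function(name, code) {
    logf("[%s] start", name)
    res <- tryCatch(code, error = function(e) {
      logf("[%s] FAILED: %s", name, conditionMessage(e))
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    logf("[%s] done", name)
    res
  }
  logf("seed: %d", config$seed)

  if (is.null(volume)) {
    volume <- stage("simulate", {
      grid <- generate_grid(config$grid$n_rings, config$grid$spacing_nm,
                            config$grid$curvature, config$grid$depth_nm)
      vol <- generate_neurons(default_type_specs(), grid, seed = config$seed)
      generate_connectivity(vol, seed = config$seed + 1L)
    })
  }
  write_tables(volume, out_dir)
  grid <- volume$grid

  coords <- stage("coordinates", {
    assign_neurons_to_columns(volume$synapses, attr(grid, "axes"), n_iter = 3L)
  })
  utils::write.csv(coords, file.path(out_dir, "coordinates.csv"), row.names = FALSE)

  pins <- stage("pins", {
    # pins come from the synapses of columnar neurons assigned to each
    # coordinate (the analogue of the 15 columnar seed types)
    columnar <- columnar_type_names(volume)
    ids <- volume$neurons$neuron_id[volume$neurons$type %in% columnar]
    syn <- merge(volume$synapses[volume$synapses$neuron_id %in% ids, ],
                 coords[, c("neuron_id", "p", "q")], by = "neuron_id")
    params <- do.call(pin_params, c(list("medulla"), config$pins$medulla[
      setdiff(names(config$pins$medulla), "neuropil")]))
    built <- build_pins(syn, attr(grid, "surfaces"), params)
    regularize_and_fill(built, grid)
  })
  utils::write.csv(pins_to_table(pins), file.path(out_dir, "pins.csv"),
                   row.names = FALSE)

  depth_asg <- stage("depth", {
    cbind(volume$synapses[, c("synapse_id", "neuron_id", "prepost")],
          assign_points_to_pins(volume$synapses, pins))
  })
  utils::write.csv(depth_asg, file.path(out_dir, "depth_assignments.csv"),
                   row.names = FALSE)

  clusters <- stage("typecells", {
    feats <- build_conn_features(volume$neurons$neuron_id, volume$connections,
                                 volume$neurons[, c("neuron_id", "type")])
    k <- length(unique(volume$neurons$type))
    cl <- cluster_features(feats, config$clustering$metric, k)
    data.frame(neuron_id = as.integer(names(cl)), cluster = as.integer(cl))
  })
  utils::write.csv(clusters, file.path(out_dir, "clusters.csv"), row.names = FALSE)

  coverage <- stage("coverage", {
    asg <- merge(depth_asg, volume$neurons[, c("neuron_id", "type")],
                 by = "neuron_id")
    do.call(rbind, lapply(split(asg, asg$type), function(d) {
      coverage_summary(d, grid, type = d$type[1])
    }))
  })
  utils::write.csv(coverage, file.path(out_dir, "coverage.csv"), row.names = FALSE)

  nt <- stage("nt", {
    nt_call_tables(volume$synapses, volume$neurons)
  })
  utils::write.csv(nt$types, file.path(out_dir, "nt_types.csv"), row.names = FALSE)

  projectome <- stage("projectome", {
    aggregate_group(volume$neurons$neuron_id, volume$connections,
                    regions = unique(volume$connections$roi), group = "all")
  })
  utils::write.csv(as.data.frame(unclass(projectome)),
                   file.path(out_dir, "projectome.csv"))

  yaml::write_yaml(list(
    stages = c("simulate", "coordinates", "pins", "depth", "typecells",
               "coverage", "nt", "projectome"),
    seed = config$seed,
    n_neurons = nrow(volume$neurons),
    n_synapses = nrow(volume$synapses),
    n_pins = length(pins)
  ), file.path(out_dir, "manifest.yaml"))

  invisible(list(volume = volume, coordinates = coords, pins = pins,
                 depth = depth_asg, clusters = clusters, coverage = coverage,
                 nt = nt, projectome = projectome, out_dir = out_dir))
}

#' Names of the strictly columnar types of a synthetic volume
#'
#' @param volume A `synthetic_volume`.
#' @return Character vector of type names with `columns_per_cell == 1`.
#' @export
columnar_type_names <- function(volume) {
  vapply(Filter(function(sp) sp$columns_per_cell == 1L, volume$specs),
         `[[`, character(1), "name")
}

#' Serialize a pin set as a flat table
#'
#' One row per pin point: coordinate, point index, position, provenance —
#' the tabular analogue of the database's per-column pin-point records.
#'
#' @param pins A `pin_set`.
#' @return Data frame `p`, `q`, `point_index`, `x`, `y`, `z`, `provenance`.
#' @export
pins_to_table <- function(pins) {
  do.call(rbind, lapply(pins, function(pin) {
    data.frame(p = pin$p, q = pin$q,
               point_index = seq_len(nrow(pin$points)) - 1L,
               x = pin$points[, 1], y = pin$points[, 2], z = pin$points[, 3],
               provenance = pin$provenance)
  }))
}

#' @rdname pins_to_table
#' @param table A data frame from `pins_to_table()`.
#' @export
pins_from_table <- function(table) {
  pins <- lapply(split(table, hex_key(table$p, table$q)), function(d) {
    d <- d[order(d$point_index), ]
    new_pin(d$p[1], d$q[1], as.matrix(d[, c("x", "y", "z")]), d$provenance[1])
  })
  structure(pins, class = "pin_set", N_samp = nrow(pins[[1]]$points))
}

#' Default synthetic study conditions
#'
#' Five planted types on the default lattice: three strictly columnar types
#' with distinct depth profiles and disjoint partner rules (a mosaic per
#' type, coverage factor about 1), one five-column type (coverage factor
#' about 5), and one sparse wide-field type. These are the conditions the
#' test-suite recovers ground truth under.
#'
#' @param n_columns Number of lattice columns the specs should tile
#'   (defaults to the 37-column, 3-ring lattice).
#' @return List of [type_spec()] objects.
#' @export
default_type_specs <- function(n_columns = 37L) {
  # profiles are broad and jointly tile depth, as the pooled synapses of the
  # real columnar types do across the medulla layers
  list(
    type_spec("McA", n_cells = n_columns, columns_per_cell = 1,
              depth_profile_pre = data.frame(depth = c(0.65, 0.75, 0.85),
                                             density = c(1, 2, 1)),
              depth_profile_post = data.frame(depth = c(0.03, 0.1, 0.2),
                                              density = c(1, 2, 1)),
              partner_rules = data.frame(partner = "McB", direction = "out",
                                         mean = 20),
              transmitter = "ACh", depth_sd = 0.04),
    type_spec("McB", n_cells = n_columns, columns_per_cell = 1,
              depth_profile_pre = data.frame(depth = c(0.45, 0.55),
                                             density = c(1, 1)),
              depth_profile_post = data.frame(depth = c(0.8, 0.9, 0.97),
                                              density = c(2, 2, 1)),
              partner_rules = data.frame(partner = "McC", direction = "out",
                                         mean = 15),
              transmitter = "Glu", depth_sd = 0.04),
    type_spec("McC", n_cells = n_columns, columns_per_cell = 1,
              depth_profile_pre = data.frame(depth = c(0.25, 0.35),
                                             density = c(1, 1)),
              depth_profile_post = data.frame(depth = c(0.55, 0.65),
                                              density = c(1, 1)),
              partner_rules = data.frame(partner = "DmX", direction = "out",
                                         mean = 12),
              transmitter = "GABA", depth_sd = 0.04),
    type_spec("DmX", n_cells = n_columns, columns_per_cell = 5,
              depth_profile_pre = data.frame(depth = c(0.05, 0.15),
                                             density = c(1, 1)),
              depth_profile_post = data.frame(depth = c(0.1, 0.25),
                                              density = c(1, 1)),
              partner_rules = data.frame(partner = "WfY", direction = "out",
                                         mean = 8),
              transmitter = "His", depth_sd = 0.04),
    type_spec("WfY", n_cells = 4, columns_per_cell = 12,
              depth_profile_pre = data.frame(depth = c(0.35, 0.9),
                                             density = c(1, 1)),
              depth_profile_post = data.frame(depth = c(0.45, 0.6),
                                              density = c(1, 1)),
              partner_rules = data.frame(partner = "McA", direction = "out",
                                         mean = 10),
              transmitter = "Dop", depth_sd = 0.04)
  )
}
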