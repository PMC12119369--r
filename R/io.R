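#' Tabular connectome I/O and SWC skeletons
#'
#' The three connectome exports are plain delimited tables: a neuron table
#' (id, type, instance, optional soma position and ground-truth columns), a
#' synapse table (neuron id, pre/post flag, 3D position in nm, confidence,
#' optional per-transmitter probabilities) and a connection table (pre id,
#' post id, weight, region). Synapses below the dataset confidence
#' threshold (0.5) are dropped on load. SWC skeletons use the standard
#' 7-column whitespace dialect.
#'
#' @name io
NULL

required_columns <- list(
  neurons = c("neuron_id", "type"),
  synapses = c("neuron_id", "prepost", "x", "y", "z", "confidence"),
  connections = c("pre_id", "post_id", "weight", "roi")
)

read_checked_csv <- function(path, what) {
  if (!file.exists(path)) {
    stop_hexpin(sprintf("file not found: %s", path), "parse_error")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required_columns[[what]], names(df))
  if (length(missing)) {
    stop_hexpin(sprintf("%s table %s is missing required column(s): %s",
                        what, path, paste(missing, collapse = ", ")),
                "parse_error")
  }
  df
}

#' Read the neuron / synapse / connection tables
#'
#' @param neurons,synapses,connections Paths to the three CSV tables.
#' @param min_confidence Synapse confidence filter applied on load
#'   (the dataset default is 0.5); use 0 to keep everything.
#' @return List of the three validated data frames.
#' @export
read_tables <- function(neurons, synapses, connections, min_confidence = 0.5) {
  n <- read_checked_csv(neurons, "neurons")
  s <- read_checked_csv(synapses, "synapses")
  c_ <- read_checked_csv(connections, "connections")
  s <- s[s$confidence >= min_confidence, , drop = FALSE]
  rownames(s) <- NULL
  bad <- !(c_$pre_id %in% n$neuron_id) | !(c_$post_id %in% n$neuron_id)
  if (any(bad)) {
    stop_hexpin(sprintf("connection table row %d references unknown neurons",
                        which(bad)[1]), "parse_error")
  }
  list(neurons = n, synapses = s, connections = c_)
}

#' Write the three tables of a synthetic volume
#'
#' @param volume A `synthetic_volume` (or a list with `neurons`,
#'   `synapses`, `connections`).
#' @param dir Output directory (created if needed).
#' @return The three file paths, invisibly.
#' @export
write_tables <- function(volume, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("neurons.csv", "synapses.csv", "connections.csv"))
  utils::write.csv(volume$neurons, paths[1], row.names = FALSE)
  utils::write.csv(volume$synapses, paths[2], row.names = FALSE)
  utils::write.csv(volume$connections, paths[3], row.names = FALSE)
  invisible(paths)
}

#' Read an SWC skeleton
#'
#' Standard dialect: whitespace-delimited, 7 columns (id, type, x, y, z,
#' radius, parent), `#` comments; the root's parent is -1.
#'
#' @param path SWC file path.
#' @return Data frame `node_id`, `type`, `x`, `y`, `z`, `radius`,
#'   `parent`.
#' @export
read_swc <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop_hexpin("SWC file has no nodes", "format_error")
  fields <- strsplit(lines, "\\s+")
  if (any(lengths(fields) != 7)) {
    stop_hexpin("SWC rows must have exactly 7 columns", "format_error")
  }
  m <- do.call(rbind, lapply(fields, as.numeric))
  df <- data.frame(node_id = as.integer(m[, 1]), type = as.integer(m[, 2]),
                   x = m[, 3], y = m[, 4], z = m[, 5], radius = m[, 6],
                   parent = as.integer(m[, 7]))
  # reject cyclic parent links by walking each node to a root
  parent_of <- stats::setNames(df$parent, df$node_id)
  for (start in df$node_id) {
    seen <- integer(0)
    node <- start
    while (node != -1) {
      if (node %in% seen) stop_hexpin("cyclic parent links in SWC", "format_error")
      seen <- c(seen, node)
      node <- parent_of[[as.character(node)]] %||% -1
    }
  }
  df
}

#' @rdname read_swc
#' @param skeleton Data frame as returned by [read_swc()].
#' @export
write_swc <- function(skeleton, path) {
  lines <- sprintf("%d %d %g %g %g %g %d", skeleton$node_id, skeleton$type,
                   skeleton$x, skeleton$y, skeleton$z, skeleton$radius,
                   skeleton$parent)
  writeLines(c("# id type x y z radius parent", lines), path)
  invisible(path)
}

#' Default pipeline configuration
#'
#' All defaults equal the published parameter values: the three
#' [pin_params()] presets, per-neuropil layer mass fractions
#' (`frac_peaks` 0.85 / 0.8 / 0.75), the synapse confidence thresholds
#' (0.5 on load, 0.9 for morphology features), the transmitter call
#' thresholds (50 / 100 presynapses, confidence 0.5), the 8 um matching
#' distance veto and the 0.9375 display cut for inter-region connections.
#' Lengths are nm internally; `_um` keys are converted on load.
#'
#' @return Nested configuration list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    grid = list(n_rings = 3L, spacing_nm = 8000, depth_nm = 40000,
                curvature = 0),
    pins = list(medulla = unclass(pin_params("medulla")),
                lobula = unclass(pin_params("lobula")),
                lobula_plate = unclass(pin_params("lobula_plate"))),
    layers = list(frac_peaks = list(medulla = 0.85, lobula = 0.8,
                                    lobula_plate = 0.75),
                  min_sep = 3L),
    clustering = list(metric = "cosine", morphology_metric = "euclidean"),
    synapse_confidence = list(load = 0.5, morphology = 0.9),
    neurotransmitters = list(cell_min_presynapses = 50L,
                             type_min_presynapses = 100L,
                             min_confidence = 0.5),
    matching = list(distance_threshold_um = 8, min_close = 3L),
    coverage = list(fallback_low = 0.775, fallback_high = 0.995,
                    kneedle_S = 1),
    interregion = list(cumulative_cut = 0.9375)
  )
}

#' Read / write a pipeline configuration
#'
#' Round-trips losslessly through YAML; `*_um` keys are additionally
#' mirrored to nm (`* 1000`) on read because thresholds are configured in
#' um while all geometry is nm.
#'
#' @param path YAML file path.
#' @return The configuration list.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$matching$distance_threshold_um)) {
    cfg$matching$distance_threshold_nm <- cfg$matching$distance_threshold_um * 1000
  }
  cfg
}

#' @rdname read_config
#' @param config Configuration list.
#' @export
write_config <- function(config, path) {
  config$matching$distance_threshold_nm <- NULL
  yaml::write_yaml(config, path)
  invisible(path)
}
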