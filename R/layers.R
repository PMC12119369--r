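#' Layer schemes from synapse depth distributions
#'
#' Layers subdivide a neuropil by depth thresholds. Each threshold is the
#' cut-off of a peak in the presynapse or postsynapse depth distribution of
#' a marker cell type: the level `syn_thre` is set so that a fraction
#' `frac_peaks` of the distribution mass lies above it, and threshold
#' crossings of that level (scanning shallow to deep, with a minimum
#' three-station separation between successive cut-offs) delimit the
#' peaks. In the lobula plate each boundary is the mean of two marker
#' thresholds. The published per-neuropil mass fractions are 0.85
#' (medulla), 0.8 (lobula) and 0.75 (lobula plate).
#'
#' @name layers
NULL

#' Depth distribution of a cell type's synapses
#'
#' Histogram of assigned depth stations for the synapses of one cell type
#' and polarity, optionally subsampled by a factor of 2 (adjacent station
#' pairs merged, so 121 stations become 61).
#'
#' @param assignments Data frame with a `station` column (0-based pin point
#'   index), e.g. from [assign_points_to_pins()], already restricted to the
#'   synapses of interest.
#' @param n_samp Number of depth stations of the neuropil's pins.
#' @param cell_type,polarity Labels recorded on the result.
#' @param subsample Merge adjacent station pairs (factor 2).
#' @return A `depth_distribution`: list with `bins` (counts), `depth`
#'   (station centres in `[0, 1]`), `n_samp`, `subsampled`, `empty` flag.
#' @export
depth_distribution <- function(assignments, n_samp, cell_type = NA_character_,
                               polarity = c("pre", "post"), subsample = FALSE) {
  polarity <- match.arg(polarity)
  counts <- tabulate(assignments$station + 1L, nbins = n_samp)
  depth <- (seq_len(n_samp) - 1) / (n_samp - 1)
  if (subsample) {
    idx <- ceiling(seq_len(n_samp) / 2)
    counts <- as.vector(tapply(counts, idx, sum))
    depth <- as.vector(tapply(depth, idx, mean))
  }
  structure(list(bins = counts, depth = depth, n_samp = n_samp,
                 subsampled = subsample, cell_type = cell_type,
                 polarity = polarity, empty = sum(counts) == 0),
            class = "depth_distribution")
}

#' Peak cut-offs of a 1D synapse distribution
#'
#' `syn_thre` is the largest observed bin level such that the fraction of
#' the distribution mass strictly above it is at least `frac_peaks`.
#' Scanning depths in ascending order, an up-crossing of `syn_thre` opens a
#' peak (lower cut-off) and the next down-crossing closes it (upper
#' cut-off); every cut-off must lie at least three depth stations from the
#' previous one, which merges narrowly separated peaks. The result is
#' invariant to uniform rescaling of the counts.
#'
#' @param dist A [depth_distribution()], or a bare numeric vector of counts.
#' @param frac_peaks Fraction of mass required above the threshold,
#'   in (0, 1).
#' @param min_sep Minimum separation between successive cut-offs, in depth
#'   stations of the distribution as given.
#' @param syn_thre Optional explicit threshold level overriding the
#'   `frac_peaks` computation; a distribution entirely below the threshold
#'   yields no peaks.
#' @return Data frame with one row per peak: `lower`, `upper` (depth
#'   values) and `lower_idx`, `upper_idx` (station indices).
#' @export
find_peak_cutoffs <- function(dist, frac_peaks, min_sep = 3L, syn_thre = NULL) {
  if (!(frac_peaks > 0 && frac_peaks < 1)) {
    stop_hexpin("`frac_peaks` must lie in (0, 1)", "invalid_parameter")
  }
  if (inherits(dist, "depth_distribution")) {
    counts <- dist$bins
    depth <- dist$depth
  } else {
    counts <- as.numeric(dist)
    depth <- (seq_along(counts) - 1) / max(1, length(counts) - 1)
  }
  total <- sum(counts)
  empty <- data.frame(lower = numeric(), upper = numeric(),
                      lower_idx = integer(), upper_idx = integer())
  if (total == 0) return(empty)
  if (is.null(syn_thre)) {
    # largest candidate level with at least frac_peaks of the mass above it
    levels <- sort(unique(c(0, counts)))
    frac_above <- vapply(levels, function(l) sum(counts[counts > l]) / total,
                         numeric(1))
    ok <- levels[frac_above >= frac_peaks]
    if (!length(ok)) return(empty)
    syn_thre <- max(ok)
  }

  above <- counts > syn_thre
  if (!any(above)) return(empty)
  n <- length(counts)
  # runs of above-threshold stations; runs closer than min_sep merge,
  # which also keeps successive cut-offs at least min_sep apart
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- cbind(starts[r$values], ends[r$values])
  merged <- runs[1, , drop = FALSE]
  for (k in seq_len(nrow(runs))[-1]) {
    if (runs[k, 1] - merged[nrow(merged), 2] < min_sep) {
      merged[nrow(merged), 2] <- runs[k, 2]
    } else {
      merged <- rbind(merged, runs[k, ])
    }
  }
  # a peak's upper cut-off sits at least min_sep past its lower cut-off
  merged[, 2] <- pmin(pmax(merged[, 2], merged[, 1] + min_sep), n)
  out <- merged
  data.frame(lower = depth[out[, 1]], upper = depth[out[, 2]],
             lower_idx = out[, 1], upper_idx = out[, 2])
}

#' Build a layer scheme from marker cut-offs
#'
#' Each marker spec names a cell type and polarity, a peak index in that
#' type's depth distribution and which side of the peak (`"lower"` or
#' `"upper"` cut-off) supplies the depth threshold. In lobula-plate mode
#' the marker specs are consumed in consecutive pairs and each boundary is
#' the mean of the two thresholds.
#'
#' @param marker_specs Data frame with columns `cell_type`, `polarity`,
#'   `peak`, `side`.
#' @param dists Named list of [depth_distribution()] objects, keyed
#'   `"type.polarity"` (e.g. `"Mi1.pre"`).
#' @param layer_names Names for the `length(boundaries) + 1` layers.
#' @param neuropil Label recorded on the scheme.
#' @param frac_peaks Mass fraction passed to [find_peak_cutoffs()].
#' @param lobula_plate_mode Average consecutive threshold pairs.
#' @return A `layer_scheme`: list with strictly increasing `boundaries` in
#'   (0, 1) and `layers` names partitioning `[0, 1]`.
#' @export
build_layer_scheme <- function(marker_specs, dists, layer_names = NULL,
                               neuropil = "ME", frac_peaks = 0.85,
                               lobula_plate_mode = FALSE) {
  thresholds <- vapply(seq_len(nrow(marker_specs)), function(i) {
    ms <- marker_specs[i, ]
    key <- paste(ms$cell_type, ms$polarity, sep = ".")
    d <- dists[[key]]
    if (is.null(d)) {
      stop_hexpin(sprintf("no depth distribution for marker '%s'", key),
                  "marker_resolution")
    }
    pk <- find_peak_cutoffs(d, frac_peaks)
    if (nrow(pk) < ms$peak) {
      stop_hexpin(sprintf("marker '%s': no peak %d (found %d)", key, ms$peak,
                          nrow(pk)), "marker_resolution")
    }
    if (ms$side == "lower") pk$lower[ms$peak] else pk$upper[ms$peak]
  }, numeric(1))
  if (lobula_plate_mode) {
    if (length(thresholds) %% 2 != 0) {
      stop_hexpin("lobula-plate mode needs marker specs in pairs",
                  "marker_resolution")
    }
    thresholds <- colMeans(matrix(thresholds, nrow = 2))
  }
  boundaries <- sort(unique(thresholds))
  if (is.null(layer_names)) {
    layer_names <- paste0("L", seq_len(length(boundaries) + 1))
  }
  if (length(layer_names) != length(boundaries) + 1) {
    stop_hexpin("need one more layer name than boundaries", "invalid_parameter")
  }
  structure(list(neuropil = neuropil, boundaries = boundaries,
                 layers = layer_names),
            class = "layer_scheme")
}

#' @export
print.layer_scheme <- function(x, ...) {
  cat(sprintf("<layer_scheme> %s: %s\n", x$neuropil,
              paste(x$layers, collapse = " | ")))
  cat("boundaries:", paste(signif(x$boundaries, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Assign depths to layers
#'
#' Half-open interval lookup `[b_k, b_{k+1})`: a depth equal to a boundary
#' falls in the deeper layer; depth 1 maps to the last layer.
#'
#' @param depth Numeric vector of depths in `[0, 1]`.
#' @param scheme A [build_layer_scheme()] result.
#' @return Character vector of layer names.
#' @export
assign_layer <- function(depth, scheme) {
  if (any(depth < 0 | depth > 1, na.rm = TRUE)) {
    stop_hexpin("depths must lie in [0, 1]", "invalid_depth")
  }
  idx <- findInterval(depth, scheme$boundaries) + 1L
  scheme$layers[idx]
}
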