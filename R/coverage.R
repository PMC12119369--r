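#' Column innervation, trimming and spatial coverage
#'
#' Columnar neurons have a clear home column, but stray synapses inflate
#' naive column counts. Per type, the columns of each neuron are ranked by
#' synapse count, the median cumulative-fraction curve across neurons is
#' formed, and a knee finder (kneedle, concave increasing, S = 1) picks the
#' rank `rank*` of highest curvature; synapses in columns with fewer
#' synapses than the neuron's own rank-`rank*` column are discarded. The
#' trimmed assignments summarize cell size (median columns per cell) and
#' the coverage factor (mean cells per occupied column); columnar
#' completeness (occupied / total columns) and convex-hull column area use
#' the untrimmed occupancy.
#'
#' @name coverage
NULL

#' Cumulative synapse-fraction curves over column ranks
#'
#' Per neuron, columns are ranked by synapse count (summed over depth) and
#' the cumulative fraction of the neuron's synapses is accumulated over
#' ranks; the type-level curve is the element-wise median across neurons,
#' with shorter curves padded with 1 beyond their last rank.
#'
#' @param column_counts List (one entry per neuron) of per-column synapse
#'   counts (named or unnamed numeric vectors); neurons with zero synapses
#'   are dropped with a warning.
#' @return List with `curves` (per neuron) and `median` (type-level curve).
#' @export
cumulative_fraction_curve <- function(column_counts) {
  tot <- vapply(column_counts, sum, numeric(1))
  if (any(tot == 0)) {
    warning(sum(tot == 0), " neuron(s) with zero synapses excluded")
    column_counts <- column_counts[tot > 0]
  }
  if (!length(column_counts)) {
    return(list(curves = list(), median = numeric(0)))
  }
  curves <- lapply(column_counts, function(ct) {
    ct <- sort(as.numeric(ct), decreasing = TRUE)
    cumsum(ct) / sum(ct)
  })
  len <- max(vapply(curves, length, integer(1)))
  padded <- vapply(curves, function(cv) c(cv, rep(1, len - length(cv))),
                   numeric(len))
  med <- if (len == 1) stats::median(padded) else apply(padded, 1, stats::median)
  list(curves = curves, median = as.numeric(med))
}

# kneedle knee detection on a concave increasing curve given as y over
# x = 0..n (both normalized internally); returns the knee x or NA
kneedle_knee <- function(x, y, S = 1) {
  if (length(x) < 3) return(NA_real_)
  xn <- (x - min(x)) / (max(x) - min(x))
  yn <- (y - min(y)) / if (max(y) > min(y)) (max(y) - min(y)) else 1
  d <- yn - xn
  n <- length(d)
  interior <- seq(2L, n - 1L)
  lmax <- interior[d[interior] >= d[interior - 1L] & d[interior] > d[interior + 1L]]
  if (!length(lmax)) return(NA_real_)
  thresh_drop <- S * mean(diff(xn))
  for (k in seq_along(lmax)) {
    i <- lmax[k]
    Tk <- d[i] - thresh_drop
    stop_at <- if (k < length(lmax)) lmax[k + 1L] else n
    j <- i + 1L
    while (j <= stop_at) {
      if (d[j] < Tk) return(x[i])
      j <- j + 1L
    }
  }
  NA_real_
}

#' Trimming rank from a median cumulative-fraction curve
#'
#' Prepends the point (0, 0), runs kneedle (concave, increasing, S = 1) and
#' returns the knee rank. If the median cumulative fraction at the knee is
#' below 0.775 (or no knee exists), the rank falls back to the first rank
#' whose median cumulative fraction reaches 0.995, or the rank of the curve
#' maximum when 0.995 is never reached.
#'
#' @param median_curve Non-decreasing numeric vector in `[0, 1]` (value at
#'   rank r = median cumulative fraction).
#' @return Integer `rank*`; attribute `"method"` records `"knee"` or
#'   `"fallback"`.
#' @export
knee_rank <- function(median_curve) {
  r <- length(median_curve)
  if (r == 0) stop_hexpin("empty curve", "invalid_parameter")
  if (r == 1) return(structure(1L, method = "knee"))
  knee <- kneedle_knee(0:r, c(0, median_curve))
  if (!is.na(knee) && knee >= 1 && median_curve[knee] >= 0.775) {
    return(structure(as.integer(knee), method = "knee"))
  }
  hit <- which(median_curve >= 0.995)
  rank <- if (length(hit)) hit[1] else which.max(median_curve)
  structure(as.integer(rank), method = "fallback")
}

#' Trim a neuron's synapses to its strong columns
#'
#' Keeps synapses in columns whose synapse count is at least the count of
#' the neuron's own rank-`rank*` column, so tied columns are retained
#' together; when `rank*` exceeds the neuron's occupied columns nothing is
#' discarded.
#'
#' @param column_counts Named numeric vector of the neuron's per-column
#'   synapse counts.
#' @param rank_star Trimming rank for the type.
#' @return The retained subset of `column_counts`.
#' @export
trim_neuron <- function(column_counts, rank_star) {
  if (!length(column_counts)) return(column_counts)
  cutoff <- sort(as.numeric(column_counts), decreasing = TRUE)[
    min(rank_star, length(column_counts))]
  column_counts[column_counts >= cutoff]
}

hex_hull_area <- function(p, q) {
  # planar embedding with unit column spacing; area in column-area units
  # (one column occupies sqrt(3)/2 in this embedding)
  xy <- axial_to_cart(p, q, 1)
  u <- unique(as.data.frame(xy))
  if (nrow(u) < 3) return(NA_real_)
  h <- grDevices::chull(u$x, u$y)
  if (length(h) < 3) return(NA_real_)
  hx <- u$x[h]; hy <- u$y[h]
  a <- abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
  if (a == 0) return(NA_real_)
  a / (sqrt(3) / 2)
}

#' Spatial coverage summary for one cell type
#'
#' Computes, for one type in one neuropil: `cell_size`, the median trimmed
#' column count per cell; `coverage_factor`, the mean number of cells
#' contributing (trimmed) synapses per occupied column; `completeness`,
#' untrimmed occupied columns over total lattice columns; and
#' `column_area`, the convex hull of the occupied coordinates in column
#' units (or the occupied-column count for `area_by_count` types where a
#' hull is a poor fit, and for degenerate hulls).
#'
#' @param assignments Data frame `neuron_id`, `p`, `q`, one row per synapse
#'   of the type (untrimmed).
#' @param grid The column lattice (for the total column count).
#' @param type Label recorded on the summary.
#' @param rank_star Optional fixed trimming rank; computed from the data
#'   via [knee_rank()] when omitted.
#' @param area_by_count Report occupied-column count instead of hull area.
#' @return A one-row data frame: `type`, `n_cells`, `rank_star`,
#'   `cell_size`, `coverage_factor`, `completeness`, `column_area`.
#' @export
coverage_summary <- function(assignments, grid, type = NA_character_,
                             rank_star = NULL, area_by_count = FALSE) {
  if (nrow(assignments) == 0) {
    return(data.frame(type = type, n_cells = 0L, rank_star = NA_integer_,
                      cell_size = NA_real_, coverage_factor = NA_real_,
                      completeness = 0, column_area = NA_real_))
  }
  key <- hex_key(assignments$p, assignments$q)
  per_neuron <- lapply(split(key, assignments$neuron_id), function(k) {
    c(table(k))
  })
  if (is.null(rank_star)) {
    med <- cumulative_fraction_curve(per_neuron)$median
    rank_star <- knee_rank(med)
  }
  trimmed <- lapply(per_neuron, trim_neuron, rank_star = rank_star)
  sizes <- vapply(trimmed, length, integer(1))
  occupied_trim <- unlist(lapply(trimmed, names), use.names = FALSE)
  coverage_factor <- length(occupied_trim) / length(unique(occupied_trim))
  occupied_raw <- unique(key)
  pq <- do.call(rbind, strsplit(occupied_raw, ","))
  area <- if (area_by_count) length(occupied_raw) else
    hex_hull_area(as.integer(pq[, 1]), as.integer(pq[, 2]))
  if (is.na(area)) area <- length(occupied_raw)
  data.frame(type = type, n_cells = length(per_neuron),
             rank_star = as.integer(rank_star),
             cell_size = stats::median(sizes),
             coverage_factor = coverage_factor,
             completeness = length(occupied_raw) / nrow(grid),
             column_area = area)
}
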