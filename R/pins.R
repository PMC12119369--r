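#' Curved column centre lines ("pins")
#'
#' A pin is an ordered list of `N_samp` 3D points modelling one column's
#' centre line from the top of a neuropil to the bottom. Pins are built from
#' the synapse cloud assigned to a column by an eight-step procedure:
#' orient a principal axis top-to-bottom, trim lateral outliers, estimate
#' the surface endpoints, smooth the depth-ordered points with a large
#' running mean, extract the shortest subsequence with bounded consecutive
#' gaps, and resample it uniformly in arc length with a shape-preserving
#' piecewise-cubic (PCHIP) interpolant. Thin neuropils use variant
#' parameter presets and acceptance criteria; missing columns are filled in
#' from lattice neighbours and existing pins regularized against them.
#'
#' @name pins
NULL

#' Pin-construction parameter presets
#'
#' Returns the per-neuropil parameter set used by [build_pin()]. The three
#' presets carry the published values: medulla `f_lat = 2`, `N_PC = 800`,
#' `N_avg = 260`, `N_tang = 7`, `N_samp = 121`; lobula `f_lat = 1.5`,
#' `N_avg = 37`, `N_tang = 2`, `N_samp = 76`; lobula plate `f_lat = 1`,
#' `N_avg = 56`, `N_tang = 2`, `N_samp = 51`.
#'
#' @param neuropil `"medulla"`, `"lobula"` or `"lobula_plate"`.
#' @param ... Named overrides of individual parameters.
#' @return A `pin_params` list: `f_lat`, `N_PC`, `N_avg`, `N_tang`,
#'   `N_samp`, `single_pca_endpoints` (variant A), `use_neuron_means`
#'   (variant B), `lobula_top_median` (lobula top exception), `criteria`
#'   (apply the three pin-acceptance criteria).
#' @export
pin_params <- function(neuropil = c("medulla", "lobula", "lobula_plate"), ...) {
  neuropil <- match.arg(neuropil)
  p <- switch(neuropil,
    medulla = list(f_lat = 2, N_PC = 800L, N_avg = 260L, N_tang = 7L,
                   N_samp = 121L, single_pca_endpoints = FALSE,
                   use_neuron_means = FALSE, lobula_top_median = FALSE,
                   criteria = FALSE),
    lobula = list(f_lat = 1.5, N_PC = 800L, N_avg = 37L, N_tang = 2L,
                  N_samp = 76L, single_pca_endpoints = TRUE,
                  use_neuron_means = FALSE, lobula_top_median = TRUE,
                  criteria = TRUE),
    lobula_plate = list(f_lat = 1, N_PC = 800L, N_avg = 56L, N_tang = 2L,
                        N_samp = 51L, single_pca_endpoints = TRUE,
                        use_neuron_means = TRUE, lobula_top_median = FALSE,
                        criteria = TRUE)
  )
  over <- list(...)
  p[names(over)] <- over
  p$neuropil <- neuropil
  if (p$N_samp < p$N_tang + 1) {
    stop_hexpin("N_samp must be at least N_tang + 1", "invalid_parameter")
  }
  if (any(unlist(p[c("N_PC", "N_avg", "N_tang", "N_samp")]) <= 0)) {
    stop_hexpin("pin parameter counts must be positive", "invalid_parameter")
  }
  structure(p, class = "pin_params")
}

# first intersection of the line origin + t*dir with a plane
line_plane_intersection <- function(origin, dir, plane) {
  den <- sum(dir * plane$normal)
  if (abs(den) < 1e-12) {
    stop_hexpin("axis is parallel to the neuropil surface", "no_intersection")
  }
  t <- sum((plane$point - origin) * plane$normal) / den
  origin + t * dir
}

#' Drop lateral outliers from a column's synapse cloud
#'
#' Distances `l_i` are measured from the centroid in the PC2-PC3 plane of
#' the cloud's own PCA; points with `l_i` exceeding `f_lat` times the
#' root-mean-square lateral distance are dropped. Points that look like
#' they belong to a neighbouring column are removed this way while the
#' column's own cloud is retained; a cloud with zero lateral spread is
#' retained in full.
#'
#' @param points n x 3 matrix, n >= 3.
#' @param f_lat Lateral trim factor.
#' @return The retained points, with the kept row indices as attribute
#'   `"kept"`.
#' @export
trim_lateral_outliers <- function(points, f_lat) {
  points <- as.matrix(points)
  if (nrow(points) < 3) {
    stop_hexpin("need at least 3 points to trim", "insufficient_data")
  }
  pc <- stats::prcomp(points, center = TRUE, scale. = FALSE)
  kept <- lateral_keep_index(points, pc$rotation, colMeans(points), f_lat)
  if (!length(kept)) stop_hexpin("all points removed as lateral outliers", "degenerate_column")
  structure(points[kept, , drop = FALSE], kept = kept)
}

# indices retained by the lateral trim rule given a PCA basis
lateral_keep_index <- function(points, rotation, center, f_lat) {
  sc <- sweep(points, 2, center) %*% rotation[, 2:3, drop = FALSE]
  l <- sqrt(rowSums(sc^2))
  sigma <- sqrt(mean(l^2))
  which(l <= f_lat * sigma)
}

#' Estimate the surface endpoints of a column axis
#'
#' Medulla mode fits separate principal axes to the top fraction
#' (`t_i < 0.1`, falling back to the `N_PC` smallest `t_i` when that
#' fraction is too small) and bottom fraction (`t_i > 0.2`, or `N_PC`
#' largest) of the cloud and intersects each with its surface. With
#' `single_pca_endpoints` one PCA of all points (or of per-neuron mean
#' points with `use_neuron_means`) supplies both intersections; with
#' `lobula_top_median` the top endpoint is instead the projection onto that
#' axis of the componentwise median of the `N_avg` shallowest points,
#' avoiding surface ridges.
#'
#' @param points n x 3 matrix of (already trimmed) synapse positions.
#' @param surfaces List with `top` and `bottom` planes, each
#'   `list(point, normal)`.
#' @param params A [pin_params()] object.
#' @param t Normalized axial positions of `points` (-1 top to +1 bottom);
#'   computed from the cloud's own PCA when omitted.
#' @param axis Optional list(origin, direction) overriding the PCA axis
#'   (used for the single-PCA variants).
#' @param neuron_ids Optional neuron id per point (variant B).
#' @return List with `r_top`, `r_bottom`, `t`, `direction`.
#' @export
estimate_endpoints <- function(points, surfaces, params, t = NULL,
                               axis = NULL, neuron_ids = NULL) {
  points <- as.matrix(points)
  if (is.null(axis)) {
    pca_input <- points
    if (isTRUE(params$use_neuron_means) && !is.null(neuron_ids)) {
      pca_input <- do.call(rbind, lapply(split(seq_len(nrow(points)), neuron_ids),
                                         function(i) colMeans(points[i, , drop = FALSE])))
    }
    ax <- compute_proto_axis(pca_input,
                             orient = surfaces$bottom$point - surfaces$top$point)
    axis <- list(origin = ax$origin, direction = ax$direction)
  }
  if (is.null(t)) {
    t <- normalized_axial_position(points, axis, surfaces)
  }
  if (isTRUE(params$single_pca_endpoints)) {
    r_bottom <- line_plane_intersection(axis$origin, axis$direction, surfaces$bottom)
    if (isTRUE(params$lobula_top_median)) {
      idx <- order(t)[seq_len(min(params$N_avg, length(t)))]
      med <- apply(points[idx, , drop = FALSE], 2, stats::median)
      # orthogonal projection of the median position onto the axis
      s <- sum((med - axis$origin) * axis$direction)
      r_top <- axis$origin + s * axis$direction
    } else {
      r_top <- line_plane_intersection(axis$origin, axis$direction, surfaces$top)
    }
  } else {
    top_idx <- which(t < 0.1)
    if (length(top_idx) < params$N_PC) {
      top_idx <- order(t)[seq_len(min(params$N_PC, length(t)))]
    }
    bot_idx <- which(t > 0.2)
    if (length(bot_idx) < params$N_PC) {
      bot_idx <- order(t, decreasing = TRUE)[seq_len(min(params$N_PC, length(t)))]
    }
    sub_axis <- function(idx) {
      ax <- compute_proto_axis(points[idx, , drop = FALSE],
                               orient = axis$direction)
      list(origin = ax$origin, direction = ax$direction)
    }
    ta <- sub_axis(top_idx)
    ba <- sub_axis(bot_idx)
    r_top <- line_plane_intersection(ta$origin, ta$direction, surfaces$top)
    r_bottom <- line_plane_intersection(ba$origin, ba$direction, surfaces$bottom)
  }
  list(r_top = r_top, r_bottom = r_bottom, t = t, direction = axis$direction)
}

# normalized projection onto an axis: -1 at the top surface, +1 at the bottom
normalized_axial_position <- function(points, axis, surfaces) {
  proj <- as.vector(sweep(as.matrix(points), 2, axis$origin) %*% axis$direction)
  p_top <- line_plane_intersection(axis$origin, axis$direction, surfaces$top)
  p_bot <- line_plane_intersection(axis$origin, axis$direction, surfaces$bottom)
  s_top <- sum((p_top - axis$origin) * axis$direction)
  s_bot <- sum((p_bot - axis$origin) * axis$direction)
  -1 + 2 * (proj - s_top) / (s_bot - s_top)
}

#' Smooth depth-ordered points with a running mean
#'
#' Builds the smoothed list from the rank-ordered cloud: the first and last
#' elements (the surface endpoints) are preserved exactly, and every
#' interior element is replaced by the mean of itself and its `N_avg`
#' nearest neighbours in list order (window truncated at the list ends).
#'
#' @param points Interior points, already rank-ordered by axial position.
#' @param r_top,r_bottom Endpoint 3D points.
#' @param N_avg Number of neighbours averaged with each element.
#' @return Matrix of smoothed points, endpoints first and last.
#' @export
smooth_ordered_points <- function(points, r_top, r_bottom, N_avg) {
  points <- as.matrix(points)
  if (nrow(points) < 1) return(rbind(r_top, r_bottom, deparse.level = 0))
  lp <- rbind(r_top, points, r_bottom, deparse.level = 0)
  n <- nrow(lp)
  half <- max(1L, N_avg %/% 2L)
  cs <- apply(rbind(0, lp), 2, cumsum)  # cs[i+1,] = sum of first i rows
  out <- lp
  for (i in seq(2L, n - 1L)) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    out[i, ] <- (cs[hi + 1L, ] - cs[lo, ]) / (hi - lo + 1L)
  }
  out
}

#' Shortest order-preserving sublist with bounded gaps
#'
#' Finds a minimum-length subsequence of the smoothed list that starts at
#' its first element, ends at its last, and has all consecutive Euclidean
#' gaps at most `d_max`. Solved exactly by dynamic programming over the
#' ordered list (O(n^2)); among equally short solutions the earliest
#' indices win.
#'
#' @param l Matrix of points, first row `r_top`, last row `r_bottom`.
#' @param d_max Maximum allowed consecutive gap.
#' @return The selected points, with row indices as attribute `"indices"`.
#' @export
shortest_bounded_sublist <- function(l, d_max) {
  l <- as.matrix(l)
  n <- nrow(l)
  if (n < 2) stop_hexpin("need at least the two endpoints", "invalid_parameter")
  best <- rep(Inf, n)
  prev <- rep(NA_integer_, n)
  best[1] <- 1
  for (i in 2:n) {
    d2 <- colSums((t(l[seq_len(i - 1), , drop = FALSE]) - l[i, ])^2)
    feas <- which(d2 <= d_max^2 & is.finite(best[seq_len(i - 1)]))
    if (length(feas)) {
      cand <- best[feas] + 1
      j <- feas[which.min(cand)]  # earliest index among minimal lengths
      best[i] <- best[j] + 1
      prev[i] <- j
    }
  }
  if (!is.finite(best[n])) {
    stop_hexpin("no subsequence with all gaps within d_max", "infeasible_pin")
  }
  idx <- integer(0)
  i <- n
  while (!is.na(i)) {
    idx <- c(i, idx)
    i <- prev[i]
  }
  structure(l[idx, , drop = FALSE], indices = idx)
}

#' Resample a polyline uniformly in arc length with PCHIP
#'
#' Each spatial coordinate is interpolated by a piecewise cubic Hermite
#' interpolating polynomial against cumulative arc length and sampled at
#' `n_samp` uniform arc-length stations; the shape-preserving interpolant
#' does not overshoot the data range and the endpoints are reproduced
#' exactly.
#'
#' @param o Matrix of at least 2 polyline points.
#' @param n_samp Number of output samples.
#' @return n_samp x 3 matrix.
#' @export
resample_pin <- function(o, n_samp) {
  o <- as.matrix(o)
  if (nrow(o) < 2) stop_hexpin("need at least 2 points to resample", "invalid_parameter")
  seg <- sqrt(rowSums(diff(o)^2))
  # collapse consecutive duplicate points so arc length is strictly increasing
  keep <- c(TRUE, seg > 0)
  o <- o[keep, , drop = FALSE]
  if (nrow(o) < 2) {
    return(matrix(rep(o[1, ], n_samp), ncol = 3, byrow = TRUE,
                  dimnames = list(NULL, colnames(o))))
  }
  s <- c(0, cumsum(sqrt(rowSums(diff(o)^2))))
  st <- seq(0, s[length(s)], length.out = n_samp)
  out <- vapply(seq_len(ncol(o)), function(j) pracma::pchip(s, o[, j], st),
                numeric(n_samp))
  colnames(out) <- colnames(o)
  out[1, ] <- o[1, ]
  out[n_samp, ] <- o[nrow(o), ]
  out
}

new_pin <- function(p, q, points, provenance = "built") {
  structure(list(p = as.integer(p), q = as.integer(q),
                 points = unname(as.matrix(points)), provenance = provenance),
            class = "pin")
}

#' @export
print.pin <- function(x, ...) {
  cat(sprintf("<pin (%d,%d)> %d points, %s\n", x$p, x$q, nrow(x$points),
              x$provenance))
  invisible(x)
}

pin_rejection <- function(p, q, reason) {
  structure(list(p = as.integer(p), q = as.integer(q), reason = reason),
            class = "pin_rejection")
}

#' Build one column pin from its synapse cloud
#'
#' Runs the full eight-step pipeline: principal axis oriented top to
#' bottom; lateral outlier trim; axial positions `t_i`; endpoint
#' estimation; running-mean smoothing of the depth-ordered cloud; shortest
#' bounded-gap subsequence with `d_max = ||r_top - r_bottom|| / N_tang`;
#' PCHIP resampling to `N_samp` points. For the thin neuropils
#' (`params$criteria`) the pin is rejected unless (i) at least `N_avg`
#' points survive the trim, (ii) the centroid of the 5% shallowest points
#' lies within `d_max` of `r_top`, and (iii) the centroid of the 5% deepest
#' points lies within `d_max` of `r_bottom`.
#'
#' @param points n x 3 synapse positions assigned to the column.
#' @param coordinate Integer `(p, q)` pair.
#' @param surfaces Neuropil surfaces (`list(top, bottom)` planes), e.g.
#'   `attr(grid, "surfaces")`.
#' @param params A [pin_params()] object.
#' @param neuron_ids Optional neuron id per point (variant B pools points
#'   to per-neuron means before PCA).
#' @return A `pin`, or a `pin_rejection` with a `reason` field.
#' @export
build_pin <- function(points, coordinate, surfaces, params,
                      neuron_ids = NULL) {
  points <- as.matrix(points)
  p <- coordinate[[1]]; q <- coordinate[[2]]
  if (nrow(points) < 3) return(pin_rejection(p, q, "insufficient-points"))

  pca_input <- points
  ids <- neuron_ids
  if (isTRUE(params$use_neuron_means) && !is.null(neuron_ids)) {
    pca_input <- do.call(rbind, lapply(split(seq_len(nrow(points)), neuron_ids),
                                       function(i) colMeans(points[i, , drop = FALSE])))
  }
  if (nrow(unique(pca_input)) < 3) return(pin_rejection(p, q, "degenerate-cloud"))
  ax0 <- compute_proto_axis(pca_input,
                            orient = surfaces$bottom$point - surfaces$top$point)
  pc <- stats::prcomp(pca_input, center = TRUE, scale. = FALSE)

  # lateral trim in the PC2-PC3 plane of the step-2 basis
  kept <- lateral_keep_index(points, pc$rotation, ax0$origin, params$f_lat)
  if (!length(kept)) return(pin_rejection(p, q, "degenerate-column"))
  r <- points[kept, , drop = FALSE]
  ids <- if (!is.null(ids)) ids[kept] else NULL
  if (isTRUE(params$criteria) && nrow(r) < params$N_avg) {
    return(pin_rejection(p, q, "criterion-i"))
  }

  axis <- list(origin = ax0$origin, direction = ax0$direction)
  t <- normalized_axial_position(r, axis, surfaces)
  ep <- estimate_endpoints(r, surfaces, params, t = t, axis = axis,
                           neuron_ids = ids)
  d_max <- sqrt(sum((ep$r_top - ep$r_bottom)^2)) / params$N_tang

  if (isTRUE(params$criteria)) {
    k <- max(1L, ceiling(0.05 * nrow(r)))
    sh <- colMeans(r[order(t)[seq_len(k)], , drop = FALSE])
    dp <- colMeans(r[order(t, decreasing = TRUE)[seq_len(k)], , drop = FALSE])
    if (sqrt(sum((sh - ep$r_top)^2)) > d_max) return(pin_rejection(p, q, "criterion-ii"))
    if (sqrt(sum((dp - ep$r_bottom)^2)) > d_max) return(pin_rejection(p, q, "criterion-iii"))
  }

  l <- smooth_ordered_points(r[order(t), , drop = FALSE],
                             ep$r_top, ep$r_bottom, params$N_avg)
  o <- tryCatch(shortest_bounded_sublist(l, d_max),
                hexpin_error = function(e) NULL)
  if (is.null(o)) return(pin_rejection(p, q, "infeasible-pin"))
  new_pin(p, q, resample_pin(o, params$N_samp))
}

#' Build pins for every column of an assigned synapse table
#'
#' @param synapses Data frame with `x`, `y`, `z`, `p`, `q` (column
#'   assignment) and optionally `neuron_id`.
#' @param surfaces Neuropil surfaces.
#' @param params A [pin_params()] object.
#' @return A `pin_set`: named list of pins (keys `"p,q"`), with rejections
#'   recorded in attribute `"rejections"`.
#' @export
build_pins <- function(synapses, surfaces, params) {
  stopifnot(all(c("x", "y", "z", "p", "q") %in% names(synapses)))
  pins <- list()
  rej <- list()
  for (chunk in split(synapses, hex_key(synapses$p, synapses$q))) {
    res <- build_pin(as.matrix(chunk[, c("x", "y", "z")]),
                     c(chunk$p[1], chunk$q[1]), surfaces, params,
                     neuron_ids = chunk$neuron_id)
    key <- hex_key(chunk$p[1], chunk$q[1])
    if (inherits(res, "pin")) pins[[key]] <- res else rej[[key]] <- res$reason
  }
  structure(pins, class = "pin_set", rejections = rej,
            N_samp = params$N_samp, neuropil = params$neuropil)
}

#' @export
print.pin_set <- function(x, ...) {
  cat(sprintf("<pin_set> %d pins of %d points (%s), %d rejected\n",
              length(x), attr(x, "N_samp") %||% NA_integer_,
              attr(x, "neuropil") %||% "?",
              length(attr(x, "rejections"))))
  invisible(x)
}

#' Regularize pins against lattice neighbours and fill in missing columns
#'
#' Iterates two steps until no pin is filled in (or `max_iter`):
#' regularization replaces every existing pin by the componentwise median,
#' across all pins whose hexagonal coordinates differ by at most 2
#' (`max(|dp|, |dq|) <= 2`, the pin itself included), of their
#' offset-from-first-point lists, re-anchored at the pin's own first point;
#' filling-in creates a missing coordinate's pin as the componentwise
#' median of its 4 axial +-1 neighbours when all exist, else of the 2
#' neighbours along a single axis. Coordinates with no qualifying
#' neighbours stay missing and are recorded.
#'
#' @param pins A `pin_set`.
#' @param grid The full column lattice (a [generate_grid()] data frame, or
#'   any data frame with `p`, `q`).
#' @param max_iter Iteration cap.
#' @return The completed `pin_set`; attribute `"missing"` lists coordinates
#'   that could not be filled, attribute `"iterations"` the rounds used.
#' @export
regularize_and_fill <- function(pins, grid, max_iter = 10L) {
  if (length(pins) == 0) stop_hexpin("need at least one built pin", "insufficient_data")
  key_of <- function(pin) hex_key(pin$p, pin$q)
  iterations <- 0L
  repeat {
    iterations <- iterations + 1L
    have <- do.call(rbind, lapply(pins, function(x) c(x$p, x$q)))
    # regularization of existing pins
    new_pins <- pins
    for (k in names(pins)) {
      a <- pins[[k]]
      nb <- which(pmax(abs(have[, 1] - a$p), abs(have[, 2] - a$q)) <= 2)
      offs <- lapply(nb, function(i) {
        pts <- pins[[i]]$points
        sweep(pts, 2, pts[1, ])
      })
      med <- apply(simplify2array(offs), c(1, 2), stats::median)
      prov <- if (a$provenance == "filled") "filled" else "regularized"
      new_pins[[k]] <- new_pin(a$p, a$q, sweep(med, 2, a$points[1, ], "+"), prov)
    }
    pins <- new_pins
    # fill in missing coordinates
    missing <- grid[!(hex_key(grid$p, grid$q) %in% names(pins)), c("p", "q")]
    filled <- 0L
    for (i in seq_len(nrow(missing))) {
      p <- missing$p[i]; q <- missing$q[i]
      four <- list(c(p - 1, q), c(p + 1, q), c(p, q - 1), c(p, q + 1))
      keys4 <- vapply(four, function(z) hex_key(z[1], z[2]), character(1))
      use <- NULL
      if (all(keys4 %in% names(pins))) {
        use <- keys4
      } else if (all(keys4[1:2] %in% names(pins))) {
        use <- keys4[1:2]
      } else if (all(keys4[3:4] %in% names(pins))) {
        use <- keys4[3:4]
      }
      if (is.null(use)) next
      stacks <- simplify2array(lapply(use, function(k) pins[[k]]$points))
      med <- apply(stacks, c(1, 2), stats::median)
      pins[[hex_key(p, q)]] <- new_pin(p, q, med, "filled")
      filled <- filled + 1L
    }
    if (filled == 0L || iterations >= max_iter) break
  }
  still_missing <- grid[!(hex_key(grid$p, grid$q) %in% names(pins)), c("p", "q")]
  structure(pins[order(names(pins))], class = "pin_set",
            rejections = attr(pins, "rejections"),
            N_samp = nrow(pins[[1]]$points),
            neuropil = attr(pins, "neuropil"),
            missing = still_missing, iterations = iterations)
}

#' Assign points to (column, depth) by nearest pin point
#'
#' Every point is assigned the coordinate of the pin containing the
#' globally nearest pin point; its depth is that pin point's index
#' normalized to `[0, 1]` (`index / (N_samp - 1)`). The assignment
#' partitions any point set.
#'
#' @param points Data frame with `x`, `y`, `z` or an n x 3 matrix.
#' @param pins A `pin_set`.
#' @return Data frame with `p`, `q`, `depth`, `station` (0-based pin point
#'   index) and `distance`.
#' @export
assign_points_to_pins <- function(points, pins) {
  if (length(pins) == 0) stop_hexpin("`pins` must be non-empty", "invalid_parameter")
  pts <- if (is.data.frame(points)) as.matrix(points[, c("x", "y", "z")]) else as.matrix(points)
  ord <- order(names(pins))
  pins <- pins[ord]
  n_samp <- nrow(pins[[1]]$points)
  ref <- do.call(rbind, lapply(pins, `[[`, "points"))
  owner <- rep(seq_along(pins), each = n_samp)
  station <- rep(seq_len(n_samp) - 1L, times = length(pins))
  if (nrow(pts) == 0) {
    return(data.frame(p = integer(), q = integer(), depth = numeric(),
                      station = integer(), distance = numeric()))
  }
  nn <- nearest_ref_index(pts, ref)
  pi <- owner[nn$index]
  data.frame(
    p = vapply(pins[pi], `[[`, integer(1), "p"),
    q = vapply(pins[pi], `[[`, integer(1), "q"),
    depth = station[nn$index] / (n_samp - 1),
    station = station[nn$index],
    distance = nn$distance,
    row.names = NULL
  )
}
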