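#' Anchor assignment by maximum-weight bipartite matching
#'
#' Candidate neurons (e.g. the four T4 classes) are assigned one-to-one to
#' anchor neurons (e.g. Mi1) by maximizing total normalized connection
#' weight, with a spatial veto: a matched pair is rejected when the
#' distance between the anchor's class-directed mean presynapse position
#' and the candidate's mean postsynapse position exceeds a threshold
#' (published gap around 8 um). Anchors with a candidate from every class,
#' at least three of which survive the veto, form valid column groups whose
#' candidate centroids seed downstream pin building.
#'
#' @name matching
NULL

#' Row-normalize a connectivity matrix
#'
#' Divides each row by its sum, leaving all-zero rows zero (their indices
#' are flagged in attribute `"zero_rows"`).
#'
#' @param C Non-negative numeric matrix (anchors x candidates).
#' @return The normalized matrix; row sums are 1 (or 0 for flagged rows).
#' @export
normalize_rows <- function(C) {
  C <- as.matrix(C)
  if (any(C < 0)) stop_hexpin("connectivity matrix must be non-negative", "invalid_input")
  rs <- rowSums(C)
  zero <- which(rs == 0)
  rs[zero] <- 1
  structure(C / rs, zero_rows = zero)
}

#' Maximum-weight bipartite assignment
#'
#' One-to-one partial matching of rows to columns maximizing total weight
#' (rectangular matrices allowed; rows or columns may stay unmatched when
#' dimensions differ or all their weights are zero). Rows and columns are
#' pre-sorted lexicographically by name so ties resolve deterministically.
#'
#' @param C Finite non-negative weight matrix.
#' @return Data frame `row`, `col` (indices into `C`), `weight`; attribute
#'   `"total_weight"` carries the objective.
#' @export
max_weight_assignment <- function(C) {
  C <- as.matrix(C)
  if (!all(is.finite(C))) stop_hexpin("weights must be finite", "invalid_input")
  m <- nrow(C); n <- ncol(C)
  ro <- if (!is.null(rownames(C))) order(rownames(C)) else seq_len(m)
  co <- if (!is.null(colnames(C))) order(colnames(C)) else seq_len(n)
  Cs <- C[ro, co, drop = FALSE]
  ij <- which(Cs > 0, arr.ind = TRUE)
  if (nrow(ij) == 0) {
    out <- data.frame(row = integer(), col = integer(), weight = numeric())
    attr(out, "total_weight") <- 0
    return(out)
  }
  edges <- as.vector(t(cbind(ij[, 1], m + ij[, 2])))
  g <- igraph::make_bipartite_graph(c(rep(FALSE, m), rep(TRUE, n)),
                                    edges = edges)
  igraph::E(g)$weight <- Cs[ij]
  mm <- igraph::max_bipartite_match(g, weights = igraph::E(g)$weight)
  mt <- mm$matching[seq_len(m)]
  matched <- which(!is.na(mt))
  out <- data.frame(row = ro[matched], col = co[mt[matched] - m],
                    weight = C[cbind(ro[matched], co[mt[matched] - m])])
  out <- out[order(out$row), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "total_weight") <- sum(out$weight)
  out
}

#' Reject matched pairs by distance
#'
#' A pair is kept iff the Euclidean distance between its anchor position
#' and candidate position is at most `threshold`; pairs with a missing
#' position are rejected with reason `"missing-position"`.
#'
#' @param pairs Data frame `row`, `col` from [max_weight_assignment()].
#' @param anchor_positions Matrix of anchor positions (rows indexed by
#'   `pairs$row`), e.g. mean presynapse positions toward the candidate
#'   class.
#' @param candidate_positions Matrix of candidate positions (rows indexed
#'   by `pairs$col`), e.g. mean postsynapse positions.
#' @param threshold Distance threshold in the positions' units (nm
#'   internally; the published value is 8 um = 8000 nm).
#' @return `pairs` with added `distance`, `accepted`, `reason` columns.
#' @export
veto_by_distance <- function(pairs, anchor_positions, candidate_positions,
                             threshold) {
  d <- rep(NA_real_, nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    a <- anchor_positions[pairs$row[i], ]
    b <- candidate_positions[pairs$col[i], ]
    if (!anyNA(a) && !anyNA(b)) d[i] <- sqrt(sum((a - b)^2))
  }
  pairs$distance <- d
  pairs$accepted <- !is.na(d) & d <= threshold
  pairs$reason <- ifelse(is.na(d), "missing-position",
                         ifelse(pairs$accepted, "", "too-far"))
  pairs
}

#' Form valid anchor groups from per-class assignments
#'
#' Per-class assignments are computed independently (one matching per
#' candidate class). An anchor forms a valid group when every class
#' assigned it a candidate and at least `min_close` of those survived the
#' distance veto; the surviving candidates' positions become the group's
#' points for pin building.
#'
#' @param assignments Named list (one entry per candidate class) of
#'   [veto_by_distance()] results, each with an added `anchor` column (or
#'   using `row` as the anchor id).
#' @param candidate_positions Named list (per class) of candidate position
#'   matrices.
#' @param n_classes Number of candidate classes required per group
#'   (default: all classes present in `assignments`).
#' @param min_close Minimum accepted pairs per valid group (default 3).
#' @return List of groups: each has `anchor`, `classes`, `points` (matrix
#'   of accepted candidate positions, >= `min_close` rows).
#' @export
form_groups <- function(assignments, candidate_positions,
                        n_classes = length(assignments), min_close = 3L) {
  per_anchor <- list()
  for (cls in names(assignments)) {
    a <- assignments[[cls]]
    anchors <- if ("anchor" %in% names(a)) a$anchor else a$row
    for (i in seq_len(nrow(a))) {
      key <- as.character(anchors[i])
      per_anchor[[key]] <- c(per_anchor[[key]], list(list(
        class = cls, col = a$col[i], accepted = a$accepted[i]
      )))
    }
  }
  groups <- list()
  for (key in names(per_anchor)) {
    entries <- per_anchor[[key]]
    if (length(entries) < n_classes) next
    ok <- Filter(function(e) isTRUE(e$accepted), entries)
    if (length(ok) < min_close) next
    pts <- do.call(rbind, lapply(ok, function(e) {
      candidate_positions[[e$class]][e$col, ]
    }))
    groups[[length(groups) + 1L]] <- list(
      anchor = key,
      classes = vapply(ok, `[[`, character(1), "class"),
      points = pts
    )
  }
  groups
}

#' Mean pre/post synapse positions per neuron
#'
#' Convenience for building the positions consumed by
#' [veto_by_distance()]: the mean presynapse position per anchor neuron and
#' mean postsynapse position per candidate neuron.
#'
#' @param synapses Synapse table (`neuron_id`, `prepost`, `x`, `y`, `z`).
#' @param neuron_ids Neurons to include, in output row order.
#' @param polarity `"pre"` or `"post"`.
#' @return Matrix with one row per neuron id (NA rows for neurons without
#'   synapses of that polarity).
#' @export
mean_synapse_positions <- function(synapses, neuron_ids,
                                   polarity = c("pre", "post")) {
  polarity <- match.arg(polarity)
  s <- synapses[synapses$prepost == polarity, , drop = FALSE]
  out <- matrix(NA_real_, nrow = length(neuron_ids), ncol = 3,
                dimnames = list(as.character(neuron_ids), c("x", "y", "z")))
  mg <- lapply(split(s[, c("x", "y", "z")], s$neuron_id), colMeans)
  hit <- intersect(names(mg), rownames(out))
  if (length(hit)) out[hit, ] <- do.call(rbind, mg[hit])
  out
}
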