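#' Weighted region-to-region connectivity ("projectome")
#'
#' A neuron that receives inputs in region A and sends outputs to region C
#' contributes to the A-to-C connectivity the product of its output count
#' in C and its fraction of inputs in A. Summing these contributions over a
#' neuron group (e.g. all intrinsic or projection neurons) gives a weighted
#' region-to-region matrix; for display, entries are ranked and binned by
#' their share of the cumulative sum, keeping the leading 93.75% by
#' default.
#'
#' @name interregion
NULL

#' Inter-region contribution matrix of one neuron
#'
#' `contribution[A, C] = outputs[C] * inputs[A] / sum(inputs)`. A neuron
#' with zero total inputs contributes nothing (all-zero matrix, flagged via
#' attribute `"no_inputs"`). Row A therefore sums to
#' `inputs[A] / sum(inputs) * sum(outputs)` and column C sums to
#' `outputs[C]`.
#'
#' @param inputs_by_region Named numeric vector of input connection counts.
#' @param outputs_by_region Named numeric vector of output connection
#'   counts.
#' @return Matrix (input regions x output regions).
#' @export
neuron_contribution <- function(inputs_by_region, outputs_by_region) {
  a <- as.numeric(inputs_by_region)
  c_ <- as.numeric(outputs_by_region)
  total_in <- sum(a)
  frac <- if (total_in > 0) a / total_in else rep(0, length(a))
  m <- outer(frac, c_)
  dimnames(m) <- list(names(inputs_by_region), names(outputs_by_region))
  structure(m, no_inputs = total_in == 0)
}

#' Aggregate neuron contributions over a group
#'
#' Element-wise sum of [neuron_contribution()] matrices over the neurons of
#' a group, on a common ordered region list. Connections in regions outside
#' `regions` are pooled under `"unmapped"` with a warning. Column sums of
#' the result equal the group's total output counts per region.
#'
#' @param neuron_ids Neurons of the group.
#' @param connections Connection table (`pre_id`, `post_id`, `weight`,
#'   `roi`); a connection's region is its `roi` (the postsynaptic site's
#'   region, following the database convention), on both the input and the
#'   output side of the scheme.
#' @param regions Ordered character vector of region names.
#' @param group Label stored on the result.
#' @return A `region_matrix`: square matrix over `regions` with attribute
#'   `"group"`.
#' @export
aggregate_group <- function(neuron_ids, connections, regions,
                            group = NA_character_) {
  unmapped <- !(connections$roi %in% regions)
  if (any(unmapped)) {
    warning(sum(unmapped), " connection(s) in unmapped regions pooled under 'unmapped'")
    connections$roi[unmapped] <- "unmapped"
    regions <- c(regions, "unmapped")
  }
  m <- matrix(0, length(regions), length(regions),
              dimnames = list(regions, regions))
  for (id in neuron_ids) {
    ins <- connections[connections$post_id == id, , drop = FALSE]
    outs <- connections[connections$pre_id == id, , drop = FALSE]
    iv <- stats::setNames(numeric(length(regions)), regions)
    ov <- iv
    if (nrow(ins)) {
      t_in <- tapply(ins$weight, ins$roi, sum)
      iv[names(t_in)] <- t_in
    }
    if (nrow(outs)) {
      t_out <- tapply(outs$weight, outs$roi, sum)
      ov[names(t_out)] <- t_out
    }
    m <- m + neuron_contribution(iv, ov)
  }
  structure(m, group = group, class = c("region_matrix", "matrix", "array"))
}

#' Rank and bin inter-region connections by cumulative share
#'
#' Entries are sorted in decreasing order; entries within the leading
#' `cumulative_cut` of the total mass are kept and binned by the
#' cumulative-share band they fall in (default halving bands 50%, 75%,
#' 87.5%, 93.75%).
#'
#' @param m Non-negative matrix.
#' @param cumulative_cut Fraction of total mass to keep (published display
#'   cut 0.9375).
#' @param bands Increasing cumulative-share band edges; the last band edge
#'   should equal `cumulative_cut`.
#' @return List with `kept` (logical mask matrix) and `bin` (integer matrix,
#'   NA outside the kept set).
#' @export
rank_and_bin <- function(m, cumulative_cut = 0.9375,
                         bands = c(0.5, 0.75, 0.875, 0.9375)) {
  if (!(cumulative_cut > 0 && cumulative_cut <= 1)) {
    stop_hexpin("`cumulative_cut` must lie in (0, 1]", "invalid_parameter")
  }
  v <- as.vector(m)
  ord <- order(v, decreasing = TRUE)
  share <- cumsum(v[ord]) / sum(v)
  keep_sorted <- share <= cumulative_cut + 1e-12 & v[ord] > 0
  bin_sorted <- findInterval(share, bands, left.open = TRUE) + 1L
  kept <- matrix(FALSE, nrow(m), ncol(m), dimnames = dimnames(m))
  bin <- matrix(NA_integer_, nrow(m), ncol(m), dimnames = dimnames(m))
  kept[ord] <- keep_sorted
  bin[ord[keep_sorted]] <- bin_sorted[keep_sorted]
  list(kept = kept, bin = bin)
}
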