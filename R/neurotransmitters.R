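#' Neurotransmitter calls from per-synapse probabilities
#'
#' Per-synapse classifier outputs (probability vectors over ACh, Glu,
#' GABA, His, Dop, OA, 5HT) are aggregated upward: a neuron is called with
#' its most frequent presynaptic transmitter when it has at least 50
#' presynapses and confidence at least 0.5; a type is called from the
#' pooled presynapses of its cells at thresholds 100 / 0.5; the consensus
#' call additionally resets aminergic (Dop, OA, 5HT) type calls to unclear
#' unless experimental evidence supports them. Confidence is the modal
#' fraction of per-synapse argmax classes by default; a variant averaging
#' the probability vectors is available behind a switch.
#'
#' @name neurotransmitters
NULL

nt_argmax <- function(probs) {
  probs <- as.matrix(probs)
  NT_CLASSES[max.col(probs, ties.method = "first")]
}

nt_call <- function(probs, min_synapses, confidence_mode) {
  n <- nrow(probs)
  if (n == 0) {
    return(list(call = "unclear", confidence = NA_real_, n_presynapses = 0L))
  }
  if (confidence_mode == "argmax") {
    cls <- nt_argmax(probs)
    tab <- table(factor(cls, levels = NT_CLASSES))
    conf <- max(tab) / n
    winners <- names(tab)[tab == max(tab)]
  } else {
    mp <- colMeans(as.matrix(probs))
    conf <- max(mp)
    winners <- NT_CLASSES[which(mp == conf)]
  }
  # a tie cannot satisfy "most frequent" uniquely
  call <- if (n >= min_synapses && conf >= 0.5 && length(winners) == 1L) {
    winners
  } else {
    "unclear"
  }
  list(call = call, confidence = conf, n_presynapses = as.integer(n))
}

#' Transmitter call for one cell
#'
#' @param probs Matrix or data frame of per-presynapse probability vectors
#'   (columns in [NT_CLASSES] order, e.g. the `prob_*` synapse columns).
#' @param min_synapses Presynapse count threshold (50 at the cell level).
#' @param confidence_mode `"argmax"` (modal fraction of per-synapse argmax
#'   classes) or `"mean_prob"` (argmax and value of the mean probability
#'   vector).
#' @return List `call` (a transmitter or `"unclear"`), `confidence`,
#'   `n_presynapses`.
#' @export
cell_call <- function(probs, min_synapses = 50L,
                      confidence_mode = c("argmax", "mean_prob")) {
  nt_call(as.matrix(probs), min_synapses, match.arg(confidence_mode))
}

#' Transmitter call for a cell type (pooled presynapses)
#'
#' @param probs Probability vectors pooled over all presynapses of the
#'   type's cells.
#' @param min_synapses Pooled presynapse count threshold (100 at the type
#'   level).
#' @inheritParams cell_call
#' @return As [cell_call()].
#' @export
type_call <- function(probs, min_synapses = 100L,
                      confidence_mode = c("argmax", "mean_prob")) {
  nt_call(as.matrix(probs), min_synapses, match.arg(confidence_mode))
}

#' Consensus transmitter call
#'
#' Passes the type call through unchanged except that aminergic calls
#' (Dop, OA, 5HT) without matching experimental support become
#' `"unclear"`; an unclear type call is never upgraded.
#'
#' @param type_call A transmitter name or `"unclear"` (or a [type_call()]
#'   result list).
#' @param experimental_support Character vector of experimentally supported
#'   transmitters for the type (may be empty or carry several, e.g. for
#'   co-transmission).
#' @return The consensus call.
#' @export
consensus_call <- function(type_call, experimental_support = character(0)) {
  call <- if (is.list(type_call)) type_call$call else type_call
  aminergic <- c("Dop", "OA", "5HT")
  if (call %in% aminergic && !(call %in% experimental_support)) {
    return("unclear")
  }
  call
}

#' Synaptic fan-out of a cell type
#'
#' Per-cell ratio of output connections to presynapses, averaged over the
#' cells of the type; polyadic synapses make this ratio exceed 1. Cells
#' with zero presynapses are excluded with a warning.
#'
#' @param presynapse_counts Per-cell presynapse counts.
#' @param output_connection_counts Parallel per-cell output connection
#'   counts.
#' @return Mean ratio.
#' @export
fanout <- function(presynapse_counts, output_connection_counts) {
  stopifnot(length(presynapse_counts) == length(output_connection_counts))
  zero <- presynapse_counts == 0
  if (any(zero)) {
    warning(sum(zero), " cell(s) with zero presynapses excluded from fan-out")
  }
  mean(output_connection_counts[!zero] / presynapse_counts[!zero])
}

#' Per-cell and per-type transmitter calls for a volume
#'
#' Driver applying [cell_call()], [type_call()] and [consensus_call()]
#' across a synapse table.
#'
#' @param synapses Synapse table with `neuron_id`, `prepost` and `prob_*`
#'   columns.
#' @param neurons Neuron table with `neuron_id`, `type`.
#' @param experimental_support Named list: type -> character vector of
#'   supported transmitters.
#' @param confidence_mode See [cell_call()].
#' @return List with `cells` and `types` data frames.
#' @export
nt_call_tables <- function(synapses, neurons,
                           experimental_support = list(),
                           confidence_mode = "argmax") {
  pre <- synapses[synapses$prepost == "pre", , drop = FALSE]
  pcols <- nt_prob_cols()
  cells <- do.call(rbind, lapply(split(pre, pre$neuron_id), function(d) {
    cc <- cell_call(d[, pcols], confidence_mode = confidence_mode)
    data.frame(neuron_id = d$neuron_id[1], call = cc$call,
               confidence = cc$confidence, n_presynapses = cc$n_presynapses)
  }))
  pre$type <- neurons$type[match(pre$neuron_id, neurons$neuron_id)]
  types <- do.call(rbind, lapply(split(pre, pre$type), function(d) {
    tc <- type_call(d[, pcols], confidence_mode = confidence_mode)
    cons <- consensus_call(tc, experimental_support[[d$type[1]]] %||% character(0))
    data.frame(type = d$type[1], call = tc$call, confidence = tc$confidence,
               n_presynapses = tc$n_presynapses, consensus = cons)
  }))
  rownames(cells) <- rownames(types) <- NULL
  list(cells = cells, types = types)
}
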