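#' Connectivity and morphology typing
#'
#' Neurons are grouped into candidate types by hierarchical clustering of
#' feature vectors: aggregate connectivity to named cell types (inputs and
#' outputs separately, restricted to the optic-lobe regions) clustered with
#' Ward linkage on cosine distances, or per-neuron morphology profiles (244
#' features: normalized presynapse and postsynapse counts by depth, and
#' presynaptic/postsynaptic column-innervation counts by depth) clustered
#' on Euclidean distances. Cluster-versus-annotation agreement is
#' summarised as a confusion matrix with the five-category colouring and
#' completeness/homogeneity scores.
#'
#' @name typing
NULL

#' Build per-neuron connectivity feature vectors
#'
#' For every neuron, sums its connection weights to all cells of each named
#' partner type, split into inputs and outputs. Connections with partners
#' typed `"_unclear"` are excluded; partners annotated as fragments of a
#' type (instance `"X_fragment..."`) count under the parent type. When
#' labels carry a `side`, bilateral partner types are split by side. Only
#' connections in `in_regions` (when given) contribute.
#'
#' @param neuron_ids Neurons to featurize.
#' @param connections Connection table (`pre_id`, `post_id`, `weight`,
#'   optionally `roi`).
#' @param labels Data frame `neuron_id`, `type` (and optionally `instance`,
#'   `side`) covering partner neurons, possibly partially.
#' @param in_regions Optional character vector of `roi` values to keep.
#' @return Numeric matrix, rows named by neuron id, columns
#'   `<type>[/<side>]:<in|out>`; neurons with no in-scope connections get a
#'   zero row (flagged in attribute `"zero_rows"`).
#' @export
build_conn_features <- function(neuron_ids, connections, labels,
                                in_regions = NULL) {
  if (!is.null(in_regions) && "roi" %in% names(connections)) {
    connections <- connections[connections$roi %in% in_regions, , drop = FALSE]
  }
  lab <- labels
  # fragments of a type count under the parent type
  if ("instance" %in% names(lab)) {
    frag <- grepl("_fragment", lab$instance, fixed = TRUE)
    lab$type[frag] <- sub("_fragment.*$", "", lab$instance[frag])
  }
  if ("side" %in% names(lab)) {
    lab$type <- paste0(lab$type, "/", lab$side)
  }
  keep <- !grepl("_unclear", lab$type, fixed = TRUE)
  type_of <- stats::setNames(lab$type[keep], lab$neuron_id[keep])

  partner_types <- sort(unique(type_of))
  cols <- c(paste0(partner_types, ":in"), paste0(partner_types, ":out"))
  mat <- matrix(0, nrow = length(neuron_ids), ncol = length(cols),
                dimnames = list(as.character(neuron_ids), cols))
  add <- function(ids, partners, weights, direction) {
    pt <- type_of[as.character(partners)]
    ok <- !is.na(pt) & as.character(ids) %in% rownames(mat)
    if (!any(ok)) return()
    key <- paste0(pt[ok], ":", direction)
    agg <- tapply(weights[ok], list(as.character(ids)[ok], key), sum)
    ri <- rownames(agg)[row(agg)[!is.na(agg)]]
    ci <- colnames(agg)[col(agg)[!is.na(agg)]]
    mat[cbind(ri, ci)] <<- mat[cbind(ri, ci)] + agg[!is.na(agg)]
  }
  add(connections$post_id, connections$pre_id, connections$weight, "in")
  add(connections$pre_id, connections$post_id, connections$weight, "out")
  zero <- rownames(mat)[rowSums(mat) == 0]
  structure(mat, zero_rows = zero)
}

cosine_distance_matrix <- function(x) {
  nrm <- sqrt(rowSums(x^2))
  sim <- tcrossprod(x / nrm)
  sim[sim > 1] <- 1
  sim[sim < -1] <- -1
  stats::as.dist(1 - sim)
}

#' Cluster feature vectors hierarchically
#'
#' Agglomerative clustering (Ward linkage) of the rows of a feature matrix,
#' cut into exactly `n_clusters` flat clusters. Connectivity features use
#' cosine distance, whose built-in normalization is what makes raw count
#' vectors comparable; morphology features use Euclidean distance. An
#' equivalent L2-normalize-then-Euclidean path is available and co-clusters
#' with the cosine path on test fixtures.
#'
#' @param features Numeric matrix, rows = neurons.
#' @param metric `"cosine"`, `"euclidean"`, or `"l2_euclidean"`
#'   (L2-normalized rows + Euclidean).
#' @param n_clusters Number of flat clusters (<= number of rows).
#' @return Integer cluster labels named by row; rows excluded as zero
#'   vectors under the cosine metric get `NA` (with a warning).
#' @export
cluster_features <- function(features, metric = c("cosine", "euclidean",
                                                  "l2_euclidean"),
                             n_clusters) {
  metric <- match.arg(metric)
  features <- as.matrix(features)
  if (is.null(rownames(features))) rownames(features) <- seq_len(nrow(features))
  labels <- stats::setNames(rep(NA_integer_, nrow(features)), rownames(features))
  use <- rep(TRUE, nrow(features))
  if (metric %in% c("cosine", "l2_euclidean")) {
    zero <- rowSums(features^2) == 0
    if (any(zero)) {
      warning(sum(zero), " zero feature vector(s) excluded (cosine distance undefined)")
      use <- !zero
    }
  }
  x <- features[use, , drop = FALSE]
  if (n_clusters > nrow(x)) {
    stop_hexpin("`n_clusters` exceeds the number of usable neurons",
                "invalid_parameter")
  }
  d <- switch(metric,
    cosine = cosine_distance_matrix(x),
    euclidean = stats::dist(x),
    l2_euclidean = stats::dist(x / sqrt(rowSums(x^2)))
  )
  hc <- stats::hclust(d, method = "ward.D2")
  labels[use] <- stats::cutree(hc, k = n_clusters)
  labels
}

#' Build a per-neuron medulla morphology feature vector
#'
#' Length `4 * ceiling(N_samp / 2)` (244 for 121-station medulla pins):
#' block 1, presynapse counts by depth (subsampled by 2) rescaled by
#' `N_pre,size / N_pre,syn` so the block sums to the presynaptic
#' innervated-column count; block 2, the same for postsynapses; blocks 3-4,
#' the untrimmed number of columns innervated by presynapses and
#' postsynapses per depth, straight from nearest-pin assignment. Only
#' synapses at or above the confidence threshold enter (default 0.9).
#'
#' @param synapses One neuron's synapse table (`x`, `y`, `z`, `prepost`,
#'   `confidence`).
#' @param pins A `pin_set` for the neuropil.
#' @param min_confidence Synapse confidence threshold.
#' @return Numeric feature vector; zero (and flagged via attribute
#'   `"empty"`) when no synapse passes the filter.
#' @export
build_morph_features <- function(synapses, pins, min_confidence = 0.9) {
  n_samp <- attr(pins, "N_samp") %||% nrow(pins[[1]]$points)
  nbin <- ceiling(n_samp / 2)
  syn <- synapses[synapses$confidence >= min_confidence, , drop = FALSE]
  blocks <- function(pol) {
    s <- syn[syn$prepost == pol, , drop = FALSE]
    if (nrow(s) == 0) return(list(syn = numeric(nbin), size = numeric(nbin)))
    asg <- assign_points_to_pins(s, pins)
    bin <- ceiling((asg$station + 1L) / 2)
    counts <- tabulate(bin, nbins = nbin)
    cols <- tapply(hex_key(asg$p, asg$q), bin, function(k) length(unique(k)))
    size <- numeric(nbin)
    size[as.integer(names(cols))] <- cols
    n_syn <- sum(counts)
    n_size <- sum(size)
    list(syn = if (n_syn > 0) counts * n_size / n_syn else counts, size = size)
  }
  pre <- blocks("pre")
  post <- blocks("post")
  out <- c(pre$syn, post$syn, pre$size, post$size)
  structure(out, empty = all(out == 0))
}

#' Confusion summary of clustering against type annotations
#'
#' Builds the type-by-cluster count matrix with rows ordered
#' lexicographically and columns by the published greedy procedure (for
#' each type in turn, pick its clusters in decreasing count order until the
#' remaining clusters hold 5% or less of the type). Every nonzero cell
#' gets exactly one of five categories from the 80%/10% rules: `red`
#' (1-to-1), `blue` (many-to-1), `green` (1-to-many), `yellow` (mixed),
#' `grey` (outliers). Completeness and homogeneity are the standard
#' entropy-based scores.
#'
#' @param true_types Character vector of type annotations.
#' @param cluster_labels Parallel vector of cluster ids.
#' @return A `confusion_summary`: list with `matrix` (counts), `category`
#'   (same shape), `completeness`, `homogeneity`.
#' @export
confusion_summary <- function(true_types, cluster_labels) {
  ok <- !is.na(true_types) & !is.na(cluster_labels)
  tt <- as.character(true_types[ok])
  cl <- as.character(cluster_labels[ok])
  m <- table(type = tt, cluster = cl)
  m <- m[order(rownames(m)), , drop = FALSE]

  # greedy column ordering with the 5% stopping rule
  remaining <- colnames(m)
  ordered <- character(0)
  for (ty in rownames(m)) {
    repeat {
      if (!length(remaining)) break
      counts <- m[ty, remaining]
      if (max(counts) <= 0.05 * sum(m[ty, ])) break
      pick <- remaining[which.max(counts)]
      ordered <- c(ordered, pick)
      remaining <- setdiff(remaining, pick)
    }
  }
  ordered <- c(ordered, remaining)
  m <- m[, ordered, drop = FALSE]

  frac_type <- sweep(m, 1, pmax(rowSums(m), 1), "/")   # fraction of the type in the cluster
  frac_clus <- sweep(m, 2, pmax(colSums(m), 1), "/")   # purity of the cluster for the type
  cat_m <- matrix("", nrow(m), ncol(m), dimnames = dimnames(m))
  nz <- m > 0
  cat_m[nz & frac_type >= 0.8 & frac_clus >= 0.8] <- "red"
  cat_m[nz & frac_type >= 0.8 & frac_clus < 0.8] <- "blue"
  cat_m[nz & frac_type < 0.8 & frac_type >= 0.1 & frac_clus >= 0.8] <- "green"
  cat_m[nz & frac_type < 0.8 & frac_type >= 0.1 &
          frac_clus < 0.8 & frac_clus >= 0.1] <- "yellow"
  cat_m[nz & cat_m == ""] <- "grey"

  structure(list(matrix = unclass(m), category = cat_m,
                 completeness = completeness_score(tt, cl),
                 homogeneity = homogeneity_score(tt, cl)),
            class = "confusion_summary")
}

entropy <- function(x) {
  p <- table(x) / length(x)
  -sum(p * log(p))
}

conditional_entropy <- function(x, given) {
  tab <- table(x, given)
  n <- sum(tab)
  h <- 0
  for (j in seq_len(ncol(tab))) {
    nj <- sum(tab[, j])
    if (nj == 0) next
    p <- tab[, j] / nj
    p <- p[p > 0]
    h <- h - (nj / n) * sum(p * log(p))
  }
  h
}

#' @rdname confusion_summary
#' @export
homogeneity_score <- function(true_types, cluster_labels) {
  h <- entropy(true_types)
  if (h == 0) return(1)
  1 - conditional_entropy(true_types, cluster_labels) / h
}

#' @rdname confusion_summary
#' @export
completeness_score <- function(true_types, cluster_labels) {
  h <- entropy(cluster_labels)
  if (h == 0) return(1)
  1 - conditional_entropy(cluster_labels, true_types) / h
}

#' @export
print.confusion_summary <- function(x, ...) {
  cat(sprintf("<confusion_summary> %d types x %d clusters; completeness %.3f, homogeneity %.3f\n",
              nrow(x$matrix), ncol(x$matrix), x$completeness, x$homogeneity))
  invisible(x)
}

#' Proportion of types with unique top-n connectivity fingerprints
#'
#' For each type, rank its aggregated connections (partner type plus
#' direction) by weight, break ties by partner name, and take the ranked
#' list of the top `n` as its fingerprint. Returns the proportion of types
#' whose fingerprint is not shared with any other type; because fingerprints
#' are ranked prefixes, the proportion is non-decreasing in `n`.
#'
#' @param type_connectivity Data frame `type`, `partner`, `direction`,
#'   `weight` of type-level aggregated connections.
#' @param n Number of top-ranked connections in the fingerprint.
#' @return Proportion in `[0, 1]`.
#' @export
top_n_fingerprint_uniqueness <- function(type_connectivity, n) {
  sets <- lapply(split(type_connectivity, type_connectivity$type), function(d) {
    d <- d[order(-d$weight, d$partner, d$direction), , drop = FALSE]
    top <- utils::head(d, n)
    paste0(top$partner, ":", top$direction)
  })
  keys <- vapply(sets, paste, character(1), collapse = "|")
  mean(table(keys)[keys] == 1)
}

#' Project cell positions onto a reference synapse-cloud PCA ("mosaic view")
#'
#' Fits a PCA to a reference set of synapse positions for the neuropil and
#' places every cell at the projection of its synapse centre of mass onto
#' the first two principal axes, giving a standardized 2D mosaic view.
#'
#' @param synapses Synapse table (`neuron_id`, `x`, `y`, `z`) of the cells
#'   to project; cells with no synapses are excluded.
#' @param reference Reference synapse positions (defaults to `synapses`).
#' @return Data frame `neuron_id`, `pc1`, `pc2`.
#' @export
mosaic_projection <- function(synapses, reference = synapses) {
  ref <- as.matrix(reference[, c("x", "y", "z")])
  pc <- stats::prcomp(ref, center = TRUE, scale. = FALSE)
  centers <- do.call(rbind, lapply(split(synapses, synapses$neuron_id),
                                   function(d) colMeans(as.matrix(d[, c("x", "y", "z")]))))
  proj <- sweep(centers, 2, pc$center) %*% pc$rotation[, 1:2]
  data.frame(neuron_id = as.integer(rownames(centers)),
             pc1 = proj[, 1], pc2 = proj[, 2], row.names = NULL)
}
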