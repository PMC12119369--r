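# Internal helpers shared across modules.

#' Neurotransmitter classes
#'
#' The seven transmitter classes carried by per-synapse probability vectors,
#' in the fixed column order used throughout the package.
#'
#' @format Character vector of length 7.
#' @export
NT_CLASSES <- c("ACh", "Glu", "GABA", "His", "Dop", "OA", "5HT")

#' @keywords internal
nt_prob_cols <- function() paste0("prob_", NT_CLASSES)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code with a temporary RNG seed
#'
#' Sets the RNG seed for the duration of `code` and restores the previous
#' global RNG state afterwards, so that no generator leaks global random
#' state.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
    get(".Random.seed", envir = .GlobalEnv)
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
        rm(".Random.seed", envir = .GlobalEnv)
      }
    } else {
      assign(".Random.seed", old, envir = .GlobalEnv)
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# squared Euclidean cross-distances between rows of two n x 3 matrices
cross_dist2 <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  an <- rowSums(a^2)
  bn <- rowSums(b^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}

# nearest row of `ref` for every row of `pts`; chunked to bound memory
nearest_ref_index <- function(pts, ref, chunk = 2000L) {
  pts <- as.matrix(pts)
  n <- nrow(pts)
  idx <- integer(n)
  dist <- numeric(n)
  start <- 1L
  while (start <= n) {
    end <- min(start + chunk - 1L, n)
    d2 <- cross_dist2(pts[start:end, , drop = FALSE], ref)
    j <- max.col(-d2, ties.method = "first")
    idx[start:end] <- j
    dist[start:end] <- sqrt(d2[cbind(seq_len(end - start + 1L), j)])
    start <- end + 1L
  }
  list(index = idx, distance = dist)
}

hex_key <- function(p, q) paste0(p, ",", q)

# axial hex-grid distance between coordinate pairs
hex_distance <- function(p1, q1, p2, q2) {
  dp <- p1 - p2
  dq <- q1 - q2
  (abs(dp) + abs(dq) + abs(dp + dq)) / 2
}

# axial (p, q) -> planar Cartesian embedding ("pointy-top" convention)
axial_to_cart <- function(p, q, spacing = 1) {
  cbind(x = spacing * (p + q / 2), y = spacing * (sqrt(3) / 2) * q)
}

stop_hexpin <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "hexpin_error")))
}

assert_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0) {
    stop_hexpin(sprintf("`%s` must be a positive scalar", name), "invalid_parameter")
  }
  invisible(x)
}

# modal value of a character vector with lexicographic tie-break;
# returns list(value, count, tied)
lexi_mode <- function(x) {
  tab <- table(x)
  top <- max(tab)
  winners <- sort(names(tab)[tab == top])
  list(value = winners[[1L]], count = as.integer(top), tied = length(winners) > 1L)
}
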