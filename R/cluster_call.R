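# Reproducible replacement for by-eye curation of the embedding: flag small
# disconnected components as outliers, then 2-means the rest, with a
# deterministic left/right cluster naming.

#' Published outlier samples of the TCGA adrenocortical cohort
#'
#' The three TCGA-ACC samples historically removed by manual curation
#' before subtype clustering (two annotated sarcomatoid, one presumed so).
#' Provided as an optional exclusion list for users running the pipeline
#' on the real cohort; the algorithmic rule in [flag_outliers()] is the
#' default and does not consult this list.
#' @format character vector of three TCGA sample ids.
#' @export
tcga_acc_published_outliers <- c("TCGA-OR-A5J8", "TCGA-OR-A5JB",
                                 "TCGA-P6-A5OG")

#' Flag outliers as small connected components of the embedding
#'
#' Builds the epsilon-graph on the embedding (epsilon = `eps_frac` of the
#' embedding diameter; single-linkage components at that height are
#' exactly its connected components) and flags every component with fewer
#' than max(2, ceiling(min_component_frac * n)) members.
#'
#' @param Y n x m embedding coordinates (or an `Embedding`).
#' @param min_component_frac minimum fraction of samples a component needs
#'   to count as a cluster (default 0.05).
#' @param eps_frac edge length as a fraction of the embedding diameter
#'   (default 0.10).
#' @return logical vector, TRUE = outlier.
#' @export
flag_outliers <- function(Y, min_component_frac = 0.05, eps_frac = 0.10) {
  if (inherits(Y, "Embedding")) Y <- Y$Y
  Y <- as.matrix(Y)
  n <- nrow(Y)
  if (n < 10) stop("need >= 10 samples to flag outliers")
  dd <- stats::dist(Y)
  diam <- max(dd)
  if (diam == 0) stop("degenerate embedding: all points coincident")
  eps <- eps_frac * diam
  comp <- stats::cutree(stats::hclust(dd, method = "single"), h = eps)
  sizes <- table(comp)
  min_size <- max(2, ceiling(min_component_frac * n))
  flags <- as.vector(sizes[as.character(comp)] < min_size)
  names(flags) <- rownames(Y)
  flags
}

#' Assign two clusters on the embedding with deterministic naming
#'
#' 2-means over non-outlier points with seeded multiple restarts; cluster
#' 1 is always the cluster whose centroid has the smaller first
#' coordinate (the "left" cluster), so labels are stable across runs and
#' mirror-flips swap them exactly.
#'
#' @param Y n x m coordinates or an `Embedding`.
#' @param flags logical outlier flags from [flag_outliers()]; NULL = none.
#' @param n_restarts seeded k-means restarts (default 10).
#' @param seed RNG seed.
#' @return object of class `ClusterAssignment`: data.frame with
#'   `sample_id`, `cluster` (1, 2, or NA for outliers), `outlier`; plus
#'   attributes `centroids` and `method`.
#' @export
assign_two_clusters <- function(Y, flags = NULL, n_restarts = 10, seed = 1L) {
  if (inherits(Y, "Embedding")) Y <- Y$Y
  Y <- as.matrix(Y)
  n <- nrow(Y)
  if (is.null(flags)) flags <- rep(FALSE, n)
  keep <- !flags
  if (sum(keep) < 4) stop("need >= 4 non-outlier samples")
  set.seed(seed)
  km <- stats::kmeans(Y[keep, , drop = FALSE], centers = 2,
                      nstart = n_restarts)
  if (any(km$size == 0)) stop("k-means produced an empty cluster")
  # left cluster (smaller first-coordinate centroid) is cluster 1
  left_first <- order(km$centers[, 1])
  relabel <- match(seq_len(2), left_first)
  cl <- rep(NA_integer_, n)
  cl[keep] <- relabel[km$cluster]
  ids <- rownames(Y)
  if (is.null(ids)) ids <- sprintf("sample%03d", seq_len(n))
  out <- data.frame(sample_id = ids, cluster = cl, outlier = flags,
                    stringsAsFactors = FALSE)
  attr(out, "centroids") <- km$centers[left_first, , drop = FALSE]
  attr(out, "method") <- sprintf("kmeans(k=2, nstart=%d, seed=%d)",
                                 n_restarts, seed)
  class(out) <- c("ClusterAssignment", "data.frame")
  out
}

#' Concordance between a cluster assignment and an external binary labeling
#'
#' Mismatches are counted under the label permutation that minimizes them
#' (cluster names are arbitrary), on the samples shared by the two
#' labelings; the adjusted Rand index is reported alongside.
#'
#' @param assignment a `ClusterAssignment`, or a named vector of labels.
#' @param external named vector (names = sample ids) of a binary labeling.
#' @return list of class `ConcordanceReport`: `n_compared`, `n_mismatch`,
#'   `pct_mismatch`, `adjusted_rand`, `contingency`.
#' @export
concordance <- function(assignment, external) {
  a <- if (inherits(assignment, "ClusterAssignment")) {
    ok <- !is.na(assignment$cluster)
    stats::setNames(assignment$cluster[ok], assignment$sample_id[ok])
  } else assignment
  if (is.null(names(a)) || is.null(names(external))) {
    stop("both labelings must be named by sample id")
  }
  shared <- intersect(names(a), names(external))
  if (length(shared) < 2) stop("need >= 2 overlapping sample ids")
  x <- as.character(a[shared]); y <- as.character(external[shared])
  tab <- table(x, y)
  if (nrow(tab) > 2 || ncol(tab) > 2) stop("labelings must be binary")
  pad <- matrix(0, 2, 2)
  pad[seq_len(nrow(tab)), seq_len(ncol(tab))] <- tab
  n_mismatch <- as.integer(length(shared) - max(pad[1, 1] + pad[2, 2],
                                                pad[1, 2] + pad[2, 1]))
  structure(
    list(n_compared = length(shared), n_mismatch = n_mismatch,
         pct_mismatch = 100 * n_mismatch / length(shared),
         adjusted_rand = mclust::adjustedRandIndex(x, y),
         contingency = tab),
    class = "ConcordanceReport"
  )
}

#' @export
print.ConcordanceReport <- function(x, ...) {
  cat(sprintf("Concordance: %d/%d mismatched (%.2f%%), ARI = %.3f\n",
              x$n_mismatch, x$n_compared, x$pct_mismatch, x$adjusted_rand))
  invisible(x)
}
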