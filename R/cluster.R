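# Module II: unsupervised extraction of temporal patterns by K-means
# (Lloyd's algorithm, k-means++ seeding) or hierarchical clustering,
# with WCSS scree support for choosing K.

# Squared Euclidean distances between rows of X and rows of C.
.sqdist <- function(X, C) {
  d <- outer(rowSums(X^2), rowSums(C^2), "+") - 2 * tcrossprod(X, C)
  d[d < 0] <- 0
  d
}

# k-means++ seeding: first center uniform, then proportional to squared
# distance from the nearest chosen center.
.kmeanspp_centers <- function(X, K) {
  m <- nrow(X)
  idx <- integer(K)
  idx[1] <- sample.int(m, 1)
  d2 <- .sqdist(X, X[idx[1], , drop = FALSE])[, 1]
  for (k in seq_len(K)[-1]) {
    if (sum(d2) <= 0) {
      idx[k] <- sample.int(m, 1)
    } else {
      idx[k] <- sample.int(m, 1, prob = d2)
    }
    d2 <- pmin(d2, .sqdist(X, X[idx[k], , drop = FALSE])[, 1])
  }
  X[idx, , drop = FALSE]
}

# Lloyd's iterations from given centers; empty clusters are repaired by
# moving the point farthest from its current center into the empty slot.
.lloyd <- function(X, centers, max_iter = 100) {
  K <- nrow(centers)
  labels <- integer(nrow(X))
  for (it in seq_len(max_iter)) {
    d2 <- .sqdist(X, centers)
    new_labels <- max.col(-d2, ties.method = "first")
    for (k in which(tabulate(new_labels, K) == 0)) {
      assigned_d <- d2[cbind(seq_len(nrow(X)), new_labels)]
      # never strip a singleton cluster while repairing another
      assigned_d[new_labels %in% which(tabulate(new_labels, K) == 1)] <- -Inf
      new_labels[which.max(assigned_d)] <- k
    }
    if (identical(new_labels, labels) && it > 1) break
    labels <- new_labels
    for (k in seq_len(K))
      centers[k, ] <- colMeans(X[labels == k, , drop = FALSE])
  }
  wcss <- sum((X - centers[labels, , drop = FALSE])^2)
  list(labels = labels, centers = centers, wcss = wcss)
}

# Renumber clusters by decreasing size (ties by first occurrence) so
# labels are stable across runs.
.canonicalize <- function(labels, centers) {
  K <- nrow(centers)
  size <- tabulate(labels, K)
  first <- vapply(seq_len(K), function(k) match(k, labels), integer(1))
  ord <- order(-size, first)
  remap <- integer(K)
  remap[ord] <- seq_len(K)
  list(labels = remap[labels], centers = centers[ord, , drop = FALSE])
}

.new_clustering <- function(labels, centers, K, wcss, method, distance,
                            linkage = NA_character_, seed = NA_integer_,
                            restarts = NA_integer_, ids = NULL) {
  rownames(centers) <- paste0("C", seq_len(K))
  if (!is.null(ids)) names(labels) <- ids
  structure(list(labels = labels, centers = centers, K = K, wcss = wcss,
                 method = method, distance = distance, linkage = linkage,
                 seed = seed, restarts = restarts),
            class = "clustering_result")
}

#' @export
print.clustering_result <- function(x, ...) {
  cat(sprintf("%s clustering (%s%s): K = %d, WCSS = %.4g\n", x$method,
              x$distance,
              if (!is.na(x$linkage)) paste0(", ", x$linkage) else "",
              x$K, x$wcss))
  print(table(cluster = x$labels))
  invisible(x)
}

#' K-means clustering of temporal profiles
#'
#' Lloyd's algorithm with k-means++ seeding, keeping the best of
#' `restarts` random initializations by within-cluster sum of squares
#' (WCSS). Deterministic given `seed`; empty clusters arising during the
#' iterations are repaired by reassigning the point farthest from its
#' center, so exactly K non-empty clusters are always returned.
#'
#' @param matrix A complete `temporal_matrix` or numeric matrix
#'   (rows = variables, columns = time points).
#' @param K Number of clusters, `1 <= K <= m`.
#' @param restarts Number of k-means++ initializations; default 20.
#' @param seed RNG seed; default 20200603.
#' @param init Optional K x n matrix of starting centers, added as one
#'   candidate initialization alongside the random restarts (used by
#'   the jackstraw re-clustering step); with `restarts = 0` a single
#'   Lloyd run from `init` is performed. When `init` is supplied labels
#'   are not renumbered.
#' @return A `clustering_result`: `labels` (1..K, clusters numbered by
#'   decreasing size), `centers` (K x n mean profiles), `K`, `wcss`,
#'   `method`, `distance`, `seed`, `restarts`.
#' @export
kmeans_cluster <- function(matrix, K, restarts = 20, seed = 20200603,
                           init = NULL) {
  X <- if (inherits(matrix, "temporal_matrix")) matrix$values
       else as.matrix(matrix)
  if (anyNA(X))
    stop_with("MissingDataError", "matrix must be complete; preprocess first")
  m <- nrow(X)
  if (K < 1 || K > m)
    stop_with("ParameterError", "K must be in 1..m = %d (got %d)", m, K)
  ids <- rownames(X)
  best <- if (!is.null(init)) .lloyd(X, as.matrix(init)) else NULL
  with_seed(seed, {
    for (r in seq_len(restarts)) {
      fit <- .lloyd(X, .kmeanspp_centers(X, K))
      if (is.null(best) || fit$wcss < best$wcss) best <- fit
    }
  })
  if (!is.null(init))
    return(.new_clustering(best$labels, best$centers, K, best$wcss,
                           "kmeans", "euclidean", seed = seed,
                           restarts = as.integer(restarts), ids = ids))
  can <- .canonicalize(best$labels, best$centers)
  .new_clustering(can$labels, can$centers, K, best$wcss, "kmeans",
                  "euclidean", seed = seed, restarts = as.integer(restarts),
                  ids = ids)
}

#' Hierarchical clustering of temporal profiles
#'
#' Agglomerates the pairwise distance matrix (Euclidean, or dynamic
#' time warping via [dtw_distance()]) and cuts the tree at K groups.
#' Centers are reported as per-cluster mean profiles regardless of the
#' distance used, for downstream membership testing.
#'
#' @param matrix Complete `temporal_matrix` or numeric matrix.
#' @param K Number of clusters.
#' @param distance `"euclidean"` or `"dtw"`.
#' @param linkage `"average"`, `"complete"`, or `"ward"` (Ward linkage
#'   is only meaningful for Euclidean distances).
#' @param window Optional Sakoe-Chiba half-width passed to
#'   [dtw_distance()].
#' @return A `clustering_result` (WCSS computed in Euclidean geometry
#'   about the cluster means).
#' @export
hierarchical_cluster <- function(matrix, K,
                                 distance = c("euclidean", "dtw"),
                                 linkage = c("average", "complete", "ward"),
                                 window = NULL) {
  distance <- match.arg(distance)
  linkage <- match.arg(linkage)
  X <- if (inherits(matrix, "temporal_matrix")) matrix$values
       else as.matrix(matrix)
  if (anyNA(X))
    stop_with("MissingDataError", "matrix must be complete; preprocess first")
  m <- nrow(X)
  if (K < 1 || K > m)
    stop_with("ParameterError", "K must be in 1..m = %d (got %d)", m, K)
  if (linkage == "ward" && distance != "euclidean")
    stop_with("ParameterError", "ward linkage requires euclidean distance")
  d <- if (distance == "euclidean") {
    stats::dist(X)
  } else {
    dm <- matrix(0, m, m)
    for (i in seq_len(m - 1))
      for (j in (i + 1):m)
        dm[i, j] <- dm[j, i] <- dtw_distance(X[i, ], X[j, ], window = window)
    stats::as.dist(dm)
  }
  hc_method <- c(average = "average", complete = "complete",
                 ward = "ward.D2")[[linkage]]
  labels <- stats::cutree(stats::hclust(d, method = hc_method), k = K)
  centers <- t(vapply(seq_len(K),
                      function(k) colMeans(X[labels == k, , drop = FALSE]),
                      numeric(ncol(X))))
  can <- .canonicalize(as.integer(labels), centers)
  wcss <- sum((X - can$centers[can$labels, , drop = FALSE])^2)
  .new_clustering(can$labels, can$centers, K, wcss, "hierarchical",
                  distance, linkage = linkage, ids = rownames(X))
}

#' WCSS scree table over a range of K
#'
#' Runs best-of-restarts K-means for each candidate K and tabulates the
#' within-cluster sum of squares, the standard scree diagnostic for
#' picking a plausible cluster-number range. K selection is advisory:
#' the platform emits the table and leaves the choice to the analyst;
#' [elbow_k()] offers a convenience heuristic.
#'
#' @param matrix Complete `temporal_matrix` or numeric matrix.
#' @param K_range Integer vector of candidate K; default 1:10.
#' @param restarts,seed Passed to [kmeans_cluster()].
#' @return A data frame with columns `K`, `wcss`, `restarts`, `seed`.
#' @export
wcss_scree <- function(matrix, K_range = 1:10, restarts = 20,
                       seed = 20200603) {
  K_range <- sort(unique(as.integer(K_range)))
  wcss <- vapply(K_range, function(K)
    kmeans_cluster(matrix, K, restarts = restarts, seed = seed)$wcss,
    numeric(1))
  data.frame(K = K_range, wcss = wcss, restarts = restarts, seed = seed)
}

#' Elbow heuristic on a scree table
#'
#' Returns the K with the largest second difference of WCSS (the
#' sharpest bend of the scree curve). Advisory only — never applied
#' silently by the pipeline.
#'
#' @param scree A data frame from [wcss_scree()].
#' @return A single integer K.
#' @export
elbow_k <- function(scree) {
  if (nrow(scree) < 3)
    stop_with("ParameterError", "elbow heuristic needs >= 3 K values")
  d2 <- diff(diff(scree$wcss))
  scree$K[which.max(d2) + 1L]
}
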