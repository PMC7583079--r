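# Independent oracles used across the suite. Each is written from the
# definition, not by calling the implementation under test.

# Principal angles (radians) between the column spans of A and B.
principal_angles <- function(A, B) {
  qa <- qr.Q(qr(A))
  qb <- qr.Q(qr(B))
  s <- svd(crossprod(qa, qb))$d
  acos(pmin(pmax(s, -1), 1))
}

# Naive agglomerative clustering: recompute all pairwise group
# distances from scratch at every merge. linkage "average" or
# "complete" on Euclidean point distances.
naive_agglomeration <- function(X, K, linkage = "average") {
  groups <- as.list(seq_len(nrow(X)))
  point_d <- as.matrix(stats::dist(X))
  group_dist <- function(g1, g2) {
    d <- point_d[g1, g2, drop = FALSE]
    if (linkage == "average") mean(d) else max(d)
  }
  while (length(groups) > K) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(groups)) for (j in seq_len(i - 1)) {
      d <- group_dist(groups[[i]], groups[[j]])
      if (d < best_d) { best_d <- d; best <- c(j, i) }
    }
    groups[[best[1]]] <- c(groups[[best[1]]], groups[[best[2]]])
    groups[[best[2]]] <- NULL
  }
  labels <- integer(nrow(X))
  for (k in seq_along(groups)) labels[groups[[k]]] <- k
  labels
}

# Exhaustive DTW by enumerating every monotone warping path with steps
# {match, insert, delete}; squared pointwise cost, sqrt of the total.
brute_dtw <- function(a, b) {
  n <- length(a); m <- length(b)
  rec <- function(i, j) {
    cost <- (a[i] - b[j])^2
    if (i == 1 && j == 1) return(cost)
    prev <- Inf
    if (i > 1) prev <- min(prev, rec(i - 1, j))
    if (j > 1) prev <- min(prev, rec(i, j - 1))
    if (i > 1 && j > 1) prev <- min(prev, rec(i - 1, j - 1))
    cost + prev
  }
  sqrt(rec(n, m))
}

# Rank-1 alternating-least-squares completion on observed cells.
als_rank1_impute <- function(M, n_iter = 500) {
  obs <- !is.na(M)
  u <- rowMeans(M, na.rm = TRUE)
  v <- rep(1, ncol(M))
  for (it in seq_len(n_iter)) {
    for (j in seq_len(ncol(M))) {
      o <- obs[, j]
      v[j] <- sum(M[o, j] * u[o]) / sum(u[o]^2)
    }
    for (i in seq_len(nrow(M))) {
      o <- obs[i, ]
      u[i] <- sum(M[i, o] * v[o]) / sum(v[o]^2)
    }
  }
  out <- M
  fill <- outer(u, v)
  out[!obs] <- fill[!obs]
  out
}

# Membership F-statistic recomputed via explicit normal equations on
# the design (1, center).
fstat_normal_equations <- function(y, x) {
  n <- length(y)
  X <- cbind(1, x)
  beta <- solve(crossprod(X), crossprod(X, y))
  rss <- sum((y - X %*% beta)^2)
  tss <- sum((y - mean(y))^2)
  (tss - rss) / (rss / (n - 2))
}

# Benjamini-Hochberg step-up applied from the textbook definition.
bh_by_hand <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[o] <- pmin(q, 1)
  out
}

expect_same_partition <- function(a, b) {
  expect_equal(temposig::adjusted_rand_index(a, b), 1)
}
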