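# Module III: the jackstraw test for cluster membership. A few rows at
# a time are replaced by permuted (null) copies, the clustering is
# re-fit, and the null rows' association F-statistics form an empirical
# null that breaks the circularity of testing variables against
# clusters learned from the same data.

#' Membership F-statistic of a variable against a cluster center
#'
#' F-statistic of the simple linear regression of the variable's time
#' course on its assigned cluster's mean profile:
#' `F = (TSS - RSS) / (RSS / (n - 2))`, with TSS about the variable's
#' mean. Large values indicate genuine membership.
#'
#' @param variable Numeric vector of length n >= 3.
#' @param center Numeric vector of the same length; must not be
#'   constant.
#' @return A non-negative number. A perfect fit (RSS = 0) returns a
#'   large finite sentinel (`1e300`) so ordering against empirical null
#'   values stays well defined.
#' @export
membership_f_stat <- function(variable, center) {
  n <- length(variable)
  if (length(center) != n)
    stop_with("ShapeError", "variable and center lengths differ")
  if (n < 3)
    stop_with("ParameterError", "need n >= 3 time points")
  if (stats::sd(center) == 0)
    stop_with("DegenerateCenterError", "cluster center is constant")
  xc <- center - mean(center)
  yc <- variable - mean(variable)
  beta <- sum(xc * yc) / sum(xc^2)
  rss <- sum((yc - beta * xc)^2)
  tss <- sum(yc^2)
  if (rss <= tss * 1e-14) return(1e300)
  (tss - rss) / (rss / (n - 2))
}

#' Jackstraw test of K-means cluster membership
#'
#' Computes an observed membership F-statistic for every row against
#' its assigned cluster center, then builds an empirical null: in each
#' of `B` iterations, `s` rows are drawn without replacement and each is
#' replaced by a permutation of its own values across the time points
#' (destroying temporal association while preserving the marginal
#' distribution); the modified matrix is re-clustered with the same K
#' and the same optimization effort as the observed clustering (its
#' recorded number of k-means++ restarts, with the observed centers as
#' one additional candidate start, run to convergence); the
#' synthetic-null rows' F-statistics against their newly assigned
#' centers are pooled over iterations. Empirical p-values use the
#' add-one estimator `p = (1 + #{null >= observed}) / (1 + s*B)`.
#'
#' Matching the refit's optimization effort to the observed
#' clustering's matters for calibration: a refit run only from the
#' observed centers gives the permuted rows less over-fitting benefit
#' than the observed rows received, which makes null p-values mildly
#' anti-conservative.
#'
#' @param matrix Complete `temporal_matrix` or numeric matrix, the same
#'   one the clustering was computed from.
#' @param clustering A `clustering_result` for `matrix`.
#' @param s Number of rows permuted per iteration; default
#'   `ceiling(0.1 * m)`. Must satisfy `1 <= s < m`.
#' @param B Number of iterations; default the smallest B with
#'   `s * B >= 10000` null draws.
#' @param seed RNG seed; default 20200603. Results are deterministic
#'   given the seed.
#' @param null_fun Optional generator of synthetic-null rows: a
#'   function of a row index returning a length-n replacement row (it
#'   may use the RNG; it is called inside the seeded loop). The default
#'   permutes the row's own values across the time points. Supply
#'   [spline_permutation_null()] when `matrix` is spline-preprocessed,
#'   so null rows pass through the same smoothing as the tested rows;
#'   otherwise smoothed noise rows look genuinely smooth while permuted
#'   nulls do not, and their p-values are anti-conservative.
#' @return A `jackstraw_result`: `observed_f`, `null_f` (length `s*B`),
#'   `p_values`, `pi0`, `lfdr`, `pip` (`= 1 - lfdr`), `labels`, `s`,
#'   `B`, `seed`.
#' @seealso [estimate_pi0()], [compute_pips()], [pip_filter()]
#' @export
jackstraw_cluster_test <- function(matrix, clustering, s = NULL, B = NULL,
                                   seed = 20200603, null_fun = NULL) {
  X <- if (inherits(matrix, "temporal_matrix")) matrix$values
       else as.matrix(matrix)
  if (anyNA(X))
    stop_with("MissingDataError", "matrix must be complete")
  stopifnot(inherits(clustering, "clustering_result"))
  m <- nrow(X); n <- ncol(X)
  s <- as.integer(s %||% ceiling(0.1 * m))
  if (s < 1 || s >= m)
    stop_with("ParameterError", "s must satisfy 1 <= s < m = %d (got %d)",
              m, s)
  B <- as.integer(B %||% ceiling(10000 / s))
  if (B < 1) stop_with("ParameterError", "B must be >= 1")

  observed_f <- vapply(seq_len(m), function(i)
    membership_f_stat(X[i, ], clustering$centers[clustering$labels[i], ]),
    numeric(1))

  refit_restarts <- clustering$restarts
  if (is.na(refit_restarts) || refit_restarts < 1) refit_restarts <- 20L
  if (is.null(null_fun)) null_fun <- function(i) X[i, sample.int(n)]
  null_f <- numeric(s * B)
  with_seed(seed, {
    for (b in seq_len(B)) {
      rows <- sample.int(m, s)
      Xb <- X
      for (i in rows) Xb[i, ] <- null_fun(i)
      refit <- kmeans_cluster(Xb, clustering$K, init = clustering$centers,
                              restarts = refit_restarts,
                              seed = sample.int(2147483646, 1))
      null_f[((b - 1) * s + 1):(b * s)] <- vapply(rows, function(i)
        membership_f_stat(Xb[i, ], refit$centers[refit$labels[i], ]),
        numeric(1))
    }
  })

  # add-one empirical p-values against the pooled null
  sorted_null <- sort(null_f)
  n_ge <- length(null_f) -
    findInterval(observed_f, sorted_null, left.open = TRUE)
  p_values <- (1 + n_ge) / (1 + length(null_f))

  pi0 <- estimate_pi0(p_values)
  pp <- compute_pips(p_values, pi0)
  structure(list(observed_f = observed_f, null_f = null_f,
                 p_values = p_values, pi0 = pi0, lfdr = pp$lfdr,
                 pip = pp$pip, labels = clustering$labels,
                 variable_ids = rownames(X), s = s, B = B, seed = seed),
            class = "jackstraw_result")
}

#' @export
print.jackstraw_result <- function(x, ...) {
  cat(sprintf(
    "jackstraw cluster-membership test: m = %d, s = %d, B = %d\n",
    length(x$observed_f), x$s, x$B))
  cat(sprintf("  pi0 = %.3f; PIP > 0.8 for %d variables\n", x$pi0,
              sum(x$pip > 0.8)))
  invisible(x)
}

#' Smoothing-aware null generator for the jackstraw test
#'
#' Builds a `null_fun` for [jackstraw_cluster_test()] on a
#' spline-preprocessed matrix: a null row is obtained by permuting the
#' raw observed values of the variable across its observed time
#' positions and re-fitting the same cubic smoothing spline (same
#' degrees of freedom), so synthetic-null rows are exchangeable with
#' genuinely unstructured rows that went through preprocessing. Rows
#' that were completed by the SVD fallback instead of a spline fall
#' back to permuting their preprocessed values.
#'
#' @param raw The original `temporal_matrix` (with missing cells) that
#'   was preprocessed.
#' @param preprocessed The `preprocessed_matrix` returned by
#'   [preprocess_spline()] for `raw`.
#' @return A function of a row index, suitable as `null_fun`.
#' @export
spline_permutation_null <- function(raw, preprocessed) {
  stopifnot(inherits(raw, "temporal_matrix"),
            inherits(preprocessed, "preprocessed_matrix"),
            identical(preprocessed$method, "spline"))
  vals <- raw$values
  tp <- raw$time_points
  n <- ncol(vals)
  dofs <- preprocessed$params$dof_per_row
  row_method <- preprocessed$row_method
  pre_vals <- preprocessed$values
  function(i) {
    if (row_method[i] == "spline") {
      obs <- which(!is.na(vals[i, ]))
      series <- rep(NA_real_, n)
      series[obs] <- vals[i, obs][sample.int(length(obs))]
      fit_spline_variable(series, tp, min(dofs[i], length(obs)))
    } else {
      pre_vals[i, sample.int(n)]
    }
  }
}

#' Estimate the null proportion pi0 from p-values
#'
#' Storey's estimator: `pi0(lambda) = #{p > lambda} / (m (1 - lambda))`
#' on the grid lambda = 0.05, ..., 0.95, smoothed with a cubic spline
#' and read off at the largest lambda, clamped to (0, 1]. With fewer
#' than 20 p-values the estimate is unstable and the conservative
#' `pi0 = 1` is returned with a warning.
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @return A single number in (0, 1].
#' @export
estimate_pi0 <- function(p_values) {
  if (any(p_values <= 0 | p_values > 1, na.rm = TRUE) || anyNA(p_values))
    stop_with("ParameterError", "p-values must lie in (0, 1]")
  m <- length(p_values)
  if (m < 20) {
    warning("fewer than 20 p-values; returning conservative pi0 = 1")
    return(1)
  }
  lambda <- seq(0.05, 0.95, by = 0.05)
  pi0_l <- vapply(lambda, function(l) mean(p_values > l) / (1 - l),
                  numeric(1))
  fit <- stats::smooth.spline(lambda, pi0_l, df = 3)
  pi0 <- stats::predict(fit, max(lambda))$y
  min(max(pi0, 1 / m), 1)
}

#' Local FDR and posterior inclusion probabilities from p-values
#'
#' Models the p-values as a two-group mixture of a Uniform(0,1) null
#' (weight `pi0`) and an alternative concentrated near 0. The marginal
#' density f(p) is estimated by a histogram forced to be monotone
#' non-increasing in p (isotonic regression), and
#' `lfdr(p) = pi0 / f(p)`, clamped to [0, 1]. The posterior inclusion
#' probability is its complement, `pip = 1 - lfdr`: the estimated
#' probability that a variable genuinely belongs to its cluster.
#'
#' @param p_values Numeric vector in (0, 1].
#' @param pi0 Null proportion, typically from [estimate_pi0()].
#' @param n_bins Histogram bins for the density estimate; default 50.
#' @return List with `lfdr` and `pip` vectors (elementwise
#'   `pip = 1 - lfdr`, exactly).
#' @export
compute_pips <- function(p_values, pi0, n_bins = 50) {
  if (any(p_values <= 0 | p_values > 1, na.rm = TRUE) || anyNA(p_values))
    stop_with("ParameterError", "p-values must lie in (0, 1]")
  if (pi0 < 0 || pi0 > 1)
    stop_with("ParameterError", "pi0 must lie in [0, 1]")
  breaks <- seq(0, 1, length.out = n_bins + 1)
  bin <- pmin(pmax(ceiling(p_values * n_bins), 1L), n_bins)
  counts <- tabulate(bin, n_bins)
  dens <- counts / (length(p_values) / n_bins)  # density: uniform -> 1
  # enforce monotone non-increase toward p = 1
  iso <- stats::isoreg(seq_len(n_bins), rev(dens))
  dens_mono <- rev(iso$yf)
  dens_mono <- pmax(dens_mono, .Machine$double.eps)
  lfdr <- pmin(pmax(pi0 / dens_mono[bin], 0), 1)
  list(lfdr = lfdr, pip = 1 - lfdr)
}

#' Select variables by posterior inclusion probability
#'
#' Retains the variables whose PIP strictly exceeds the threshold —
#' the platform's feature-selection rule for keeping variables strongly
#' related to their temporal cluster.
#'
#' @param result A `jackstraw_result`.
#' @param threshold PIP cutoff in [0, 1]; default 0.8.
#' @return A `selection_report`: `pip_threshold`, `retained_ids`,
#'   `retained_idx`, `n_input`, `n_retained`.
#' @export
pip_filter <- function(result, threshold = 0.8) {
  stopifnot(inherits(result, "jackstraw_result"))
  if (threshold < 0 || threshold > 1)
    stop_with("ParameterError", "threshold must lie in [0, 1]")
  keep <- which(result$pip > threshold)
  ids <- if (!is.null(result$variable_ids)) result$variable_ids[keep]
         else as.character(keep)
  structure(list(pip_threshold = threshold, retained_ids = ids,
                 retained_idx = keep, n_input = length(result$pip),
                 n_retained = length(keep)),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat(sprintf("PIP > %.2f selection: retained %d / %d variables\n",
              x$pip_threshold, x$n_retained, x$n_input))
  invisible(x)
}
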