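# Module I, reduced-rank path: iterative SVD imputation, NIPALS PCA for
# incomplete matrices, and low-rank reconstruction for denoising.

#' Iterative low-rank (SVD) imputation of missing cells
#'
#' Missing cells are initialized at their row mean (column mean when the
#' row mean is unavailable), then refined by repeating: truncate the SVD
#' of the filled matrix at rank `rank` and overwrite only the
#' originally-missing cells with the rank-`rank` reconstruction, until
#' the imputed cells stabilize. Observed cells are never altered.
#'
#' @param matrix A `temporal_matrix` or plain numeric matrix with `NA`s.
#' @param rank Target rank, `1 <= rank < min(m, n)`.
#' @param tol Convergence tolerance on the relative change of imputed
#'   cells; default 1e-6.
#' @param max_iter Iteration cap; default 100. Non-convergence returns
#'   the best iterate with a warning and attribute `converged = FALSE`.
#' @return A complete m x n numeric matrix.
#' @export
svd_impute <- function(matrix, rank, tol = 1e-6, max_iter = 100) {
  vals <- if (inherits(matrix, "temporal_matrix")) matrix$values
          else as.matrix(matrix)
  m <- nrow(vals); n <- ncol(vals)
  if (rank < 1 || rank >= min(m, n))
    stop_with("ParameterError", "rank must satisfy 1 <= r < min(m, n) = %d",
              min(m, n))
  miss <- is.na(vals)
  if (!any(miss)) {
    attr(vals, "converged") <- TRUE
    return(vals)
  }
  row_means <- rowMeans(vals, na.rm = TRUE)
  col_means <- colMeans(vals, na.rm = TRUE)
  col_means[is.nan(col_means)] <- mean(vals, na.rm = TRUE)
  filled <- vals
  init <- matrix(row_means, m, n)[miss]
  nan_init <- is.nan(init)
  if (any(nan_init))
    init[nan_init] <- matrix(col_means, m, n, byrow = TRUE)[miss][nan_init]
  filled[miss] <- init
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    sv <- svd(filled, nu = rank, nv = rank)
    recon <- sv$u %*% (sv$d[seq_len(rank)] * t(sv$v))
    new_imp <- recon[miss]
    old_imp <- filled[miss]
    delta <- sqrt(sum((new_imp - old_imp)^2)) /
      max(sqrt(sum(old_imp^2)), .Machine$double.eps)
    filled[miss] <- new_imp
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning(sprintf("svd_impute: not converged in %d iterations", max_iter))
  attr(filled, "converged") <- converged
  filled
}

#' NIPALS principal components for matrices with missing cells
#'
#' Extracts principal components sequentially by the nonlinear iterative
#' partial least squares algorithm: each component alternates a
#' missing-skipping regression for the scores and for the loadings until
#' convergence, the loading is scaled to unit norm, and the fitted
#' rank-one term is deflated before the next component. On a complete
#' matrix the extracted subspaces coincide with the truncated SVD.
#'
#' @param matrix A `temporal_matrix` or numeric matrix with `NA`s; every
#'   row and column must have at least one observed value.
#' @param r Number of components, `1 <= r < min(m, n)`.
#' @param center Subtract row means (over observed cells) before
#'   extraction; default `TRUE`.
#' @param tol,max_iter Convergence control for each component's
#'   alternating iteration.
#' @return List with `scores` (m x r), `loadings` (n x r, unit-norm
#'   columns), `explained_variance` (fraction per component, decreasing),
#'   `center` (row means used), and `converged` (logical per component;
#'   a non-converged component triggers a warning).
#' @export
nipals_pca <- function(matrix, r, center = TRUE, tol = 1e-9,
                       max_iter = 500) {
  X <- if (inherits(matrix, "temporal_matrix")) matrix$values
       else as.matrix(matrix)
  m <- nrow(X); n <- ncol(X)
  if (r < 1 || r >= min(m, n))
    stop_with("ParameterError", "r must satisfy 1 <= r < min(m, n) = %d",
              min(m, n))
  obs <- !is.na(X)
  if (any(rowSums(obs) == 0) || any(colSums(obs) == 0))
    stop_with("EmptyRowError", "every row and column needs >= 1 observation")
  ctr <- if (center) rowMeans(X, na.rm = TRUE) else rep(0, m)
  R <- X - ctr
  O <- matrix(as.numeric(obs), m, n)
  Rz <- R; Rz[!obs] <- 0
  total_ss <- sum(Rz^2)
  scores <- matrix(0, m, r)
  loadings <- matrix(0, n, r)
  comp_ss <- numeric(r)
  conv <- logical(r)
  for (h in seq_len(r)) {
    t_vec <- Rz[, which.max(colSums(Rz^2))]
    if (all(t_vec == 0)) t_vec <- rep(1, m)
    p <- rep(0, n)
    for (it in seq_len(max_iter)) {
      # loadings: column-wise regression of residual on scores, NA-skipping
      p_den <- drop(crossprod(O, t_vec^2))
      p <- drop(crossprod(Rz, t_vec)) / pmax(p_den, .Machine$double.eps)
      p_norm <- sqrt(sum(p^2))
      if (p_norm == 0) break
      p <- p / p_norm
      # scores: row-wise regression of residual on the unit loading
      t_den <- drop(O %*% p^2)
      t_new <- drop(Rz %*% p) / pmax(t_den, .Machine$double.eps)
      if (sqrt(sum((t_new - t_vec)^2)) <=
          tol * max(sqrt(sum(t_new^2)), .Machine$double.eps)) {
        t_vec <- t_new
        conv[h] <- TRUE
        break
      }
      t_vec <- t_new
    }
    if (!conv[h])
      warning(sprintf("nipals_pca: component %d not converged", h))
    # deterministic sign: largest-magnitude loading element positive
    s <- sign(p[which.max(abs(p))])
    if (s < 0) { p <- -p; t_vec <- -t_vec }
    fit <- tcrossprod(t_vec, p)
    comp_ss[h] <- sum((fit * O)^2)
    scores[, h] <- t_vec
    loadings[, h] <- p
    Rz <- Rz - fit * O
  }
  ord <- order(comp_ss, decreasing = TRUE)
  list(scores = scores[, ord, drop = FALSE],
       loadings = loadings[, ord, drop = FALSE],
       explained_variance = comp_ss[ord] / max(total_ss,
                                               .Machine$double.eps),
       center = ctr, converged = conv[ord])
}

#' Denoise a temporal matrix by reduced-rank PCA reconstruction
#'
#' The PCA preprocessing path: missing cells are first completed
#' ([svd_impute()] or NIPALS-based reconstruction), then the completed
#' row-centered matrix is decomposed and rebuilt from its top `r`
#' principal components (centers restored), so systematic temporal
#' variation is kept and high-frequency noise discarded.
#'
#' @param matrix A `temporal_matrix`.
#' @param r Number of components, or `"auto"` to use the smallest rank
#'   whose cumulative explained variance reaches `var_target`.
#' @param impute `"svdimpute"` (default) or `"nipals"`.
#' @param var_target Cumulative explained-variance target for
#'   `r = "auto"`; default 0.9.
#' @param impute_rank Rank used by the imputation step; defaults to `r`
#'   (or 2 when `r = "auto"`).
#' @return A list with `matrix` (a `preprocessed_matrix`) and `qc`
#'   (a [qc_compare()] report against the input).
#' @export
preprocess_pca <- function(matrix, r = "auto",
                           impute = c("svdimpute", "nipals"),
                           var_target = 0.9, impute_rank = NULL) {
  impute <- match.arg(impute)
  stopifnot(inherits(matrix, "temporal_matrix"))
  vals <- matrix$values
  m <- nrow(vals); n <- ncol(vals)
  auto <- identical(r, "auto")
  if (!auto && (r < 1 || r >= min(m, n)))
    stop_with("ParameterError", "r must satisfy 1 <= r < min(m, n) = %d",
              min(m, n))
  ir <- impute_rank %||% if (auto) 2L else r
  if (anyNA(vals)) {
    complete <- if (impute == "svdimpute") {
      svd_impute(matrix, rank = ir)
    } else {
      np <- nipals_pca(matrix, r = ir)
      recon <- np$center + tcrossprod(np$scores, np$loadings)
      out <- vals
      out[is.na(out)] <- recon[is.na(vals)]
      out
    }
  } else {
    complete <- vals
  }
  ctr <- rowMeans(complete)
  centered <- complete - ctr
  sv <- svd(centered)
  if (auto) {
    cumvar <- cumsum(sv$d^2) / sum(sv$d^2)
    r <- min(which(cumvar >= var_target))
    r <- min(r, min(m, n) - 1L)
  }
  recon <- sv$u[, seq_len(r), drop = FALSE] %*%
    (sv$d[seq_len(r)] * t(sv$v[, seq_len(r), drop = FALSE]))
  out <- recon + ctr
  pm <- temporal_matrix(out, matrix$time_points, matrix$variable_ids,
                        matrix$meta)
  pm$method <- "pca"
  pm$params <- list(r = r, impute = impute,
                    var_target = if (auto) var_target else NA_real_)
  pm$row_method <- rep("pca", m)
  class(pm) <- c("preprocessed_matrix", class(pm))
  list(matrix = pm, qc = qc_compare(matrix, pm))
}
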