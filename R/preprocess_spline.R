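# Module I, spline path: cubic smoothing splines fit per variable at an
# effective degrees of freedom chosen by cross-validation; imputes
# missing cells and smooths observed ones in a single fit.

# Design matrix of the cubic regression-spline family at `dof` degrees
# of freedom (model dimension incl. intercept): dof = 2 line, 3
# quadratic, 4 cubic polynomial, >= 5 cubic B-splines with dof - 4
# interior knots at quantiles of the observed times. Evaluated at `x`
# with basis anchored on the observed times `x_obs`.
.spline_basis <- function(x, x_obs, dof) {
  if (dof <= 4) {
    outer(x, seq_len(dof - 1), `^`)
  } else {
    knots <- stats::quantile(x_obs, probs =
                               seq_len(dof - 4) / (dof - 3), names = FALSE)
    suppressWarnings(
      splines::bs(x, knots = knots, degree = 3,
                  Boundary.knots = range(x_obs)))
  }
}

#' Fit a cubic spline to one time course
#'
#' Fits a cubic regression spline to the observed (time, value) pairs
#' of one variable at the requested degrees of freedom and evaluates it
#' at every time point, so missing cells are imputed and observed cells
#' are denoised by the same model. `dof` counts the model dimension
#' (including the intercept): 2 is a straight line, 3 a quadratic, 4 a
#' cubic polynomial, and each further degree adds an interior knot;
#' `dof` equal to the number of observed points interpolates them.
#'
#' @param series Numeric vector of length n; `NA` marks missing cells.
#' @param time_points Strictly increasing numeric vector of length n.
#' @param dof Degrees of freedom, between 2 and the number of observed
#'   points.
#' @return Numeric vector of length n: the fitted curve evaluated at
#'   all `time_points`. Time points outside the observed range follow
#'   the boundary polynomial piece.
#' @details Requires at least 4 observed points; variables with fewer
#'   must be routed to the PCA/SVD imputation path (see
#'   [preprocess_spline()]).
#' @export
fit_spline_variable <- function(series, time_points, dof) {
  obs <- which(!is.na(series))
  n_obs <- length(obs)
  if (n_obs < 4)
    stop_with("InsufficientPointsError",
              "spline requires >= 4 observed points (got %d)", n_obs)
  if (dof < 2 - 1e-9)
    stop_with("ParameterError", "dof must be >= 2 (got %s)", format(dof))
  dof <- min(round(dof), n_obs)
  x <- time_points[obs]
  y <- series[obs]
  B <- cbind(1, .spline_basis(x, x, dof))
  coef <- qr.coef(qr(B), y)
  coef[is.na(coef)] <- 0
  drop(cbind(1, .spline_basis(time_points, x, dof)) %*% coef)
}

# Cross-validation scores for one variable over a dof grid. "gcv" is
# generalized cross-validation, n * RSS / (n - dof)^2; "loo" is the
# exact leave-one-out identity for least-squares fits,
# err_i = ((y_i - yhat_i) / (1 - h_ii))^2 with h the hat-matrix
# leverage. Returns summed scores (NA where a grid dof would
# interpolate, making held-out prediction meaningless).
.cv_errors <- function(series, time_points, dof_grid,
                       criterion = c("gcv", "loo")) {
  criterion <- match.arg(criterion)
  obs <- which(!is.na(series))
  x <- time_points[obs]
  y <- series[obs]
  n_obs <- length(obs)
  errs <- rep(NA_real_, length(dof_grid))
  for (g in seq_along(dof_grid)) {
    dof <- dof_grid[g]
    if (dof > n_obs - 1) next
    B <- cbind(1, .spline_basis(x, x, dof))
    qrB <- qr(B)
    yhat <- qr.fitted(qrB, y)
    errs[g] <- if (criterion == "gcv") {
      n_obs * sum((y - yhat)^2) / (n_obs - dof)^2
    } else {
      h <- rowSums(qr.Q(qrB)[, seq_len(qrB$rank), drop = FALSE]^2)
      sum(((y - yhat) / pmax(1 - h, 1e-12))^2)
    }
  }
  errs
}

#' Choose spline degrees of freedom by cross-validation
#'
#' Scores each candidate dof by a cross-validation estimate of the
#' held-out squared prediction error, either globally (one dof
#' minimizing the total score summed across eligible variables,
#' matching a single shared smoothness for the whole matrix) or per
#' variable. Ties — including numerically indistinguishable scores, as
#' on noiseless data — break toward the smallest dof (the smoother
#' model).
#'
#' @param matrix A `temporal_matrix`.
#' @param dof_grid Numeric grid of candidate degrees of freedom
#'   (default `c(2, 3, 4, 5)`, suited to a 6-point time axis).
#' @param mode `"global"` or `"per_variable"`.
#' @param criterion `"gcv"` (generalized cross-validation,
#'   `n RSS / (n - dof)^2`, the default) or `"loo"` (the exact
#'   leave-one-out identity `sum(((y - yhat)/(1 - h))^2)`). With only a
#'   handful of time points the LOO score is dominated by the boundary
#'   points, whose leverages approach 1 as dof grows, which biases
#'   selection toward the line model; GCV replaces the pointwise
#'   leverages by their average and is the standard criterion for
#'   spline smoothness selection.
#' @return For `"global"`, a list with `dof`, `cv_error` (total score at
#'   each grid value) and `n_eligible`; for `"per_variable"`, a list with
#'   `dof` (named vector, NA for ineligible variables) and `cv_error`
#'   matrix.
#' @details A variable is eligible when it has at least 5 observed
#'   points, so every held-out fit retains the 4 points a cubic spline
#'   needs.
#' @export
select_dof_cv <- function(matrix, dof_grid = c(2, 3, 4, 5),
                          mode = c("global", "per_variable"),
                          criterion = c("gcv", "loo")) {
  mode <- match.arg(mode)
  criterion <- match.arg(criterion)
  stopifnot(inherits(matrix, "temporal_matrix"))
  if (any(dof_grid < 2))
    stop_with("ParameterError", "dof grid values must be >= 2")
  dof_grid <- sort(unique(dof_grid))
  n_obs <- rowSums(!is.na(matrix$values))
  eligible <- which(n_obs >= 5)
  if (!length(eligible))
    stop_with("NoEligibleVariablesError",
              "no variable has >= 5 observed points for leave-one-out CV")
  errs <- t(vapply(eligible, function(i)
    .cv_errors(matrix$values[i, ], matrix$time_points, dof_grid,
               criterion),
    numeric(length(dof_grid))))
  rownames(errs) <- matrix$variable_ids[eligible]
  colnames(errs) <- as.character(dof_grid)
  # near-equal CV errors (numerical noise) tie toward the smallest dof
  pick <- function(e) {
    tol <- 1e-6 * (1 + min(e, na.rm = TRUE))
    which(!is.na(e) & e <= min(e, na.rm = TRUE) + tol)[1]
  }
  if (mode == "global") {
    tot <- colSums(errs, na.rm = TRUE)
    usable <- colSums(is.na(errs)) == 0
    if (any(usable)) tot[!usable] <- Inf
    list(dof = dof_grid[pick(tot)], cv_error = tot,
         n_eligible = length(eligible))
  } else {
    dof <- rep(NA_real_, nrow(matrix$values))
    names(dof) <- matrix$variable_ids
    dof[eligible] <- dof_grid[apply(errs, 1, pick)]
    list(dof = dof, cv_error = errs, n_eligible = length(eligible))
  }
}

#' Impute and denoise a temporal matrix with cubic splines
#'
#' The spline preprocessing path: every variable with at least 4
#' observed points is fit by [fit_spline_variable()] (imputing its
#' missing cells and smoothing the observed ones); variables with fewer
#' observations are completed by [svd_impute()] on the full matrix and
#' left unsmoothed.
#'
#' @param matrix A `temporal_matrix`.
#' @param dof `"cv.global"` (one CV-chosen dof for all variables, the
#'   default), `"cv.per_variable"`, or a fixed numeric value.
#' @param dof_grid Grid searched when `dof` is a CV mode.
#' @param fallback_rank Rank of the SVD-imputation fallback for rows
#'   with < 4 observations; default 2.
#' @return A list with `matrix` (a `preprocessed_matrix`: complete
#'   `temporal_matrix` plus `method`, `params`, and per-row `row_method`
#'   tags `"spline"`/`"svdimpute"`) and `qc` (a [qc_compare()] report
#'   against the input).
#' @export
preprocess_spline <- function(matrix, dof = "cv.global",
                              dof_grid = c(2, 3, 4, 5),
                              fallback_rank = 2) {
  stopifnot(inherits(matrix, "temporal_matrix"))
  vals <- matrix$values
  n_obs <- rowSums(!is.na(vals))
  spline_rows <- which(n_obs >= 4)
  fallback_rows <- which(n_obs < 4)

  dof_per_row <- rep(NA_real_, nrow(vals))
  if (identical(dof, "cv.global")) {
    sel <- select_dof_cv(matrix, dof_grid, mode = "global")
    dof_per_row[spline_rows] <- sel$dof
    dof_label <- sprintf("cv.global=%g", sel$dof)
  } else if (identical(dof, "cv.per_variable")) {
    sel <- select_dof_cv(matrix, dof_grid, mode = "per_variable")
    dof_per_row <- sel$dof
    # eligible for spline but not for CV (exactly 4 obs): smallest grid dof
    dof_per_row[spline_rows][is.na(dof_per_row[spline_rows])] <- min(dof_grid)
    dof_label <- "cv.per_variable"
  } else if (is.numeric(dof) && length(dof) == 1) {
    dof_per_row[spline_rows] <- dof
    dof_label <- sprintf("fixed=%g", dof)
  } else {
    stop_with("ParameterError",
              "dof must be 'cv.global', 'cv.per_variable' or a number")
  }

  out <- vals
  for (i in spline_rows) {
    d <- min(dof_per_row[i], n_obs[i])
    out[i, ] <- fit_spline_variable(vals[i, ], matrix$time_points, d)
  }
  if (length(fallback_rows)) {
    completed <- svd_impute(matrix, rank = fallback_rank)
    out[fallback_rows, ] <- completed[fallback_rows, ]
  }

  row_method <- unname(ifelse(n_obs >= 4, "spline", "svdimpute"))
  pm <- temporal_matrix(out, matrix$time_points, matrix$variable_ids,
                        matrix$meta)
  pm$method <- "spline"
  pm$params <- list(dof = dof_label, dof_per_row = dof_per_row,
                    fallback_rank = fallback_rank)
  pm$row_method <- row_method
  class(pm) <- c("preprocessed_matrix", class(pm))
  list(matrix = pm, qc = qc_compare(matrix, pm))
}
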