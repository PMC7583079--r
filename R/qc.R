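# Quality control: compare a preprocessed matrix with its input.

#' Compare preprocessed and original matrices
#'
#' For every variable, the Pearson correlation and the mean squared
#' difference between the original and processed values are computed
#' over the cells observed in the original, summarized by their medians.
#' High median correlation and low median MSD indicate that
#' preprocessing preserved the input's temporal signal while imputing
#' and denoising.
#'
#' @param original A `temporal_matrix` (may contain missing cells).
#' @param processed A complete matrix of the same shape and ids
#'   (typically a `preprocessed_matrix`).
#' @return A `qc_report` list: `per_variable_pearson`,
#'   `per_variable_msd` (named length-m vectors), `median_pearson`,
#'   `median_msd`, and `n_pearson_excluded` (rows with < 3 observed
#'   cells or zero variance, excluded from the correlation median but
#'   kept in the MSD median).
#' @export
qc_compare <- function(original, processed) {
  stopifnot(inherits(original, "temporal_matrix"))
  pv <- if (inherits(processed, "temporal_matrix")) processed$values
        else as.matrix(processed)
  ov <- original$values
  if (!all(dim(ov) == dim(pv)))
    stop_with("ShapeError", "shape mismatch: %dx%d vs %dx%d",
              nrow(ov), ncol(ov), nrow(pv), ncol(pv))
  m <- nrow(ov)
  pearson <- rep(NA_real_, m)
  msd <- rep(NA_real_, m)
  for (i in seq_len(m)) {
    o <- which(!is.na(ov[i, ]))
    x <- ov[i, o]; y <- pv[i, o]
    msd[i] <- mean((x - y)^2)
    if (length(o) >= 3 && stats::sd(x) > 0 && stats::sd(y) > 0)
      pearson[i] <- stats::cor(x, y)
  }
  names(pearson) <- names(msd) <- original$variable_ids
  structure(list(per_variable_pearson = pearson,
                 per_variable_msd = msd,
                 median_pearson = stats::median(pearson, na.rm = TRUE),
                 median_msd = stats::median(msd),
                 n_pearson_excluded = sum(is.na(pearson))),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("QC: median Pearson %.3f (%d rows excluded), median MSD %.4g\n",
              x$median_pearson, x$n_pearson_excluded, x$median_msd))
  invisible(x)
}
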