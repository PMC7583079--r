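# Dynamic time warping distance for equal-length series.

#' Dynamic time warping distance
#'
#' Classical DTW between two equal-length series: a cumulative-cost grid
#' with squared pointwise cost and steps {match, insert, delete}
#' (symmetric step pattern, no path-length normalization), optionally
#' restricted to a Sakoe-Chiba band. The returned value is the square
#' root of the terminal cumulative cost, so it coincides with the
#' Euclidean distance when the optimal path is the diagonal and is
#' never larger than it.
#'
#' @param a,b Numeric vectors of equal length.
#' @param window Sakoe-Chiba half-width (cells with `|i - j| > window`
#'   are forbidden); `NULL` for the unconstrained distance.
#' @return A single non-negative number.
#' @export
dtw_distance <- function(a, b, window = NULL) {
  if (length(a) != length(b))
    stop_with("ShapeError", "series lengths differ (%d vs %d)",
              length(a), length(b))
  n <- length(a)
  if (n < 1) stop_with("ParameterError", "series must be non-empty")
  if (!is.null(window)) {
    if (window < 0)
      stop_with("ParameterError", "window must be >= 0")
    # equal lengths: the diagonal satisfies any band, but reject bands
    # that cannot connect the corners for completeness
    if (abs(n - n) > window && window < abs(n - n))
      stop_with("ParameterError", "window too small to connect corners")
  }
  D <- matrix(Inf, n + 1, n + 1)
  D[1, 1] <- 0
  for (i in seq_len(n)) {
    jr <- if (is.null(window)) seq_len(n) else
      seq(max(1, i - window), min(n, i + window))
    for (j in jr) {
      cost <- (a[i] - b[j])^2
      D[i + 1, j + 1] <- cost + min(D[i, j], D[i, j + 1], D[i + 1, j])
    }
  }
  sqrt(D[n + 1, n + 1])
}
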