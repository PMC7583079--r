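# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

stop_with <- function(class, msg, ...) {
  stop(structure(class = c(class, "temposig_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Adjusted Rand Index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items,
#' computed from the pair-counting contingency formula. Used to score how
#' well a clustering recovers known group structure (1 = identical
#' partitions up to relabeling, ~0 = chance agreement).
#'
#' @param a,b Vectors of cluster labels of equal length (any atomic type).
#' @return A single number, at most 1.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b))
    stop_with("ShapeError", "label vectors differ in length (%d vs %d)",
              length(a), length(b))
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}
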