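# Post-clustering functional summary: cluster x biological-function
# bubble table with hypergeometric over-representation tests.

#' Read an annotation map from two TSV files
#'
#' @param variable_protein_path TSV with columns `variable_id`,
#'   `protein_id` (one variable per line).
#' @param protein_function_path TSV with columns `protein_id`,
#'   `function_term` (one pair per line; a protein may appear under
#'   several biological functions).
#' @return An `annotation_map` list with `variable_to_protein` (named
#'   character vector) and `protein_to_functions` (named list of
#'   character vectors).
#' @export
read_annotation_map <- function(variable_protein_path,
                                protein_function_path) {
  vp <- utils::read.table(variable_protein_path, sep = "\t", header = TRUE,
                          colClasses = "character")
  pf <- utils::read.table(protein_function_path, sep = "\t", header = TRUE,
                          colClasses = "character")
  annotation_map(stats::setNames(vp[[2]], vp[[1]]),
                 split(pf[[2]], pf[[1]]))
}

#' Construct an annotation map
#'
#' @param variable_to_protein Named character vector: variable id ->
#'   host protein id.
#' @param protein_to_functions Named list: protein id -> character
#'   vector of biological-function terms (may be empty).
#' @return An `annotation_map`.
#' @export
annotation_map <- function(variable_to_protein, protein_to_functions) {
  stopifnot(!is.null(names(variable_to_protein)))
  structure(list(variable_to_protein = variable_to_protein,
                 protein_to_functions = protein_to_functions),
            class = "annotation_map")
}

#' Hypergeometric over-representation test
#'
#' Upper-tail probability `P(X >= k)` for
#' `X ~ Hypergeometric(N, K_f, n_c)`: the chance of drawing at least
#' `k` members of a function set of size `K_f` when sampling `n_c`
#' proteins from a universe of `N`.
#'
#' @param k Observed overlap.
#' @param K_f Function-set size in the universe.
#' @param n_c Draw (cluster) size.
#' @param N Universe size.
#' @return A p-value in (0, 1].
#' @export
hypergeometric_test <- function(k, K_f, n_c, N) {
  if (k < 0 || K_f < 0 || n_c < 0 || N < 0 ||
      k > min(K_f, n_c) || K_f > N || n_c > N)
    stop_with("ParameterError",
              "need 0 <= k <= min(K_f, n_c) and K_f, n_c <= N")
  stats::phyper(k - 1, K_f, N - K_f, n_c, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up adjusted values (monotone, clamped to [0, 1]).
#'
#' @param p_values Numeric vector in [0, 1].
#' @return Vector of q-values, `q >= p` elementwise.
#' @export
bh_fdr <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop_with("ParameterError", "p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Cluster-by-function bubble table
#'
#' Summarizes the selected variables by (temporal cluster x biological
#' function): the number of selected molecular events in the cell, the
#' number of distinct host proteins among them, and a hypergeometric
#' over-representation p-value computed at the protein level (distinct
#' proteins of the cluster drawn from the annotated protein universe),
#' with Benjamini-Hochberg q-values across all emitted cells and a
#' significance flag at q < 0.05. Directly plottable as a bubble chart.
#'
#' @param selection A `selection_report` from [pip_filter()].
#' @param clustering A `clustering_result` whose labels cover the
#'   selected variables.
#' @param annot An `annotation_map`.
#' @param universe `"selected"` (default: all proteins hosting at least
#'   one selected variable) or `"annotation"` (all proteins in the map).
#' @param alpha Significance cutoff on q; default 0.05.
#' @return A data frame with columns `cluster`, `fun`, `event_count`,
#'   `protein_count`, `p`, `q`, `significant`; zero rows (with a
#'   warning) when no selected variable is annotated.
#' @export
build_bubble_table <- function(selection, clustering, annot,
                               universe = c("selected", "annotation"),
                               alpha = 0.05) {
  universe <- match.arg(universe)
  stopifnot(inherits(selection, "selection_report"),
            inherits(clustering, "clustering_result"),
            inherits(annot, "annotation_map"))
  ids <- selection$retained_ids
  labels <- clustering$labels[ids]
  if (anyNA(labels))
    stop_with("ParameterError", "selected ids missing cluster labels")
  prot <- annot$variable_to_protein[ids]
  annotated <- !is.na(prot)
  if (!any(annotated)) {
    warning("no selected variable is covered by the annotation map")
    return(data.frame(cluster = integer(), fun = character(),
                      event_count = integer(), protein_count = integer(),
                      p = numeric(), q = numeric(),
                      significant = logical()))
  }
  ids <- ids[annotated]; labels <- labels[annotated]; prot <- prot[annotated]

  univ_prot <- if (universe == "selected") unique(prot)
               else unique(names(annot$protein_to_functions))
  # proteins per function, restricted to the universe
  pf <- annot$protein_to_functions[names(annot$protein_to_functions)
                                   %in% univ_prot]
  fun_to_prot <- split(rep(names(pf), lengths(pf)), unlist(pf))
  N <- length(univ_prot)

  cells <- list()
  for (k in sort(unique(labels))) {
    in_k <- labels == k
    prot_k <- unique(prot[in_k])
    for (f in sort(unique(unlist(annot$protein_to_functions[prot[in_k]])))) {
      f_prot <- unique(fun_to_prot[[f]])
      overlap_prot <- intersect(prot_k, f_prot)
      if (!length(overlap_prot)) next
      events <- sum(in_k & prot %in% f_prot)
      p <- hypergeometric_test(length(overlap_prot), length(f_prot),
                               length(prot_k), N)
      cells[[length(cells) + 1]] <- data.frame(
        cluster = k, fun = f, event_count = events,
        protein_count = length(overlap_prot), p = p)
    }
  }
  if (!length(cells)) {
    warning("no (cluster, function) cell has any event")
    return(data.frame(cluster = integer(), fun = character(),
                      event_count = integer(), protein_count = integer(),
                      p = numeric(), q = numeric(),
                      significant = logical()))
  }
  tab <- do.call(rbind, cells)
  tab$q <- bh_fdr(tab$p)
  tab$significant <- tab$q < alpha
  tab[order(tab$cluster, tab$fun), ]
}
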