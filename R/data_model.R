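# Temporal matrix container, replicate collapsing and the fold-change
# pre-filter that defines the platform's input.

MISSING_TOKENS <- c("", "na", "nan", "null")

#' Construct a temporal matrix
#'
#' The platform's central object: an m x n numeric matrix of log-ratio
#' values (rows = molecular events such as protein modification sites,
#' columns = ordered time points, e.g. days 1, 3, 5, 7, 10, 14), with
#' missing cells allowed.
#'
#' @param values Numeric matrix, m x n; `NA` marks missing cells.
#' @param time_points Strictly increasing numeric vector of length n
#'   (days); n >= 2.
#' @param variable_ids Character vector of m unique row identifiers.
#'   Defaults to `rownames(values)`.
#' @param meta Named list of free-form provenance strings.
#' @return An object of class `temporal_matrix` with elements `values`
#'   (rownames = variable ids, colnames = time points), `time_points`,
#'   `variable_ids` and `meta`.
#' @details Every row must retain at least one observed value; rows of
#'   all-missing cells are rejected.
#' @export
temporal_matrix <- function(values, time_points,
                            variable_ids = rownames(values),
                            meta = list()) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  time_points <- as.numeric(time_points)
  if (length(time_points) != ncol(values))
    stop_with("ShapeError", "time axis length %d does not match %d columns",
              length(time_points), ncol(values))
  if (length(time_points) < 2 || any(diff(time_points) <= 0))
    stop_with("TimeAxisError",
              "time points must be strictly increasing with n >= 2")
  if (is.null(variable_ids))
    variable_ids <- paste0("V", seq_len(nrow(values)))
  variable_ids <- as.character(variable_ids)
  if (length(variable_ids) != nrow(values))
    stop_with("ShapeError", "%d variable ids for %d rows",
              length(variable_ids), nrow(values))
  if (anyDuplicated(variable_ids))
    stop_with("DuplicateIdError", "duplicate variable ids: %s",
              paste(unique(variable_ids[duplicated(variable_ids)]),
                    collapse = ", "))
  all_na <- rowSums(!is.na(values)) == 0
  if (any(all_na))
    stop_with("EmptyRowError", "rows with no observed value: %s",
              paste(variable_ids[all_na], collapse = ", "))
  dimnames(values) <- list(variable_ids, as.character(time_points))
  structure(list(values = values, time_points = time_points,
                 variable_ids = variable_ids, meta = meta),
            class = "temporal_matrix")
}

#' @export
print.temporal_matrix <- function(x, ...) {
  cat(sprintf("temporal_matrix: %d variables x %d time points (%s)\n",
              nrow(x$values), length(x$time_points),
              paste(x$time_points, collapse = ", ")))
  n_miss <- sum(is.na(x$values))
  cat(sprintf("  missing cells: %d (%.1f%%)\n", n_miss,
              100 * n_miss / length(x$values)))
  invisible(x)
}

#' @export
dim.temporal_matrix <- function(x) dim(x$values)

#' Read a temporal matrix from a delimited text file
#'
#' Expects a header row of time points (parseable as numbers) and a first
#' column of variable identifiers. The tokens `""`, `"NA"`, `"NaN"` and
#' `"null"` (case-insensitive) become missing cells.
#'
#' @param path File path.
#' @param delimiter Field separator; default tab.
#' @param extra_missing_tokens Additional strings to treat as missing.
#' @return A [temporal_matrix()].
#' @export
read_temporal_matrix <- function(path, delimiter = "\t",
                                 extra_missing_tokens = character()) {
  df <- utils::read.table(path, sep = delimiter, header = TRUE,
                          check.names = FALSE, colClasses = "character",
                          comment.char = "", quote = "\"",
                          na.strings = character(0))
  tp <- suppressWarnings(as.numeric(sub("^[Xx]", "", colnames(df)[-1])))
  if (anyNA(tp))
    stop_with("TimeAxisError", "header time points not numeric: %s",
              paste(colnames(df)[-1][is.na(tp)], collapse = ", "))
  ids <- df[[1]]
  cells <- as.matrix(df[, -1, drop = FALSE])
  miss <- tolower(trimws(cells)) %in%
    c(MISSING_TOKENS, tolower(extra_missing_tokens))
  vals <- suppressWarnings(as.numeric(cells))
  bad <- !miss & is.na(vals)
  if (any(bad))
    stop_with("ParseError", "non-numeric cell(s), e.g. '%s' in row '%s'",
              cells[which(bad)[1]], ids[(which(bad)[1] - 1) %% nrow(df) + 1])
  vals[miss] <- NA_real_
  m <- matrix(vals, nrow = nrow(df))
  temporal_matrix(m, tp, ids, meta = list(source = path))
}

#' Write a temporal matrix as TSV
#'
#' Inverse of [read_temporal_matrix()]: header = time points, first
#' column `variable_id`, missing cells written as `NA`.
#'
#' @param x A `temporal_matrix`.
#' @param path Output file path.
#' @param delimiter Field separator; default tab.
#' @export
write_temporal_matrix <- function(x, path, delimiter = "\t") {
  df <- data.frame(variable_id = x$variable_ids, x$values,
                   check.names = FALSE)
  colnames(df)[-1] <- as.character(x$time_points)
  utils::write.table(df, path, sep = delimiter, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Collapse a replicate-level occupancy table to a log-ratio matrix
#'
#' Each (variable, time) cell is formed by pairing treated and control
#' occupancies within matched replicates, taking per-replicate
#' treated/control ratios, averaging the ratios, and then taking the
#' logarithm: `cell = log_base(mean(ratio))`.
#'
#' @param table Data frame with columns `variable_id`, `time`,
#'   `condition` (`"treated"` or `"control"`), `replicate`, `occupancy`.
#' @param log_base Base of the final log transform; default 2 so a cell
#'   value of 1 means a 2-fold increase.
#' @return A [temporal_matrix()].
#' @details Replicates are paired by replicate index; unmatched
#'   replicates are skipped. A matched pair with control occupancy 0 is
#'   discarded rather than producing an infinite ratio; a (variable,
#'   time) with no usable pair becomes a missing cell.
#' @export
collapse_replicates <- function(table, log_base = 2) {
  table <- as.data.frame(table)
  need <- c("variable_id", "time", "condition", "replicate", "occupancy")
  missing_cols <- setdiff(need, colnames(table))
  if (length(missing_cols))
    stop_with("ParseError", "replicate table lacks column(s): %s",
              paste(missing_cols, collapse = ", "))
  if (any(table$occupancy < 0, na.rm = TRUE))
    stop_with("ParameterError", "occupancy must be non-negative")
  cond <- tolower(as.character(table$condition))
  if (!all(cond %in% c("treated", "control")))
    stop_with("ParameterError", "condition must be 'treated' or 'control'")

  ids <- unique(as.character(table$variable_id))
  tps <- sort(unique(as.numeric(table$time)))
  vals <- matrix(NA_real_, length(ids), length(tps))
  key <- interaction(table$variable_id, table$time, drop = TRUE)
  for (grp in split(seq_len(nrow(table)), key)) {
    sub <- table[grp, ]
    trt <- sub[cond[grp] == "treated", ]
    ctl <- sub[cond[grp] == "control", ]
    reps <- intersect(trt$replicate, ctl$replicate)
    ratios <- numeric(0)
    for (r in reps) {
      tv <- trt$occupancy[match(r, trt$replicate)]
      cv <- ctl$occupancy[match(r, ctl$replicate)]
      if (!is.na(tv) && !is.na(cv) && cv > 0) ratios <- c(ratios, tv / cv)
    }
    if (length(ratios)) {
      i <- match(as.character(sub$variable_id[1]), ids)
      j <- match(as.numeric(sub$time[1]), tps)
      vals[i, j] <- log(mean(ratios), base = log_base)
    }
  }
  temporal_matrix(vals, tps, ids,
                  meta = list(log_base = as.character(log_base)))
}

#' Filter variables with limited dynamic change
#'
#' Keeps a variable only if at least one observed time point shows at
#' least a `threshold`-fold change in either direction, i.e.
#' `max |cell| >= log_base(threshold)` over observed cells.
#'
#' @param matrix A `temporal_matrix` of log ratios.
#' @param threshold Fold-change ratio, > 1 (default 1.2, the conventional
#'   cutoff for removing flat profiles).
#' @param log_base Base in which the matrix cells are logged; default 2.
#' @return A list with `matrix` (the filtered `temporal_matrix`) and
#'   `report` (a `filter_report` with counts and dropped ids).
#' @export
fold_change_filter <- function(matrix, threshold = 1.2, log_base = 2) {
  stopifnot(inherits(matrix, "temporal_matrix"))
  if (!is.numeric(threshold) || threshold <= 1)
    stop_with("ParameterError", "threshold must be > 1 (got %s)",
              format(threshold))
  cut <- log(threshold, base = log_base)
  mx <- apply(abs(matrix$values), 1, max, na.rm = TRUE)
  keep <- mx >= cut
  report <- structure(list(threshold = threshold, log_base = log_base,
                           n_input = length(keep), n_kept = sum(keep),
                           n_dropped = sum(!keep),
                           dropped_ids = matrix$variable_ids[!keep]),
                      class = "filter_report")
  filtered <- temporal_matrix(matrix$values[keep, , drop = FALSE],
                              matrix$time_points,
                              matrix$variable_ids[keep], matrix$meta)
  list(matrix = filtered, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf(
    "fold-change filter (>= %.3g-fold): kept %d / %d, dropped %d\n",
    x$threshold, x$n_kept, x$n_input, x$n_dropped))
  invisible(x)
}
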