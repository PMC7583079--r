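# Seeded generators of temporal matrices with known cluster structure,
# so every stage of the platform is testable without any download. The
# defaults emulate the structure of a cardiac oxidative-PTM time
# course: ~6 time points over two weeks, five temporal archetypes,
# four replicates, additive Gaussian noise on the log-ratio scale.

#' Default temporal cluster templates
#'
#' Five archetypal time-course shapes over the default 6-point axis
#' (days 1, 3, 5, 7, 10, 14), unit amplitude: continual descent,
#' continual ascent, early descent then floor, slight descent then
#' accelerated rise, and early rise then relapse to baseline.
#'
#' @param time_points Time axis; default `c(1, 3, 5, 7, 10, 14)`.
#' @return A 5 x n matrix, rows named T1..T5.
#' @export
default_templates <- function(time_points = c(1, 3, 5, 7, 10, 14)) {
  t01 <- (time_points - min(time_points)) /
    (max(time_points) - min(time_points))
  tmpl <- rbind(
    1 - 2 * t01,                                   # continual descent
    2 * t01 - 1,                                   # continual ascent
    pmax(1 - 4 * t01, -1),                         # descent then floor
    ifelse(t01 < 0.5, -0.6 * t01, -0.3 + 2.6 * (t01 - 0.5)),
    sin(pi * pmin(t01 / 0.85, 1))                  # rise then relapse
  )
  rownames(tmpl) <- paste0("T", 1:5)
  colnames(tmpl) <- as.character(time_points)
  tmpl
}

#' Generate a clustered synthetic time-course matrix with known truth
#'
#' Each signal row is a cluster template plus i.i.d. Gaussian noise of
#' standard deviation `amplitude / snr` (amplitude = largest absolute
#' template value); a `spike_noise_fraction` of rows are pure noise
#' with true label 0; cells are then deleted uniformly at random at
#' `missing_rate`, keeping at least `min_observed` cells per row.
#' Deterministic given `seed`.
#'
#' @param m Number of rows; default 1600.
#' @param K Number of clusters; default 5 (requires `K <=
#'   nrow(templates)`).
#' @param time_points Time axis; default days `c(1, 3, 5, 7, 10, 14)`.
#' @param templates K x n template matrix; default the first K rows of
#'   [default_templates()].
#' @param snr Signal-to-noise ratio (template amplitude over noise sd);
#'   default 4.
#' @param missing_rate Fraction of cells deleted; default 0.15.
#' @param spike_noise_fraction Fraction of pure-noise rows; default 0.
#' @param min_observed Minimum observed cells kept per row; default 4
#'   (the spline path's requirement).
#' @param seed RNG seed; default 20200603.
#' @return A list with `matrix` (a [temporal_matrix()]), and `truth`
#'   (`true_labels` with 0 = noise row, `noiseless_matrix`,
#'   `missing_mask`, `noise_sd`).
#' @export
generate_clustered_timecourses <- function(m = 1600, K = 5,
                                           time_points = c(1, 3, 5, 7, 10, 14),
                                           templates = NULL,
                                           snr = 4, missing_rate = 0.15,
                                           spike_noise_fraction = 0,
                                           min_observed = 4,
                                           seed = 20200603) {
  n <- length(time_points)
  templates <- templates %||% default_templates(time_points)[seq_len(K), ,
                                                             drop = FALSE]
  if (nrow(templates) != K || ncol(templates) != n)
    stop_with("ShapeError", "templates must be K x n")
  if (missing_rate < 0 || missing_rate >= 1)
    stop_with("ParameterError", "missing_rate must lie in [0, 1)")
  if (min_observed > n)
    stop_with("ParameterError",
              "cannot keep %d observed cells of %d", min_observed, n)
  amplitude <- max(abs(templates))
  noise_sd <- amplitude / snr
  with_seed(seed, {
    n_spike <- round(spike_noise_fraction * m)
    labels <- c(sample(rep_len(seq_len(K), m - n_spike)),
                rep(0L, n_spike))
    labels <- labels[sample.int(m)]
    noiseless <- matrix(0, m, n)
    noiseless[labels > 0, ] <- templates[labels[labels > 0], ]
    vals <- noiseless + matrix(stats::rnorm(m * n, sd = noise_sd), m, n)
    mask <- matrix(FALSE, m, n)
    if (missing_rate > 0) {
      for (i in seq_len(m)) {
        drop <- which(stats::runif(n) < missing_rate)
        if (n - length(drop) < min_observed)
          drop <- sample.int(n, n - min_observed)
        mask[i, drop] <- TRUE
      }
    }
    vals[mask] <- NA_real_
    ids <- sprintf("V%04d", seq_len(m))
    tm <- temporal_matrix(vals, time_points, ids,
                          meta = list(generator = "clustered", snr =
                                        as.character(snr)))
    dimnames(noiseless) <- dimnames(mask) <- list(ids,
                                                  as.character(time_points))
    list(matrix = tm,
         truth = list(true_labels = stats::setNames(labels, ids),
                      noiseless_matrix = noiseless, missing_mask = mask,
                      noise_sd = noise_sd, templates = templates))
  })
}

#' Generate a pure-noise temporal matrix
#'
#' An m x n matrix of i.i.d. standard Gaussian cells with no missing
#' values and no cluster structure; used to calibrate the jackstraw
#' null.
#'
#' @param m,n Dimensions (both >= 2).
#' @param seed RNG seed.
#' @return A [temporal_matrix()] with time axis 1..n.
#' @export
generate_null_matrix <- function(m, n, seed = 20200603) {
  if (m < 2 || n < 2)
    stop_with("ParameterError", "need m, n >= 2")
  with_seed(seed, {
    vals <- matrix(stats::rnorm(m * n), m, n)
    temporal_matrix(vals, seq_len(n), sprintf("N%04d", seq_len(m)),
                    meta = list(generator = "null"))
  })
}

#' Generate a replicate-level occupancy table with known truth
#'
#' Emulates a treated-vs-control occupancy design: per (variable, time),
#' control occupancies are drawn around a positive baseline and treated
#' occupancies equal control times the template fold change (in
#' `log_base`) times multiplicative replicate noise, so
#' [collapse_replicates()] recovers the noiseless log-ratio matrix as
#' the replicate count grows.
#'
#' @param m Number of variables; default 50.
#' @param K Number of clusters; default 5.
#' @param time_points Time axis; default `c(1, 3, 5, 7, 10, 14)`.
#' @param n_replicates Replicates per condition; default 4.
#' @param replicate_cv Coefficient of variation of the multiplicative
#'   replicate noise (0 = noiseless); default 0.05.
#' @param baseline Mean control occupancy; default 1.
#' @param log_base Log base of the template log ratios; default 2.
#' @param seed RNG seed.
#' @return A list with `table` (long-format data frame with columns
#'   `variable_id`, `time`, `condition`, `replicate`, `occupancy`) and
#'   `truth` (`noiseless_matrix`, `true_labels`).
#' @export
generate_replicate_table <- function(m = 50, K = 5,
                                     time_points = c(1, 3, 5, 7, 10, 14),
                                     n_replicates = 4, replicate_cv = 0.05,
                                     baseline = 1, log_base = 2,
                                     seed = 20200603) {
  templates <- default_templates(time_points)[seq_len(K), , drop = FALSE]
  n <- length(time_points)
  with_seed(seed, {
    labels <- sample(rep_len(seq_len(K), m))
    noiseless <- templates[labels, , drop = FALSE]
    ids <- sprintf("V%04d", seq_len(m))
    rows <- vector("list", m * n * n_replicates * 2)
    idx <- 1
    for (i in seq_len(m)) {
      for (j in seq_len(n)) {
        fold <- log_base^noiseless[i, j]
        for (r in seq_len(n_replicates)) {
          ctl <- baseline * if (replicate_cv > 0)
            exp(stats::rnorm(1, sd = replicate_cv)) else 1
          noise <- if (replicate_cv > 0)
            exp(stats::rnorm(1, sd = replicate_cv)) else 1
          rows[[idx]] <- data.frame(
            variable_id = rep(ids[i], 2), time = rep(time_points[j], 2),
            condition = c("control", "treated"), replicate = rep(r, 2),
            occupancy = c(ctl, ctl * fold * noise))
          idx <- idx + 1
        }
      }
    }
    dimnames(noiseless) <- list(ids, as.character(time_points))
    list(table = do.call(rbind, rows[seq_len(idx - 1)]),
         truth = list(noiseless_matrix = noiseless,
                      true_labels = stats::setNames(labels, ids)))
  })
}

#' Generate a synthetic annotation map matched to cluster structure
#'
#' Assigns each variable to a host protein (several variables may share
#' one protein) and each protein to one of `n_functions`
#' biological-function terms. When `enriched = TRUE`, proteins are
#' preferentially annotated to a function aligned with their dominant
#' cluster, so the bubble table has true over-representation signal;
#' otherwise function labels are independent of cluster (a null map).
#'
#' @param true_labels Named integer vector (variable -> cluster; 0s
#'   allowed and annotated like any other row).
#' @param variables_per_protein Average number of variables per host
#'   protein; default 2.
#' @param n_functions Number of function terms; default 10.
#' @param enriched Couple functions to clusters; default `TRUE`.
#' @param seed RNG seed.
#' @return An [annotation_map()].
#' @export
generate_annotation_map <- function(true_labels, variables_per_protein = 2,
                                    n_functions = 10, enriched = TRUE,
                                    seed = 20200603) {
  ids <- names(true_labels)
  stopifnot(!is.null(ids))
  with_seed(seed, {
    n_prot <- max(1, ceiling(length(ids) / variables_per_protein))
    prot_ids <- sprintf("P%04d", seq_len(n_prot))
    # group variables of the same cluster on the same protein
    ord <- order(true_labels, sample.int(length(ids)))
    v2p <- character(length(ids))
    v2p[ord] <- prot_ids[ceiling(seq_along(ids) / variables_per_protein)]
    names(v2p) <- ids
    fun_ids <- sprintf("BF%02d", seq_len(n_functions))
    # dominant cluster per protein
    p2f <- lapply(prot_ids, function(p) {
      cl <- true_labels[names(v2p)[v2p == p]]
      dom <- as.integer(names(which.max(table(cl))))
      if (enriched && dom > 0 && stats::runif(1) < 0.7) {
        fun_ids[(dom - 1) %% n_functions + 1]
      } else {
        sample(fun_ids, 1)
      }
    })
    names(p2f) <- prot_ids
    annotation_map(v2p, p2f)
  })
}
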