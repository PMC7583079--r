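# End-to-end pipeline with YAML configuration and a JSON run manifest.

.known_keys <- c(
  "io.matrix", "io.replicate_table", "io.annotation_variable_protein",
  "io.annotation_protein_function", "io.out_dir",
  "filter.threshold", "filter.log_base", "filter.enabled",
  "preprocess.method", "preprocess.dof", "preprocess.rank",
  "preprocess.impute", "preprocess.fallback_rank",
  "cluster.method", "cluster.K", "cluster.K_range", "cluster.restarts",
  "cluster.distance", "cluster.linkage", "cluster.scree",
  "jackstraw.s", "jackstraw.B", "jackstraw.pip_threshold",
  "enrich.universe", "enrich.alpha", "seed")

.defaults <- list(
  "filter.enabled" = TRUE, "filter.threshold" = 1.2,
  "filter.log_base" = 2,
  "preprocess.method" = "spline", "preprocess.dof" = "cv.global",
  "preprocess.rank" = "auto", "preprocess.impute" = "svdimpute",
  "preprocess.fallback_rank" = 2,
  "cluster.method" = "kmeans", "cluster.K" = 5,
  "cluster.restarts" = 20, "cluster.distance" = "euclidean",
  "cluster.linkage" = "average", "cluster.scree" = FALSE,
  "jackstraw.pip_threshold" = 0.8,
  "enrich.universe" = "selected", "enrich.alpha" = 0.05,
  "seed" = 20200603)

# Flatten a nested YAML list into dotted keys.
.flatten_config <- function(x, prefix = "") {
  out <- list()
  for (nm in names(x)) {
    key <- if (prefix == "") nm else paste0(prefix, ".", nm)
    if (is.list(x[[nm]]) && !is.null(names(x[[nm]]))) {
      out <- c(out, .flatten_config(x[[nm]], key))
    } else {
      out[[key]] <- x[[nm]]
    }
  }
  out
}

#' Resolve a pipeline configuration
#'
#' Accepts a YAML file path or a (possibly nested) named list with
#' dotted keys as documented per module (`io.*`, `filter.*`,
#' `preprocess.*`, `cluster.*`, `jackstraw.*`, `enrich.*`, `seed`);
#' unknown keys are rejected and defaults filled in.
#'
#' @param config File path or named list; `NULL` for pure defaults.
#' @param overrides Named list applied on top (e.g. CLI flags).
#' @return A named list of resolved settings.
#' @export
resolve_config <- function(config = NULL, overrides = list()) {
  cfg <- if (is.character(config)) yaml::read_yaml(config)
         else config %||% list()
  cfg <- .flatten_config(cfg)
  for (nm in names(overrides)) cfg[[nm]] <- overrides[[nm]]
  unknown <- setdiff(names(cfg), .known_keys)
  if (length(unknown))
    stop_with("ConfigError", "unknown config key(s): %s",
              paste(unknown, collapse = ", "))
  for (nm in names(.defaults))
    if (is.null(cfg[[nm]])) cfg[[nm]] <- .defaults[[nm]]
  cfg
}

#' Run the full temporal-signature pipeline
#'
#' Executes, in order: replicate collapsing (if a replicate table is
#' given), the fold-change pre-filter, preprocessing (spline or PCA
#' path), optional WCSS scree, clustering, the jackstraw membership
#' test, PIP selection, and (if annotations are given) the
#' cluster-by-function bubble table. Every intermediate artifact is
#' written to `out_dir` together with the resolved configuration and a
#' JSON manifest recording the variable counts entering and leaving
#' each stage.
#'
#' @param config Path to a YAML config file or a named list (see
#'   [resolve_config()]). Either `io.matrix` or `io.replicate_table`
#'   must point at an input file unless `matrix` is supplied directly.
#' @param matrix Optional in-memory `temporal_matrix` input (overrides
#'   `io.*` inputs).
#' @param annotations Optional in-memory `annotation_map`.
#' @param out_dir Output directory (created); overrides `io.out_dir`.
#'   `NULL` suppresses all file output.
#' @return Invisibly, a list with elements `filtered`, `preprocessed`,
#'   `qc`, `scree`, `clustering`, `jackstraw`, `selection`, `bubble`
#'   (present stages only) and `manifest`.
#' @export
run_pipeline <- function(config = NULL, matrix = NULL, annotations = NULL,
                         out_dir = NULL) {
  cfg <- resolve_config(config)
  out_dir <- out_dir %||% cfg[["io.out_dir"]]
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  seed <- cfg[["seed"]]
  emit <- function(name, writer) {
    if (!is.null(out_dir)) writer(file.path(out_dir, name))
  }
  stage <- function(what) message(sprintf("[temposig] %s", what))
  manifest <- list(package_version =
                     as.character(utils::packageVersion("temposig")),
                   seed = seed, stages = list())
  note <- function(stage_name, n_in, n_out, extra = list())
    manifest$stages[[stage_name]] <<- c(list(n_in = n_in, n_out = n_out),
                                        extra)

  # --- input ------------------------------------------------------------
  if (is.null(matrix)) {
    if (!is.null(cfg[["io.replicate_table"]])) {
      stage("collapsing replicate table")
      tab <- utils::read.table(cfg[["io.replicate_table"]], sep = "\t",
                               header = TRUE)
      matrix <- collapse_replicates(tab, log_base = cfg[["filter.log_base"]])
      note("collapse", length(unique(tab$variable_id)),
           nrow(matrix$values))
    } else if (!is.null(cfg[["io.matrix"]])) {
      stage("reading matrix")
      matrix <- read_temporal_matrix(cfg[["io.matrix"]])
    } else {
      stop_with("ConfigError",
                "no input: supply matrix, io.matrix or io.replicate_table")
    }
  }

  # --- fold-change filter ----------------------------------------------
  if (isTRUE(cfg[["filter.enabled"]])) {
    stage("fold-change filter")
    fc <- fold_change_filter(matrix, cfg[["filter.threshold"]],
                             cfg[["filter.log_base"]])
    note("filter", fc$report$n_input, fc$report$n_kept,
         list(threshold = fc$report$threshold))
    emit("filter_report.json", function(p)
      jsonlite::write_json(unclass(fc$report), p, auto_unbox = TRUE))
    matrix <- fc$matrix
  } else fc <- NULL

  # --- preprocessing ----------------------------------------------------
  stage(sprintf("preprocessing (%s)", cfg[["preprocess.method"]]))
  pre <- if (cfg[["preprocess.method"]] == "spline") {
    preprocess_spline(matrix, dof = cfg[["preprocess.dof"]],
                      fallback_rank = cfg[["preprocess.fallback_rank"]])
  } else {
    preprocess_pca(matrix, r = cfg[["preprocess.rank"]],
                   impute = cfg[["preprocess.impute"]])
  }
  note("preprocess", nrow(matrix$values), nrow(pre$matrix$values),
       list(method = cfg[["preprocess.method"]],
            median_pearson = pre$qc$median_pearson,
            median_msd = pre$qc$median_msd))
  emit("preprocessed.tsv", function(p)
    write_temporal_matrix(pre$matrix, p))
  emit("qc_report.json", function(p)
    jsonlite::write_json(list(median_pearson = pre$qc$median_pearson,
                              median_msd = pre$qc$median_msd,
                              n_pearson_excluded =
                                pre$qc$n_pearson_excluded),
                         p, auto_unbox = TRUE))

  # --- scree (advisory) -------------------------------------------------
  scree <- NULL
  if (isTRUE(cfg[["cluster.scree"]])) {
    stage("WCSS scree")
    K_range <- cfg[["cluster.K_range"]] %||% 1:10
    scree <- wcss_scree(pre$matrix, K_range,
                        restarts = cfg[["cluster.restarts"]], seed = seed)
    emit("scree.tsv", function(p)
      utils::write.table(scree, p, sep = "\t", row.names = FALSE,
                         quote = FALSE))
  }

  # --- clustering -------------------------------------------------------
  stage(sprintf("clustering (%s, K = %d)", cfg[["cluster.method"]],
                cfg[["cluster.K"]]))
  clustering <- if (cfg[["cluster.method"]] == "kmeans") {
    kmeans_cluster(pre$matrix, K = cfg[["cluster.K"]],
                   restarts = cfg[["cluster.restarts"]], seed = seed)
  } else {
    hierarchical_cluster(pre$matrix, K = cfg[["cluster.K"]],
                         distance = cfg[["cluster.distance"]],
                         linkage = cfg[["cluster.linkage"]])
  }
  note("cluster", nrow(pre$matrix$values), nrow(pre$matrix$values),
       list(K = clustering$K, wcss = clustering$wcss))
  emit("cluster_labels.tsv", function(p)
    utils::write.table(data.frame(variable_id = names(clustering$labels),
                                  cluster = clustering$labels),
                       p, sep = "\t", row.names = FALSE, quote = FALSE))
  emit("cluster_centers.tsv", function(p)
    utils::write.table(data.frame(cluster = seq_len(clustering$K),
                                  clustering$centers, check.names = FALSE),
                       p, sep = "\t", row.names = FALSE, quote = FALSE))

  # --- jackstraw evaluation --------------------------------------------
  stage("jackstraw membership test")
  null_fun <- if (cfg[["preprocess.method"]] == "spline")
    spline_permutation_null(matrix, pre$matrix) else NULL
  js <- jackstraw_cluster_test(pre$matrix, clustering,
                               s = cfg[["jackstraw.s"]],
                               B = cfg[["jackstraw.B"]], seed = seed,
                               null_fun = null_fun)
  selection <- pip_filter(js, cfg[["jackstraw.pip_threshold"]])
  note("jackstraw", selection$n_input, selection$n_retained,
       list(s = js$s, B = js$B, pi0 = js$pi0,
            pip_threshold = selection$pip_threshold))
  emit("jackstraw.tsv", function(p)
    utils::write.table(data.frame(variable_id = js$variable_ids,
                                  cluster = js$labels, F = js$observed_f,
                                  p = js$p_values, lfdr = js$lfdr,
                                  pip = js$pip,
                                  q = bh_fdr(js$p_values)),
                       p, sep = "\t", row.names = FALSE, quote = FALSE))
  emit("selection.json", function(p)
    jsonlite::write_json(unclass(selection), p, auto_unbox = TRUE))

  # --- enrichment -------------------------------------------------------
  bubble <- NULL
  if (is.null(annotations) &&
      !is.null(cfg[["io.annotation_variable_protein"]])) {
    annotations <- read_annotation_map(
      cfg[["io.annotation_variable_protein"]],
      cfg[["io.annotation_protein_function"]])
  }
  if (!is.null(annotations)) {
    stage("functional enrichment")
    bubble <- build_bubble_table(selection, clustering, annotations,
                                 universe = cfg[["enrich.universe"]],
                                 alpha = cfg[["enrich.alpha"]])
    note("enrich", selection$n_retained, nrow(bubble))
    emit("bubble_table.tsv", function(p)
      utils::write.table(bubble, p, sep = "\t", row.names = FALSE,
                         quote = FALSE))
  }

  emit("config.json", function(p)
    jsonlite::write_json(cfg, p, auto_unbox = TRUE))
  emit("manifest.json", function(p)
    jsonlite::write_json(manifest, p, auto_unbox = TRUE, digits = NA))

  invisible(list(filtered = if (!is.null(fc)) fc$matrix else matrix,
                 filter_report = if (!is.null(fc)) fc$report,
                 preprocessed = pre$matrix, qc = pre$qc, scree = scree,
                 clustering = clustering, jackstraw = js,
                 selection = selection, bubble = bubble,
                 manifest = manifest))
}
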