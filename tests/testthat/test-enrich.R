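test_that("hypergeometric tail matches direct pmf summation", {
  expect_equal(hypergeometric_test(0, 5, 8, 20), 1)
  expect_equal(hypergeometric_test(5, 5, 5, 10), 1 / choose(10, 5),
               tolerance = 1e-12)
  # toy from first principles: sum the pmf over the tail
  direct <- sum(sapply(5:5, function(k)
    choose(5, k) * choose(15, 8 - k) / choose(20, 8)))
  expect_equal(hypergeometric_test(5, 5, 8, 20), direct,
               tolerance = 1e-12)
  for (k in 0:5) {
    direct_k <- sum(sapply(k:5, function(j)
      choose(5, j) * choose(15, 8 - j) / choose(20, 8)))
    expect_equal(hypergeometric_test(k, 5, 8, 20), direct_k,
                 tolerance = 1e-12)
  }
  # pmf normalization
  expect_equal(sum(stats::dhyper(0:5, 5, 15, 8)), 1, tolerance = 1e-12)
  expect_error(hypergeometric_test(6, 5, 8, 20), class = "ParameterError")
})

test_that("BH q-values reproduce the hand-applied step-up", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  set.seed(71)
  p <- runif(40)
  q <- bh_fdr(p)
  expect_equal(q, bh_by_hand(p))
  expect_true(all(q >= p))
  expect_true(all(diff(q[order(p)]) >= -1e-15))
})

toy_setup <- function() {
  # 12 variables on 8 proteins, 2 clusters, 2 functions
  v2p <- setNames(paste0("P", c(1, 1, 2, 3, 4, 4, 4, 5, 6, 7, 8, 8)),
                  paste0("v", 1:12))
  p2f <- list(P1 = "F1", P2 = "F1", P3 = "F1", P4 = "F2", P5 = "F2",
              P6 = "F2", P7 = "F2", P8 = "F1")
  annot <- annotation_map(v2p, p2f)
  labels <- setNames(c(1, 1, 1, 1, 2, 2, 2, 2, 2, 2, 1, 1),
                     paste0("v", 1:12))
  clustering <- structure(
    list(labels = labels, centers = matrix(0, 2, 6), K = 2,
         wcss = 0, method = "kmeans", distance = "euclidean",
         linkage = NA, seed = 1, restarts = 1),
    class = "clustering_result")
  selection <- structure(
    list(pip_threshold = 0.8, retained_ids = paste0("v", 1:12),
         retained_idx = 1:12, n_input = 12, n_retained = 12),
    class = "selection_report")
  list(annot = annot, clustering = clustering, selection = selection)
}

test_that("bubble table counts events and distinct proteins correctly", {
  ts <- toy_setup()
  tab <- build_bubble_table(ts$selection, ts$clustering, ts$annot)
  # cluster 1 holds v1,v2 (P1), v3 (P2), v4 (P3), v11,v12 (P8): all F1
  c1f1 <- tab[tab$cluster == 1 & tab$fun == "F1", ]
  expect_equal(c1f1$event_count, 6)
  expect_equal(c1f1$protein_count, 4)
  expect_true(all(tab$event_count >= tab$protein_count))
  expect_identical(tab$significant, tab$q < 0.05)
  # p recomputed from the hypergeometric definition (protein level)
  expect_equal(c1f1$p, hypergeometric_test(4, 4, 4, 8))
})

test_that("a function covering the whole universe cannot be enriched", {
  v2p <- setNames(paste0("P", 1:6), paste0("v", 1:6))
  p2f <- setNames(as.list(rep("ALL", 6)), paste0("P", 1:6))
  annot <- annotation_map(v2p, p2f)
  clustering <- structure(
    list(labels = setNames(rep(1, 6), paste0("v", 1:6)),
         centers = matrix(0, 1, 6), K = 1, wcss = 0, method = "kmeans",
         distance = "euclidean", linkage = NA, seed = 1, restarts = 1),
    class = "clustering_result")
  selection <- structure(
    list(pip_threshold = 0.8, retained_ids = paste0("v", 1:6),
         retained_idx = 1:6, n_input = 6, n_retained = 6),
    class = "selection_report")
  tab <- build_bubble_table(selection, clustering, annot)
  expect_equal(tab$p, 1)
})

test_that("multiple events on one protein count once at the protein level", {
  ts <- toy_setup()
  tab <- build_bubble_table(ts$selection, ts$clustering, ts$annot)
  # P4 hosts v5, v6, v7 in cluster 2 under F2
  c2f2 <- tab[tab$cluster == 2 & tab$fun == "F2", ]
  expect_equal(c2f2$event_count, 6)   # v5-v7 (P4), v8 (P5), v9 (P6), v10 (P7)
  expect_equal(c2f2$protein_count, 4)
})

test_that("permuting cluster labels destroys enrichment", {
  set.seed(73)
  gen <- generate_clustered_timecourses(m = 300, K = 5, snr = 10,
                                        missing_rate = 0, seed = 73)
  truth <- gen$truth$true_labels
  annot <- generate_annotation_map(truth, seed = 73)
  selection <- structure(
    list(pip_threshold = 0.8, retained_ids = names(truth),
         retained_idx = seq_along(truth), n_input = length(truth),
         n_retained = length(truth)),
    class = "selection_report")
  make_cl <- function(labels) structure(
    list(labels = labels, centers = matrix(0, 5, 6), K = 5, wcss = 0,
         method = "kmeans", distance = "euclidean", linkage = NA,
         seed = 1, restarts = 1), class = "clustering_result")
  # true labels: strong enrichment expected
  tab_true <- build_bubble_table(selection, make_cl(truth), annot)
  expect_gt(sum(tab_true$significant), 0)
  # permuted labels: significance should essentially vanish
  frac <- replicate(20, {
    perm <- setNames(sample(truth), names(truth))
    tab <- build_bubble_table(selection, make_cl(perm), annot)
    mean(tab$significant)
  })
  expect_lte(mean(frac), 0.06)
})

test_that("annotation maps round-trip through their TSV representation", {
  ts <- toy_setup()
  vp_path <- withr::local_tempfile(fileext = ".tsv")
  pf_path <- withr::local_tempfile(fileext = ".tsv")
  v2p <- ts$annot$variable_to_protein
  utils::write.table(data.frame(variable_id = names(v2p),
                                protein_id = unname(v2p)),
                     vp_path, sep = "\t", row.names = FALSE, quote = FALSE)
  p2f <- ts$annot$protein_to_functions
  utils::write.table(data.frame(protein_id = rep(names(p2f),
                                                 lengths(p2f)),
                                fun = unlist(p2f)),
                     pf_path, sep = "\t", row.names = FALSE, quote = FALSE)
  annot <- read_annotation_map(vp_path, pf_path)
  expect_identical(annot$variable_to_protein, v2p)
  expect_identical(lapply(annot$protein_to_functions, sort),
                   lapply(p2f[names(annot$protein_to_functions)], sort))
})
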