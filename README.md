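# temposig

Temporal clustering and jackstraw evaluation of omics time courses.

## The problem

Temporal omics experiments — the motivating case is proteome-wide
cysteine oxidative post-translational modification (O-PTM) occupancy in
mouse hearts over 1–14 days of isoproterenol-induced hypertrophy —
yield a matrix of thousands of molecular events measured at a handful
of ordered time points, with missing cells and substantial noise.
Analysts want to know *which temporal patterns exist* and *which
individual events genuinely follow them*. The second question is
statistically delicate: clusters are estimated from the same rows one
then wants to test, so naive per-row tests against cluster means are
circular.

`temposig` is for biostatisticians and computational biologists working
with such variables-by-timepoints matrices (proteomics, metabolomics,
or any short dense time course). It provides:

- **Input handling** — replicate collapsing to log occupancy ratios
  (`collapse_replicates`), a two-sided fold-change pre-filter
  (`fold_change_filter`), delimited-text I/O.
- **Preprocessing (imputation + denoising)** — cubic regression splines
  per variable with cross-validated degrees of freedom
  (`preprocess_spline`, `select_dof_cv`), or reduced-rank PCA with
  iterative SVD imputation / NIPALS (`preprocess_pca`, `svd_impute`,
  `nipals_pca`), with QC against the input (`qc_compare`).
- **Clustering** — K-means (Lloyd + k-means++, best-of-restarts,
  seeded) and hierarchical clustering with Euclidean or dynamic time
  warping distance, plus a WCSS scree table for choosing K
  (`kmeans_cluster`, `hierarchical_cluster`, `dtw_distance`,
  `wcss_scree`).
- **Evaluation** — the jackstraw test of cluster membership
  (`jackstraw_cluster_test`): an empirical null built by permuting a
  few rows at a time and re-clustering, giving per-variable p-values,
  Storey π₀, local FDR, and posterior inclusion probabilities
  (PIP = 1 − lfdr); selection by `pip_filter`.
- **Functional summary** — a cluster-by-biological-function bubble
  table with protein-level hypergeometric over-representation tests and
  Benjamini–Hochberg FDR (`build_bubble_table`).
- **Synthetic data** — seeded generators with known truth
  (`generate_clustered_timecourses`, `generate_null_matrix`,
  `generate_replicate_table`, `generate_annotation_map`), so every
  stage is testable offline.

## The statistics in brief

A variable's membership in its assigned cluster is scored by the
regression F-statistic of its profile `y` on the cluster mean profile
`c`:

    F = (TSS − RSS) / (RSS / (n − 2)),  TSS about the mean of y.

The null distribution of F is estimated by the jackstraw: repeat B
times — replace `s` random rows by permutations of their own values,
re-cluster with the same K and the same optimization effort (observed
centers enter as one candidate start), and pool the permuted rows'
F-statistics. The empirical p-value is `(1 + #{F₀ ≥ F}) / (1 + sB)`.
From the p-values, Storey's estimator gives the null proportion π₀, a
monotone histogram density estimate `f̂(p)` gives the local FDR
`π₀/f̂(p)`, and `PIP = 1 − lfdr` is the posterior probability that the
variable truly follows its cluster; selection keeps `PIP > 0.8`.
Enrichment of function `g` in cluster `k` uses the upper hypergeometric
tail `P(X ≥ k_obs)` over distinct proteins, BH-adjusted across all
(cluster × function) cells.

## Worked example

```r
library(temposig)

# a synthetic O-PTM-like dataset with known truth:
# 400 events, 5 temporal patterns, snr 4, 15% missing, 10% noise rows
gen <- generate_clustered_timecourses(m = 400, K = 5, snr = 4,
                                      missing_rate = 0.15,
                                      spike_noise_fraction = 0.1, seed = 7)
gen$matrix
#> temporal_matrix: 400 variables x 6 time points (1, 3, 5, 7, 10, 14)
#>   missing cells: 328 (13.7%)

pre <- preprocess_spline(gen$matrix)   # impute + denoise, dof by global CV
pre$qc
#> QC: median Pearson 0.966 (0 rows excluded), median MSD 0.0208

cl <- kmeans_cluster(pre$matrix, K = 5, restarts = 20, seed = 7)
cl
#> kmeans clustering (euclidean): K = 5, WCSS = 222.5
#> cluster
#>   1   2   3   4   5
#> 111  76  74  70  69

js <- jackstraw_cluster_test(pre$matrix, cl, seed = 7,
        null_fun = spline_permutation_null(gen$matrix, pre$matrix))
js
#> jackstraw cluster-membership test: m = 400, s = 40, B = 250
#>   pi0 = 0.170; PIP > 0.8 for 331 variables

sel <- pip_filter(js, 0.8)
sel
#> PIP > 0.80 selection: retained 331 / 400 variables

annot <- generate_annotation_map(gen$truth$true_labels, seed = 7)
head(build_bubble_table(sel, cl, annot), 3)
#>   cluster  fun event_count protein_count            p            q significant
#> 1       1 BF02           6             5 9.642601e-01 9.998649e-01       FALSE
#> 2       1 BF03           2             2 9.982224e-01 9.998649e-01       FALSE
#> 3       1 BF04          37            23 1.234098e-13 9.379147e-13        TRUE
```

Reading the output: preprocessing kept the observed signal (median
per-variable Pearson 0.97 between input and fitted values) while
filling 328 missing cells; K-means found the five planted patterns;
the jackstraw estimated that ~17% of rows are unrelated to their
cluster and retained 331 events at PIP > 0.8; the bubble table flags
cluster–function pairs (here cluster 1 × BF04, 37 modification events
on 23 proteins) whose protein overlap is far beyond hypergeometric
chance at FDR < 0.05.

`run_pipeline()` chains all stages from a YAML config or named list,
writing every intermediate artifact plus a stage-count manifest; a thin
command-line wrapper with the same stages as subcommands is installed
at `inst/cli/temposig.R`.

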