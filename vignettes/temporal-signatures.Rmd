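---
title: "Temporal signatures in omics time courses: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal signatures in omics time courses: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(temposig)
```

## The problem

A temporal omics experiment measures many molecular events — here the
motivating case is cysteine oxidative post-translational modification
(O-PTM) occupancy in mouse hearts during agonist-induced hypertrophy —
at a handful of ordered time points (days 1, 3, 5, 7, 10, 14), in a
treated-versus-control design with a few replicates. After collapsing
replicates to per-time log occupancy ratios, the data form an
`m x n` matrix with `m` in the thousands and `n` around six, with
missing cells. Three questions follow:

1. **Preprocessing** — how to impute missing cells and suppress
   measurement noise without inventing signal;
2. **Clustering** — which shared temporal patterns exist;
3. **Evaluation** — which individual variables *genuinely* follow the
   pattern of the cluster they were assigned to, given that the
   clusters were learned from the same data (the circularity problem).

`temposig` implements all three stages plus a seeded synthetic-data
module so that every claim below is testable without any download.

## Input model and pre-filter

`collapse_replicates()` pairs treated and control occupancies by
replicate index, forms per-replicate ratios, averages the ratios and
takes `log2` (the base is configurable; fold-change thresholds are
interpreted on the ratio scale, so the base only rescales). A matched
pair with control occupancy 0 is discarded rather than imputed as an
infinite ratio; a cell with no usable pair becomes missing.

`fold_change_filter()` removes variables whose largest absolute log
ratio never reaches the threshold (default 1.2-fold), two-sided:
flatness is a property of magnitude, not direction. The filter is
applied to the collapsed log-ratio matrix, i.e. after replicate
averaging.

## Preprocessing

Two mutually exclusive paths return a complete matrix.

**Cubic splines.** Each variable with at least 4 observed points is fit
by a cubic regression spline at `dof` degrees of freedom counted as the
model dimension: 2 is a straight line, 3 a quadratic, 4 a cubic
polynomial, and every further degree adds an interior knot at time
quantiles. This family makes the degrees of freedom exact and
interpretable at `n = 6`: `dof` equal to the number of observations
interpolates, a line is recovered exactly at `dof = 2` and a cubic at
`dof = 4`. (A penalized smoothing spline tuned to an *effective* dof
was considered and rejected: with any nonzero penalty an exact cubic is
shrunk and never reproduced, and the penalized leave-one-out score at
six points is dominated by boundary leverage, see below.)

`select_dof_cv()` scores a dof grid (default 2–5) by generalized
cross-validation, `n·RSS/(n − dof)²`, summed over variables
(`cv.global`) or per variable. GCV rather than exact leave-one-out is a
deliberate numerical choice: the exact LOO identity
`((y − ŷ)/(1 − h))²` is exact for these least-squares fits, but at six
points the two boundary time points carry leverages approaching 1 as
dof grows, so their inflated terms dominate the sum and push the global
choice to the line model — which is degenerate downstream, because
rank-2 rows correlate perfectly with any non-constant center and every
membership F-statistic becomes infinite. GCV replaces pointwise
leverages by their average and is the standard smoothness criterion for
splines; the exact-LOO score remains available via
`criterion = "loo"`. Ties (including numerically indistinguishable
scores on noiseless data) break toward the smallest dof.

Variables with fewer than 4 observations cannot support a cubic fit and
are completed by `svd_impute()` on the whole matrix instead, at
`fallback_rank` (default 2), and left unsmoothed; per-row routing is
recorded in the result.

**Reduced-rank PCA.** `svd_impute()` initializes missing cells at the
row mean and alternates truncated-SVD reconstruction of only the
missing cells until their relative change falls below `tol` (1e-6; cap
100 iterations, with a warning on slow convergence — typical for noisy
data, harmless because only the plateau tail is cut). Observed cells
are never altered. `nipals_pca()` extracts components sequentially with
missing-skipping regressions and deflation; it equals the truncated SVD
on complete data but is an *approximate* completion under missingness
(the suite cross-checks it against an independent implementation rather
than against exact recovery). `preprocess_pca()` completes the matrix,
row-centers it, and reconstructs from the top `r` components
(`r = "auto"` takes the smallest rank reaching 90% cumulative
variance). Rows are centered because all variables share the log-ratio
scale and the object of interest is temporal shape, not level.

`qc_compare()` reports per-variable Pearson correlation and mean
squared difference between input and output over the cells observed in
the input, with medians; rows with fewer than 3 observations or zero
variance are excluded from the correlation median (counted) and kept in
the MSD median.

### What denoising can and cannot achieve at n = 6

For an unbiased linear smoother the per-row error against the noiseless
truth is `σ²·χ²_dof/n`, so even perfect smoothing leaves
`P(MSD < σ²) ≈ 0.95` at dof 2 and only `≈ 0.89` at dof 3, less under
missingness. More consequentially, projecting every row onto a shared
low-dof basis collapses the matrix rank: after global dof-3 smoothing
all rows live in a 3-dimensional space in which *any* profile —
including smoothed noise — correlates strongly with some cluster
center. This interacts with the membership test below and drives two
design choices: smoothing is never chained with PCA denoising, and
membership inference is best run on completed-but-unsmoothed data (see
the jackstraw section).

## Clustering

`kmeans_cluster()` implements Lloyd's iterations with k-means++
seeding, best of `restarts` (default 20) initializations by WCSS,
deterministic under an explicit seed. Empty clusters arising during
iteration are repaired by moving the point farthest from its current
center, so exactly K non-empty clusters always return (`stats::kmeans`
with Lloyd's algorithm instead errors on empty clusters, and offers no
k-means++ seeding; a test cross-checks our best-of-restarts WCSS
against a heavy-restart `stats::kmeans`). Labels are canonicalized by
decreasing cluster size. Profiles are clustered as-is — occupancy log
ratios share a scale, and amplitude is part of the signal — with no
per-row standardization.

`hierarchical_cluster()` delegates to `stats::hclust` on Euclidean or
dynamic-time-warping distances (`ward` maps to `ward.D2`,
Euclidean-only) and cuts at K; centers are reported as per-cluster
means regardless of distance, because downstream membership testing
regresses on mean profiles. `dtw_distance()` is the classical
cumulative-cost recursion with squared pointwise cost, symmetric steps,
an optional Sakoe–Chiba band, and no path normalization; it equals the
Euclidean distance when the diagonal path is optimal and never exceeds
it. Same-length series only.

K selection is advisory: `wcss_scree()` tabulates WCSS over a K range
and `elbow_k()` offers the max-second-difference heuristic, but the
pipeline never picks K silently — on the motivating data the choice
K = 5 was a judgment about which patterns are distinct, and the
package keeps that judgment with the analyst.

## The jackstraw membership test

Because the clusters were estimated from the very rows being tested,
testing a row against its own cluster center with a textbook F
distribution would be circular and wildly anti-conservative. The
jackstraw builds the correct reference distribution empirically: in
each of `B` iterations, `s` randomly chosen rows are replaced by
permutations of their own values across the time axis (destroying
temporal association, preserving the marginal distribution), the
clustering is re-fit, and the permuted rows' F-statistics against their
newly assigned centers are pooled into a null. The observed statistic
is the regression F of a row on its assigned cluster mean; a perfect
fit is capped at a large finite sentinel so ordering against the null
pool stays defined. P-values use the add-one empirical estimator, so
they are never 0 and never below `1/(sB + 1)`. Defaults
`s = ⌈0.1·m⌉` and `B` such that `s·B ≥ 10,000` give the empirical null
enough resolution for PIP work.

**Calibration requires matching optimization effort.** The re-fit is
initialized at the observed centers *and* given the same number of
k-means++ restarts as the observed clustering. Re-fitting only from the
observed centers — a single descent — systematically under-optimizes
the null rows relative to observed rows that enjoyed a best-of-20
search, and measurably skews null p-values small (pooled type-I rate
~0.061 at nominal 0.05, KS distance to uniform ~0.05–0.06 on pure-noise
matrices); with effort matched the same conditions give ~0.051 and KS
~0.02. This is the one place the package deliberately refines the
textbook recipe, and the acceptance suite checks the resulting
calibration directly.

**Test on data, not on fits.** If the tested matrix was smoothed, the
permutation null is no longer exchangeable with genuinely unstructured
rows: a smoothed noise row *is* smooth, while its permutation is not,
so plain-permutation p-values for smoothed noise are far too small. Two
remedies are provided. `spline_permutation_null()` permutes the *raw*
observed values and re-applies the same spline, restoring
exchangeability (the pipeline uses it automatically on the spline
path). Better still, for membership inference we recommend — and the
recovery benchmark uses — running clustering and jackstraw on the
completion-only matrix (`svd_impute`, observed cells untouched), where
permutation exchangeability holds by construction and the test retains
full resolution; rank-collapsed smoothed data cannot distinguish
members from any smooth impostor at n = 6.

From the p-values, `estimate_pi0()` applies Storey's λ-grid estimator
(grid 0.05–0.95, cubic-spline smoothed, read at the largest λ, clamped
to (0,1]; conservative `π₀ = 1` under 20 p-values).
`compute_pips()` estimates the p-value density with a 50-bin histogram
forced monotone non-increasing by isotonic regression, sets
`lfdr(p) = π₀/f̂(p)` clamped to [0,1], and `PIP = 1 − lfdr` exactly.
`pip_filter()` retains variables with PIP strictly above the threshold
(default 0.8, i.e. local FDR below 0.2).

A consequence worth stating: PIP thresholding is a posterior rule. With
10% genuinely null rows mixed into strong clusters, a null row that
lands at a small p-value by chance sits among many times as many true
members and *correctly* receives a high PIP; at the package's study
conditions the PIP > 0.8 rule excludes roughly 78–80% of planted noise
rows while retaining ~94% of true members, and no estimator tweak can
push exclusion higher without sacrificing recall — the limit is the
overlap of the F distributions at six time points, not the estimator.

## Functional summary

`build_bubble_table()` crosses the selected variables' clusters with
biological-function annotations: per (cluster, function) cell it
reports the number of selected events, the number of distinct host
proteins, and a hypergeometric over-representation p-value computed at
the **protein** level — multiple modification sites on one protein are
pseudo-replicates, so enrichment counts each protein once; event counts
are reported but not tested. The universe defaults to proteins hosting
at least one selected variable (configurable to the whole annotation
map). Benjamini–Hochberg correction is applied across all emitted cells
jointly, flagging q < 0.05. Under random label permutation the
significant fraction collapses toward zero (BH under a full null admits
few discoveries), which the suite checks.

## Synthetic data

`generate_clustered_timecourses()` emulates the motivating dataset's
structure: five template shapes over days 1–14 (continual descent,
continual ascent, descent to a floor, slight descent then accelerated
rise, rise then relapse), unit amplitude, additive Gaussian noise of
sd `amplitude/snr` on the log-ratio scale (the log transform motivates
additive noise), optional pure-noise "spike" rows with true label 0,
and uniform missingness with at least 4 observed cells per row.
`generate_replicate_table()` inverts the collapse step with
multiplicative replicate noise; `generate_null_matrix()` supplies pure
Gaussian matrices for calibration; `generate_annotation_map()` builds
protein and function maps optionally coupled to the true clusters. All
generators are bitwise deterministic under a seed.

What the generator does *not* model: mass-spectrometry-specific
missingness (censoring at low abundance, i.e. missing-not-at-random),
batch structure, heteroscedastic noise, or correlated variables within
a protein. Passing tests therefore demonstrate correctness of the
machinery and honest statistical behavior under the stated model, not
robustness to every failure mode of real proteomics data.

## Problem sizes and reproducibility

The test suite and the acceptance script use: pure-noise calibration at
m = 500, n = 10, K = 3, s = 50, B = 100 pooled over seeds; recovery at
m = 1000, K = 5, snr = 4, 15% missing, 10% spikes, averaged over a few
seeds; oracle checks on instances small enough for exhaustive
enumeration (length-3 DTW paths, 8-point agglomeration). These sizes
give stable statistics while keeping a full run in minutes. Every
stochastic step takes an explicit integer seed (default 20200603), and
`run_pipeline()` writes the resolved configuration, a stage-count
manifest, and all intermediate artifacts so a run is reproducible
bitwise from its output directory.

## Known limitations

- Same-length, shared time axis only; DTW here compares profiles on a
  common grid and no time-axis alignment is performed.
- The F-statistic tests linear association with a single center;
  anti-correlated profiles receive large F and are distinguished only
  by cluster assignment, which is distance-based.
- At n = 6, spline dof above 4 is rarely selectable and cubic fits are
  boundary-sensitive; the platform is designed for the dense-m,
  tiny-n regime, not long time series.
- NIPALS under missingness is approximate; when exact completion
  matters, `svd_impute` is the default for a reason.
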