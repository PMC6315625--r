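# gmvnmf — graph-regularized multi-view non-negative matrix factorization

Multi-omic cohorts measure the same patients and genes on several molecular
layers at once — gene expression, copy-number variation, methylation. Each
layer is one *view* of a shared biological state: the same patient subtypes,
and the same jointly perturbed genes, should be visible in all of them. This
package factorizes all views at once so that sample clustering and
co-differential gene selection come out of a single model, for
bioinformaticians analyzing matched multi-view matrices (bulk or
single-cell) and for methodologists who want reproducible baselines for
integrative NMF.

## The model

Given `d` non-negative sample-by-feature matrices `X_I` (n × m, row-scaled
to [0, 1]), the core model factors every view through a **shared basis** and
a **shared coefficient matrix**:

    X_I ≈ W U_I V,    W ≥ 0 (n × k),  U_I ≥ 0 (k × r),  V ≥ 0 (r × m),  r ≤ k − 1

optionally regularized by each view's K-nearest-neighbor graph Laplacian
`L_I = D_I − E_I`:

    min Σ_I ‖X_I − W U_I V‖_F² + λ_I tr(Wᵀ L_I W)

K-means on the rows of `W` clusters the samples; the column norms of `V`
rank genes that are differential jointly across all views. With λ = 0 the
model is plain shared-coefficient multi-view NMF (MvNMF). The package also
implements the three standard integrative baselines — joint NMF, integrative
NMF with heterogeneous terms (penalty λ), and orthogonality-regularized
joint NMF (penalty α) — all by multiplicative updates with objective
tracking, plus grid search over `(k, r, λ)`, clustering evaluation
(accuracy under optimal label matching, pairwise recall/precision/F),
a synthetic multi-view generator with planted ground truth, and a CLI.

## Worked example

Simulate a three-view cohort with 3 planted sample clusters and 50 planted
co-differential genes, fit the graph-regularized model, then recover both:

```r
library(gmvnmf)

spec <- synthetic_spec(n_samples = 150, n_features = 300, n_views = 3,
                       n_clusters = 3, n_diff_genes = 50, seed = 42)
gt <- generate_factor_model(spec)

graphs <- lapply(gt$dataset$views, knn_adjacency, K = 5)
cfg <- solver_config(k = 3, r = 2, lambdas = 100, seed = 42)
fit <- gmvnmf_fit(gt$dataset, graphs, cfg)
fit
#> <factorization_result> model = gmvnmf, 100 iteration(s), max_iter reached
#>   final objective: 79.8554

pred <- cluster_basis(fit$W, n_clusters = 3, seed = 42)
clustering_report(gt$truth$labels, pred)
#> <clustering_report> n = 150
#>   AC        1.0000
#>   recall    1.0000
#>   precision 1.0000
#>   F-measure 1.0000

ranking <- select_top(gene_scores(fit$V), N = 50,
                      feature_ids = gt$dataset$feature_ids)
recovery_metrics(ranking, gt$truth$diff_gene_ids)
#> precision    recall
#>         1         1
```

All 150 samples are assigned to the correct planted cluster (accuracy 1.0
after the optimal permutation of cluster identities), and the 50 top-ranked
columns of the shared coefficient matrix are exactly the 50 planted
co-differential genes. Fitting the same data with `mvnmf_fit()` (no graph
term) leaves clustering near chance — with `r < k` the residual constrains
`W` only through `W U_I`, and it is the Laplacian term that resolves the
remaining freedom towards cluster-concentrated bases; see the vignette
(`vignettes/multiview-factorization.Rmd`) for the full account.

The same pipeline is available from a shell via the `exec/gmvnmf` wrapper:

```sh
exec/gmvnmf simulate --out data/ --seed 42
exec/gmvnmf fit --data data/ --out fit/ --model gmvnmf --k 3 --r 2 --lam 100 --seed 42
exec/gmvnmf evaluate --fit fit/ --labels data/labels.tsv --out eval/
exec/gmvnmf select-genes --fit fit/ --out genes/ --top 50
```

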