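# traitprop

Map fine-mapped GWAS variants to their relevant cellular context at
single-cell resolution, from scATAC-seq peak-by-cell count matrices.

## The problem and the method

Fine-mapping assigns each GWAS variant a posterior probability (PP) of
being causal; most causal variants fall in non-coding regulatory elements,
so the cell types and states they act in can be inferred from where those
elements are accessible. In single cells this inference is crippled by
sparsity: a cell samples only a small fraction of its open chromatin, so
per-cell co-localization scores miss most truly relevant cells.

`traitprop` propagates the signal over a cell-to-cell similarity network:

1. **Per-cell enrichment z.** Variant PPs are summed onto the peaks that
   contain them; each cell's weighted accessibility deviation
   `sum_p w_p (x_pc − e_pc)` (expected counts `e` from the matrix
   marginals) is standardized against bias-matched background peaks,
   giving a bias-corrected z-score.
2. **Seed cells.** Cells with upper-tail normal p < 0.05
   (z > 1.6449), capped at the top 5% of cells by z.
3. **Cell graph.** TF-IDF weighting `w_ij = tf_ij log(1 + N/df_i)` of the
   binarized matrix, rank-30 truncated SVD (LSI), exact k-nearest
   neighbors (k = 30) in LSI space, and a mutual-kNN graph (edge only when
   both cells list each other; isolated cells fall back to their single
   nearest neighbor).
4. **Random walk with restart.** `v ← (1 − γ) M v + γ v0` with
   column-stochastic `M`, restart probability γ = 0.05, uniform seed
   distribution `v0`, iterated to `|v_{s+1} − v_s|_1 < 1e-5`. The
   stationary distribution is the per-cell network-propagation score.
5. **TRS.** Stationary scores are clipped at their 99th percentile,
   min-max scaled to [0, 1], and multiplied by the mean z of the top-1%
   cells — the trait relevance score.
6. **Enrichment calls.** B = 1000 degree-matched permuted seed sets give
   each cell an empirical p `(1 + #{perm ≥ real})/(1 + B)`; cells with
   p < 0.05 are trait-enriched.

A binomial read-sampling simulator (`binom(2, p)` with
`p = (1−q) r/2 + q n/2k`) generates ground-truth synthetic datasets from
bulk profiles — real or fully synthetic — for benchmarking and testing.

## Worked example

Fully synthetic, self-contained run: two cell types, trait variants
concentrated in type A's specific peaks, 300 cells per type,
n = 10,000 fragments, noise q = 0.3.

```r
library(traitprop)

bulk     <- synthetic_bulk_profiles(seed = 7)
sim      <- synthesize_cells(bulk, n = 10000, q = 0.3,
                             cells_per_type = 300, seed = 7)
variants <- synthetic_variants(bulk, "typeA", seed = 7)
sim$pcm
#> <peak_cell_matrix> 10000 peaks x 600 cells, 3107498 non-zeros (48.2% sparse)

fit <- trait_relevance(sim$pcm, variants = variants,
                       permute = TRUE, B = 1000, seed = 7)
fit
#> <trait_relevance> 600 cells, 30 seeds, converged in 24 iterations; scale factor 3.261
#>   33.2% of cells trait-enriched (empirical p < 0.05, B = 1000)

head(tidy(fit), 5)
#> # A tibble: 5 x 7
#>   barcode         z is_seed      np   trs       p state
#>   <chr>       <dbl> <lgl>     <dbl> <dbl>   <dbl> <chr>
#> 1 cell_00001 -0.290 FALSE   0.00107 0.530 0.0639  depleted
#> 2 cell_00002  1.17  FALSE   0.00197 0.975 0.0500  enriched
#> 3 cell_00003  1.79  FALSE   0.00603 3.00  0.00599 enriched
#> 4 cell_00004 -0.604 FALSE   0.00269 1.33  0.0789  depleted
#> 5 cell_00005 -0.675 FALSE   0.00310 1.54  0.0609  depleted
```

Each row is a cell: its bias-corrected enrichment `z`, whether it seeded
the walk, the stationary propagation score `np` (sums to 1 over cells),
the rescaled `trs`, and the permutation-test call. Ranking cells by TRS
recovers the ground-truth trait-relevant type far better than the
z-score alone:

```r
evaluate_ranking(fit$cells$z,   sim$labels, "typeA")$accuracy
#> [1] 0.667
evaluate_ranking(fit$cells$trs, sim$labels, "typeA")$accuracy
#> [1] 0.963
```

`glance(fit)` returns a one-row run summary, and
`autoplot(fit)` / `plot_trs(fit)` draw the cells in LSI space colored by
TRS (or any other per-cell column).

For file-based, staged runs there are `cmd_simulate()`, `cmd_score()`,
`cmd_propagate()`, `cmd_permute()` and `cmd_run()` over a
`default_config()` list (every stage writes TSV outputs plus a JSON
config echo), and a thin command-line wrapper at
`inst/cli/traitprop.R`:

```sh
Rscript inst/cli/traitprop.R simulate outdir=sim_out
```

Externally computed z-scores (`load_external_zscores()`) or
batch-corrected embeddings (`load_external_embedding()`) can replace the
built-in stages at any point.

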