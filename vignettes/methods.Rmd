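---
title: "Trait relevance scoring by network propagation: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trait relevance scoring by network propagation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(traitprop)
```

## The problem

Genome-wide association studies followed by statistical fine-mapping yield
putative causal variants, each with a posterior probability (PP) of
causality. Most of these variants sit in non-coding regulatory elements, so
a natural way to assign them a cellular context is to ask which cells'
accessible chromatin (scATAC-seq peaks) they co-localize with. The obstacle
is sparsity: a single cell samples only a small fraction of its accessible
sites, so most truly relevant cells show no signal at the handful of
variant-bearing peaks, and per-cell co-localization scores are noisy and
mostly uninformative.

`traitprop` addresses this with network propagation. The few cells whose
per-cell enrichment is reliably high ("seed cells") inject probability mass
into a cell-to-cell similarity graph; a random walk with restart spreads
that mass to transcriptionally/epigenomically similar cells; and the
stationary distribution — rescaled into a trait relevance score (TRS) —
quantifies every cell's relevance to the trait, including cells whose own
variant-level signal dropped out.

## The pipeline, stage by stage

### Per-cell enrichment z-scores

For each cell $c$ the raw enrichment is a weighted accessibility deviation

$$\mathrm{raw}_c \;=\; \sum_p w_p\,(x_{pc} - e_{pc}), \qquad
  e_{pc} = \frac{(\text{row total})_p\,(\text{column total})_c}{\text{grand total}},$$

where the peak weight $w_p$ is the summed PP of the fine-mapped variants
falling inside peak $p$ (variants are retained when PP > 0.001). The raw
deviation is standardized against `n_background = 50` background deviations
in which every weighted peak is replaced by a peak sampled (with
replacement) from its nearest neighbors in standardized bias-feature space
— log1p mean accessibility, plus GC fraction when supplied. This
bias-corrected z-score follows the weighted-deviation family of scorers
used for bulk and single-cell chromatin enrichment; it is an independent
implementation, and externally computed z-scores can be substituted
verbatim via `load_external_zscores()` when exact parity with another
scorer matters.

Conventions fixed here because they are genuinely open: a variant inside
several overlapping peaks contributes its full PP to each of them
(duplication is the conservative choice for a weighted deviation); peaks
are BED 0-based half-open and variants 1-based (VCF-like), with the
variant position converted to 0-based before the containment test.

### Seed cells

Cells with upper-tail normal $p < 0.05$ (i.e. $z > \Phi^{-1}(0.95) =
1.6449$) form the initial seed set. If more than 5% of cells pass, only
the `floor(0.05 * N)` highest-z cells are kept, with ties broken by lower
cell index — floor and the index tie-break are deterministic choices the
underlying procedure leaves open. At least one seed is always required;
when no cell passes, the run stops with the maximum z and the threshold in
the message rather than silently seeding nothing.

### Embedding and the mutual-kNN graph

The binarized peak-by-cell matrix is TF-IDF weighted,

$$w_{ij} = tf_{ij}\,\log\!\left(1 + \frac{N}{df_i}\right),$$

with natural log, $df_i$ the number of cells where peak $i$ is open, and
$tf_{ij}$ the binary entry divided by the cell's total open-peak count
(`tf_mode = "frequency"`, the default, weighting each cell against its
total feature count; `tf_mode = "binary"` gives the unnormalized reading).
A rank-30 truncated SVD of the TF-IDF matrix yields the LSI coordinates
(`d = 30`). The SVD is computed exactly from the eigendecomposition of the
cells-by-cells cross-product, so the embedding is deterministic — there is
no randomized solver and hence no seed to set — and component signs are
canonicalized (largest-magnitude loading positive). No depth-correlated
component is dropped by default; batch-corrected or otherwise external
embeddings can replace this stage via `load_external_embedding()`.

Euclidean distances in LSI space define each cell's `k = 30` nearest
neighbors (exact search; ties broken by lower index). An edge joins two
cells only when each is in the other's list (mutual kNN), which caps the
mutual degree at $k$ and suppresses hubs; a cell with no mutual edge is
connected to its single nearest neighbor (a recorded "fallback" edge), so
minimum degree is 1. This guarantees a minimum degree, not global
connectedness: when the graph still has several components a warning is
emitted and propagation mass simply remains inside the seeded components,
which is well-defined and sometimes exactly what the data mean (fully
separated cell populations).

### Random walk with restart

With binary adjacency $A$ and column-stochastic transition matrix
$M_{ij} = A_{ij}/\deg(j)$, the walk iterates

$$v \leftarrow (1-\gamma)\,M v + \gamma\,v_0,$$

from $v = v_0$, the uniform distribution over seeds, with restart
probability $\gamma = 0.05$. Column vectors and a column-stochastic $M$
are used throughout so that every iterate is a probability vector and the
total mass stays exactly 1. The iteration is a $\gamma$-damped affine
contraction (Lipschitz constant $1-\gamma$ in $L^1$), so convergence is
geometric; the stopping rule is $\lVert v_{s+1} - v_s\rVert_1 < \alpha$
with $\alpha = 10^{-5}$ ($L^1$ is the natural norm for probability
vectors; $L^\infty$ is available via `norm = "linf"`), guarded by
`max_iter = 1000`, which only triggers on tolerance pathologies and is
reported rather than hidden. `solve_stationary_exact()` returns the fixed
point $\gamma (I - (1-\gamma)M)^{-1} v_0$ directly and serves as the
independent cross-check of the iterative path in the tests.

### From stationary scores to the TRS

Stationary scores scale like $1/N$ and are not comparable across datasets.
The TRS therefore (1) clips the scores at their 99th percentile
(linear-interpolation quantile; values equal to the ceiling are left
unchanged), (2) min-max scales the clipped vector to $[0, 1]$, and (3)
multiplies by the mean z of the top 1% of cells by z (`ceiling ceil(0.01 N)`
cells), re-attaching the magnitude of the original enrichment analysis.
Consequences worth knowing: the TRS is a non-decreasing transform of the
stationary score (ties only from clipping); its minimum is exactly 0; a
constant stationary vector yields an all-zero TRS with a warning; and a
negative scale factor (all top z-scores negative) is passed through with a
loud warning rather than clamped, because silently flipping the sign would
misrank cells.

### Per-cell enrichment calls

The permutation test redraws `B = 1000` seed sets matched to the real
seeds' degree multiset (sampling without replacement within each degree
class; real seeds remain eligible candidates — excluding them would
distort the null whenever seeds dominate a degree class). Degrees include
fallback edges, since total degree is what shapes propagation. When a
degree class is too small the pool expands to the nearest degree values
(±1, ±2, ...) with a warning. Each permuted set is propagated identically
and the empirical p-value is

$$p_c = \frac{1 + \#\{b : \mathrm{np}_c \le \mathrm{np}^{(b)}_c\}}{1 + B},$$

with ties counted against the real score, so $p_c \in [1/(B+1), 1]$ and
the floor is reached exactly when the real score beats every permutation.
Cells with $p < 0.05$ (strict) are labelled enriched, the rest depleted.
The comparison uses stationary scores, not the TRS, because they sum to 1
independently of the seed set and are therefore directly comparable across
permutations. No multiple-testing correction is applied across cells — the
call is a per-cell empirical test by construction; users who want FDR
control across cells can apply it to the returned p-values.

## Parameters at a glance

| parameter | default | meaning |
|---|---|---|
| `variants.pp_threshold` | 0.001 | strict PP retention filter |
| `scorer.n_background` | 50 | background draws per z-score |
| `seeds.alpha` | 0.05 | upper-tail p cutoff for initial seeds |
| `seeds.cap_fraction` | 0.05 | maximum seed fraction of cells |
| `lsi.d` | 30 | LSI components |
| `lsi.tf_mode` | frequency | per-cell tf normalization |
| `graph.k` | 30 | neighbors for the mutual-kNN graph |
| `propagation.gamma` | 0.05 | restart probability |
| `propagation.alpha` | 1e-5 | convergence tolerance (L1) |
| `propagation.max_iter` | 1000 | iteration guard |
| `trs.ceiling_quantile` | 0.99 | clipping quantile |
| `trs.top_fraction` | 0.01 | top-z fraction for the scale factor |
| `perm.B` | 1000 | permutations |
| `perm.alpha` | 0.05 | enrichment call threshold |

## The synthetic benchmark: what it emulates and what it does not

`synthetic_bulk_profiles()` builds a peaks-by-cell-types bulk table from
scratch so the whole pipeline (and its tests) runs self-contained, with no
downloads. Its structure mimics FACS-sorted bulk ATAC-seq of distinct
hematopoietic identities:

* a shared heavy-tailed log-normal baseline per peak (`baseline_sdlog =
  1.5`) — reads concentrate in strong peaks;
* an independent genome-wide log-normal per-type effect
  (`type_dispersion = 0.6`) — distinct cell types differ broadly in
  accessibility, which is what separates them in LSI space;
* per type, a disjoint block of 300 trait-specific peaks
  (`n_specific_peaks_per_type`), damped to 5% of baseline strength
  (`specific_scale = 0.05`) and elevated 5-fold in their own type
  (`signal_ratio = 5`) — weak, cell-type-restricted regulatory elements,
  the kind fine-mapped variants actually fall in. Their weakness is the
  point: per-cell signal at variant peaks is sparse and noisy, so z-scores
  alone rank cells imperfectly and propagation has real work to do.

`synthesize_cells()` then draws each cell's count for peak $i$ in type $t$
from $\mathrm{binom}(2, p_i^t)$ with

$$p_i^t = (1-q)\,\frac{r_i^t}{2} + q\,\frac{n}{2k},$$

where $r_i^t$ is read as the expected fragment count $n \times$ (bulk
fraction of peak $i$ in type $t$): this is the only reading under which
the $q = 1$ limit $n/2k$ — a uniform scatter of $n$ fragments over $k$
peaks — is dimensionally consistent, and it makes the $q = 0$ limit
$E[\text{count}_i] = r_i$ exact. Probabilities above 1 are clamped and
counted. `synthetic_variants()` places variants uniformly inside peaks,
by default 80% of them inside the target type's specific block, with
Beta-distributed PPs.

Deliberate limitations, so that green tests are read correctly: cells
within a type are exchangeable draws (no doublets, batch effects,
trajectories or within-type substructure); counts are capped at 2 by the
two-trial binomial; and with `n_peaks = 10000` and `n = 10000` fragments
the per-cell sparsity is around 50%, well below the >95% typical of real
scATAC-seq (matching real sparsity at fixed $n$ would need the several
hundred thousand peaks of a genome-wide atlas, which is beyond a
self-contained test fixture). Passing tests demonstrate the algorithmic
properties — oracle equivalence, conservation, calibration, recovery,
robustness — under a faithful miniature of the benchmark's structure, not
performance on any real dataset.

## Problem sizes and statistical checks used by the test-suite

The standard fixture is two types at 300 cells each ($n = 10{,}000$,
$q = 0.3$); the acceptance script scales the headline benchmark to 500
cells per type. Oracle equivalence of the iterative and direct stationary
solutions is checked on 20 random mutual-kNN graphs of up to 2000 nodes;
structural oracles (kNN lists, mutual edges, TF-IDF weights,
variant-peak overlaps, auROC) are brute-force re-computations on
instances of up to 300 cells.

One statistical reading deserves a note. In the null-calibration check
(seeds drawn from the degree-matched null, then tested against their own
permutation distribution) each cell's empirical p is uniform on the
permutation lattice, so the expected enriched rate at $\alpha = 0.05$
with $B = 200$ is $10/201 \approx 0.0498$. But enrichment calls within
one run share a single propagation and are strongly correlated across
cells, so the sampling error of the mean rate is estimated empirically
across independent repetitions — a per-cell binomial SE would understate
it badly. The check asserts the mean rate over 10 repetitions does not
exceed $\alpha + 3\,\widehat{SE}$ with $\widehat{SE}$ the standard error
of the per-repetition rates.

## Degenerate inputs and numerical choices

* Cells with zero open peaks are a fatal error in the TF-IDF stage (the
  term frequency is undefined); the offending barcodes are listed.
* A trait whose variants land in no peak is fatal ("no accessible causal
  variants") rather than an all-zero weight vector.
* Zero background variance in the z scorer yields z = 0 with a warning.
* kNN distance ties and equal-z seed cutoffs are broken by lower cell
  index; all stochastic stages (scorer backgrounds, permutations,
  simulator) are driven by explicit seeds, and permutation $b$ uses seed
  `seed + b` so the B draws are independent and reproducible.
* Quantiles use R's default type-7 (linear interpolation) everywhere a
  percentile is taken.

## Known limitations

The exact kNN search and the dense fallback in the direct solver are
designed for datasets that fit comfortably in memory (tens of thousands
of cells); approximate neighbor search is not built in. Only binary
adjacency is supported (no distance- or Jaccard-weighted edges), matching
the underlying procedure. The built-in z scorer is faithful in spirit but
not numerically identical to external bias-corrected deviation tools;
where parity matters, import external z-scores and the rest of the
pipeline is unchanged.
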