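---
title: "Variance-gated hierarchical clustering of LCMS feature tables: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variance-gated hierarchical clustering of LCMS feature tables: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hcapca)
```

## The model and its assumptions

`hcapca` operates on a samples × features matrix of LCMS spectral
intensities, where each feature is an aligned (*m/z*, retention time) pair.
The working assumption is the standard one in strain dereplication: extracts
with similar metabolic profiles are chemically related and should be grouped
together, while samples that no group absorbs well are the interesting ones.
The *m/z* and rt values are carried as metadata for interpretation only —
distances and PCA see nothing but intensities, so the method applies
unchanged to any non-negative sample × variable table (an all-zero rt or
*m/z* vector is explicitly legal).

The procedure combines three standard components:

1. **Distance.** Euclidean distance between intensity profiles (the
   default), or 1 − Pearson correlation. Intensities enter as-is: no log
   transform and no normalization are applied, because the choice of such
   pre-treatment is sample-preparation-specific and is deliberately left
   upstream of this tool.

2. **UPGMA.** Average-linkage agglomeration: the pair of clusters with the
   smallest mean inter-cluster distance merges, at a height equal to that
   mean. Average linkage is reducible, so merge heights never decrease.
   The implementation records merges in `hclust`-compatible form; ties are
   broken deterministically (smallest cluster-index pair), which matters
   only on degenerate inputs but makes every run reproducible.

3. **Pareto-scaled PCA and the SoV12 gate.** For any candidate cluster, its
   own submatrix is re-centered per feature and divided by the square root
   of the per-feature sample standard deviation (n − 1 denominator). A
   scaled column's variance then equals the raw column's standard
   deviation, which damps intense features without letting weak ones
   dominate the way unit-variance scaling would. SoV12 is 100 × (e₁ + e₂),
   the summed explained-variance fractions of the first two PCs of the
   scaled submatrix. If SoV12 is below the cutoff, a 2-D PCA view of the
   cluster would be misleadingly lossy, so the cluster's dendrogram is
   split at its first branch point and the rule recurses on both children;
   otherwise the cluster is terminal and keeps its full PCA model.

### Why the recursion terminates

Column-centering n samples leaves rank at most n − 1, and explained
fractions are non-increasing, so SoV12 ≥ 200/(n−1) %. With the default 25%
cutoff, any cluster of nine or fewer samples is guaranteed terminal, and
every split strictly reduces cluster size, so the recursion halts on any
input. Clusters of ≤ 3 samples always have SoV12 = 100.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `cutoff` | 25 (%) | SoV12 at or above which a node is terminal. Lower values stop earlier (coarser groups); 100 recurses until the rank bound bites. |
| `metric` | `"euclidean"` | distance between intensity profiles; `"correlation"` groups by profile shape rather than magnitude. |
| `min_split_size` | 2 | nodes smaller than this are never split; raising it forces small clusters terminal before the gate is consulted. |

Both metrics depend only on the two samples' rows, so a child node's
distance matrix is the restriction of the parent's — sub-clustering is
exact without recomputation, and the suite verifies that every child's
dendrogram equals the corresponding clade of its parent's.

## Conventions and numerical choices

- **Root gating.** The root is judged by the same rule as every other
  node; a homogeneous dataset yields a single terminal root.
- **Singletons and degenerate nodes.** A PCA model of one sample is not
  possible; singletons are terminal with `NA` SoV12. Likewise a
  multi-member node whose samples are identical has an all-zero scaled
  matrix, no meaningful PCA, and zero distances — it is terminal with `NA`
  SoV12 rather than an error, since splitting a zero-distance clique would
  be arbitrary.
- **Zero-variance features** within a node are zeroed, not dropped, so
  loadings keep global feature indices; this is mathematically identical
  for the PCA.
- **Sign convention.** Each loading column is oriented so its
  largest-magnitude entry is positive (SVD signs are otherwise arbitrary);
  scores flip with their loadings so the reconstruction identity
  `scores = X · loadings` holds exactly.
- **Rank.** Components with singular values above
  `max(dim) · eps · σ₁` are retained; explained fractions are computed
  over the full spectrum, so they sum to 1 to numerical precision.
- **Tie-breaks and ordering.** UPGMA ties merge the smallest cluster-index
  pair; the left child of a split is the one containing the
  lexicographically smallest sample id (radix order, locale-independent);
  nodes are named `a`, `b`, …, `z`, `aa`, … in depth-first creation order.
  Together these make the whole tree, and its JSON export, byte-for-byte
  reproducible. The node-naming scheme is a deterministic stand-in — it is
  not a claim about any particular historical labelling.
- **Cut boundary.** `cut_at_height(h)` removes merges at height ≥ h:
  groups lie strictly below the line.
- **Newick layout.** Branch lengths are chosen so each root-to-leaf path
  equals the root merge height; the patristic distance between two leaves
  is twice the height of their lowest common merge.
- **Serialization.** JSON and TSV numbers are written with 17 significant
  digits, so export → import → export is the identity at the byte level.

## The synthetic generator: what it emulates, and what it does not

`synthetic_spec()` plants a known structure so that every claim the package
makes can be tested without any external dataset: `n_groups` strain groups
sharing `n_core_features` core features, each group carrying
`n_group_features` exclusive marker features, a large sparse background of
`n_noise_features` low-intensity features (each present in a sample with
probability `dropout_rate`), multiplicative log-normal intensity noise
(`noise_sd`, on the log scale), dropout of present features, and optionally
one outlier sample with its own block of exclusive features. Intensity
parameters only scale the random draws, so at a fixed seed raising
`group_intensity` strictly widens between-group separation — a property
the suite asserts.

The defaults (4 groups × 6 samples; 40 core, 15 group-exclusive and 24,000
noise features; base intensity 1e5; group intensity 2e6; `noise_sd` 0.3;
dropout 0.15; outlier block 600 features at 3.2e5) were fixed by an
explicit variance budget *before* the test suite was frozen, to realize the
regime the method is designed for:

- Raw Euclidean distances are dominated by the group-marker blocks
  (intensity enters the between-group distance quadratically), so UPGMA
  recovers the planted groups.
- Pareto-scaled variance is dominated by the many weak noise features
  (intensity enters scaled variance only linearly), spreading variance over
  all available components; mixed nodes therefore sit well under the 25%
  gate (measured ≈ 11% at the root, ≈ 15% and ≈ 21% for 18- and 12-sample
  mixed nodes) and keep splitting, while pure 6-sample groups are terminal
  by the rank bound (SoV12 ≥ 40%).
- The outlier block uses many moderate features rather than few intense
  ones for the same reason: it must exceed the node's noise eigenvalues in
  scaled variance (linear in intensity) while adding less raw distance
  (quadratic) than the between-group separation, so the outlier stays
  inside its group's terminal node yet owns that node's first principal
  component.

In this regime the outlier is the top-leverage sample of its node and its
features fill the large majority of the top radial loadings. The very
first few loading slots sometimes belong to the node's own 15 group-marker
features, whose residual log-normal/dropout variation at 2e6 intensity is
individually large after Pareto scaling — an honest property of
high-intensity markers, and why dominance is assessed over the top 50
loadings (planted outlier features are >70% of them, against a 2.4% base
rate) rather than the top handful.

What the generator does **not** emulate: correlated features from isotopes
and adducts of one metabolite, retention-time drift, batch effects,
censored low-intensity values, or heteroscedastic detector noise. Passing
the recovery tests therefore demonstrates the algorithm's correctness and
its intended variance behavior, not robustness to every artifact of real
acquisitions; on real tables the upstream alignment quality and the choice
of cutoff still matter.

## Problem sizes used in the checks

The automated checks run at desk scale, chosen to finish in minutes on one
CPU: 200 random distance matrices (≤ 10 samples) against a brute-force
average-linkage oracle; 100 random small synthetic tables for the
gate/partition invariants; and the default 24 × ~24,600 generator regime
for end-to-end recovery. All scale-dependent claims (rank bound, gate
logic, subset consistency) are size-independent properties and are also
exercised on the small fixtures.

## Known limitations

- UPGMA is O(S³) in the implementation here; collections of a few thousand
  samples are fine, but very large libraries would want a heap-based
  linkage.
- The SoV12 gate inherits PCA's blind spots: variance concentrated by a few
  extreme features can mask structure, and correlation distance is
  undefined for constant profiles (rejected with a clear error).
- No multiple-testing or significance machinery is attached to leverage or
  loading ranks; they are triage aids, not statistics.
- The interactive exploration the output invites is delegated to the JSON
  export and static report; no server component ships with the package.
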