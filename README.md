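# hcapca

Dereplication and prioritization of large microbial strain collections from
untargeted LCMS metabolomics feature tables.

## The problem

Natural-product discovery programs accumulate hundreds to thousands of
strain extracts, each profiled by LCMS as a vector of molecular-feature
intensities (one aligned *m/z* × retention-time feature per dimension).
Most strains are chemically redundant; the interesting ones are the
outliers. Picking sub-groups off a single hierarchical clustering by eye —
drawing a dissimilarity line across the dendrogram — is arbitrary: any
fixed cutoff merges distinct chemistry in one part of the tree while
shattering a homogeneous clade in another.

`hcapca` replaces the arbitrary cutoff with a variance criterion. Samples
are clustered by UPGMA on distances between intensity profiles

d(p, q) = sqrt( Σᵢ (qᵢ − pᵢ)² )   (or 1 − Pearson(p, q)),

the tree is partitioned at the point where it first branches, and each
resulting cluster is judged by the PCA of its own Pareto-scaled submatrix:
if the summed explained variance of the first two principal components
(**SoV12**) is below a preset cutoff (default 25%), a 2-D PCA plot cannot
faithfully summarize the cluster, and it is split again at its first
branch point. Recursion stops when SoV12 ≥ cutoff, producing a
"tree-of-trees" whose terminal nodes each carry an interpretable PCA model.
High-leverage samples in a terminal node's PC1–PC2 score plane are the
chemically unusual strains; the top loadings name the *m/z*/rt features
responsible.

Pareto scaling divides each mean-centered feature by the square root of its
standard deviation, damping — without erasing — the dominance of intense
features; a scaled column's variance equals the raw column's standard
deviation. Because a centered cluster of n samples has rank at most n − 1,
SoV12 ≥ 200/(n−1)%, so small clusters terminate automatically and the
recursion always halts.

## Worked example

The built-in generator plants known group structure (shared core features,
group-exclusive features, a large sparse noise background) so the whole
method can be exercised with known ground truth:

```r
library(hcapca)
sim <- simulate_feature_table(synthetic_spec(seed = 17))  # 4 groups x 6 samples
fit <- hcapca(sim$table, verbose = TRUE)
#> node a: n=24 SoV12=11.2% -> split
#> node b: n=18 SoV12=14.8% -> split
#> node c: n=12 SoV12=20.7% -> split
#> node d: n=6 SoV12=41.0% -> terminal
#> node e: n=6 SoV12=40.9% -> terminal
#> node f: n=6 SoV12=41.1% -> terminal
#> node g: n=6 SoV12=40.9% -> terminal
fit
#> hcapca tree: 24 samples, 7 nodes (4 terminal)
#>   cutoff = 25% SoV12, metric = euclidean, min_split_size = 2
#>   root SoV12 = 11.2%
```

Mixed nodes (a, b, c) sit well below the 25% gate and keep splitting; the
four pure 6-sample groups come out as the four terminal nodes (d–g), each
adequately summarized by two PCs (SoV12 ≈ 41%). The triage table ranks,
per terminal node, the most extreme sample in the PC1–PC2 score plane and
the features with the largest radial loadings:

```r
summary(fit)
#>   node n sov12 top_sample top_leverage                                    top_features
#> 1    d 6 41.05    samp002        22904 898.6076@7.95, 1333.8741@11.28, 1436.3989@11.47
#> 2    e 6 40.91    samp024        23761   1460.5237@13.69, 366.9175@7.34, 864.9219@5.52
#> 3    f 6 41.07    samp018        23272    423.7165@5.83, 714.6655@4.61, 1127.7358@9.15
#> 4    g 6 40.94    samp007        24176   245.0226@11.53, 1026.0199@3.18, 311.3036@3.99
```

`plot(fit)` draws the tree-of-trees; `plot(fit, "scores", node = "d")` and
`plot(fit, "loadings", node = "d")` show a terminal node's PCA with the
explained variance of each PC in parentheses on the axis labels.
`export_tree(fit, "out/")` writes a deterministic `tree.json` plus
per-node members/scores/loadings TSVs; `to_newick()` exports any node's
dendrogram.

## Command line

```sh
inst/cli/hcapca simulate --seed 17 --out demo_in
inst/cli/hcapca run --input demo_in --format dat --cutoff 25 --out demo_out
inst/cli/hcapca report --tree demo_out --out demo_report
```

`run` accepts a four-file `.dat` bundle (`Analyses.dat`, `Variables_m.dat`,
`Variables_t.dat`, `Table.dat`) or an MZmine-style aligned feature CSV
(`--format csv`), and writes `tree.json`, per-node TSVs, a static markdown
report with scores/loadings figures, and a run manifest with input
checksums.

## Scope

Feature finding, peak alignment and deconvolution are upstream of this
package (use MZmine or vendor tools and export the aligned table); MS/MS
annotation and dereplication against spectral databases are downstream.
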