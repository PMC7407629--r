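test_that("Euclidean distance matches the coordinate formula and the naive oracle", {
  ft <- feature_table(c("p", "q"), c(1, 2), c(1, 2), rbind(c(0, 0), c(3, 4)))
  d <- feature_distance(ft)
  expect_identical(d["p", "q"], 5)
  expect_identical(d["p", "p"], 0)
  for (seed in 1:4) {
    ft <- random_table(4, 6, seed)
    expect_equal(unname(feature_distance(ft)),
                 unname(oracle_euclidean(ft$intensities)), tolerance = 1e-12)
  }
})

test_that("correlation distance is 1 - Pearson and rejects constant samples", {
  ft <- feature_table(c("p", "q"), c(1, 2, 3), c(1, 2, 3),
                      rbind(c(1, 2, 3), c(2, 4, 6)))
  d <- feature_distance(ft, metric = "correlation")
  expect_equal(d["p", "q"], 0, tolerance = 1e-12)
  flat <- feature_table(c("p", "flat"), c(1, 2, 3), c(1, 2, 3),
                        rbind(c(1, 2, 3), c(5, 5, 5)))
  expect_error(feature_distance(flat, metric = "correlation"), "'flat'")
})

test_that("UPGMA reproduces the worked ultrametric agglomeration", {
  hc <- upgma(abcd_dist())
  expect_equal(hc$height, c(2, 4, 6))
  cm <- canonical_merges(hc)
  expect_identical(cm$leafsets,
                   list(c("A", "B"), c("A", "B", "C"), c("A", "B", "C", "D")))
  expect_identical(hc$sizes, c(2L, 3L, 4L))
  # two leaves: single merge at their distance
  d2 <- abcd_dist()[c("A", "B"), c("A", "B")]
  hc2 <- upgma(d2)
  expect_equal(hc2$height, 2)
})

test_that("UPGMA agrees with the brute-force average-linkage oracle", {
  for (seed in 1:30) {
    S <- sample(3:10, 1)
    d <- random_dist(S, seed = 1000 + seed)
    hc <- upgma(d)
    orc <- oracle_upgma(d)
    cm <- canonical_merges(hc)
    expect_equal(cm$heights, sort(orc$heights), tolerance = 1e-10)
    expect_identical(cm$leafsets, orc$leafsets[order(orc$heights)])
    expect_true(all(diff(hc$height) >= -1e-12))  # reducibility
  }
})

test_that("UPGMA heights match stats::hclust average linkage", {
  for (seed in 1:10) {
    d <- random_dist(7, seed = 2000 + seed)
    hc <- upgma(d)
    ref <- stats::hclust(stats::as.dist(d), method = "average")
    expect_equal(hc$height, ref$height, tolerance = 1e-10)
  }
})

test_that("top_split returns the two clades of the final merge", {
  hc <- upgma(abcd_dist())
  halves <- top_split(hc)
  halves <- halves[order(vapply(halves, length, integer(1)), decreasing = TRUE)]
  expect_setequal(halves[[1]], c("A", "B", "C"))
  expect_setequal(halves[[2]], "D")
  for (seed in 1:5) {
    d <- random_dist(6, seed = 3000 + seed)
    halves <- top_split(upgma(d))
    expect_length(intersect(halves[[1]], halves[[2]]), 0)
    expect_setequal(c(halves[[1]], halves[[2]]), rownames(d))
  }
})

test_that("cutting at a height yields 1 + #removed merges groups, boundary cut", {
  hc <- upgma(abcd_dist())
  g5 <- cut_at_height(hc, 5)
  expect_identical(lapply(g5, sort), list(c("A", "B", "C"), "D"))
  expect_length(cut_at_height(hc, 100), 1L)
  expect_length(cut_at_height(hc, 0), 4L)
  # a merge exactly at h is removed (groups lie strictly below the line)
  expect_length(cut_at_height(hc, 6), 2L)
  for (seed in 1:5) {
    hc <- upgma(random_dist(8, seed = 4000 + seed))
    for (h in c(0, stats::quantile(hc$height, c(0.3, 0.8)), max(hc$height) + 1)) {
      expect_length(cut_at_height(hc, h), 1L + sum(hc$height >= h))
    }
  }
})

test_that("newick export is ultrametric and survives an independent parser", {
  skip_if_not_installed("ape")
  d2 <- abcd_dist()[c("A", "B"), c("A", "B")]
  expect_identical(to_newick(upgma(d2)), "(A:2,B:2);")

  hc <- upgma(abcd_dist())
  tr <- ape::read.tree(text = to_newick(hc))
  pat <- ape::cophenetic.phylo(tr)
  expect_equal(pat["A", "D"], 12, tolerance = 1e-9)  # 2 x root height 6
  expect_equal(pat["A", "B"], 4, tolerance = 1e-9)
  # topology round trip on a random tree
  hc <- upgma(random_dist(7, seed = 5150))
  tr <- ape::read.tree(text = to_newick(hc))
  expect_setequal(tr$tip.label, hc$labels)
  pat <- ape::cophenetic.phylo(tr)
  # every leaf is at the same depth (ultrametric): pairwise distance to the
  # farthest leaf equals 2 x root height for all tips
  expect_equal(unname(apply(pat, 1, max)),
               rep(2 * max(hc$height), 7), tolerance = 1e-6)
})
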