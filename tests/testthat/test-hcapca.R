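small_spec <- function(seed, ...) {
  synthetic_spec(n_groups = 2, samples_per_group = 4, n_core_features = 10,
                 n_group_features = 6, n_noise_features = 60,
                 noise_sd = 0.6, dropout_rate = 0.2, seed = seed, ...)
}

test_that("node names follow the bijective base-26 creation sequence", {
  expect_identical(node_name(1), "a")
  expect_identical(node_name(26), "z")
  expect_identical(node_name(27), "aa")
  expect_identical(node_name(28), "ab")
  expect_identical(node_name(53), "ba")
  sim <- simulate_feature_table(small_spec(3))
  fit <- hcapca(sim$table)
  expect_identical(fit$root, "a")
  expect_identical(names(fit$nodes), vapply(seq_along(fit$nodes), node_name, ""))
  if (!fit$nodes[["a"]]$terminal) {
    expect_identical(fit$nodes[["a"]]$children[1], "b")
  }
})

test_that("a rank-2 dataset terminates at the root", {
  set.seed(11)
  basis <- matrix(runif(2 * 20, 0, 1), 2, 20)
  coords <- matrix(runif(8 * 2, 0, 50), 8, 2)
  x <- coords %*% basis  # exactly rank 2 (before centering rank <= 3)
  ft <- feature_table(paste0("s", 1:8), runif(20, 150, 1500), runif(20, 2, 14), x)
  fit <- hcapca(ft, cutoff = 25)
  expect_length(fit$nodes, 1L)
  expect_true(fit$nodes[[fit$root]]$terminal)
  expect_gte(fit$nodes[[fit$root]]$sov12, 25)
})

test_that("terminal member sets partition the samples and the gate is respected", {
  for (seed in 1:15) {
    sim <- simulate_feature_table(small_spec(seed))
    cutoff <- sample(c(15, 25, 40, 60), 1)
    fit <- hcapca(sim$table, cutoff = cutoff)
    members <- unlist(lapply(terminal_nodes(fit), function(nm) fit$nodes[[nm]]$members))
    expect_setequal(members, sim$table$sample_ids)
    expect_false(anyDuplicated(members) > 0)
    for (nd in fit$nodes) {
      n <- length(nd$members)
      if (!nd$terminal) {
        expect_lt(nd$sov12, cutoff)
        expect_length(nd$children, 2L)
        kids <- unlist(lapply(nd$children, function(ch) fit$nodes[[ch]]$members))
        expect_setequal(kids, nd$members)
      } else if (n >= 2 && !is.na(nd$sov12)) {
        expect_gte(nd$sov12, cutoff)
      }
      if (n == 1) expect_true(nd$terminal)
    }
  }
})

test_that("children's dendrograms equal the corresponding clades of the parent", {
  sim <- simulate_feature_table(synthetic_spec(
    n_groups = 3, samples_per_group = 4, n_core_features = 10,
    n_group_features = 6, n_noise_features = 80, noise_sd = 0.6,
    dropout_rate = 0.2, seed = 21))
  fit <- hcapca(sim$table, cutoff = 95)  # high cutoff -> deep tree, many splits
  splits <- Filter(function(nd) !nd$terminal, fit$nodes)
  expect_gt(length(splits), 0)
  for (nd in splits) {
    parent_cm <- canonical_merges(nd$dendrogram)
    for (ch in nd$children) {
      child <- fit$nodes[[ch]]
      if (length(child$members) < 2) next
      # child dendrogram recomputed from scratch off the table
      sub <- feature_table(child$members,
                           sim$table$mz, sim$table$rt,
                           sim$table$intensities[child$members, , drop = FALSE])
      fresh <- canonical_merges(upgma(feature_distance(sub)))
      keep <- vapply(parent_cm$leafsets, function(s) all(s %in% child$members),
                     logical(1))
      expect_identical(fresh$leafsets, parent_cm$leafsets[keep])
      expect_equal(fresh$heights, parent_cm$heights[keep], tolerance = 1e-10)
    }
  }
})

test_that("identical samples give a terminal degenerate node, not an error", {
  x <- rbind(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3))
  ft <- feature_table(c("a", "b", "c"), c(1, 2, 3), c(1, 2, 3), x)
  fit <- hcapca(ft)
  expect_length(fit$nodes, 1L)
  expect_true(fit$nodes[["a"]]$terminal)
  expect_true(is.na(fit$nodes[["a"]]$sov12))
  expect_null(fit$nodes[["a"]]$pca)
})

test_that("configuration is validated", {
  sim <- simulate_feature_table(small_spec(2))
  expect_error(hcapca(sim$table, cutoff = 0), "cutoff")
  expect_error(hcapca(sim$table, cutoff = 101), "cutoff")
  expect_error(hcapca(sim$table, min_split_size = 1), "min_split_size")
  one <- feature_table("s1", c(1, 2), c(1, 2), matrix(c(1, 2), 1))
  expect_error(hcapca(one), "at least 2 samples")
})

test_that("the terminal summary has one row per terminal node", {
  sim <- simulate_feature_table(small_spec(8))
  fit <- hcapca(sim$table)
  sm <- summary(fit)
  expect_identical(sm$node, terminal_nodes(fit))
  expect_identical(sm$n, vapply(terminal_nodes(fit),
                                function(nm) length(fit$nodes[[nm]]$members), 1L),
                   ignore_attr = TRUE)
  singles <- sm[sm$n == 1, ]
  if (nrow(singles) > 0) {
    expect_true(all(is.na(singles$top_sample)))
    expect_true(all(singles$top_features == ""))
  }
  multi <- sm[sm$n > 1 & !is.na(sm$sov12), ]
  expect_true(all(!is.na(multi$top_leverage)))
})

test_that("a raised cutoff never yields a shallower tree", {
  sim <- simulate_feature_table(small_spec(4))
  t25 <- hcapca(sim$table, cutoff = 25)
  t100 <- hcapca(sim$table, cutoff = 100)
  expect_gte(length(terminal_nodes(t100)), length(terminal_nodes(t25)))
})
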