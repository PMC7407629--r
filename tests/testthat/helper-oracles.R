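# Independent oracles and fixture builders shared across the suite.

# Naive double-loop Euclidean distance, written directly from the formula
# d(p, q) = sqrt(sum_i (q_i - p_i)^2); deliberately independent of
# feature_distance().
oracle_euclidean <- function(x) {
  S <- nrow(x)
  d <- matrix(0, S, S, dimnames = list(rownames(x), rownames(x)))
  for (i in seq_len(S)) {
    for (j in seq_len(S)) {
      acc <- 0
      for (k in seq_len(ncol(x))) acc <- acc + (x[j, k] - x[i, k])^2
      d[i, j] <- sqrt(acc)
    }
  }
  d
}

# Brute-force O(S^3) average-linkage agglomeration: clusters kept as leaf
# index sets, every step recomputes all pairwise average linkages from the
# original matrix. Returns merge heights and the canonical leaf set of each
# merge.
oracle_upgma <- function(d) {
  labels <- rownames(d)
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric(0)
  leafsets <- list()
  while (length(clusters) > 1L) {
    best <- Inf; bi <- bj <- NA
    for (i in seq_len(length(clusters) - 1L)) {
      for (j in (i + 1L):length(clusters)) {
        lk <- mean(d[clusters[[i]], clusters[[j]]])
        if (lk < best) { best <- lk; bi <- i; bj <- j }
      }
    }
    merged <- c(clusters[[bi]], clusters[[bj]])
    heights <- c(heights, best)
    leafsets <- c(leafsets, list(sort(labels[merged])))
    clusters[[bj]] <- NULL
    clusters[[bi]] <- merged
  }
  list(heights = heights, leafsets = leafsets)
}

# Canonical form of an upgma()/hclust result for comparison with the oracle
# and across sub/parent trees: per merge, the sorted leaf label set and the
# height, ordered by height then leaf set.
canonical_merges <- function(hc) {
  sets <- lapply(hcapca:::.merge_leafsets(hc), sort)
  keys <- vapply(sets, paste, character(1), collapse = "|")
  ord <- order(hc$height, keys)
  list(heights = hc$height[ord], leafsets = sets[ord])
}

# Ultrametric 4-leaf worked example: d(A,B)=2, d(.,C)=4, d(.,D)=6.
abcd_dist <- function() {
  d <- matrix(c(0, 2, 4, 6,
                2, 0, 4, 6,
                4, 4, 0, 6,
                6, 6, 6, 0), 4, 4,
              dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D")))
  d
}

# Random symmetric distance matrix with distinct entries (wsp seeded).
random_dist <- function(S, seed) {
  set.seed(seed)
  x <- matrix(runif(S * 3, 0, 10), S)
  rownames(x) <- paste0("s", seq_len(S))
  oracle_euclidean(x)
}

random_table <- function(S, F, seed) {
  set.seed(seed)
  feature_table(paste0("s", seq_len(S)),
                mz = runif(F, 150, 1500), rt = runif(F, 2, 14),
                intensities = matrix(rexp(S * F, rate = 1e-4), S, F))
}

# Tiny bundle written to a temp dir; returns the dir.
write_tiny_bundle <- function(dir = tempfile("bundle")) {
  dir.create(dir)
  writeLines(c("s1", "s2"), file.path(dir, "Analyses.dat"))
  writeLines("100.0 200.0 300.0", file.path(dir, "Variables_m.dat"))
  writeLines("1.0 2.0 3.0", file.path(dir, "Variables_t.dat"))
  writeLines(c("1 0 2", "0 5 0"), file.path(dir, "Table.dat"))
  dir
}

# Eigendecomposition-based explained-variance oracle (covariance route,
# independent of the SVD implementation under test).
oracle_explained <- function(x) {
  ev <- eigen(crossprod(x), symmetric = TRUE, only.values = TRUE)$values
  ev <- ev[ev > max(ev) * 1e-12]
  ev / sum(ev)
}

# Terminal-node group assignment of a fitted tree, as a named vector.
terminal_assignment <- function(fit) {
  ids <- fit$nodes[[fit$root]]$members
  lab <- stats::setNames(rep(NA_character_, length(ids)), ids)
  for (nm in terminal_nodes(fit)) lab[fit$nodes[[nm]]$members] <- nm
  lab
}
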