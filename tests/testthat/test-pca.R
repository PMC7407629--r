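test_that("Pareto scaling matches its closed forms", {
  # sd of (1,2,3) is 1: scaling fixed point
  expect_equal(unname(pareto_scale(cbind(c(1, 2, 3)))[, 1]), c(-1, 0, 1))
  # constant column zeroed
  expect_identical(unname(pareto_scale(cbind(c(5, 5, 5)))[, 1]), c(0, 0, 0))
  # direct arithmetic: sd(0,0,8,8) = sqrt(64/3)
  y <- pareto_scale(cbind(c(0, 0, 8, 8)))[, 1]
  expect_equal(unname(y), c(-4, -4, 4, 4) / sqrt(sqrt(64 / 3)), tolerance = 1e-12)
  expect_equal(unname(y), c(-1.8612, -1.8612, 1.8612, 1.8612), tolerance = 1e-4)
  expect_error(pareto_scale(matrix(1, 1, 3)), "at least 2 samples")
})

test_that("scaled columns have zero mean and variance equal to the raw sd", {
  for (seed in 1:5) {
    set.seed(seed)
    x <- matrix(rlnorm(8 * 20, 10, 1), 8, 20)
    x[, 1] <- 7  # constant column
    y <- pareto_scale(x)
    expect_lt(max(abs(colMeans(y))), 1e-10)
    raw_sd <- apply(x, 2, sd)[-1]
    expect_equal(apply(y, 2, var)[-1], raw_sd, tolerance = 1e-8)
    expect_identical(unname(y[, 1]), rep(0, 8))
  }
})

test_that("explained variance matches an eigendecomposition oracle and sums to 1", {
  for (seed in 1:5) {
    set.seed(seed)
    x <- pareto_scale(matrix(rnorm(6 * 10), 6, 10))
    m <- node_pca(x, paste0("s", 1:6))
    expect_equal(m$explained, oracle_explained(x), tolerance = 1e-9)
    expect_equal(sum(m$explained), 1, tolerance = 1e-9)
    expect_true(all(diff(m$explained) <= 1e-12))
    # reconstruction identity
    expect_equal(unname(m$scores), unname(x %*% m$loadings), tolerance = 1e-8)
  }
})

test_that("rank structure: 2 samples give one component, planar data two", {
  x <- pareto_scale(rbind(c(1, 5, 2), c(4, 1, 8)))
  m <- node_pca(x)
  expect_length(m$explained, 1L)
  expect_equal(m$explained, 1)
  expect_equal(sov12(m), 100)

  # data on a 2-D plane through the centroid: rank 2 exactly
  set.seed(42)
  basis <- matrix(rnorm(2 * 12), 2, 12)
  coords <- matrix(rnorm(6 * 2), 6, 2)
  x <- scale(coords %*% basis, center = TRUE, scale = FALSE)
  m <- node_pca(x)
  expect_equal(sum(m$explained[1:2]), 1, tolerance = 1e-9)
  expect_equal(sov12(m), 100, tolerance = 1e-7)

  expect_error(node_pca(matrix(0, 3, 4)), "degenerate")
})

test_that("explained variance is invariant under orthogonal rotation", {
  set.seed(7)
  x <- pareto_scale(matrix(rlnorm(8 * 15, 8, 1), 8, 15))
  Q <- qr.Q(qr(matrix(rnorm(15 * 15), 15)))
  m1 <- node_pca(x)
  m2 <- node_pca(x %*% Q)
  expect_equal(m1$explained, m2$explained, tolerance = 1e-9)
  expect_equal(sov12(m1), sov12(m2), tolerance = 1e-9)
})

test_that("SoV12 is 100 for any cluster of at most 3 samples", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(2:3, 1)
    x <- pareto_scale(matrix(rlnorm(n * 30, 9, 0.8), n, 30))
    expect_equal(sov12(node_pca(x)), 100, tolerance = 1e-9)
  }
})

test_that("leverage ranks score-plane norms, descending", {
  m <- structure(list(sample_ids = c("u", "v", "w"),
                      scores = rbind(c(3, 4), c(1, 1), c(0, 0)),
                      loadings = diag(2), explained = c(0.6, 0.4)),
                 class = "node_pca")
  lev <- sample_leverage(m)
  expect_identical(lev$sample_id, c("u", "v", "w"))
  expect_equal(lev$leverage, c(5, sqrt(2), 0))
  m$scores <- rbind(c(0, 0), c(0, 0), c(0, 0))
  expect_equal(sample_leverage(m)$leverage, c(0, 0, 0))
})

test_that("top loadings rank by the requested axis and annotate m/z, rt", {
  m <- structure(list(sample_ids = c("a", "b"),
                      loadings = rbind(c(0.9, 0.1), c(-0.1, 0.6), c(0.05, 0.79)),
                      scores = matrix(0, 2, 2), explained = c(0.7, 0.3)),
                 class = "node_pca")
  expect_identical(top_loadings(m, "PC1", k = 1)$feature, 1L)
  # radial: (0.6, 0.8) norm 1.0 beats (0.9, 0.1) norm 0.906
  m$loadings <- rbind(c(0.6, 0.8), c(0.9, 0.1))
  tl <- top_loadings(m, "radial", k = 2, mz = c(111.1, 222.2), rt = c(1.5, 2.5))
  expect_identical(tl$feature, c(1L, 2L))
  expect_identical(tl$mz, c(111.1, 222.2))
  expect_warning(top_loadings(m, "radial", k = 10), "truncating")
})
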