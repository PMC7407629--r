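#' Pareto scaling
#'
#' Per-feature transformation standard in metabolomics: each column is
#' mean-centered and divided by the square root of its sample standard
#' deviation (n - 1 denominator). Compared to unit-variance scaling this
#' damps the dominance of intense features less aggressively: a scaled
#' column's variance equals the original column's standard deviation, so
#' intense, variable features still lead the PCA but cannot drown everything
#' else. Zero-variance columns are set to all zeros (rather than dropped) to
#' preserve feature indexing.
#'
#' @param x numeric matrix, samples in rows (n >= 2).
#' @return The scaled matrix, with `"center"` (column means) and `"scale"`
#'   (`sqrt(sd)`, 1 for constant columns) attributes.
#' @export
pareto_scale <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) {
    stop("Pareto scaling needs at least 2 samples", call. = FALSE)
  }
  mu <- colMeans(x)
  s <- apply(x, 2L, stats::sd)
  y <- sweep(x, 2L, mu, "-")
  nz <- s > 0
  sc <- rep(1, ncol(x))
  sc[nz] <- sqrt(s[nz])
  y <- sweep(y, 2L, sc, "/")
  y[, !nz] <- 0
  attr(y, "center") <- mu
  attr(y, "scale") <- sc
  y
}

#' PCA of a (Pareto-scaled) node submatrix
#'
#' Singular value decomposition of an already-scaled matrix (no re-centering
#' is done here). All `K = rank` components are retained; the explained
#' variance fraction of component k is `sigma_k^2 / sum(sigma^2)`. Loadings
#' columns are oriented so their largest-magnitude entry is positive
#' (resolving the SVD sign ambiguity deterministically), and scores satisfy
#' `scores == x %*% loadings`.
#'
#' @param x numeric matrix (n x F), rows = samples, already Pareto scaled /
#'   centered.
#' @param sample_ids sample labels (defaults to rownames).
#' @return An object of class `node_pca`: list with `sample_ids`, `scores`
#'   (n x K), `loadings` (F x K), `explained` (length-K fractions, summing to
#'   1, non-increasing) and `sov12` (percentage, see [sov12()]).
#' @export
node_pca <- function(x, sample_ids = rownames(x)) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("PCA needs at least 2 samples", call. = FALSE)
  if (is.null(sample_ids)) sample_ids <- as.character(seq_len(nrow(x)))
  sv <- svd(x)
  if (!is.finite(sv$d[1L]) || sv$d[1L] <= 0) {
    stop("degenerate PCA model: matrix is all zeros", call. = FALSE)
  }
  tol <- max(dim(x)) * .Machine$double.eps * sv$d[1L]
  K <- sum(sv$d > tol)
  total <- sum(sv$d^2)
  explained <- sv$d[seq_len(K)]^2 / total
  loadings <- sv$v[, seq_len(K), drop = FALSE]
  scores <- sv$u[, seq_len(K), drop = FALSE] %*% diag(sv$d[seq_len(K)], nrow = K)
  for (k in seq_len(K)) {
    j <- which.max(abs(loadings[, k]))
    if (loadings[j, k] < 0) {
      loadings[, k] <- -loadings[, k]
      scores[, k] <- -scores[, k]
    }
  }
  rownames(scores) <- sample_ids
  colnames(scores) <- paste0("PC", seq_len(K))
  colnames(loadings) <- paste0("PC", seq_len(K))
  model <- structure(
    list(sample_ids = sample_ids, scores = scores, loadings = loadings,
         explained = explained),
    class = "node_pca")
  model$sov12 <- sov12(model)
  model
}

#' Summed variance of the first two principal components (SoV12)
#'
#' The stopping statistic of the recursive partitioner: 100 times the sum of
#' the explained-variance fractions of PC1 and PC2 (just PC1 when the model
#' has a single component). A cluster whose SoV12 reaches the cutoff is
#' considered adequately summarized by a 2-D PCA plot and is not split
#' further.
#'
#' @param model a [node_pca()] model.
#' @return A percentage in \[0, 100\].
#' @export
sov12 <- function(model) {
  e <- model$explained
  100 * sum(e[seq_len(min(2L, length(e)))])
}

#' Rank samples by leverage in the PC1-PC2 plane
#'
#' A sample's leverage is the Euclidean norm of its (PC1, PC2) score
#' coordinates (PC2 taken as 0 for single-component models). Large values
#' flag the chemically unusual samples a user inspects first; this
#' operationalizes reading the extreme point off a 2-D scores plot.
#'
#' @param model a [node_pca()] model.
#' @return A data.frame with columns `sample_id`, `leverage`, sorted in
#'   decreasing leverage (ties keep input order).
#' @export
sample_leverage <- function(model) {
  s1 <- model$scores[, 1L]
  s2 <- if (ncol(model$scores) >= 2L) model$scores[, 2L] else 0
  lev <- sqrt(s1^2 + s2^2)
  ord <- order(-lev)
  data.frame(sample_id = model$sample_ids[ord], leverage = unname(lev[ord]),
             stringsAsFactors = FALSE)
}

#' Top-ranked features by loading weight
#'
#' Ranks features by absolute loading on PC1, PC2, or by the radial norm
#' over the (PC1, PC2) loading plane, and returns the top `k`. Because
#' scores and loadings are algebraically linked, the features ranked here
#' are the ones pulling high-leverage samples out in the scores plot.
#'
#' @param model a [node_pca()] model.
#' @param axis `"PC1"`, `"PC2"` or `"radial"` (norm over PC1-PC2).
#' @param k number of features to return (truncated to F with a warning if
#'   larger).
#' @param mz,rt optional per-feature m/z and retention-time vectors to attach.
#' @return A data.frame with columns `feature` (column index in the node's
#'   matrix), `weight`, and `mz`/`rt` when supplied; sorted by decreasing
#'   weight.
#' @export
top_loadings <- function(model, axis = c("radial", "PC1", "PC2"), k = 10L,
                         mz = NULL, rt = NULL) {
  axis <- match.arg(axis)
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  L <- model$loadings
  w <- switch(axis,
    PC1 = abs(L[, 1L]),
    PC2 = {
      if (ncol(L) < 2L) stop("model has no PC2", call. = FALSE)
      abs(L[, 2L])
    },
    radial = {
      l2 <- if (ncol(L) >= 2L) L[, 2L] else 0
      sqrt(L[, 1L]^2 + l2^2)
    })
  if (k > length(w)) {
    warning(sprintf("k = %d exceeds the %d features available; truncating", k, length(w)))
    k <- length(w)
  }
  ord <- order(-w)[seq_len(k)]
  out <- data.frame(feature = ord, weight = unname(w[ord]))
  if (!is.null(mz)) out$mz <- mz[ord]
  if (!is.null(rt)) out$rt <- rt[ord]
  out
}

#' @export
print.node_pca <- function(x, ...) {
  cat(sprintf("node_pca: %d samples, %d components, SoV12 = %.1f%%\n",
              length(x$sample_ids), length(x$explained), x$sov12))
  ek <- utils::head(x$explained, 5L)
  cat("  explained: ", paste(sprintf("%.1f%%", 100 * ek), collapse = ", "),
      if (length(x$explained) > 5L) ", ..." else "", "\n", sep = "")
  invisible(x)
}
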