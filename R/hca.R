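#' Sample-to-sample distance matrix
#'
#' Computes the full symmetric distance matrix between sample intensity
#' profiles. With `metric = "euclidean"` the distance between samples p and q
#' is `sqrt(sum_i (q_i - p_i)^2)` over all feature intensities; with
#' `metric = "correlation"` it is `1 - Pearson(p, q)`.
#'
#' @param table a [feature_table()] with at least 2 samples.
#' @param metric `"euclidean"` (default) or `"correlation"`.
#' @return A labelled symmetric S x S numeric matrix with zero diagonal.
#' @export
feature_distance <- function(table, metric = c("euclidean", "correlation")) {
  metric <- match.arg(metric)
  x <- table$intensities
  if (nrow(x) < 2L) stop("distance matrix needs at least 2 samples", call. = FALSE)
  if (metric == "euclidean") {
    d <- as.matrix(stats::dist(x, method = "euclidean"))
  } else {
    sds <- apply(x, 1L, stats::sd)
    flat <- which(sds == 0 | !is.finite(sds))
    if (length(flat) > 0L) {
      stop(sprintf("correlation distance undefined: sample '%s' has constant intensities",
                   table$sample_ids[flat[1L]]), call. = FALSE)
    }
    d <- 1 - stats::cor(t(x))
    d[d < 0] <- pmax(d[d < 0], 0)  # clamp -eps from rounding
    diag(d) <- 0
  }
  dimnames(d) <- list(table$sample_ids, table$sample_ids)
  d
}

#' UPGMA agglomerative clustering
#'
#' Unweighted pair group method with arithmetic mean: repeatedly merges the
#' pair of clusters (A, B) with minimal average inter-cluster distance
#' `D(A,B) = (1/(|A||B|)) * sum_{a in A, b in B} d(a, b)`, records the merge
#' at height `D(A,B)`, and updates distances to the merged cluster by the
#' size-weighted average. Ties are broken deterministically by merging the
#' pair with the smallest cluster indices (leaves are indexed 1..S in label
#' order, merged clusters S+1, S+2, ... in creation order).
#'
#' The result is `hclust`-compatible (plot, cutree, etc. work) with merge
#' heights on the dissimilarity scale of the input matrix; average linkage is
#' reducible, so heights are non-decreasing.
#'
#' @param d symmetric distance matrix with zero diagonal and labelled
#'   dimnames (as from [feature_distance()]), S >= 2.
#' @return An object of class `c("upgma", "hclust")` with the usual `merge`,
#'   `height`, `order`, `labels` components plus `sizes` (cluster size at
#'   each merge).
#' @seealso [top_split()], [cut_at_height()], [to_newick()]
#' @export
upgma <- function(d) {
  d <- as.matrix(d)
  S <- nrow(d)
  if (S < 2L) stop("UPGMA needs at least 2 samples", call. = FALSE)
  if (ncol(d) != S) stop("distance matrix must be square", call. = FALSE)
  if (any(!is.finite(d)) || any(d < 0)) {
    stop("distance matrix entries must be finite and non-negative", call. = FALSE)
  }
  if (max(abs(d - t(d))) > 0) stop("distance matrix must be symmetric", call. = FALSE)
  labels <- rownames(d)
  if (is.null(labels)) labels <- as.character(seq_len(S))

  # working matrix indexed by cluster id 1..(2S-1); leaves are 1..S
  n_total <- 2L * S - 1L
  W <- matrix(NA_real_, n_total, n_total)
  W[1:S, 1:S] <- d
  sizes <- integer(n_total)
  sizes[1:S] <- 1L
  active <- rep(FALSE, n_total)
  active[1:S] <- TRUE

  merge <- matrix(0L, S - 1L, 2L)
  height <- numeric(S - 1L)
  msize <- integer(S - 1L)

  for (step in seq_len(S - 1L)) {
    act <- which(active)
    sub <- W[act, act, drop = FALSE]
    sub[lower.tri(sub, diag = TRUE)] <- Inf
    m <- min(sub)
    cand <- which(sub == m, arr.ind = TRUE)
    # lexicographically smallest (i, j) cluster-id pair among ties
    pairs <- cbind(act[cand[, 1L]], act[cand[, 2L]])
    ord <- order(pairs[, 1L], pairs[, 2L])
    i <- pairs[ord[1L], 1L]
    j <- pairs[ord[1L], 2L]

    new_id <- S + step
    height[step] <- m
    msize[step] <- sizes[i] + sizes[j]
    code <- function(id) if (id <= S) -id else id - S
    merge[step, ] <- c(code(i), code(j))

    others <- act[act != i & act != j]
    if (length(others) > 0L) {
      W[new_id, others] <- (sizes[i] * W[i, others] + sizes[j] * W[j, others]) /
        (sizes[i] + sizes[j])
      W[others, new_id] <- W[new_id, others]
    }
    sizes[new_id] <- sizes[i] + sizes[j]
    active[c(i, j)] <- FALSE
    active[new_id] <- TRUE
  }

  # leaf display order by depth-first walk of the final merge
  ord <- integer(0)
  walk <- function(node) {
    if (node < 0L) {
      ord[length(ord) + 1L] <<- -node
    } else {
      walk(merge[node, 1L])
      walk(merge[node, 2L])
    }
  }
  walk(as.integer(S - 1L))

  structure(list(merge = merge, height = height, order = ord,
                 labels = labels, sizes = msize, method = "average",
                 dist.method = "euclidean",
                 call = match.call()),
            class = c("upgma", "hclust"))
}

# leaf label sets for every merge row (list of character vectors)
.merge_leafsets <- function(hc) {
  n <- nrow(hc$merge)
  sets <- vector("list", n)
  for (k in seq_len(n)) {
    grab <- function(code) {
      if (code < 0L) hc$labels[-code] else sets[[code]]
    }
    sets[[k]] <- c(grab(hc$merge[k, 1L]), grab(hc$merge[k, 2L]))
  }
  sets
}

#' Split a dendrogram into its first two clusters
#'
#' Returns the two leaf sets of the children of the root merge — the point
#' where the tree first branches. These two sets are disjoint and together
#' cover every leaf.
#'
#' @param hc a dendrogram from [upgma()] (any `hclust` works).
#' @return A list of two character vectors of sample ids.
#' @export
top_split <- function(hc) {
  S <- length(hc$labels)
  if (S < 2L) stop("cannot split a dendrogram with fewer than 2 leaves", call. = FALSE)
  sets <- .merge_leafsets(hc)
  root <- nrow(hc$merge)
  grab <- function(code) if (code < 0L) hc$labels[-code] else sets[[code]]
  list(grab(hc$merge[root, 1L]), grab(hc$merge[root, 2L]))
}

#' Cut a dendrogram at a fixed dissimilarity height
#'
#' Draws a horizontal line across the tree at dissimilarity `h` and returns
#' the maximal subtrees lying entirely below it: every merge at height >= `h`
#' is removed, so the number of groups equals 1 plus the number of removed
#' merges.
#'
#' @param hc a dendrogram from [upgma()].
#' @param h cutting height, >= 0.
#' @return A list of character vectors (sample-id groups), ordered by each
#'   group's first leaf in `hc$labels` order.
#' @export
cut_at_height <- function(hc, h) {
  if (!is.numeric(h) || length(h) != 1L || !is.finite(h) || h < 0) {
    stop("cut height must be a single finite number >= 0", call. = FALSE)
  }
  S <- length(hc$labels)
  parent <- seq_len(S)  # union-find over leaves
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  sets <- .merge_leafsets(hc)
  for (k in seq_len(nrow(hc$merge))) {
    if (hc$height[k] < h) {
      members <- match(sets[[k]], hc$labels)
      r <- find(members[1L])
      for (m in members[-1L]) parent[find(m)] <- r
    }
  }
  roots <- vapply(seq_len(S), find, integer(1))
  groups <- split(hc$labels, roots)
  first <- vapply(groups, function(g) min(match(g, hc$labels)), integer(1))
  out <- groups[order(first)]
  names(out) <- NULL
  lapply(out, function(g) g[order(match(g, hc$labels))])
}

.escape_newick <- function(lab) {
  if (grepl("[ \t()\\[\\]:;,']", lab)) {
    paste0("'", gsub("'", "''", lab), "'")
  } else lab
}

#' Export a dendrogram as a newick string
#'
#' Ultrametric layout: the branch length of a child equals the parent's merge
#' height minus the child's merge height (leaves have height 0), so every
#' root-to-leaf path length equals the root merge height and the patristic
#' distance between two leaves is twice the height of their lowest common
#' merge.
#'
#' @param hc a dendrogram from [upgma()].
#' @param digits significant digits for branch lengths.
#' @return A single newick string, terminated by `;`.
#' @export
to_newick <- function(hc, digits = 10L) {
  fmt <- function(x) formatC(x, digits = digits, format = "g", width = 1)
  node_str <- function(code, parent_h) {
    if (code < 0L) {
      paste0(.escape_newick(hc$labels[-code]), ":", fmt(parent_h))
    } else {
      h <- hc$height[code]
      paste0("(", node_str(hc$merge[code, 1L], h), ",",
             node_str(hc$merge[code, 2L], h), "):", fmt(parent_h - h))
    }
  }
  root <- nrow(hc$merge)
  h <- hc$height[root]
  paste0("(", node_str(hc$merge[root, 1L], h), ",",
         node_str(hc$merge[root, 2L], h), ");")
}
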