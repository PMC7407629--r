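# Node names follow the creation sequence a, b, ..., z, aa, ab, ...
# (bijective base 26), assigned depth-first, left child first, so the
# labelling is stable across runs for identical input and configuration.
node_name <- function(n) {
  stopifnot(n >= 1)
  out <- character(0)
  while (n > 0) {
    r <- (n - 1) %% 26
    out <- c(letters[r + 1], out)
    n <- (n - 1) %/% 26
  }
  paste(out, collapse = "")
}

#' Fit a variance-gated hierarchical cluster tree (tree-of-trees)
#'
#' The core procedure of the package. Starting from the node holding every
#' sample, each node is evaluated by the SoV12 gate:
#'
#' 1. Pareto-scale the node's intensity submatrix (re-centered and re-scaled
#'    within the node) and compute its PCA and SoV12.
#' 2. The node is *terminal* if it has fewer than `min_split_size` members,
#'    is a singleton, or its SoV12 is at or above `cutoff` — i.e. a 2-D PCA
#'    plot already explains enough of the cluster's variance.
#' 3. Otherwise, build the node's UPGMA dendrogram (on the restriction of
#'    the full distance matrix, which is exact because both metrics depend
#'    only on the two samples' rows), split it into the first two clusters
#'    that formed, and recurse on each.
#'
#' Recursion always halts: each split strictly reduces member counts, and a
#' node of n samples has at most n - 1 components after centering, so
#' SoV12 >= 200/(n-1) % — any node with n <= 3 has SoV12 = 100. The terminal
#' member sets always partition the input samples.
#'
#' Terminal nodes with >= 2 members carry their full PCA model; singletons
#' carry none (a PCA model of one sample is not possible) and report `NA`
#' SoV12, as does the degenerate case of a multi-member node whose samples
#' are identical.
#'
#' The left child of a split is the one containing the lexicographically
#' smallest sample id; nodes are named `a`, `b`, ... in depth-first creation
#' order, so the whole tree is deterministic for a given input and
#' configuration.
#'
#' @param table a [feature_table()] with >= 2 samples.
#' @param cutoff SoV12 termination threshold in percent, in (0, 100].
#'   Default 25.
#' @param metric distance metric for clustering, `"euclidean"` (default) or
#'   `"correlation"`.
#' @param min_split_size nodes smaller than this are never split
#'   (default 2, i.e. only singletons are forced terminal).
#' @param verbose log one line per node (name, size, SoV12, decision).
#' @return An object of class `hcapca`: a list with `root` (node name),
#'   `nodes` (named list of node records with `name`, `parent`, `children`,
#'   `members`, `sov12`, `terminal`, `dendrogram`, `pca`), `config`, and the
#'   input `table`.
#' @seealso [summary.hcapca()], [plot.hcapca()], [export_tree()],
#'   [run_hcapca()]
#' @examples
#' sim <- simulate_feature_table(synthetic_spec(
#'   n_groups = 2, samples_per_group = 3, n_core_features = 10,
#'   n_group_features = 5, n_noise_features = 0, noise_sd = 0,
#'   dropout_rate = 0, seed = 1))
#' fit <- hcapca(sim$table)
#' summary(fit)
#' @export
hcapca <- function(table, cutoff = 25, metric = c("euclidean", "correlation"),
                   min_split_size = 2L, verbose = FALSE) {
  metric <- match.arg(metric)
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0 || cutoff > 100) {
    stop("cutoff must be a percentage in (0, 100]", call. = FALSE)
  }
  if (!is.numeric(min_split_size) || min_split_size < 2L) {
    stop("min_split_size must be >= 2", call. = FALSE)
  }
  min_split_size <- as.integer(min_split_size)
  findings <- validate_feature_table(table)
  if (nrow(findings) > 0L) {
    stop("invalid feature table:\n",
         paste0("  - ", findings$message, collapse = "\n"), call. = FALSE)
  }
  if (length(table$sample_ids) < 2L) {
    stop("insufficient input: need at least 2 samples", call. = FALSE)
  }

  dm <- feature_distance(table, metric)
  x <- table$intensities
  env <- new.env(parent = emptyenv())
  env$counter <- 0L
  env$nodes <- list()

  recurse <- function(members, parent) {
    env$counter <- env$counter + 1L
    name <- node_name(env$counter)
    n <- length(members)
    node <- list(name = name, parent = parent, children = character(0),
                 members = members, sov12 = NA_real_, terminal = TRUE,
                 dendrogram = NULL, pca = NULL)

    if (n == 1L) {
      if (verbose) message(sprintf("node %s: n=1 -> terminal (singleton)", name))
      env$nodes[[name]] <- node
      return(name)
    }

    node$dendrogram <- upgma(dm[members, members, drop = FALSE])
    scaled <- pareto_scale(x[members, , drop = FALSE])
    pca <- NULL
    sv <- NA_real_
    if (any(scaled != 0)) {
      pca <- node_pca(scaled, sample_ids = members)
      sv <- pca$sov12
    }
    node$sov12 <- sv

    terminal <- is.na(sv) || n < min_split_size || sv >= cutoff
    if (terminal) {
      node$terminal <- TRUE
      node$pca <- pca
      if (verbose) {
        message(sprintf("node %s: n=%d SoV12=%s -> terminal", name, n,
                        if (is.na(sv)) "NA" else sprintf("%.1f%%", sv)))
      }
      env$nodes[[name]] <- node
      return(name)
    }

    if (verbose) message(sprintf("node %s: n=%d SoV12=%.1f%% -> split", name, n, sv))
    halves <- top_split(node$dendrogram)
    firsts <- vapply(halves, function(h) {
      h[order(h, method = "radix")][1L]
    }, character(1))
    if (order(firsts, method = "radix")[1L] == 2L) halves <- rev(halves)
    # keep members in input table row order within each child
    halves <- lapply(halves, function(h) members[members %in% h])

    node$terminal <- FALSE
    env$nodes[[name]] <- node  # reserve slot; children filled below
    left <- recurse(halves[[1L]], name)
    right <- recurse(halves[[2L]], name)
    node$children <- c(left, right)
    env$nodes[[name]] <- node
    name
  }

  root <- recurse(table$sample_ids, NA_character_)
  structure(list(root = root, nodes = env$nodes,
                 config = list(cutoff = cutoff, metric = metric,
                               min_split_size = min_split_size),
                 table = table),
            class = "hcapca")
}

#' Terminal node names of a fitted tree
#' @param tree an `hcapca` object.
#' @return Character vector of terminal node names, in creation order.
#' @export
terminal_nodes <- function(tree) {
  names(tree$nodes)[vapply(tree$nodes, `[[`, logical(1), "terminal")]
}

#' @export
print.hcapca <- function(x, ...) {
  term <- terminal_nodes(x)
  cat(sprintf("hcapca tree: %d samples, %d nodes (%d terminal)\n",
              length(x$nodes[[x$root]]$members), length(x$nodes), length(term)))
  cat(sprintf("  cutoff = %g%% SoV12, metric = %s, min_split_size = %d\n",
              x$config$cutoff, x$config$metric, x$config$min_split_size))
  root_sv <- x$nodes[[x$root]]$sov12
  cat(sprintf("  root SoV12 = %s\n",
              if (is.na(root_sv)) "NA" else sprintf("%.1f%%", root_sv)))
  invisible(x)
}

#' Triage table over the terminal nodes
#'
#' One row per terminal node: its size and SoV12, the top-leverage sample of
#' its PCA model, and the top radial loadings annotated with m/z and
#' retention time — the table a user scans to pick which nodes (and which
#' strains in them) to chase further.
#'
#' @param object a fitted `hcapca` tree.
#' @param n_loadings number of top radial loadings to summarize per node.
#' @param ... unused.
#' @return A data.frame with columns `node`, `n`, `sov12`, `top_sample`,
#'   `top_leverage`, `top_features` (comma-separated `m/z@rt` strings; empty
#'   for singleton/degenerate nodes).
#' @export
summary.hcapca <- function(object, n_loadings = 3L, ...) {
  term <- terminal_nodes(object)
  rows <- lapply(term, function(nm) {
    node <- object$nodes[[nm]]
    top_sample <- NA_character_
    top_lev <- NA_real_
    feats <- ""
    if (!is.null(node$pca) && !is.null(node$pca$scores)) {
      lev <- sample_leverage(node$pca)
      top_sample <- lev$sample_id[1L]
      top_lev <- lev$leverage[1L]
      k <- min(n_loadings, nrow(node$pca$loadings))
      tl <- top_loadings(node$pca, axis = "radial", k = k,
                         mz = object$table$mz, rt = object$table$rt)
      feats <- if (is.null(object$table)) {
        paste(sprintf("f%d", tl$feature), collapse = ", ")
      } else {
        paste(sprintf("%.4f@%.2f", tl$mz, tl$rt), collapse = ", ")
      }
    }
    data.frame(node = nm, n = length(node$members), sov12 = node$sov12,
               top_sample = top_sample, top_leverage = top_lev,
               top_features = feats, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
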