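# Static report replacing an interactive browser: markdown plus PNG figures.
# Per-PC explained variance is printed in parentheses next to each axis
# label, the usual convention for metabolomics PCA plots.

.axis_label <- function(pc, frac) sprintf("%s (%.1f%%)", pc, 100 * frac)

#' Scores plot for one terminal node
#'
#' PC1 vs PC2 scatter of a terminal node's PCA model (PC2 is zero for
#' single-component models), axis labels carrying each PC's explained
#' variance, the top-leverage sample highlighted and labelled.
#'
#' @param tree a fitted `hcapca` object.
#' @param node terminal node name.
#' @param ... passed to [graphics::plot()].
#' @export
plot_node_scores <- function(tree, node, ...) {
  nd <- tree$nodes[[node]]
  if (is.null(nd) || is.null(nd$pca)) {
    stop(sprintf("node '%s' has no PCA model", node), call. = FALSE)
  }
  m <- nd$pca
  s1 <- m$scores[, 1L]
  s2 <- if (ncol(m$scores) >= 2L) m$scores[, 2L] else rep(0, length(s1))
  e2 <- if (length(m$explained) >= 2L) m$explained[2L] else 0
  lev <- sample_leverage(m)
  top <- lev$sample_id[1L]
  graphics::plot(s1, s2, pch = 19, col = ifelse(m$sample_ids == top, "red", "grey30"),
                 xlab = .axis_label("PC1", m$explained[1L]),
                 ylab = .axis_label("PC2", e2),
                 main = sprintf("Node %s scores (SoV12 = %.1f%%)", node, m$sov12), ...)
  graphics::abline(h = 0, v = 0, col = "grey80", lty = 3)
  graphics::text(s1[m$sample_ids == top], s2[m$sample_ids == top],
                 labels = top, pos = 3, col = "red", cex = 0.8)
  invisible(NULL)
}

#' Loadings plot for one terminal node
#'
#' PC1 vs PC2 loading weights of every feature; the top radial loadings are
#' highlighted — these are the m/z-rt features responsible for pulling
#' high-leverage samples out in the scores plot.
#'
#' @param tree a fitted `hcapca` object.
#' @param node terminal node name.
#' @param highlight number of top radial loadings to mark in red.
#' @param ... passed to [graphics::plot()].
#' @export
plot_node_loadings <- function(tree, node, highlight = 10L, ...) {
  nd <- tree$nodes[[node]]
  if (is.null(nd) || is.null(nd$pca)) {
    stop(sprintf("node '%s' has no PCA model", node), call. = FALSE)
  }
  m <- nd$pca
  l1 <- m$loadings[, 1L]
  l2 <- if (ncol(m$loadings) >= 2L) m$loadings[, 2L] else rep(0, length(l1))
  e2 <- if (length(m$explained) >= 2L) m$explained[2L] else 0
  k <- min(highlight, nrow(m$loadings))
  top <- top_loadings(m, axis = "radial", k = k)$feature
  col <- rep("grey60", length(l1)); col[top] <- "red"
  graphics::plot(l1, l2, pch = ifelse(seq_along(l1) %in% top, 15, 1), col = col,
                 cex = 0.6,
                 xlab = .axis_label("PC1", m$explained[1L]),
                 ylab = .axis_label("PC2", e2),
                 main = sprintf("Node %s loadings", node), ...)
  graphics::abline(h = 0, v = 0, col = "grey80", lty = 3)
  invisible(NULL)
}

#' Plot method for fitted trees
#'
#' `type = "tree"` draws the tree-of-trees diagram: one circle per node
#' (solid = terminal, dashed = split), labelled with name, size and SoV12.
#' `type = "dendrogram"` plots a node's UPGMA dendrogram; `"scores"` and
#' `"loadings"` dispatch to the per-node PCA plots.
#'
#' @param x a fitted `hcapca` object.
#' @param type what to draw.
#' @param node node name (defaults to the root for `"dendrogram"`; required
#'   to be terminal for `"scores"`/`"loadings"`).
#' @param ... passed on to the underlying plot.
#' @export
plot.hcapca <- function(x, type = c("tree", "dendrogram", "scores", "loadings"),
                        node = NULL, ...) {
  type <- match.arg(type)
  if (type == "dendrogram") {
    if (is.null(node)) node <- x$root
    hc <- x$nodes[[node]]$dendrogram
    if (is.null(hc)) stop(sprintf("node '%s' has no dendrogram", node), call. = FALSE)
    graphics::plot(hc, ylab = "Dissimilarity",
                   main = sprintf("Node %s", node), sub = "", xlab = "", ...)
    return(invisible(NULL))
  }
  if (type == "scores") return(plot_node_scores(x, node, ...))
  if (type == "loadings") return(plot_node_loadings(x, node, ...))

  # tree-of-trees layout: terminals evenly spaced, internals centered
  depth <- function(nm) {
    d <- 0L
    while (!is.na(x$nodes[[nm]]$parent)) { nm <- x$nodes[[nm]]$parent; d <- d + 1L }
    d
  }
  term <- terminal_nodes(x)
  xs <- stats::setNames(rep(NA_real_, length(x$nodes)), names(x$nodes))
  pos <- 0
  assign_x <- function(nm) {
    nd <- x$nodes[[nm]]
    if (nd$terminal) {
      pos <<- pos + 1
      xs[nm] <<- pos
    } else {
      for (ch in nd$children) assign_x(ch)
      xs[nm] <<- mean(xs[nd$children])
    }
  }
  assign_x(x$root)
  ys <- -vapply(names(x$nodes), depth, integer(1))
  graphics::plot(NA, xlim = c(0.5, length(term) + 0.5),
                 ylim = c(min(ys) - 0.6, 0.6), axes = FALSE, xlab = "", ylab = "",
                 main = "Tree of trees", ...)
  for (nd in x$nodes) {
    if (!is.na(nd$parent)) {
      graphics::segments(xs[nd$parent], ys[nd$parent], xs[nd$name], ys[nd$name],
                         col = "grey60")
    }
  }
  for (nd in x$nodes) {
    solid <- nd$terminal
    graphics::points(xs[nd$name], ys[nd$name], pch = 21, cex = 3,
                     bg = if (solid) "palegreen" else "white",
                     lty = if (solid) 1 else 2,
                     col = if (solid) "darkgreen" else "red3")
    lab <- sprintf("%s\nn=%d", nd$name, length(nd$members))
    graphics::text(xs[nd$name], ys[nd$name], lab, cex = 0.55)
    sv <- nd$sov12
    graphics::text(xs[nd$name], ys[nd$name] - 0.3,
                   if (is.na(sv)) "" else sprintf("%.1f%%", sv),
                   cex = 0.5, col = if (solid) "darkgreen" else "red3")
  }
  invisible(NULL)
}

#' Render a static report for a fitted tree
#'
#' Writes `report.md` plus a `figures/` directory: the tree-of-trees
#' diagram, one scores and one loadings PNG per multi-member terminal node
#' (axis labels carry each PC's explained variance, rounded to 0.1), and the
#' terminal-node triage table. Singleton nodes are listed without plots.
#'
#' @param tree a fitted `hcapca` object.
#' @param directory output directory.
#' @return Invisibly, the path of `report.md`.
#' @export
hcapca_report <- function(tree, directory) {
  dir.create(file.path(directory, "figures"), recursive = TRUE, showWarnings = FALSE)
  figdir <- file.path(directory, "figures")
  dev <- function(file, w = 900, h = 700) {
    grDevices::png(file, width = w, height = h, res = 110)
  }

  dev(file.path(figdir, "tree.png"), 1100, 700)
  plot(tree, type = "tree")
  grDevices::dev.off()

  term <- terminal_nodes(tree)
  lines <- c("# hcapca report", "",
             sprintf("- samples: %d", length(tree$nodes[[tree$root]]$members)),
             sprintf("- nodes: %d (%d terminal)", length(tree$nodes), length(term)),
             sprintf("- SoV12 cutoff: %g%%; metric: %s; min split size: %d",
                     tree$config$cutoff, tree$config$metric,
                     tree$config$min_split_size),
             "", "![tree of trees](figures/tree.png)", "",
             "## Terminal nodes", "")
  sm <- summary(tree)
  header <- paste0("| ", paste(names(sm), collapse = " | "), " |")
  sepr <- paste0("|", paste(rep("---", ncol(sm)), collapse = "|"), "|")
  fmtcell <- function(v) {
    if (is.numeric(v)) ifelse(is.na(v), "", formatC(v, digits = 4, format = "g"))
    else ifelse(is.na(v), "", as.character(v))
  }
  cells <- matrix(vapply(sm, fmtcell, character(nrow(sm))), nrow = nrow(sm))
  rows <- apply(cells, 1L, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  lines <- c(lines, header, sepr, rows, "")

  for (nm in term) {
    nd <- tree$nodes[[nm]]
    lines <- c(lines, sprintf("### Node %s (n = %d)", nm, length(nd$members)), "")
    if (is.null(nd$pca)) {
      lines <- c(lines,
                 if (length(nd$members) == 1L) {
                   "Singleton node: no PCA model is possible for a single sample."
                 } else {
                   "Degenerate node (identical samples): no PCA model."
                 },
                 sprintf("Members: %s", paste(nd$members, collapse = ", ")), "")
      next
    }
    e <- nd$pca$explained
    e2 <- if (length(e) >= 2L) e[2L] else 0
    lines <- c(lines,
               sprintf("SoV12 = %.1f%% (PC1 %.1f%%, PC2 %.1f%%)",
                       nd$sov12, 100 * e[1L], 100 * e2), "")
    sfile <- sprintf("figures/%s_scores.png", nm)
    lfile <- sprintf("figures/%s_loadings.png", nm)
    dev(file.path(directory, sfile)); plot_node_scores(tree, nm); grDevices::dev.off()
    dev(file.path(directory, lfile)); plot_node_loadings(tree, nm); grDevices::dev.off()
    lines <- c(lines, sprintf("![scores](%s)", sfile),
               sprintf("![loadings](%s)", lfile), "")
  }
  out <- file.path(directory, "report.md")
  writeLines(lines, out)
  invisible(out)
}
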