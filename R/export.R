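# Serialization of the tree-of-trees. tree.json is fully deterministic for a
# given input and configuration (no timestamps, canonical key order, 17
# significant digits), so identical runs produce byte-identical files and
# export -> import -> export is the identity.

.dendro_to_list <- function(hc) {
  if (is.null(hc)) return(NULL)
  list(labels = as.list(hc$labels),
       merge = unname(apply(hc$merge, 1L, as.list, simplify = FALSE)),
       height = as.list(hc$height))
}

.dendro_from_list <- function(lst) {
  if (is.null(lst)) return(NULL)
  S <- length(lst$labels)
  merge <- matrix(vapply(unlist(lst$merge, recursive = FALSE), as.integer, integer(1)),
                  ncol = 2L, byrow = TRUE)
  hc <- structure(list(merge = merge,
                       height = vapply(lst$height, as.numeric, numeric(1)),
                       labels = vapply(lst$labels, as.character, character(1)),
                       method = "average", dist.method = "euclidean",
                       call = quote(upgma(d))),
                  class = c("upgma", "hclust"))
  sets <- .merge_leafsets(hc)
  hc$sizes <- vapply(sets, length, integer(1))
  ord <- integer(0)
  walk <- function(node) {
    if (node < 0L) ord[length(ord) + 1L] <<- -node
    else { walk(hc$merge[node, 1L]); walk(hc$merge[node, 2L]) }
  }
  walk(nrow(hc$merge))
  hc$order <- ord
  hc
}

.node_to_list <- function(node, files = NULL) {
  out <- list(
    name = node$name,
    parent = if (is.na(node$parent)) NULL else node$parent,
    children = as.list(node$children),
    members = as.list(node$members),
    size = length(node$members),
    sov12 = if (is.na(node$sov12)) NULL else node$sov12,
    terminal = node$terminal,
    dendrogram = .dendro_to_list(node$dendrogram)
  )
  if (!is.null(node$pca)) {
    out$pca <- list(explained = as.list(node$pca$explained))
    if (!is.null(files)) out$pca$files <- files
  }
  out
}

#' Serialize a fitted tree to JSON
#'
#' Produces the machine-readable export of the tree-of-trees: configuration
#' plus one record per node (name, parent, children, members, SoV12,
#' terminal flag, the node's dendrogram merge list, and for terminal PCA
#' models the explained-variance vector and, when written via
#' [export_tree()], references to the score/loading TSV files). The schema
#' is shipped at `system.file("schema", "hcapca-tree.schema.json",
#' package = "hcapca")`.
#'
#' @param tree a fitted `hcapca` object.
#' @param file_index optional named list mapping node name to a list of
#'   relative file paths (as built by [export_tree()]).
#' @return A single JSON string (class `json`).
#' @export
tree_json <- function(tree, file_index = NULL) {
  nodes <- lapply(tree$nodes, function(node) {
    .node_to_list(node, files = file_index[[node$name]])
  })
  names(nodes) <- NULL
  doc <- list(format = "hcapca-tree", format_version = 1L,
              config = tree$config, root = tree$root, nodes = nodes)
  # digits = I(17): significant digits sufficient for exact double round trips
  jsonlite::toJSON(doc, auto_unbox = TRUE, digits = I(17), null = "null",
                   pretty = TRUE)
}

#' Export a fitted tree to a directory
#'
#' Writes `tree.json` plus per-node tab-separated files under `nodes/`:
#' `members.tsv` for every node, and `scores.tsv` / `loadings.tsv` (features
#' annotated with m/z and rt) for every terminal node carrying a PCA model.
#' Optionally a newick file per multi-member node. Numeric TSV values are
#' written with 17 significant digits so a round trip is exact.
#'
#' @param tree a fitted `hcapca` object.
#' @param directory output directory (created if needed).
#' @param newick also write `dendrogram.nwk` per multi-member node.
#' @return Invisibly, the file index: named list (by node) of relative paths.
#' @export
export_tree <- function(tree, directory, newick = FALSE) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  fmt <- function(x) formatC(x, digits = 17L, format = "g", width = 1)
  index <- list()
  for (node in tree$nodes) {
    ndir <- file.path(directory, "nodes", node$name)
    dir.create(ndir, recursive = TRUE, showWarnings = FALSE)
    rel <- function(f) file.path("nodes", node$name, f)
    files <- list(members = rel("members.tsv"))
    writeLines(c("sample_id", node$members), file.path(ndir, "members.tsv"))
    if (!is.null(node$pca)) {
      sc <- node$pca$scores
      df <- data.frame(sample_id = node$pca$sample_ids, stringsAsFactors = FALSE)
      for (k in seq_len(ncol(sc))) df[[colnames(sc)[k]]] <- fmt(sc[, k])
      utils::write.table(df, file.path(ndir, "scores.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      ld <- node$pca$loadings
      mzv <- if (!is.null(tree$table)) tree$table$mz else node$pca$mz
      rtv <- if (!is.null(tree$table)) tree$table$rt else node$pca$rt
      if (is.null(mzv)) mzv <- rep(NA_real_, nrow(ld))
      if (is.null(rtv)) rtv <- rep(NA_real_, nrow(ld))
      ldf <- data.frame(feature = seq_len(nrow(ld)),
                        mz = fmt(mzv), rt = fmt(rtv),
                        stringsAsFactors = FALSE)
      for (k in seq_len(ncol(ld))) ldf[[colnames(ld)[k]]] <- fmt(ld[, k])
      utils::write.table(ldf, file.path(ndir, "loadings.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      files$scores <- rel("scores.tsv")
      files$loadings <- rel("loadings.tsv")
    }
    if (newick && !is.null(node$dendrogram)) {
      writeLines(to_newick(node$dendrogram), file.path(ndir, "dendrogram.nwk"))
      files$newick <- rel("dendrogram.nwk")
    }
    index[[node$name]] <- files
  }
  writeLines(as.character(tree_json(tree, file_index = index)),
             file.path(directory, "tree.json"))
  invisible(index)
}

#' Re-import a tree exported with [export_tree()]
#'
#' Reconstructs the `hcapca` object from `tree.json` (and the per-node score
#' and loading TSVs referenced in it, when present, so terminal PCA models
#' come back numerically identical). The original feature table is not part
#' of the export; the returned object has `table = NULL`.
#'
#' @param path either the export directory or the `tree.json` file itself.
#' @return An `hcapca` object (without `table`).
#' @export
import_tree <- function(path) {
  if (dir.exists(path)) {
    json_file <- file.path(path, "tree.json")
    base <- path
  } else {
    json_file <- path
    base <- dirname(path)
  }
  if (!file.exists(json_file)) {
    stop(sprintf("no tree.json at '%s'", path), call. = FALSE)
  }
  doc <- jsonlite::fromJSON(json_file, simplifyVector = FALSE)
  if (!identical(doc$format, "hcapca-tree")) {
    stop("not an hcapca tree export (missing format tag)", call. = FALSE)
  }
  nodes <- list()
  for (nl in doc$nodes) {
    node <- list(
      name = nl$name,
      parent = if (is.null(nl$parent)) NA_character_ else nl$parent,
      children = vapply(nl$children, as.character, character(1)),
      members = vapply(nl$members, as.character, character(1)),
      sov12 = if (is.null(nl$sov12)) NA_real_ else as.numeric(nl$sov12),
      terminal = isTRUE(nl$terminal),
      dendrogram = .dendro_from_list(nl$dendrogram),
      pca = NULL
    )
    if (length(node$children) == 0L) node$children <- character(0)
    if (!is.null(nl$pca)) {
      explained <- vapply(nl$pca$explained, as.numeric, numeric(1))
      pca <- list(explained = explained)
      f <- nl$pca$files
      if (!is.null(f$scores) && file.exists(file.path(base, f$scores))) {
        sdf <- utils::read.table(file.path(base, f$scores), sep = "\t",
                                 header = TRUE, stringsAsFactors = FALSE)
        pca$sample_ids <- as.character(sdf$sample_id)
        pca$scores <- as.matrix(sdf[, -1L, drop = FALSE])
        rownames(pca$scores) <- pca$sample_ids
      }
      if (!is.null(f$loadings) && file.exists(file.path(base, f$loadings))) {
        ldf <- utils::read.table(file.path(base, f$loadings), sep = "\t",
                                 header = TRUE, stringsAsFactors = FALSE)
        pca$loadings <- as.matrix(ldf[, setdiff(names(ldf), c("feature", "mz", "rt")),
                                      drop = FALSE])
        pca$mz <- as.numeric(ldf$mz)
        pca$rt <- as.numeric(ldf$rt)
      }
      if (is.null(pca$sample_ids)) pca$sample_ids <- node$members
      pca$sov12 <- 100 * sum(explained[seq_len(min(2L, length(explained)))])
      class(pca) <- "node_pca"
      node$pca <- pca
    }
    nodes[[node$name]] <- node
  }
  structure(list(root = doc$root, nodes = nodes,
                 config = list(cutoff = as.numeric(doc$config$cutoff),
                               metric = as.character(doc$config$metric),
                               min_split_size = as.integer(doc$config$min_split_size)),
                 table = NULL),
            class = "hcapca")
}

#' Structural check of a tree JSON document
#'
#' Verifies that a JSON string or file conforms to the shipped tree export
#' schema: required top-level keys, required per-node fields and types, the
#' parent/child linkage, and that terminal member sets partition the sample
#' set. Findings are returned as a character vector (empty when valid).
#'
#' @param json a JSON string, or path to a `tree.json` file.
#' @return Character vector of problems; `character(0)` if conformant.
#' @export
validate_tree_json <- function(json) {
  problems <- character(0)
  doc <- tryCatch(
    if (length(json) == 1L && file.exists(json)) {
      jsonlite::fromJSON(json, simplifyVector = FALSE)
    } else {
      jsonlite::fromJSON(paste(json, collapse = "\n"), simplifyVector = FALSE)
    },
    error = function(e) NULL)
  if (is.null(doc)) return("not parseable as JSON")
  for (key in c("format", "format_version", "config", "root", "nodes")) {
    if (is.null(doc[[key]])) problems <- c(problems, sprintf("missing top-level key '%s'", key))
  }
  if (length(problems) > 0L) return(problems)
  if (!identical(doc$format, "hcapca-tree")) {
    problems <- c(problems, "format is not 'hcapca-tree'")
  }
  for (key in c("cutoff", "metric", "min_split_size")) {
    if (is.null(doc$config[[key]])) {
      problems <- c(problems, sprintf("config lacks '%s'", key))
    }
  }
  seen <- character(0)
  all_members <- character(0)
  term_members <- character(0)
  for (nl in doc$nodes) {
    for (key in c("name", "children", "members", "size", "terminal")) {
      if (is.null(nl[[key]]) && !(key %in% c("children", "members"))) {
        problems <- c(problems, sprintf("node record lacks '%s'", key))
      }
    }
    if (is.null(nl$name)) next
    seen <- c(seen, nl$name)
    mem <- vapply(nl$members, as.character, character(1))
    if (length(mem) != nl$size) {
      problems <- c(problems, sprintf("node '%s': size %s != %d members",
                                      nl$name, nl$size, length(mem)))
    }
    if (isTRUE(nl$terminal) && length(nl$children) != 0L) {
      problems <- c(problems, sprintf("terminal node '%s' has children", nl$name))
    }
    if (!isTRUE(nl$terminal) && length(nl$children) != 2L) {
      problems <- c(problems, sprintf("non-terminal node '%s' lacks two children", nl$name))
    }
    if (isTRUE(nl$terminal)) term_members <- c(term_members, mem)
    if (is.null(nl$parent)) all_members <- mem
  }
  if (!doc$root %in% seen) problems <- c(problems, "root node not among node records")
  if (anyDuplicated(term_members)) {
    problems <- c(problems, "terminal member sets overlap")
  }
  if (!setequal(term_members, all_members)) {
    problems <- c(problems, "terminal member sets do not cover the root members")
  }
  problems
}
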