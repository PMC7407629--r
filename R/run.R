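#' Run the full pipeline on an input table
#'
#' One call from a spectral-intensity table on disk to the complete output
#' directory: read (`.dat` bundle or aligned feature CSV), fit the
#' variance-gated tree with [hcapca()], export `tree.json` and per-node
#' TSVs, optionally newick files, render the static report, and write a run
#' manifest (`manifest.json`) recording the inputs, their checksums, the
#' executed configuration, tool version and the output file index.
#'
#' @param input path to a `.dat` bundle directory (`format = "dat"`) or an
#'   aligned feature CSV (`format = "csv"`).
#' @param out output directory.
#' @param format input format.
#' @param cutoff,metric,min_split_size passed to [hcapca()].
#' @param newick also export per-node newick dendrograms.
#' @param report render the static markdown report with figures.
#' @param csv_mapping optional named list overriding [import_feature_csv()]
#'   column mapping (`mz_col`, `rt_col`, `sample_suffix`, `sample_cols`).
#' @param verbose log one line per node.
#' @return Invisibly, the manifest list.
#' @export
run_hcapca <- function(input, out, format = c("dat", "csv"), cutoff = 25,
                       metric = c("euclidean", "correlation"),
                       min_split_size = 2L, newick = FALSE, report = TRUE,
                       csv_mapping = NULL, verbose = FALSE) {
  format <- match.arg(format)
  metric <- match.arg(metric)
  table <- if (format == "dat") {
    read_dat_bundle(input)
  } else {
    do.call(import_feature_csv, c(list(path = input), csv_mapping))
  }
  tree <- hcapca(table, cutoff = cutoff, metric = metric,
                 min_split_size = min_split_size, verbose = verbose)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  index <- export_tree(tree, out, newick = newick)
  outputs <- c("tree.json", unlist(index, use.names = FALSE))
  if (report) {
    hcapca_report(tree, out)
    outputs <- c(outputs, "report.md")
  }

  input_files <- if (format == "dat") {
    file.path(input, .bundle_files)
  } else input
  manifest <- list(
    tool = "hcapca",
    version = as.character(utils::packageVersion("hcapca")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    input = list(path = input, format = format,
                 md5 = as.list(tools::md5sum(input_files))),
    config = tree$config,
    tree_json_md5 = unname(tools::md5sum(file.path(out, "tree.json"))),
    outputs = as.list(outputs))
  writeLines(as.character(jsonlite::toJSON(manifest, auto_unbox = TRUE,
                                           digits = NA, pretty = TRUE)),
             file.path(out, "manifest.json"))
  missing <- outputs[!file.exists(file.path(out, outputs))]
  if (length(missing) > 0L) {
    stop("manifest references missing outputs: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  invisible(manifest)
}
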