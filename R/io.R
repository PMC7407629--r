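# .dat bundle dialect: Analyses.dat = one sample name per line;
# Variables_m.dat / Variables_t.dat = space-separated m/z / rt values on one
# line; Table.dat = one line of space-separated intensities per sample, in
# Analyses.dat order, columns in Variables_m.dat order. Any run of spaces or
# tabs separates tokens; a trailing newline is optional.

.bundle_files <- c("Analyses.dat", "Variables_m.dat", "Variables_t.dat", "Table.dat")

.parse_numeric_tokens <- function(tokens, file, line) {
  vals <- suppressWarnings(as.numeric(tokens))
  bad <- which(is.na(vals) & !(tokens %in% c("NA", "NaN")))
  if (length(bad) > 0L) {
    stop(sprintf("parse error in %s, line %d, token %d: '%s' is not numeric",
                 file, line, bad[1L], tokens[bad[1L]]), call. = FALSE)
  }
  vals
}

.split_tokens <- function(line) {
  tokens <- strsplit(trimws(line), "[ \t]+")[[1L]]
  tokens[nzchar(tokens)]
}

#' Read a four-file .dat bundle
#'
#' Reads the spectral-intensity table dialect this tool consumes: a directory
#' holding `Analyses.dat` (sample names, one per line), `Variables_m.dat`
#' (m/z values, space-separated, one line), `Variables_t.dat` (retention
#' times, likewise) and `Table.dat` (one line of space-separated intensities
#' per sample). Row order follows `Analyses.dat`; column order follows
#' `Variables_m.dat`. Users without one of the two feature coordinates may
#' supply an all-zero `Variables_m.dat` or `Variables_t.dat`; the vector is
#' metadata only and has no effect on clustering.
#'
#' @param directory path to a directory containing the four files.
#' @return A [feature_table()].
#' @export
read_dat_bundle <- function(directory) {
  if (!dir.exists(directory)) {
    stop(sprintf("bundle directory '%s' does not exist", directory), call. = FALSE)
  }
  paths <- file.path(directory, .bundle_files)
  missing <- .bundle_files[!file.exists(paths)]
  if (length(missing) > 0L) {
    stop(sprintf("missing bundle member: %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  names(paths) <- .bundle_files

  sample_lines <- readLines(paths[["Analyses.dat"]], warn = FALSE)
  # drop a single trailing empty line (trailing newline), reject interior blanks
  if (length(sample_lines) > 0L && !nzchar(trimws(sample_lines[length(sample_lines)]))) {
    sample_lines <- sample_lines[-length(sample_lines)]
  }
  blank <- which(!nzchar(trimws(sample_lines)))
  if (length(blank) > 0L) {
    stop(sprintf("Analyses.dat line %d is blank; blank sample names are not allowed",
                 blank[1L]), call. = FALSE)
  }
  sample_ids <- trimws(sample_lines)
  if (length(sample_ids) == 0L) stop("Analyses.dat contains no sample names", call. = FALSE)

  read_vector <- function(file) {
    lines <- readLines(paths[[file]], warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0L) stop(sprintf("%s is empty", file), call. = FALSE)
    if (length(lines) > 1L) {
      stop(sprintf("%s must hold a single line of values (found %d lines)",
                   file, length(lines)), call. = FALSE)
    }
    .parse_numeric_tokens(.split_tokens(lines[1L]), file, 1L)
  }
  mz <- read_vector("Variables_m.dat")
  rt <- read_vector("Variables_t.dat")
  if (length(rt) != length(mz)) {
    stop(sprintf("dimension error: Variables_m.dat has %d values but Variables_t.dat has %d",
                 length(mz), length(rt)), call. = FALSE)
  }

  tab_lines <- readLines(paths[["Table.dat"]], warn = FALSE)
  tab_lines <- tab_lines[nzchar(trimws(tab_lines))]
  if (length(tab_lines) != length(sample_ids)) {
    stop(sprintf("dimension error: Table.dat has %d rows but Analyses.dat has %d sample names",
                 length(tab_lines), length(sample_ids)), call. = FALSE)
  }
  rows <- vector("list", length(tab_lines))
  for (i in seq_along(tab_lines)) {
    vals <- .parse_numeric_tokens(.split_tokens(tab_lines[i]), "Table.dat", i)
    if (length(vals) != length(mz)) {
      stop(sprintf("dimension error: Table.dat row %d has %d values but Variables_m.dat has %d",
                   i, length(vals), length(mz)), call. = FALSE)
    }
    rows[[i]] <- vals
  }
  feature_table(sample_ids, mz, rt, do.call(rbind, rows))
}

# shortest decimal representation that round-trips a double
.fmt_num <- function(x) {
  vapply(x, function(v) {
    for (d in 1:17) {
      s <- formatC(v, digits = d, format = "g", width = 1)
      if (as.numeric(s) == v) return(s)
    }
    formatC(v, digits = 17, format = "g", width = 1)
  }, character(1))
}

#' Write a four-file .dat bundle
#'
#' Round-trip counterpart of [read_dat_bundle()]: writes `Analyses.dat`,
#' `Variables_m.dat`, `Variables_t.dat` and `Table.dat` into `directory`
#' (created if needed). Numbers are written in their shortest round-trip
#' decimal form, so `read_dat_bundle(write_dat_bundle(t))` reproduces `t`
#' exactly.
#'
#' @param table a [feature_table()] with at least one feature.
#' @param directory output directory.
#' @return Invisibly, the paths of the four files written.
#' @export
write_dat_bundle <- function(table, directory) {
  if (length(table$mz) == 0L) {
    stop("refusing to write an empty bundle (feature table has 0 features)",
         call. = FALSE)
  }
  if (!dir.exists(directory)) {
    ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop(sprintf("cannot create directory '%s'", directory), call. = FALSE)
  }
  paths <- file.path(directory, .bundle_files)
  names(paths) <- .bundle_files
  writeLines(table$sample_ids, paths[["Analyses.dat"]])
  writeLines(paste(.fmt_num(table$mz), collapse = " "), paths[["Variables_m.dat"]])
  writeLines(paste(.fmt_num(table$rt), collapse = " "), paths[["Variables_t.dat"]])
  lines <- apply(table$intensities, 1L, function(r) paste(.fmt_num(r), collapse = " "))
  writeLines(lines, paths[["Table.dat"]])
  invisible(paths)
}

#' Import an MZmine-style aligned feature CSV
#'
#' Reads the aligned-feature CSV that peak-picking tools export: one row per
#' molecular feature with an m/z column, a retention-time column and one
#' intensity (peak area) column per sample, and transposes it into the
#' samples-by-features [feature_table()] this package works on. Missing or
#' blank intensity cells become 0.
#'
#' @param path CSV file (comma-separated, header row, UTF-8).
#' @param mz_col,rt_col names of the feature-coordinate columns. Defaults
#'   match the common MZmine export (`"row m/z"`, `"row retention time"`).
#' @param sample_suffix suffix identifying sample intensity columns; the
#'   sample id is the column name with the suffix stripped. Ignored when
#'   `sample_cols` is given.
#' @param sample_cols optional explicit character vector of intensity column
#'   names to use as samples (suffix still stripped from ids if present).
#' @return A [feature_table()].
#' @export
import_feature_csv <- function(path, mz_col = "row m/z",
                               rt_col = "row retention time",
                               sample_suffix = " Peak area",
                               sample_cols = NULL) {
  if (!file.exists(path)) stop(sprintf("CSV file '%s' does not exist", path), call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  cols <- names(df)
  for (needed in c(mz_col, rt_col)) {
    if (!needed %in% cols) {
      stop(sprintf("mapping error: column '%s' not found in CSV", needed), call. = FALSE)
    }
  }
  if (is.null(sample_cols)) {
    sample_cols <- cols[endsWith(cols, sample_suffix) & cols != mz_col & cols != rt_col]
  } else {
    absent <- setdiff(sample_cols, cols)
    if (length(absent) > 0L) {
      stop(sprintf("mapping error: sample column(s) not in CSV: %s",
                   paste(absent, collapse = ", ")), call. = FALSE)
    }
  }
  if (length(sample_cols) == 0L) {
    stop("mapping error: no sample intensity columns matched", call. = FALSE)
  }
  dup <- unique(sample_cols[duplicated(sample_cols)])
  if (length(dup) > 0L) {
    stop(sprintf("uniqueness error: duplicate sample column name(s): %s",
                 paste(dup, collapse = ", ")), call. = FALSE)
  }
  sample_ids <- sample_cols
  strip <- endsWith(sample_ids, sample_suffix)
  sample_ids[strip] <- substr(sample_ids[strip], 1L,
                              nchar(sample_ids[strip]) - nchar(sample_suffix))
  dup <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup) > 0L) {
    stop(sprintf("uniqueness error: duplicate sample id(s) after suffix strip: %s",
                 paste(dup, collapse = ", ")), call. = FALSE)
  }
  to_num <- function(v) {
    if (is.character(v)) v[!nzchar(trimws(v))] <- NA
    v <- suppressWarnings(as.numeric(v))
    v[is.na(v)] <- 0
    v
  }
  # features x samples, then transpose to samples x features
  intens <- matrix(0, nrow = nrow(df), ncol = length(sample_cols))
  for (k in seq_along(sample_cols)) intens[, k] <- to_num(df[[sample_cols[k]]])
  feature_table(sample_ids, mz = to_num(df[[mz_col]]), rt = to_num(df[[rt_col]]),
                intensities = t(intens))
}
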