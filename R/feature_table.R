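#' Construct a feature table
#'
#' The central data container: a samples-by-features matrix of LCMS spectral
#' intensities, with the mass-to-charge ratio (m/z, Thomson) and retention
#' time (minutes) of every aligned molecular feature carried as column
#' metadata. Row `s` of `intensities` holds the profile of `sample_ids[s]`;
#' column `j` is the feature with coordinates `(mz[j], rt[j])`.
#'
#' m/z and rt are metadata only: they never enter distance computation or
#' PCA, so an all-zero `mz` or `rt` vector is legal (e.g. for non-LCMS data
#' pushed through the same pipeline).
#'
#' @param sample_ids character vector of unique sample labels, length S.
#' @param mz numeric vector of per-feature m/z values, length F (finite, >= 0).
#' @param rt numeric vector of per-feature retention times, length F
#'   (finite, >= 0).
#' @param intensities numeric S x F matrix of non-negative finite intensities.
#' @return An object of class `feature_table`: a list with elements
#'   `sample_ids`, `mz`, `rt` and `intensities` (the matrix acquires
#'   `sample_ids` as rownames).
#' @seealso [read_dat_bundle()], [import_feature_csv()],
#'   [validate_feature_table()]
#' @examples
#' ft <- feature_table(c("s1", "s2"), mz = c(100, 200, 300),
#'                     rt = c(1, 2, 3),
#'                     intensities = rbind(c(1, 0, 2), c(0, 5, 0)))
#' ft
#' @export
feature_table <- function(sample_ids, mz, rt, intensities) {
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  sample_ids <- as.character(sample_ids)
  mz <- as.numeric(mz)
  rt <- as.numeric(rt)
  rownames(intensities) <- sample_ids
  colnames(intensities) <- NULL
  tbl <- structure(
    list(sample_ids = sample_ids, mz = mz, rt = rt, intensities = intensities),
    class = "feature_table"
  )
  findings <- validate_feature_table(tbl)
  if (nrow(findings) > 0L) {
    stop("invalid feature table:\n", paste0("  - ", findings$message, collapse = "\n"),
         call. = FALSE)
  }
  tbl
}

#' Validate a feature table
#'
#' Checks every container invariant and returns findings as data, not
#' exceptions: dimension agreement between `sample_ids`, `mz`, `rt` and the
#' intensity matrix; uniqueness of sample ids; finiteness and non-negativity
#' of intensities, m/z and rt.
#'
#' @param table a `feature_table` (or a bare list with the same elements).
#' @return A data.frame with columns `invariant`, `row`, `col`, `message`;
#'   zero rows for a valid table. `row`/`col` are `NA` where a finding has no
#'   single coordinate.
#' @export
validate_feature_table <- function(table) {
  findings <- list()
  add <- function(invariant, row, col, message) {
    findings[[length(findings) + 1L]] <<- data.frame(
      invariant = invariant, row = row, col = col, message = message,
      stringsAsFactors = FALSE)
  }
  x <- table$intensities
  S <- length(table$sample_ids)
  Fn <- length(table$mz)

  if (length(table$rt) != Fn) {
    add("dimensions", NA_integer_, NA_integer_,
        sprintf("mz has %d entries but rt has %d", Fn, length(table$rt)))
  }
  if (!is.matrix(x)) {
    add("dimensions", NA_integer_, NA_integer_, "intensities is not a matrix")
    out <- do.call(rbind, findings)
    return(out)
  }
  if (ncol(x) != Fn) {
    add("dimensions", NA_integer_, NA_integer_,
        sprintf("intensities has %d columns but %d m/z values", ncol(x), Fn))
  }
  if (nrow(x) != S) {
    add("dimensions", NA_integer_, NA_integer_,
        sprintf("intensities has %d rows but %d sample ids", nrow(x), S))
  }
  dup <- unique(table$sample_ids[duplicated(table$sample_ids)])
  for (id in dup) {
    add("unique_sample_ids", NA_integer_, NA_integer_,
        sprintf("sample id '%s' is repeated", id))
  }
  bad <- which(!is.finite(x) | x < 0)
  for (k in bad) {
    i <- ((k - 1L) %% nrow(x)) + 1L
    j <- ((k - 1L) %/% nrow(x)) + 1L
    add("intensities_nonnegative_finite", i, j,
        sprintf("intensity at row %d (sample '%s'), column %d is %s",
                i, if (i <= S) table$sample_ids[i] else "?", j,
                format(x[i, j])))
  }
  for (j in which(!is.finite(table$mz) | table$mz < 0)) {
    add("mz_nonnegative_finite", NA_integer_, j,
        sprintf("m/z at column %d is %s", j, format(table$mz[j])))
  }
  for (j in which(!is.finite(table$rt) | table$rt < 0)) {
    add("rt_nonnegative_finite", NA_integer_, j,
        sprintf("rt at column %d is %s", j, format(table$rt[j])))
  }
  out <- do.call(rbind, findings)
  if (is.null(out)) {
    out <- data.frame(invariant = character(), row = integer(),
                      col = integer(), message = character(),
                      stringsAsFactors = FALSE)
  }
  out
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d samples x %d features\n",
              length(x$sample_ids), length(x$mz)))
  if (length(x$mz) > 0L && any(x$mz > 0)) {
    cat(sprintf("  m/z range: %.4f - %.4f\n", min(x$mz), max(x$mz)))
  }
  if (length(x$rt) > 0L && any(x$rt > 0)) {
    cat(sprintf("  rt range:  %.2f - %.2f min\n", min(x$rt), max(x$rt)))
  }
  ids <- x$sample_ids
  shown <- paste(utils::head(ids, 5L), collapse = ", ")
  if (length(ids) > 5L) shown <- paste0(shown, ", ...")
  cat("  samples:   ", shown, "\n", sep = "")
  invisible(x)
}
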