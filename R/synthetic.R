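# Planted-structure generator. Emulates the statistics an aligned untargeted
# LCMS feature table presents to this pipeline: a few shared "core"
# metabolite features, a block of group-exclusive features per strain group
# (the chemistry that makes groups cluster together), a large sparse
# background of low-information noise features (the bulk of any real
# feature table), and optionally one outlier strain carrying its own
# exclusive chemistry. Intensity noise is multiplicative log-normal with
# dropout, matching LCMS intensity behavior; it is not additive Gaussian.

#' Parameters of the synthetic feature-table generator
#'
#' Defaults define the documented "strong separation" regime used throughout
#' the package's tests: 4 groups x 6 samples, 40 core and 15 group-exclusive
#' features, 24000 sparse noise features, group features more than an order
#' of magnitude above base intensity. Under these conditions the
#' between-group structure dominates raw Euclidean distances (so UPGMA
#' recovers the groups) while the many weak noise features spread
#' Pareto-scaled variance over all available components (so mixed nodes stay
#' under a 25% SoV12 gate and keep splitting, and pure 6-sample groups are
#' terminal by the rank bound). See the methods vignette for the variance
#' budget behind these numbers.
#'
#' @param n_groups number of planted strain groups.
#' @param samples_per_group samples in each group.
#' @param n_core_features features shared by all samples at `base_intensity`.
#' @param n_group_features group-exclusive features per group at
#'   `group_intensity`.
#' @param n_noise_features sparse background features, each present in a
#'   sample with probability `dropout_rate`, at `base_intensity`.
#' @param base_intensity typical intensity of core and noise features.
#' @param group_intensity intensity of group-exclusive features.
#' @param noise_sd sd of the multiplicative log-normal intensity noise
#'   (on the log scale; 0 = noiseless).
#' @param dropout_rate probability that a present core/group feature is
#'   zeroed in a given sample; doubles as the presence probability of the
#'   sparse noise background.
#' @param outlier `NULL`, or a list as from [outlier_spec()] planting one
#'   chemically unusual sample.
#' @param seed integer RNG seed; generation is fully deterministic given it.
#' @return A validated list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_groups = 4L, samples_per_group = 6L,
                           n_core_features = 40L, n_group_features = 15L,
                           n_noise_features = 24000L,
                           base_intensity = 1e5, group_intensity = 2e6,
                           noise_sd = 0.3, dropout_rate = 0.15,
                           outlier = NULL, seed = 17L) {
  spec <- structure(
    list(n_groups = as.integer(n_groups),
         samples_per_group = as.integer(samples_per_group),
         n_core_features = as.integer(n_core_features),
         n_group_features = as.integer(n_group_features),
         n_noise_features = as.integer(n_noise_features),
         base_intensity = as.numeric(base_intensity),
         group_intensity = as.numeric(group_intensity),
         noise_sd = as.numeric(noise_sd),
         dropout_rate = as.numeric(dropout_rate),
         outlier = outlier, seed = as.integer(seed)),
    class = "synthetic_spec")
  counts <- c(spec$n_groups, spec$samples_per_group, spec$n_core_features,
              spec$n_group_features, spec$n_noise_features)
  if (any(counts < 0L)) stop("spec error: counts must be >= 0", call. = FALSE)
  if (spec$n_groups * spec$samples_per_group < 2L) {
    stop("spec error: need at least 2 samples in total", call. = FALSE)
  }
  total_features <- spec$n_core_features +
    spec$n_groups * spec$n_group_features + spec$n_noise_features +
    if (is.null(outlier)) 0L else outlier$n_features
  if (total_features < 1L) stop("spec error: need at least 1 feature", call. = FALSE)
  if (spec$dropout_rate < 0 || spec$dropout_rate > 1) {
    stop("spec error: dropout_rate must be in [0, 1]", call. = FALSE)
  }
  if (spec$noise_sd < 0) stop("spec error: noise_sd must be >= 0", call. = FALSE)
  if (spec$base_intensity <= 0 || spec$group_intensity <= 0) {
    stop("spec error: intensities must be positive", call. = FALSE)
  }
  if (!is.null(outlier)) {
    if (is.null(outlier$group) || outlier$group < 1L || outlier$group > spec$n_groups) {
      stop("spec error: outlier group index out of range", call. = FALSE)
    }
  }
  spec
}

#' Outlier parameters for [synthetic_spec()]
#'
#' Plants one chemically unusual sample: the first sample of `group`
#' additionally expresses `n_features` exclusive features at `intensity`.
#' Defaults keep the outlier close enough to its group in raw Euclidean
#' distance to stay inside the group's terminal node, while its exclusive
#' features carry enough Pareto-scaled variance to take over that node's
#' first principal component.
#'
#' @param group 1-based index of the group receiving the outlier.
#' @param n_features number of outlier-exclusive features.
#' @param intensity their intensity.
#' @return A list suitable for the `outlier` argument of [synthetic_spec()].
#' @export
outlier_spec <- function(group = 1L, n_features = 600L, intensity = 3.2e5) {
  list(group = as.integer(group), n_features = as.integer(n_features),
       intensity = as.numeric(intensity))
}

#' Generate a synthetic feature table with known ground truth
#'
#' Deterministic given `spec$seed` (the global RNG state is saved and
#' restored). All random draws (log-normal factors, presence masks, feature
#' coordinates) are made independently of the intensity parameters, which
#' only scale them — so raising `group_intensity` at a fixed seed changes
#' nothing except the magnitude of the group blocks.
#'
#' Feature coordinates are drawn uniformly: m/z in \[150, 1500\] Th, rt in
#' \[2, 14\] min (typical evaluated ranges for microbial extract LCMS); both
#' are metadata only.
#'
#' @param spec a [synthetic_spec()].
#' @return A list with `table` (a [feature_table()]), `groups` (named
#'   character vector, sample id -> group label), `outlier_id` (sample id or
#'   `NA`), and `feature_roles` (character vector: `"core"`, `"group<k>"`,
#'   `"noise"`, `"outlier"`).
#' @export
simulate_feature_table <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(spec$seed)

  S <- spec$n_groups * spec$samples_per_group
  sample_ids <- sprintf("samp%03d", seq_len(S))
  group_of <- rep(seq_len(spec$n_groups), each = spec$samples_per_group)
  groups <- stats::setNames(sprintf("group%d", group_of), sample_ids)

  n_out <- if (is.null(spec$outlier)) 0L else spec$outlier$n_features
  Fn <- spec$n_core_features + spec$n_groups * spec$n_group_features +
    spec$n_noise_features + n_out
  mz <- stats::runif(Fn, 150, 1500)
  rt <- stats::runif(Fn, 2, 14)

  lognoise <- function(n) {
    if (spec$noise_sd == 0) rep(1, n) else exp(stats::rnorm(n, 0, spec$noise_sd))
  }
  keep_mask <- function(n) {  # TRUE where a present feature survives dropout
    if (spec$dropout_rate == 0) rep(TRUE, n) else stats::runif(n) >= spec$dropout_rate
  }

  x <- matrix(0, S, Fn)
  roles <- character(Fn)
  col <- 0L

  if (spec$n_core_features > 0L) {
    idx <- col + seq_len(spec$n_core_features)
    fac <- matrix(lognoise(S * length(idx)), S)
    msk <- matrix(keep_mask(S * length(idx)), S)
    x[, idx] <- spec$base_intensity * fac * msk
    roles[idx] <- "core"
    col <- col + length(idx)
  }
  for (g in seq_len(spec$n_groups)) {
    if (spec$n_group_features == 0L) break
    idx <- col + seq_len(spec$n_group_features)
    rows <- which(group_of == g)
    fac <- matrix(lognoise(length(rows) * length(idx)), length(rows))
    msk <- matrix(keep_mask(length(rows) * length(idx)), length(rows))
    x[rows, idx] <- spec$group_intensity * fac * msk
    roles[idx] <- sprintf("group%d", g)
    col <- col + length(idx)
  }
  if (spec$n_noise_features > 0L) {
    idx <- col + seq_len(spec$n_noise_features)
    pres <- matrix(stats::runif(S * length(idx)) < spec$dropout_rate, S)
    fac <- matrix(lognoise(S * length(idx)), S)
    x[, idx] <- spec$base_intensity * fac * pres
    roles[idx] <- "noise"
    col <- col + length(idx)
  }
  outlier_id <- NA_character_
  if (n_out > 0L) {
    idx <- col + seq_len(n_out)
    out_row <- which(group_of == spec$outlier$group)[1L]
    outlier_id <- sample_ids[out_row]
    fac <- lognoise(n_out)
    msk <- keep_mask(n_out)
    x[out_row, idx] <- spec$outlier$intensity * fac * msk
    roles[idx] <- "outlier"
    col <- col + length(idx)
  }

  list(table = feature_table(sample_ids, mz, rt, x),
       groups = groups, outlier_id = outlier_id, feature_roles = roles)
}

#' Write a synthetic fixture to disk
#'
#' Generates the table for `spec` and writes the four-file .dat bundle plus
#' two ground-truth sidecars: `ground_truth.tsv` (sample_id, group,
#' is_outlier) and `feature_roles.tsv` (feature index, role, m/z, rt). The
#' sidecars exist for evaluation only; nothing in the pipeline reads them —
#' the clustering stays agnostic of sample metadata.
#'
#' @param spec a [synthetic_spec()].
#' @param directory output directory.
#' @return Invisibly, the generated simulation list (see
#'   [simulate_feature_table()]).
#' @export
write_fixture <- function(spec, directory) {
  sim <- simulate_feature_table(spec)
  write_dat_bundle(sim$table, directory)
  gt <- data.frame(sample_id = names(sim$groups), group = unname(sim$groups),
                   is_outlier = names(sim$groups) %in% sim$outlier_id,
                   stringsAsFactors = FALSE)
  utils::write.table(gt, file.path(directory, "ground_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  fr <- data.frame(feature = seq_along(sim$feature_roles),
                   role = sim$feature_roles,
                   mz = sim$table$mz, rt = sim$table$rt,
                   stringsAsFactors = FALSE)
  utils::write.table(fr, file.path(directory, "feature_roles.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(sim)
}
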