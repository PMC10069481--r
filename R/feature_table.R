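#' Feature x sample peak-area table
#'
#' Container for an aligned untargeted GC/QTOF-MS dataset: features keyed by
#' accurate mass and retention time ("mass@RT"), one column of peak areas per
#' sample, and the sample metadata needed by the downstream filters. Missing
#' peak areas are explicit `NA`s, never zeros (zero is a legal, if unlikely,
#' peak area). The pre-imputation missingness mask travels with the table so
#' prevalence and quality decisions never depend on imputed values.
#'
#' @param features Tibble with `feature_id`, `mz` (Da, deprotonated ion) and
#'   `rt` (minutes); `feature_id` defaults to `"mz@rt"`.
#' @param samples Tibble with `sample_id`, `experiment_id`, `group` (subject
#'   id, `"unworn"` or `"solvent"`), `attractor_class` (`"high"`, `"low"` or
#'   `"none"`; controls must be `"none"`) and `replicate`.
#' @param areas Numeric matrix, features x samples; `NA` marks a missing
#'   (non-detected) value.
#' @param scale `"raw"` or `"log2"`.
#' @param mask Logical observed-value matrix; defaults to `!is.na(areas)`.
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(features, samples, areas, scale = c("raw", "log2"),
                          mask = NULL) {
  scale <- match.arg(scale)
  features <- tibble::as_tibble(features)
  samples <- tibble::as_tibble(samples)
  if (!all(c("mz", "rt") %in% names(features))) {
    abort_input("`features` needs `mz` and `rt` columns.")
  }
  if (!"feature_id" %in% names(features)) {
    features$feature_id <- make_feature_id(features$mz, features$rt)
  }
  required <- c("sample_id", "experiment_id", "group", "attractor_class")
  if (!all(required %in% names(samples))) {
    abort_input(paste0("`samples` needs columns: ", paste(required, collapse = ", ")))
  }
  areas <- as.matrix(areas)
  if (nrow(areas) != nrow(features) || ncol(areas) != nrow(samples)) {
    abort_input("`areas` dimensions must match features x samples.")
  }
  if (any(features$mz <= 0) || any(features$rt < 0)) {
    abort_input("feature masses must be positive and retention times nonnegative.")
  }
  if (scale == "raw" && any(areas < 0, na.rm = TRUE)) {
    abort_input("raw peak areas must be nonnegative.")
  }
  if (scale == "log2" && anyNA(areas)) {
    abort_input("log2 tables must be fully imputed (no missing entries).")
  }
  ctrl <- samples$group %in% c("unworn", "solvent")
  if (any(samples$attractor_class[ctrl] != "none")) {
    abort_input("control groups must have attractor_class \"none\".")
  }
  dimnames(areas) <- list(features$feature_id, samples$sample_id)
  if (is.null(mask)) mask <- !is.na(areas)
  dimnames(mask) <- dimnames(areas)
  structure(list(features = features, samples = samples, areas = areas,
                 mask = mask, scale = scale),
            class = "feature_table")
}

#' Build "mass@RT" feature labels
#'
#' @param mz Accurate masses (Da).
#' @param rt Retention times (minutes).
#' @return Character labels such as `"241.2173@10.00"`.
#' @export
make_feature_id <- function(mz, rt) sprintf("%.4f@%.2f", mz, rt)

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d features x %d samples (%s scale)\n",
              nrow(x$features), nrow(x$samples), x$scale))
  cat(sprintf("  experiments: %s\n",
              paste(unique(x$samples$experiment_id), collapse = ", ")))
  cat(sprintf("  missing entries: %d (%.1f%%)\n",
              sum(!x$mask), 100 * mean(!x$mask)))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) c(nrow(x$features), nrow(x$samples))

#' Long tidy view of a feature table
#'
#' @param x A [feature_table()].
#' @param ... Unused.
#' @return A tibble with one row per feature x sample, carrying the feature
#'   keys, sample metadata, `area` and the pre-imputation `observed` flag.
#' @method as_tibble feature_table
#' @export
as_tibble.feature_table <- function(x, ...) {
  long <- tibble::tibble(
    feature_id = rep(x$features$feature_id, times = nrow(x$samples)),
    mz = rep(x$features$mz, times = nrow(x$samples)),
    rt = rep(x$features$rt, times = nrow(x$samples)),
    sample_id = rep(x$samples$sample_id, each = nrow(x$features)),
    area = as.vector(x$areas),
    observed = as.vector(x$mask)
  )
  dplyr::left_join(long, x$samples, by = "sample_id")
}

# row/column subsetting that keeps features, samples, areas and mask in step
ft_subset <- function(ft, rows = NULL, cols = NULL) {
  if (!is.null(rows)) {
    ft$features <- ft$features[rows, , drop = FALSE]
    ft$areas <- ft$areas[rows, , drop = FALSE]
    ft$mask <- ft$mask[rows, , drop = FALSE]
  }
  if (!is.null(cols)) {
    ft$samples <- ft$samples[cols, , drop = FALSE]
    ft$areas <- ft$areas[, cols, drop = FALSE]
    ft$mask <- ft$mask[, cols, drop = FALSE]
  }
  ft
}

#' Combine per-experiment feature tables into one aligned table
#'
#' @param tables A list of [feature_table()]s sharing one feature universe
#'   (aligned by `feature_id`).
#' @return A single `feature_table` whose samples are the concatenation of
#'   the inputs' samples.
#' @export
bind_feature_tables <- function(tables) {
  stopifnot(length(tables) >= 1, all(purrr::map_lgl(tables, inherits, "feature_table")))
  if (length(tables) == 1) return(tables[[1]])
  ref <- tables[[1]]
  ids <- ref$features$feature_id
  aligned <- purrr::map(tables[-1], function(t) {
    if (!setequal(t$features$feature_id, ids)) {
      abort_input("feature tables must share one feature universe to be combined.")
    }
    ft_subset(t, rows = match(ids, t$features$feature_id))
  })
  all_tabs <- c(list(ref), aligned)
  feature_table(
    features = ref$features,
    samples = dplyr::bind_rows(purrr::map(all_tabs, "samples")),
    areas = do.call(cbind, purrr::map(all_tabs, "areas")),
    scale = ref$scale,
    mask = do.call(cbind, purrr::map(all_tabs, "mask"))
  )
}

#' Read / write a feature table as delimited text
#'
#' The areas file has columns `mz`, `rt`, then one column per sample; the
#' metadata file has one row per sample. Empty cells are missing values; with
#' `zero_as_missing = TRUE` zeros are reinterpreted as missing on read.
#'
#' @param areas_path,samples_path CSV file paths.
#' @param zero_as_missing Treat zeros in the areas file as missing.
#' @return A [feature_table()].
#' @export
read_feature_table <- function(areas_path, samples_path, zero_as_missing = FALSE) {
  wide <- readr::read_csv(areas_path, show_col_types = FALSE)
  samples <- readr::read_csv(samples_path, show_col_types = FALSE)
  if (!all(c("mz", "rt") %in% names(wide))) {
    abort_input("areas file must start with `mz` and `rt` columns.")
  }
  sample_cols <- setdiff(names(wide), c("feature_id", "mz", "rt"))
  if (!setequal(sample_cols, samples$sample_id)) {
    abort_input("sample columns of the areas file must match the metadata `sample_id`s.")
  }
  areas <- as.matrix(wide[samples$sample_id])
  if (zero_as_missing) areas[areas == 0] <- NA_real_
  feature_table(features = wide[intersect(names(wide), c("feature_id", "mz", "rt"))],
                samples = samples, areas = areas)
}

#' @rdname read_feature_table
#' @param ft A [feature_table()] to write.
#' @export
write_feature_table <- function(ft, areas_path, samples_path) {
  wide <- dplyr::bind_cols(ft$features, tibble::as_tibble(ft$areas))
  readr::write_csv(wide, areas_path, na = "")
  readr::write_csv(ft$samples, samples_path, na = "")
  invisible(c(areas_path, samples_path))
}
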