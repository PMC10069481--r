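#' Thresholds for the feature-consensus workflow
#'
#' Defaults follow the published workflow: fuzzy duplicates merged within
#' +/-100 ppm and +/-0.05 min (the targeted re-extraction windows), features
#' detected in fewer than 10 data files removed, features present in <10% of
#' samples removed, quality features found in at least 50% of samples of at
#' least one subject group with a coefficient of variation <40% in at least
#' one group, human-derived features at least 2-fold enriched on worn nylons
#' versus controls at FDR < 0.05, per-experiment differential features at
#' least 2-fold different between high and low attractors at FDR < 0.05, and
#' targeted re-analysis significance at FDR <= 0.10.
#'
#' Strictness mirrors the printed rules: "<10 files", "<10%", "<40%" and
#' "FDR<0.05" are strict; "at least 50%" and "at least 2-fold" are
#' non-strict; the targeted FDR is `q <= 0.10`.
#'
#' @param dedup_mass_tol_ppm,dedup_rt_tol_min Fuzzy-duplicate merge windows.
#' @param min_files Minimum number of samples a feature must be detected in.
#' @param min_sample_fraction Minimum observed fraction of all samples.
#' @param quality_group_fraction,quality_cv_max Quality-filter thresholds.
#' @param enrich_fold_min,enrich_fdr Human-derived filter thresholds.
#' @param diff_fold_min,diff_fdr Per-experiment volcano thresholds.
#' @param targeted_fdr FDR level of the targeted re-analysis.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(dedup_mass_tol_ppm = 100,
                            dedup_rt_tol_min = 0.05,
                            min_files = 10L,
                            min_sample_fraction = 0.10,
                            quality_group_fraction = 0.50,
                            quality_cv_max = 0.40,
                            enrich_fold_min = 2,
                            enrich_fdr = 0.05,
                            diff_fold_min = 2,
                            diff_fdr = 0.05,
                            targeted_fdr = 0.10) {
  stopifnot(dedup_mass_tol_ppm > 0, dedup_rt_tol_min > 0,
            min_sample_fraction > 0, min_sample_fraction <= 1,
            quality_group_fraction > 0, quality_group_fraction <= 1,
            quality_cv_max > 0,
            enrich_fold_min >= 1, diff_fold_min >= 1,
            enrich_fdr > 0, enrich_fdr < 1,
            diff_fdr > 0, diff_fdr < 1,
            targeted_fdr > 0, targeted_fdr < 1)
  structure(
    list(dedup_mass_tol_ppm = dedup_mass_tol_ppm,
         dedup_rt_tol_min = dedup_rt_tol_min,
         min_files = check_count(min_files, "min_files"),
         min_sample_fraction = min_sample_fraction,
         quality_group_fraction = quality_group_fraction,
         quality_cv_max = quality_cv_max,
         enrich_fold_min = enrich_fold_min,
         enrich_fdr = enrich_fdr,
         diff_fold_min = diff_fold_min,
         diff_fdr = diff_fdr,
         targeted_fdr = targeted_fdr),
    class = "pipeline_config"
  )
}

# greedy duplicate clustering: representatives taken in order of decreasing
# detection count (ties: total area, then feature_id for determinism); each
# representative absorbs every unassigned feature within both tolerances
dedup_assignments <- function(mz, rt, n_detected, total_area, ids,
                              mass_tol_ppm, rt_tol_min) {
  n <- length(mz)
  order_idx <- order(-n_detected, -total_area, ids)
  rep_of <- integer(n)
  for (i in order_idx) {
    if (rep_of[i] != 0L) next
    ppm <- abs(mz - mz[i]) / mz[i] * 1e6
    hit <- rep_of == 0L & ppm <= mass_tol_ppm & abs(rt - rt[i]) <= rt_tol_min
    rep_of[hit] <- i
  }
  rep_of
}

#' Merge fuzzy duplicate features and drop rarely detected ones
#'
#' Features whose accurate masses differ by at most `dedup_mass_tol_ppm`
#' *and* whose retention times differ by at most `dedup_rt_tol_min` are
#' merged into one representative: the member detected in the most samples
#' (ties broken by total area). A duplicate is a split detection of one
#' compound, not extra signal, so the merged row takes, per sample, the
#' maximum of the members' areas. Features detected in fewer than
#' `min_files` samples are then removed.
#'
#' @param ft A raw-scale [feature_table()].
#' @param config A [pipeline_config()].
#' @return A list with `table` (the deduplicated `feature_table`) and
#'   `merge_log` (tibble: every absorbed feature and its representative) and
#'   `n_removed_rare` (features dropped by the `min_files` rule).
#' @export
dedup_features <- function(ft, config = pipeline_config()) {
  stopifnot(inherits(ft, "feature_table"))
  if (ft$scale != "raw") abort_input("dedup_features() requires a raw-scale table.")
  n_detected <- rowSums(ft$mask)
  total_area <- rowSums(ft$areas, na.rm = TRUE)
  rep_of <- dedup_assignments(ft$features$mz, ft$features$rt,
                              n_detected, total_area, ft$features$feature_id,
                              config$dedup_mass_tol_ppm, config$dedup_rt_tol_min)

  merged <- which(rep_of != seq_along(rep_of))
  merge_log <- tibble::tibble(
    feature_id = ft$features$feature_id[merged],
    merged_into = ft$features$feature_id[rep_of[merged]]
  )
  areas <- ft$areas
  for (i in merged) {
    r <- rep_of[i]
    areas[r, ] <- pmax(areas[r, ], areas[i, ], na.rm = TRUE)
  }
  areas[is.nan(areas)] <- NA_real_   # pmax(NA, NA, na.rm = TRUE) degenerates
  keep <- rep_of == seq_along(rep_of)
  out <- ft
  out$areas <- areas
  out$mask <- !is.na(areas)
  out <- ft_subset(out, rows = which(keep))

  rare <- rowSums(out$mask) < config$min_files
  n_rare <- sum(rare)
  out <- ft_subset(out, rows = which(!rare))
  list(table = out, merge_log = merge_log, n_removed_rare = n_rare)
}

#' Remove features observed in too small a fraction of samples
#'
#' Features observed (pre-imputation) in fewer than
#' `min_sample_fraction` of all samples are removed; a feature at exactly the
#' boundary is retained.
#'
#' @inheritParams dedup_features
#' @return The filtered `feature_table`.
#' @export
prevalence_filter <- function(ft, config = pipeline_config()) {
  stopifnot(inherits(ft, "feature_table"))
  if (ft$scale != "raw") abort_input("prevalence_filter() requires a raw-scale table.")
  frac <- rowMeans(ft$mask)
  ft_subset(ft, rows = which(frac >= config$min_sample_fraction))
}

#' Half-minimum imputation of missing peak areas
#'
#' Each missing entry is replaced by half the smallest observed area of that
#' feature (across all samples); observed entries are untouched and the
#' missingness mask is preserved for downstream prevalence decisions.
#'
#' @param ft A raw-scale [feature_table()] in which every feature has at
#'   least one observed value.
#' @return The imputed `feature_table`.
#' @export
impute_half_minimum <- function(ft) {
  stopifnot(inherits(ft, "feature_table"))
  if (ft$scale != "raw") abort_input("impute on the raw scale, before log2.")
  n_obs <- rowSums(ft$mask)
  if (any(n_obs == 0)) {
    abort_input("feature(s) with no observed value; remove them with the prevalence filters first.")
  }
  mins <- apply(ft$areas, 1L, min, na.rm = TRUE)
  fill <- matrix(mins / 2, nrow(ft$areas), ncol(ft$areas))
  ft$areas[!ft$mask] <- fill[!ft$mask]
  ft
}

#' log2-transform a fully imputed feature table
#'
#' @param ft A raw-scale, fully imputed [feature_table()] with strictly
#'   positive areas.
#' @return The table on the log2 scale (`scale = "log2"`).
#' @export
log2_transform <- function(ft) {
  stopifnot(inherits(ft, "feature_table"))
  if (ft$scale != "raw") abort_input("table is already transformed.")
  if (anyNA(ft$areas)) abort_input("impute missing values before log2 transformation.")
  if (any(ft$areas <= 0)) abort_input("log2 transform requires strictly positive areas.")
  ft$areas <- log2(ft$areas)
  ft$scale <- "log2"
  ft
}

# per-group observed fraction and raw-area CV for each feature;
# groups with < 2 observed values contribute no CV
group_stats <- function(ft_raw) {
  groups <- split(seq_len(nrow(ft_raw$samples)), ft_raw$samples$group)
  frac <- sapply(groups, function(cols) rowMeans(ft_raw$mask[, cols, drop = FALSE]))
  cv <- sapply(groups, function(cols) {
    a <- ft_raw$areas[, cols, drop = FALSE]
    a[!ft_raw$mask[, cols, drop = FALSE]] <- NA    # CV uses observed raw areas only
    n <- rowSums(!is.na(a))
    m <- rowMeans(a, na.rm = TRUE)
    v <- apply(a, 1L, stats::var, na.rm = TRUE)
    out <- sqrt(v) / m
    out[n < 2] <- NA
    out
  })
  list(frac = matrix(frac, nrow = nrow(ft_raw$features)),
       cv = matrix(cv, nrow = nrow(ft_raw$features)))
}

#' Quality filter on per-group prevalence and coefficient of variation
#'
#' Keeps a feature iff it is observed in at least `quality_group_fraction` of
#' the samples of at least one subject group *and* has a raw-area coefficient
#' of variation below `quality_cv_max` in at least one subject group. Both
#' clauses use the pre-imputation missingness mask and raw areas carried by
#' the table, never imputed values.
#'
#' @param ft A [feature_table()] (raw or log2 scale; decisions are made on
#'   the raw areas supplied via `raw`, which defaults to `ft` when it is
#'   still raw).
#' @param config A [pipeline_config()].
#' @param raw The raw-scale table aligned with `ft`, required when `ft` is
#'   already log2-transformed.
#' @return The filtered table (same scale as `ft`).
#' @export
quality_filter <- function(ft, config = pipeline_config(), raw = NULL) {
  stopifnot(inherits(ft, "feature_table"))
  raw <- raw %||% ft
  if (raw$scale != "raw") abort_input("`raw` must be a raw-scale table.")
  if (!identical(raw$features$feature_id, ft$features$feature_id)) {
    abort_input("`raw` must be aligned feature-for-feature with `ft`.")
  }
  gs <- group_stats(raw)
  keep <- apply(gs$frac >= config$quality_group_fraction, 1L, any) &
    apply(gs$cv < config$quality_cv_max, 1L, function(z) any(z, na.rm = TRUE))
  ft_subset(ft, rows = which(keep))
}

# vectorised Welch two-sample t-test across the rows of a log2 matrix;
# returns mean difference (a - b), t, df and two-sided p per row
welch_rows <- function(mat, idx_a, idx_b) {
  a <- mat[, idx_a, drop = FALSE]
  b <- mat[, idx_b, drop = FALSE]
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- rowSums((a - ma)^2) / (na - 1)
  vb <- rowSums((b - mb)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  t <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  zero <- se2 == 0
  t[zero] <- 0
  df[zero] <- na + nb - 2
  p <- 2 * stats::pt(-abs(t), df)
  p[zero] <- 1
  tibble::tibble(diff = unname(ma - mb), t = unname(t),
                 df = unname(df), p = unname(p))
}

#' Flag human-derived features
#'
#' For every subject group, the worn-nylon samples are compared with the
#' pooled controls (unworn nylons plus solvent blanks) by a Welch test on
#' log2 areas per feature, with Benjamini-Hochberg correction across
#' features. A feature is human-derived if, for *any* subject, it is at least
#' `enrich_fold_min`-fold enriched with `q < enrich_fdr`.
#'
#' @param ft A log2-scale [feature_table()] containing control samples.
#' @param config A [pipeline_config()].
#' @return A list with `per_subject` (tibble: one row per feature x subject
#'   with `log2_fc`, `p`, `q`, `passes`) and `human_derived` (character
#'   vector of flagged feature ids).
#' @export
human_derived_filter <- function(ft, config = pipeline_config()) {
  stopifnot(inherits(ft, "feature_table"))
  if (ft$scale != "log2") abort_input("human_derived_filter() expects a log2 table.")
  ctrl <- which(ft$samples$group %in% c("unworn", "solvent"))
  if (length(ctrl) == 0) abort_input("no control samples (unworn/solvent) present.")
  subjects <- setdiff(unique(ft$samples$group), c("unworn", "solvent"))
  per_subject <- purrr::map(subjects, function(s) {
    idx <- which(ft$samples$group == s)
    res <- welch_rows(ft$areas, idx, ctrl)
    q <- benjamini_hochberg(res$p, config$enrich_fdr)$q
    tibble::tibble(
      feature_id = ft$features$feature_id,
      subject = s,
      log2_fc = res$diff,
      p = res$p,
      q = q,
      passes = res$diff >= log2(config$enrich_fold_min) & q < config$enrich_fdr
    )
  }) |>
    dplyr::bind_rows()
  flagged <- per_subject |>
    dplyr::group_by(.data$feature_id) |>
    dplyr::summarise(human_derived = any(.data$passes), .groups = "drop")
  list(per_subject = per_subject,
       human_derived = flagged$feature_id[flagged$human_derived])
}

#' Per-experiment differential abundance, high versus low attractors
#'
#' Welch two-sample test on log2 areas of high- versus low-attractor samples
#' of one experiment, per feature; `log2_fold_change` is mean(high) -
#' mean(low); Benjamini-Hochberg correction across features. A feature passes
#' when `|log2_fold_change| >= log2(diff_fold_min)` and `q < diff_fdr`.
#'
#' @param ft A log2-scale [feature_table()].
#' @param experiment_id The experiment to test (must have samples of both
#'   attractor classes).
#' @param config A [pipeline_config()].
#' @return A tibble of differential records: `feature_id`, `experiment_id`,
#'   `log2_fold_change`, `p`, `q`, `passes`.
#' @export
differential_high_vs_low <- function(ft, experiment_id, config = pipeline_config()) {
  stopifnot(inherits(ft, "feature_table"))
  if (ft$scale != "log2") abort_input("differential testing expects a log2 table.")
  in_exp <- ft$samples$experiment_id == experiment_id
  hi <- which(in_exp & ft$samples$attractor_class == "high")
  lo <- which(in_exp & ft$samples$attractor_class == "low")
  if (length(hi) == 0 || length(lo) == 0) {
    abort_input(sprintf("experiment %s lacks high- or low-attractor samples.", experiment_id))
  }
  res <- welch_rows(ft$areas, hi, lo)
  q <- benjamini_hochberg(res$p, config$diff_fdr)$q
  tibble::tibble(
    feature_id = ft$features$feature_id,
    experiment_id = experiment_id,
    log2_fold_change = res$diff,
    p = res$p,
    q = q,
    passes = abs(res$diff) >= log2(config$diff_fold_min) & q < config$diff_fdr
  )
}

#' Consensus hits across replicate experiments
#'
#' A feature is a consensus hit when it passes the differential criteria in
#' *every* experiment with a consistent sign of the fold change. A post-hoc
#' redundancy sweep with the dedup tolerances collapses residual duplicate
#' hits (keeping, per cluster, the hit with the smallest combined q), the
#' in-code analogue of the published manual inspection step.
#'
#' @param records A tibble of differential records from
#'   [differential_high_vs_low()], covering at least 2 experiments.
#' @param features Feature key tibble (`feature_id`, `mz`, `rt`) used for the
#'   redundancy sweep; optional - without it the sweep is skipped.
#' @param config A [pipeline_config()].
#' @return A tibble of consensus hits: `feature_id`, `direction`,
#'   `n_experiments`, `mean_log2_fc`, `max_q`.
#' @export
consensus_hits <- function(records, features = NULL, config = pipeline_config()) {
  exps <- unique(records$experiment_id)
  if (length(exps) < 2) abort_input("consensus calling needs at least 2 experiments.")
  universe <- table(records$feature_id)
  if (any(universe < length(exps))) {
    rlang::warn("feature universes differ across experiments; aligning on feature_id.")
  }
  hits <- records |>
    dplyr::group_by(.data$feature_id) |>
    dplyr::summarise(
      n_experiments = dplyr::n_distinct(.data$experiment_id),
      all_pass = all(.data$passes),
      same_sign = dplyr::n_distinct(sign(.data$log2_fold_change)) == 1,
      mean_log2_fc = mean(.data$log2_fold_change),
      max_q = max(.data$q),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_experiments == length(exps), .data$all_pass, .data$same_sign) |>
    dplyr::mutate(direction = ifelse(.data$mean_log2_fc > 0, "high_enriched", "low_enriched")) |>
    dplyr::select("feature_id", "direction", "n_experiments", "mean_log2_fc", "max_q")

  if (!is.null(features) && nrow(hits) > 1) {
    key <- dplyr::left_join(hits, features, by = "feature_id")
    rep_of <- dedup_assignments(key$mz, key$rt,
                                n_detected = -key$max_q,   # best-supported = smallest q
                                total_area = key$mean_log2_fc,
                                ids = key$feature_id,
                                config$dedup_mass_tol_ppm, config$dedup_rt_tol_min)
    hits <- hits[rep_of == seq_along(rep_of), , drop = FALSE]
  }
  hits
}

#' Benjamini-Hochberg step-up false discovery rate control
#'
#' @param p Vector of p-values in \[0, 1\].
#' @param alpha FDR level used for the rejection decision (default 0.05).
#' @return A list with `q` (monotone step-up q-values, input order) and
#'   `rejected` (`q <= alpha`).
#' @export
benjamini_hochberg <- function(p, alpha = 0.05) {
  if (length(p) == 0) return(list(q = numeric(0), rejected = logical(0)))
  if (anyNA(p) || any(p < 0 | p > 1)) abort_input("p-values must lie in [0, 1].")
  m <- length(p)
  ord <- order(p)
  ranked <- p[ord] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(ranked)))       # enforce step-up monotonicity
  q <- numeric(m)
  q[ord] <- pmin(1, q_sorted)
  list(q = q, rejected = q <= alpha)
}
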