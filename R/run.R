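new_manifest_row <- function(stage, n_in, n_out, note = "") {
  tibble::tibble(stage = stage, records_in = n_in, records_out = n_out,
                 removed = n_in - n_out, note = note)
}

#' End-to-end behavioral analysis
#'
#' Runs the complete behavioral workflow on a trial table: pairwise
#' preference tests for every stimulus pair present (Bonferroni family =
#' number of pairs unless overridden), pair totals, and round-robin
#' attraction scores. A run manifest records how many trials every stage
#' consumed and dropped.
#'
#' @param trials A trial tibble, or the path to a trial CSV.
#' @param criteria An [inclusion_criteria()] object.
#' @param family_size Bonferroni family size; defaults to the number of
#'   stimulus pairs in the input.
#' @param denominator Passed to [percent_attracted()].
#' @return A list of class `behavior_run`: `preferences` (tidy tibble, one
#'   row per pair, ordered by descending absolute effect size), `tournament`
#'   (a `tournament_result`), and `manifest`.
#' @export
run_behavior <- function(trials, criteria = inclusion_criteria(),
                         family_size = NULL,
                         denominator = c("live_end", "loaded")) {
  denominator <- match.arg(denominator)
  if (is.character(trials)) trials <- readr::read_csv(trials, show_col_types = FALSE)
  validate_trials(trials)
  if (nrow(trials) == 0) abort_input("the trial table is empty.")

  lab_a <- stimulus_label(trials$kind_a, trials$subject_a)
  lab_b <- stimulus_label(trials$kind_b, trials$subject_b)
  pair_key <- purrr::map2_chr(lab_a, lab_b, ~ paste(sort(c(.x, .y)), collapse = " vs "))
  pairs <- split(seq_len(nrow(trials)), pair_key)
  m <- family_size %||% length(pairs)

  preferences <- purrr::map(pairs, function(idx) {
    tidy(compare_pair(trials[idx, , drop = FALSE], criteria,
                      family_size = m, denominator = denominator))
  }) |>
    dplyr::bind_rows() |>
    dplyr::arrange(dplyr::desc(abs(.data$effect_size)))

  totals <- build_pair_totals(trials)
  tournament <- if (nrow(totals) > 0) attraction_scores(totals) else NULL

  n_inc <- sum(preferences$n_trials_included)
  manifest <- list(
    stages = dplyr::bind_rows(
      new_manifest_row("input", nrow(trials), nrow(trials)),
      new_manifest_row("inclusion_criteria", nrow(trials), n_inc,
                       "live-count and attracted-total rules")
    ),
    n_pairs = length(pairs),
    family_size = m,
    criteria = unclass(criteria),
    denominator = denominator,
    package_version = as.character(utils::packageVersion("hostpref"))
  )
  structure(list(preferences = preferences, tournament = tournament,
                 manifest = manifest),
            class = "behavior_run")
}

#' End-to-end metabolomics consensus analysis
#'
#' Runs the full feature-consensus workflow on aligned per-experiment feature
#' tables: fuzzy deduplication and rare-feature removal, prevalence filter,
#' half-minimum imputation, log2 transform, group-level quality filter,
#' human-derived enrichment filter against the pooled controls,
#' per-experiment high-versus-low differential testing, cross-experiment
#' consensus calling, and CHNO formula annotation of the hits. The manifest
#' reconciles feature counts across every stage.
#'
#' @param tables A list of per-experiment [feature_table()]s (or one combined
#'   table).
#' @param config A [pipeline_config()].
#' @param ppm_window Formula-annotation window in ppm.
#' @return A list of class `metabolomics_run`: `hits` (annotated consensus
#'   tibble), `differential` (per-experiment records for the human-derived
#'   features), `human_derived` (feature ids), `table` (final log2
#'   `feature_table`), `merge_log`, and `manifest`.
#' @export
run_metabolomics <- function(tables, config = pipeline_config(), ppm_window = 100) {
  if (inherits(tables, "feature_table")) tables <- list(tables)
  ft <- bind_feature_tables(tables)
  n0 <- nrow(ft$features)

  dd <- dedup_features(ft, config)
  n_dedup <- nrow(dd$table$features)
  ft2 <- prevalence_filter(dd$table, config)
  n_prev <- nrow(ft2$features)
  lg <- log2_transform(impute_half_minimum(ft2))
  lg <- quality_filter(lg, config, raw = ft2)
  n_qual <- nrow(lg$features)

  hd <- human_derived_filter(lg, config)
  lg_h <- ft_subset(lg, rows = match(hd$human_derived, lg$features$feature_id))
  n_human <- length(hd$human_derived)

  records <- purrr::map(unique(lg_h$samples$experiment_id),
                        ~ differential_high_vs_low(lg_h, .x, config)) |>
    dplyr::bind_rows()
  hits <- consensus_hits(records, features = lg_h$features, config = config)
  hits <- annotate_hits(dplyr::left_join(hits, lg_h$features, by = "feature_id"),
                        ppm_window = ppm_window)

  stages <- dplyr::bind_rows(
    new_manifest_row("input", n0, n0),
    new_manifest_row("dedup_merge", n0, n0 - nrow(dd$merge_log), "fuzzy duplicates merged"),
    new_manifest_row("min_files", n0 - nrow(dd$merge_log), n_dedup,
                     sprintf("detected in < %d samples", config$min_files)),
    new_manifest_row("prevalence", n_dedup, n_prev,
                     sprintf("observed in < %.0f%% of samples", 100 * config$min_sample_fraction)),
    new_manifest_row("quality", n_prev, n_qual, "group prevalence / CV rules"),
    new_manifest_row("human_derived", n_qual, n_human, "enrichment vs pooled controls"),
    new_manifest_row("consensus", n_human, nrow(hits),
                     "differential in every experiment, consistent direction")
  )
  manifest <- list(
    stages = stages,
    n_samples = nrow(ft$samples),
    n_experiments = length(unique(ft$samples$experiment_id)),
    config = unclass(config),
    package_version = as.character(utils::packageVersion("hostpref"))
  )
  structure(list(hits = hits, differential = records,
                 human_derived = hd$human_derived, table = lg,
                 merge_log = dd$merge_log, manifest = manifest),
            class = "metabolomics_run")
}

#' @export
print.behavior_run <- function(x, ...) {
  cat("Behavioral run:", x$manifest$n_pairs, "stimulus pair(s)\n")
  print(x$preferences)
  if (!is.null(x$tournament)) print(x$tournament)
  invisible(x)
}

#' @export
print.metabolomics_run <- function(x, ...) {
  cat("Metabolomics consensus run\n")
  print(x$manifest$stages)
  cat(sprintf("consensus hits: %d\n", nrow(x$hits)))
  invisible(x)
}
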