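#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a pairwise preference test
#'
#' @param x A `preference_test` from [compare_pair()].
#' @param ... Unused.
#' @return A one-row tibble with the pair labels, trial counts, median percent
#'   attracted per stimulus, and the test statistics.
#' @method tidy preference_test
#' @export
tidy.preference_test <- function(x, ...) {
  tibble::tibble(
    stimulus_a = x$stimulus_a,
    stimulus_b = x$stimulus_b,
    n_trials_included = x$n_trials_included,
    n_trials_excluded = x$n_trials_excluded,
    median_pct_a = if (x$n_trials_included) stats::median(x$pct_a) else NA_real_,
    median_pct_b = if (x$n_trials_included) stats::median(x$pct_b) else NA_real_,
    Z = x$Z,
    p = x$p,
    p_adj = x$p_adj,
    effect_size = x$effect_size,
    N = x$N
  )
}

#' @rdname tidy.preference_test
#' @method glance preference_test
#' @export
glance.preference_test <- function(x, ...) {
  tibble::tibble(
    n_trials_included = x$n_trials_included,
    n_trials_excluded = x$n_trials_excluded,
    family_size = x$family_size,
    denominator = x$denominator,
    p = x$p,
    p_adj = x$p_adj,
    effect_size = x$effect_size
  )
}

#' Tidy a tournament result
#'
#' @param x A `tournament_result` from [attraction_scores()].
#' @param ... Unused.
#' @return The ranked per-subject score tibble (`tidy`) or a one-row summary
#'   (`glance`).
#' @method tidy tournament_result
#' @export
tidy.tournament_result <- function(x, ...) x$scores

#' @rdname tidy.tournament_result
#' @method glance tournament_result
#' @export
glance.tournament_result <- function(x, ...) {
  tibble::tibble(
    n_subjects = x$n_subjects,
    n_pairs = nrow(x$margins),
    n_pairs_expected = expected_pair_count(max(2L, x$n_subjects)),
    top_subject = x$scores$subject[1],
    top_score = x$scores$score[1]
  )
}
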