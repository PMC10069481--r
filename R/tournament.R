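#' Number of pairwise competitions in a full round-robin
#'
#' @param n_subjects Number of subjects (at least 2).
#' @return `n (n - 1) / 2`.
#' @export
expected_pair_count <- function(n_subjects) {
  n <- check_count(n_subjects, "n_subjects", min = 2L)
  n * (n - 1L) / 2L
}

#' Sum attracted counts per unordered subject pair
#'
#' Bridges a two-choice trial table to the tournament scoring: for every
#' unordered pair of subjects it sums the mosquitoes attracted to each subject
#' across all that pair's trials. Trials whose stimuli are not both
#' subject-worn nylons (or live forearms) are skipped with a warning; the
#' round-robin worked example in the assay uses every trial of a pair, so no
#' inclusion filtering is applied unless `criteria` is supplied.
#'
#' @param trials A two-choice trial tibble.
#' @param criteria Optional [inclusion_criteria()]; when supplied, trials are
#'   filtered with [include_trials()] first.
#' @return A tibble with columns `subject_x`, `subject_y` (sorted within
#'   pair), `total_attracted_x`, `total_attracted_y`, `n_trials`.
#' @export
build_pair_totals <- function(trials, criteria = NULL) {
  validate_trials(trials)
  if (nrow(trials) == 0) {
    return(tibble::tibble(subject_x = character(), subject_y = character(),
                          total_attracted_x = integer(),
                          total_attracted_y = integer(),
                          n_trials = integer()))
  }
  subject_sided <- trials$assay == "two_choice" &
    trials$kind_a %in% c("subject_nylon", "live_forearm") &
    trials$kind_b %in% c("subject_nylon", "live_forearm")
  if (any(!subject_sided)) {
    rlang::warn(sprintf(
      "skipping %d trial(s) without subject stimuli on both sides.",
      sum(!subject_sided)))
    trials <- trials[subject_sided, , drop = FALSE]
  }
  if (!is.null(criteria)) {
    trials <- dplyr::filter(include_trials(trials, criteria), .data$included)
  }
  if (nrow(trials) == 0) return(build_pair_totals(trials[0, ]))

  swap <- trials$subject_a > trials$subject_b
  trials |>
    dplyr::mutate(
      subject_x = ifelse(swap, .data$subject_b, .data$subject_a),
      subject_y = ifelse(swap, .data$subject_a, .data$subject_b),
      att_x = ifelse(swap, .data$n_attracted_b, .data$n_attracted_a),
      att_y = ifelse(swap, .data$n_attracted_a, .data$n_attracted_b)
    ) |>
    dplyr::group_by(.data$subject_x, .data$subject_y) |>
    dplyr::summarise(
      total_attracted_x = sum(.data$att_x),
      total_attracted_y = sum(.data$att_y),
      n_trials = dplyr::n(),
      .groups = "drop"
    )
}

#' Average margin of victory per trial for each subject pair
#'
#' For each pair, the winner is the subject with the larger total attracted
#' count; the margin is the count difference divided by the number of trials,
#' rounded to the nearest integer (half away from zero). The loser receives
#' 0; ties award 0 to both. With `round = FALSE` the unrounded per-trial
#' margin is returned instead.
#'
#' @param pair_totals A tibble as produced by [build_pair_totals()].
#' @param round Round each margin to the nearest integer (default `TRUE`).
#' @return The input with `winner` (`NA` for ties), `loser` and `margin`
#'   columns.
#' @export
margin_of_victory <- function(pair_totals, round = TRUE) {
  stopifnot(all(c("subject_x", "subject_y", "total_attracted_x",
                  "total_attracted_y", "n_trials") %in% names(pair_totals)))
  if (any(pair_totals$n_trials < 1)) abort_input("every pair needs `n_trials` >= 1.")
  if (any(pair_totals$total_attracted_x < 0 | pair_totals$total_attracted_y < 0)) {
    abort_input("attracted totals must be nonnegative.")
  }
  raw <- abs(pair_totals$total_attracted_x - pair_totals$total_attracted_y) /
    pair_totals$n_trials
  margin <- if (round) round_half_away(raw) else raw
  tie <- pair_totals$total_attracted_x == pair_totals$total_attracted_y
  dplyr::mutate(
    pair_totals,
    winner = dplyr::case_when(
      tie ~ NA_character_,
      .data$total_attracted_x > .data$total_attracted_y ~ .data$subject_x,
      TRUE ~ .data$subject_y
    ),
    loser = dplyr::case_when(
      tie ~ NA_character_,
      .data$total_attracted_x > .data$total_attracted_y ~ .data$subject_y,
      TRUE ~ .data$subject_x
    ),
    margin = ifelse(tie, 0, margin)
  )
}

#' Round-robin attraction scores
#'
#' Aggregates the pairwise margins of victory into a per-subject attraction
#' score: each subject's score is the sum of the margins it was awarded
#' across all its pairs (losers and tied subjects receive 0 from a pair). A
#' subject that attracted fewer mosquitoes than every opponent therefore
#' scores 0. Subjects are ranked by score, ties broken by total mosquitoes
#' attracted and then by label.
#'
#' @param pair_totals A tibble as produced by [build_pair_totals()]; every
#'   unordered pair may appear at most once. An incomplete round-robin
#'   triggers a warning, not an error.
#' @param round Round margins before summation (default `TRUE`, matching the
#'   integer margins of the worked example); `FALSE` sums unrounded margins.
#' @return An object of class `tournament_result` with elements `margins`
#'   (tibble), `scores` (tibble, ranked) and `n_subjects`.
#' @export
attraction_scores <- function(pair_totals, round = TRUE) {
  key <- paste(pmin(pair_totals$subject_x, pair_totals$subject_y),
               pmax(pair_totals$subject_x, pair_totals$subject_y), sep = "\r")
  if (anyDuplicated(key)) abort_input("duplicate subject pair in `pair_totals`.")
  margins <- margin_of_victory(pair_totals, round = round)

  subjects <- sort(unique(c(pair_totals$subject_x, pair_totals$subject_y)))
  n_expected <- expected_pair_count(max(2L, length(subjects)))
  if (length(subjects) >= 2 && nrow(pair_totals) < n_expected) {
    rlang::warn(sprintf(
      "incomplete round-robin: %d of %d pairs present; scores cover available pairs.",
      nrow(pair_totals), n_expected))
  }

  awarded <- margins |>
    dplyr::filter(!is.na(.data$winner)) |>
    dplyr::group_by(subject = .data$winner) |>
    dplyr::summarise(score = sum(.data$margin), .groups = "drop")
  totals <- dplyr::bind_rows(
    dplyr::select(margins, subject = "subject_x", attracted = "total_attracted_x"),
    dplyr::select(margins, subject = "subject_y", attracted = "total_attracted_y")
  ) |>
    dplyr::group_by(.data$subject) |>
    dplyr::summarise(total_attracted = sum(.data$attracted), .groups = "drop")

  scores <- tibble::tibble(subject = subjects) |>
    dplyr::left_join(awarded, by = "subject") |>
    dplyr::left_join(totals, by = "subject") |>
    dplyr::mutate(score = ifelse(is.na(.data$score), 0, .data$score)) |>
    dplyr::arrange(dplyr::desc(.data$score), dplyr::desc(.data$total_attracted),
                   .data$subject) |>
    dplyr::mutate(rank = dplyr::row_number())

  structure(list(margins = margins, scores = scores,
                 n_subjects = length(subjects)),
            class = "tournament_result")
}

#' @export
print.tournament_result <- function(x, ...) {
  cat(sprintf("Round-robin tournament: %d subjects, %d pairs\n",
              x$n_subjects, nrow(x$margins)))
  print(x$scores)
  invisible(x)
}
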