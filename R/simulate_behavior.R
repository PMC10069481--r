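#' Configuration for the two-choice trial simulator
#'
#' Describes a round-robin behavioral study: each subject carries a latent
#' attractiveness weight, and in a trial between subjects A and B each loaded
#' mosquito independently (i) dies with `mortality_rate`, (ii) otherwise
#' activates (leaves the start canister) with `p_activate`, (iii) if
#' activated, is attracted to either trap with `p_attract_given_activate`,
#' and (iv) if attracted, chooses A with probability `w_A / (w_A + w_B)`.
#'
#' @param subjects Named numeric vector of nonnegative attractiveness weights
#'   (names are subject ids), or a data frame with `subject_id` and `weight`
#'   columns.
#' @param p_activate Probability a live mosquito activates.
#' @param p_attract_given_activate Probability an activated mosquito reaches
#'   either trap.
#' @param n_per_trial_range Integer pair: mosquitoes loaded per trial are
#'   drawn uniformly from this range (default 30-40).
#' @param n_trials_per_pair Trials per subject pair (default 18, the trial
#'   count of the scoring worked example).
#' @param mortality_rate Probability a mosquito dies during the assay.
#' @param seed Integer seed; the whole simulation is reproducible from it.
#' @return An object of class `behavior_sim_config`.
#' @export
behavior_sim_config <- function(subjects,
                                p_activate = 0.85,
                                p_attract_given_activate = 0.8,
                                n_per_trial_range = c(30L, 40L),
                                n_trials_per_pair = 18L,
                                mortality_rate = 0.05,
                                seed = 1L) {
  if (is.data.frame(subjects)) {
    w <- stats::setNames(subjects$weight, subjects$subject_id)
  } else {
    w <- subjects
  }
  if (length(w) == 0 || is.null(names(w)) || any(!nzchar(names(w)))) {
    abort_config("`subjects` must be a nonempty named weight vector.")
  }
  if (any(w < 0) || anyNA(w)) abort_config("subject weights must be nonnegative.")
  check_prob(p_activate, "p_activate")
  check_prob(p_attract_given_activate, "p_attract_given_activate")
  check_prob(mortality_rate, "mortality_rate")
  if (length(n_per_trial_range) != 2L || n_per_trial_range[1] > n_per_trial_range[2]) {
    abort_config("`n_per_trial_range` must be an increasing integer pair.")
  }
  structure(
    list(subjects = w,
         p_activate = p_activate,
         p_attract_given_activate = p_attract_given_activate,
         n_per_trial_range = as.integer(n_per_trial_range),
         n_trials_per_pair = check_count(n_trials_per_pair, "n_trials_per_pair", 1L),
         mortality_rate = mortality_rate,
         seed = check_count(seed, "seed")),
    class = "behavior_sim_config"
  )
}

# run one batch of two-choice trials between weights wa and wb;
# assumes the RNG state is already set by the caller
sim_pair_trials <- function(config, id_a, id_b, wa, wb, n_trials,
                            fraction_a = 1, fraction_b = 1, trial_offset = 0L) {
  lo <- config$n_per_trial_range[1]
  hi <- config$n_per_trial_range[2]
  n_loaded <- lo + sample.int(hi - lo + 1L, n_trials, replace = TRUE) - 1L
  p_choose_a <- if (wa + wb > 0) wa / (wa + wb) else 0.5
  n_dead <- stats::rbinom(n_trials, n_loaded, config$mortality_rate)
  n_live <- n_loaded - n_dead
  n_activated <- stats::rbinom(n_trials, n_live, config$p_activate)
  n_attracted <- stats::rbinom(n_trials, n_activated, config$p_attract_given_activate)
  n_a <- stats::rbinom(n_trials, n_attracted, p_choose_a)
  tibble::tibble(
    trial_id = sprintf("%s_vs_%s_t%03d", id_a, id_b, trial_offset + seq_len(n_trials)),
    assay = "two_choice",
    genotype = "wild_type",
    subject_a = id_a, subject_b = id_b,
    kind_a = "subject_nylon", kind_b = "subject_nylon",
    fraction_a = fraction_a, fraction_b = fraction_b,
    n_loaded = n_loaded,
    n_live_end = n_live,
    n_attracted_a = n_a,
    n_attracted_b = n_attracted - n_a,
    n_activated_not_attracted = n_activated - n_attracted,
    n_not_activated = n_live - n_activated
  )
}

#' Simulate a round-robin of two-choice olfactometer trials
#'
#' Generates `n_trials_per_pair` trials for every unordered pair of subjects
#' in the configuration, with independent Bernoulli mosquito outcomes (see
#' [behavior_sim_config()]). Category counts sum to `n_loaded` in every trial
#' and the same configuration always reproduces the same table.
#'
#' @param config A [behavior_sim_config()].
#' @return A trial tibble with one row per trial (the schema consumed by
#'   [include_trials()], [compare_pair()] and [build_pair_totals()]).
#' @export
simulate_trials <- function(config) {
  stopifnot(inherits(config, "behavior_sim_config"))
  if (length(config$subjects) < 2) {
    abort_config("pairwise simulation needs at least 2 subjects.")
  }
  ids <- names(config$subjects)
  pairs <- utils::combn(ids, 2L)
  old <- globalenv()$.Random.seed
  on.exit(restore_rng(old), add = TRUE)
  set.seed(config$seed)
  out <- purrr::map(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1, k]; b <- pairs[2, k]
    sim_pair_trials(config, a, b, config$subjects[[a]], config$subjects[[b]],
                    config$n_trials_per_pair)
  })
  dplyr::bind_rows(out)
}

#' Simulate a nylon dilution series
#'
#' Emulates a dose-response experiment: a fixed reference stimulus (subject
#' `low`) is competed against decreasing swatch fractions of subject `high`'s
#' nylon, whose effective attractant weight scales linearly with the fraction.
#'
#' @param config A [behavior_sim_config()] containing both subjects.
#' @param high,low Subject ids: `high` is diluted (stimulus A), `low` is the
#'   constant reference (stimulus B).
#' @param fractions Numeric vector of swatch fractions in (0, 1].
#' @return A trial tibble with `fraction_a` varying, ready for
#'   [dilution_series_analysis()].
#' @export
simulate_dilution_trials <- function(config, high, low,
                                     fractions = c(1, 1 / 2, 1 / 4, 1 / 8, 1 / 16, 1 / 32)) {
  stopifnot(inherits(config, "behavior_sim_config"))
  if (!all(c(high, low) %in% names(config$subjects))) {
    abort_config("`high` and `low` must be subjects of the configuration.")
  }
  if (any(fractions <= 0 | fractions > 1)) {
    abort_config("`fractions` must lie in (0, 1].")
  }
  old <- globalenv()$.Random.seed
  on.exit(restore_rng(old), add = TRUE)
  set.seed(config$seed)
  out <- purrr::map(sort(fractions, decreasing = TRUE), function(f) {
    sim_pair_trials(config, high, low,
                    f * config$subjects[[high]], config$subjects[[low]],
                    config$n_trials_per_pair, fraction_a = f) |>
      dplyr::mutate(trial_id = paste0(.data$trial_id, "_f", format(f)))
  })
  dplyr::bind_rows(out)
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
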