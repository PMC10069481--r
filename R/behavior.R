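#' Inclusion criteria for olfactometer trials
#'
#' Trials with too few surviving or too few participating mosquitoes are
#' excluded before preference statistics are computed. A two-choice trial is
#' kept when at least `min_live_two_choice` mosquitoes are alive at the end of
#' the assay *and* at least `min_attracted_total` mosquitoes entered either
#' trap; low-participation trials are dominated by "jackpotting" (2 vs 1
#' mosquitoes is not a meaningful preference). Single-stimulus trials only
#' require `min_live_single` live mosquitoes.
#'
#' @param min_live_two_choice Minimum live mosquitoes at assay end for a
#'   two-choice trial (default 30).
#' @param min_attracted_total Minimum mosquitoes attracted to either stimulus
#'   in a two-choice trial (default 10, i.e. trials with 9 or fewer are
#'   excluded).
#' @param min_live_single Minimum live mosquitoes for a single-stimulus trial
#'   (default 15, i.e. more than 14).
#' @return An object of class `inclusion_criteria`.
#' @export
inclusion_criteria <- function(min_live_two_choice = 30,
                               min_attracted_total = 10,
                               min_live_single = 15) {
  structure(
    list(
      min_live_two_choice = check_count(min_live_two_choice, "min_live_two_choice"),
      min_attracted_total = check_count(min_attracted_total, "min_attracted_total"),
      min_live_single     = check_count(min_live_single, "min_live_single")
    ),
    class = "inclusion_criteria"
  )
}

validate_trials <- function(trials) {
  required <- c(
    "trial_id", "assay", "n_loaded", "n_live_end",
    "n_attracted_a", "n_attracted_b",
    "n_activated_not_attracted", "n_not_activated"
  )
  missing <- setdiff(required, names(trials))
  if (length(missing) > 0) {
    abort_input(paste0("trial table lacks column(s): ", paste(missing, collapse = ", ")))
  }
  counts <- trials[c("n_loaded", "n_live_end", "n_attracted_a",
                     "n_activated_not_attracted", "n_not_activated")]
  two_choice <- trials$assay == "two_choice"
  if (any(two_choice & is.na(trials$n_attracted_b))) {
    abort_input("two-choice trials must carry `n_attracted_b`.")
  }
  if (any(!two_choice & !is.na(trials$n_attracted_b))) {
    abort_input("single-stimulus trials must not carry a second stimulus (`n_attracted_b`).")
  }
  if (any(unlist(counts) < 0, na.rm = TRUE) || any(trials$n_attracted_b < 0, na.rm = TRUE)) {
    abort_input("trial counts must be nonnegative.")
  }
  b <- ifelse(is.na(trials$n_attracted_b), 0L, trials$n_attracted_b)
  tot <- trials$n_attracted_a + b + trials$n_activated_not_attracted + trials$n_not_activated
  if (any(tot > trials$n_loaded)) {
    abort_input("per-trial category counts exceed `n_loaded`.")
  }
  if (any(trials$n_live_end > trials$n_loaded)) {
    abort_input("`n_live_end` exceeds `n_loaded`.")
  }
  invisible(trials)
}

#' Apply inclusion criteria to a trial table
#'
#' @param trials A trial tibble (see [simulate_trials()] for the schema).
#' @param criteria An [inclusion_criteria()] object.
#' @return The input tibble with logical `included` and character
#'   `exclusion_reason` columns (`NA` for included trials). The reason names
#'   the first failed rule: `"live_count"` then `"attracted_total"`.
#' @export
include_trials <- function(trials, criteria = inclusion_criteria()) {
  validate_trials(trials)
  two_choice <- trials$assay == "two_choice"
  attracted_total <- trials$n_attracted_a +
    ifelse(is.na(trials$n_attracted_b), 0L, trials$n_attracted_b)

  reason <- rep(NA_character_, nrow(trials))
  fail_live <- ifelse(two_choice,
                      trials$n_live_end < criteria$min_live_two_choice,
                      trials$n_live_end < criteria$min_live_single)
  fail_attr <- two_choice & attracted_total < criteria$min_attracted_total
  reason[fail_attr] <- "attracted_total"
  reason[fail_live] <- "live_count"   # live-count rule reported first
  dplyr::mutate(trials,
                included = is.na(reason),
                exclusion_reason = reason)
}

#' Percent of mosquitoes attracted to each stimulus
#'
#' @param trials A trial tibble.
#' @param denominator Either `"live_end"` (default: mosquitoes alive at assay
#'   end, so trials are not penalised for deaths) or `"loaded"`.
#' @return The input tibble with numeric `pct_a` and `pct_b` columns (percent,
#'   0-100).
#' @export
percent_attracted <- function(trials, denominator = c("live_end", "loaded")) {
  denominator <- match.arg(denominator)
  validate_trials(trials)
  den <- if (denominator == "live_end") trials$n_live_end else trials$n_loaded
  if (any(den == 0)) {
    abort_input("percent attracted is undefined for trials with a zero denominator.")
  }
  dplyr::mutate(trials,
                pct_a = 100 * .data$n_attracted_a / den,
                pct_b = 100 * .data$n_attracted_b / den)
}

#' Mean percent of mosquitoes per behavioral category
#'
#' Summarises where the mosquitoes ended up: attracted (either trap),
#' activated but not attracted, or never activated. Computed over *all*
#' supplied trials, before any inclusion filtering, with loaded mosquitoes as
#' the denominator; dead mosquitoes appear in no numerator, so per-trial
#' percents sum to at most 100.
#'
#' @param trials A trial tibble.
#' @return A one-row tibble with `pct_attracted`,
#'   `pct_activated_not_attracted`, `pct_not_activated` and `n_trials`.
#' @export
category_breakdown <- function(trials) {
  validate_trials(trials)
  if (nrow(trials) == 0) abort_input("`trials` must contain at least one trial.")
  b <- ifelse(is.na(trials$n_attracted_b), 0L, trials$n_attracted_b)
  tibble::tibble(
    pct_attracted = mean(100 * (trials$n_attracted_a + b) / trials$n_loaded),
    pct_activated_not_attracted =
      mean(100 * trials$n_activated_not_attracted / trials$n_loaded),
    pct_not_activated = mean(100 * trials$n_not_activated / trials$n_loaded),
    n_trials = nrow(trials)
  )
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Rank-sum (Mann-Whitney) test with midranks for ties. For combined sample
#' sizes of 12 or fewer the p-value is exact, from full enumeration of all
#' `choose(n, n_x)` group labelings of the observed midranks; for larger
#' samples a tie-corrected normal approximation with continuity correction is
#' used. The standardised statistic `Z` is positive when `x` tends to exceed
#' `y`.
#'
#' @param x,y Nonempty numeric vectors.
#' @param exact_max Largest combined sample size at which the exact
#'   enumeration is used (default 12).
#' @return A one-row tibble: `W` (rank sum of `x`), `Z`, `p`, `n_x`, `n_y`,
#'   `method`.
#' @export
rank_sum_test <- function(x, y, exact_max = 12) {
  if (length(x) == 0 || length(y) == 0) abort_input("both samples must be nonempty.")
  if (anyNA(x) || anyNA(y)) abort_input("samples must not contain NA.")
  nx <- length(x); ny <- length(y); n <- nx + ny
  r <- rank(c(x, y))            # midranks
  W <- sum(r[seq_len(nx)])
  mu <- nx * (n + 1) / 2
  tie_tab <- table(r)
  tie_term <- sum(tie_tab^3 - tie_tab) / (n * (n - 1))
  sigma2 <- nx * ny / 12 * ((n + 1) - tie_term)

  if (sigma2 <= 0) {            # every value identical: no evidence either way
    return(tibble::tibble(W = W, Z = 0, p = 1, n_x = nx, n_y = ny, method = "degenerate"))
  }
  sigma <- sqrt(sigma2)

  if (n <= exact_max) {
    sets <- utils::combn(n, nx)
    Wdist <- colSums(matrix(r[sets], nrow = nx))
    eps <- 1e-8
    p <- min(1, 2 * min(mean(Wdist <= W + eps), mean(Wdist >= W - eps)))
    Z <- (W - mu) / sigma
    method <- "exact"
  } else {
    cc <- 0.5 * sign(W - mu)    # continuity correction
    Z <- (W - mu - cc) / sigma
    p <- min(1, 2 * stats::pnorm(-abs(Z)))
    method <- "normal"
  }
  tibble::tibble(W = W, Z = Z, p = p, n_x = nx, n_y = ny, method = method)
}

#' Bonferroni adjustment with an explicit family size
#'
#' @param p Vector of p-values in \[0, 1\].
#' @param m Family size; may exceed `length(p)` when only a subset of a
#'   larger comparison family is supplied. Defaults to `length(p)`.
#' @return `pmin(1, m * p)`, order preserved.
#' @export
bonferroni_adjust <- function(p, m = length(p)) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) abort_input("p-values must lie in [0, 1].")
  check_count(m, "m", min = 1L)
  pmin(1, m * p)
}

#' Nonparametric effect size ES = Z / sqrt(N)
#'
#' @param Z Standardised rank-sum statistic.
#' @param N Number of observations entering the comparison.
#' @return `Z / sqrt(N)`.
#' @export
rank_effect_size <- function(Z, N) {
  if (any(N <= 0)) abort_input("`N` must be positive.")
  Z / sqrt(N)
}

stimulus_label <- function(kind, subject) {
  ifelse(kind %in% c("subject_nylon", "live_forearm") & !is.na(subject),
         as.character(subject), as.character(kind))
}

#' Pairwise preference test for one stimulus pair
#'
#' Filters trials of a single stimulus pair by the inclusion criteria,
#' computes per-trial percent-attracted vectors, and compares them with a
#' two-sided rank-sum test, Bonferroni correction over `family_size`
#' comparisons, and the nonparametric effect size `Z / sqrt(N)` where `N` is
#' the total number of per-trial percent observations.
#'
#' Trials may arrive with either stimulus orientation; they are normalised to
#' the orientation of the first trial before testing.
#'
#' @param trials A trial tibble; all rows must concern the same unordered
#'   stimulus pair.
#' @param criteria An [inclusion_criteria()] object.
#' @param family_size Bonferroni family size (default 1: a lone comparison).
#' @param denominator Passed to [percent_attracted()].
#' @return An object of class `preference_test`; see [tidy.preference_test()].
#'   When every trial is excluded, a sentinel with `n_trials_included = 0`
#'   and `NA` statistics is returned rather than an error.
#' @export
compare_pair <- function(trials, criteria = inclusion_criteria(),
                         family_size = 1,
                         denominator = c("live_end", "loaded")) {
  denominator <- match.arg(denominator)
  validate_trials(trials)
  if (nrow(trials) == 0) abort_input("`trials` must contain at least one trial.")
  if (any(trials$assay != "two_choice")) {
    abort_input("compare_pair() expects two-choice trials only.")
  }

  lab_a <- stimulus_label(trials$kind_a, trials$subject_a)
  lab_b <- stimulus_label(trials$kind_b, trials$subject_b)
  pair_key <- purrr::map2_chr(lab_a, lab_b, ~ paste(sort(c(.x, .y)), collapse = " vs "))
  if (length(unique(pair_key)) != 1L) {
    abort_input("all trials passed to compare_pair() must share one stimulus pair.")
  }

  # normalise orientation to that of the first trial
  ref_a <- lab_a[1]
  flip <- lab_a != ref_a
  trials_n <- trials
  trials_n$n_attracted_a <- ifelse(flip, trials$n_attracted_b, trials$n_attracted_a)
  trials_n$n_attracted_b <- ifelse(flip, trials$n_attracted_a, trials$n_attracted_b)

  flagged <- include_trials(trials_n, criteria)
  kept <- dplyr::filter(flagged, .data$included)
  n_excl <- sum(!flagged$included)

  out <- list(
    stimulus_a = ref_a, stimulus_b = lab_b[1][[1]],
    pct_a = numeric(0), pct_b = numeric(0),
    n_trials_included = nrow(kept), n_trials_excluded = n_excl,
    Z = NA_real_, p = NA_real_, p_adj = NA_real_,
    effect_size = NA_real_, N = 0L,
    family_size = family_size, denominator = denominator
  )
  class(out) <- "preference_test"
  if (nrow(kept) == 0) return(out)

  pct <- percent_attracted(kept, denominator)
  ts <- rank_sum_test(pct$pct_a, pct$pct_b)
  N <- length(pct$pct_a) + length(pct$pct_b)
  out$pct_a <- pct$pct_a
  out$pct_b <- pct$pct_b
  out$Z <- ts$Z
  out$p <- ts$p
  out$p_adj <- bonferroni_adjust(ts$p, family_size)
  out$N <- N
  out$effect_size <- rank_effect_size(ts$Z, N)
  out
}

#' @export
print.preference_test <- function(x, ...) {
  cat("Two-choice preference test:", x$stimulus_a, "vs", x$stimulus_b, "\n")
  cat(sprintf("  trials included: %d (excluded: %d)\n",
              x$n_trials_included, x$n_trials_excluded))
  if (x$n_trials_included > 0) {
    cat(sprintf("  median %% attracted: %.1f vs %.1f\n",
                stats::median(x$pct_a), stats::median(x$pct_b)))
    cat(sprintf("  Z = %.3f, p = %.4g, Bonferroni p = %.4g (m = %d), ES = %.3f\n",
                x$Z, x$p, x$p_adj, x$family_size, x$effect_size))
  } else {
    cat("  no trials passed the inclusion criteria.\n")
  }
  invisible(x)
}

#' Dilution-series preference analysis
#'
#' Analyses a dose-response design in which decreasing swatch fractions of one
#' subject's worn nylon (stimulus A) are competed against a fixed reference
#' stimulus. Runs one [compare_pair()] per swatch fraction (Bonferroni family
#' = number of fractions unless overridden) and reports the largest fraction
#' at which significance is lost.
#'
#' @param trials A trial tibble with a `fraction_a` column giving the swatch
#'   fraction of stimulus A in each trial.
#' @param criteria An [inclusion_criteria()] object.
#' @param family_size Bonferroni family size; defaults to the number of
#'   distinct fractions.
#' @param alpha Significance level applied to the adjusted p-values
#'   (default 0.05).
#' @param denominator Passed to [percent_attracted()].
#' @return A tibble with one row per fraction, ordered by descending fraction,
#'   with the tidied test columns, a logical `significant` column and
#'   attribute `fraction_significance_lost` (largest non-significant
#'   fraction, `NA` if all fractions are significant).
#' @export
dilution_series_analysis <- function(trials, criteria = inclusion_criteria(),
                                     family_size = NULL, alpha = 0.05,
                                     denominator = c("live_end", "loaded")) {
  denominator <- match.arg(denominator)
  if (!"fraction_a" %in% names(trials) || anyNA(trials$fraction_a)) {
    abort_input("every trial needs a non-missing `fraction_a` swatch fraction.")
  }
  fractions <- sort(unique(trials$fraction_a), decreasing = TRUE)
  m <- family_size %||% length(fractions)
  res <- purrr::map(fractions, function(f) {
    sub <- dplyr::filter(trials, .data$fraction_a == f)
    fit <- compare_pair(sub, criteria, family_size = m, denominator = denominator)
    if (fit$n_trials_included == 0) {
      abort_input(sprintf("no trials pass the inclusion criteria at fraction %g.", f))
    }
    dplyr::mutate(tidy(fit), fraction = f, .before = 1)
  })
  out <- dplyr::bind_rows(res)
  out$significant <- !is.na(out$p_adj) & out$p_adj < alpha
  lost <- out$fraction[!out$significant]
  attr(out, "fraction_significance_lost") <- if (length(lost)) max(lost) else NA_real_
  out
}
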