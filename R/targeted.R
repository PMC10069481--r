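#' Targeted re-analysis, initial cohort: rank-based repeated measures
#'
#' For a small cohort measured in several replicate experiments (the design
#' is 2 high- plus 2 low-attractor subjects x 4 experiments), each compound's
#' abundances are first reduced to one median per subject per experiment,
#' rank-transformed across all observations of that compound, and fit with a
#' linear mixed model on the ranks: attractor group as the fixed effect and
#' subject as a random intercept (lme4). Significance of the group effect is
#' a Wald normal test on its coefficient, followed by Benjamini-Hochberg
#' correction across compounds at `targeted_fdr`.
#'
#' @param data Tibble with columns `compound`, `subject`, `group` (`"high"`
#'   or `"low"`), `experiment` and `value`. Multiple replicate rows per
#'   subject x experiment are reduced to their median first.
#' @param config A [pipeline_config()]; only `targeted_fdr` is used.
#' @return A tibble with one row per compound: `statistic` (Wald z for the
#'   group effect, positive when the high group ranks higher), `p`, `q`,
#'   `significant` (`q <= targeted_fdr`).
#' @export
targeted_cohort1 <- function(data, config = pipeline_config()) {
  stopifnot(all(c("compound", "subject", "group", "experiment", "value") %in% names(data)))
  if (!all(data$group %in% c("high", "low"))) {
    abort_input("`group` must be \"high\" or \"low\".")
  }
  per_group <- dplyr::distinct(data, .data$subject, .data$group) |>
    dplyr::count(.data$group)
  if (nrow(per_group) < 2 || any(per_group$n < 2)) {
    abort_input("the repeated-measures model needs at least 2 subjects per group.")
  }
  med <- data |>
    dplyr::group_by(.data$compound, .data$subject, .data$group, .data$experiment) |>
    dplyr::summarise(value = stats::median(.data$value), .groups = "drop")

  fits <- med |>
    dplyr::group_by(.data$compound) |>
    dplyr::group_modify(function(d, key) {
      d$r <- rank(d$value)
      d$group <- factor(d$group, levels = c("low", "high"))
      fit <- suppressWarnings(suppressMessages(
        lme4::lmer(r ~ group + (1 | subject), data = d,
                   control = lme4::lmerControl(check.conv.singular = "ignore"))
      ))
      cf <- summary(fit)$coefficients
      z <- cf["grouphigh", "Estimate"] / cf["grouphigh", "Std. Error"]
      tibble::tibble(statistic = z, p = 2 * stats::pnorm(-abs(z)))
    }) |>
    dplyr::ungroup()
  bh <- benjamini_hochberg(fits$p, config$targeted_fdr)
  dplyr::mutate(fits, q = bh$q, significant = .data$q <= config$targeted_fdr)
}

#' Targeted re-analysis, validation cohort: per-subject rank-sum tests
#'
#' Each compound is reduced to one median value per subject (across replicate
#' experiments), the high- and low-attractor groups are compared with the
#' two-sided Wilcoxon rank-sum test of [rank_sum_test()], and
#' Benjamini-Hochberg correction is applied across compounds at
#' `targeted_fdr`. The study's design is 11 high versus 7 low attractors.
#'
#' @param data Tibble with columns `compound`, `subject`, `group` and
#'   `value`; multiple rows per subject (replicate experiments) are reduced
#'   to their median.
#' @param config A [pipeline_config()]; only `targeted_fdr` is used.
#' @return A tibble with one row per compound: `Z`, `p`, `q`, `significant`.
#' @export
targeted_cohort2 <- function(data, config = pipeline_config()) {
  stopifnot(all(c("compound", "subject", "group", "value") %in% names(data)))
  if (!all(data$group %in% c("high", "low"))) {
    abort_input("`group` must be \"high\" or \"low\".")
  }
  med <- data |>
    dplyr::group_by(.data$compound, .data$subject, .data$group) |>
    dplyr::summarise(value = stats::median(.data$value), .groups = "drop")
  sizes <- dplyr::distinct(med, .data$subject, .data$group) |> dplyr::count(.data$group)
  if (nrow(sizes) < 2 || any(sizes$n < 2)) {
    abort_input("both groups need at least 2 subjects.")
  }
  res <- med |>
    dplyr::group_by(.data$compound) |>
    dplyr::group_modify(function(d, key) {
      ts <- rank_sum_test(d$value[d$group == "high"], d$value[d$group == "low"])
      tibble::tibble(Z = ts$Z, p = ts$p)
    }) |>
    dplyr::ungroup()
  bh <- benjamini_hochberg(res$p, config$targeted_fdr)
  dplyr::mutate(res, q = bh$q, significant = .data$q <= config$targeted_fdr)
}
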