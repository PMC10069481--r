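#' Violin-style plot of per-trial percent attracted for one pair
#'
#' @param object A `preference_test` from [compare_pair()].
#' @param ... Unused.
#' @return A ggplot: per-trial percent attracted to each stimulus.
#' @method autoplot preference_test
#' @export
autoplot.preference_test <- function(object, ...) {
  if (object$n_trials_included == 0) abort_input("nothing to plot: no included trials.")
  df <- tibble::tibble(
    stimulus = rep(c(object$stimulus_a, object$stimulus_b),
                   each = object$n_trials_included),
    pct = c(object$pct_a, object$pct_b)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stimulus, y = .data$pct)) +
    ggplot2::geom_violin(fill = "grey85", colour = NA) +
    ggplot2::geom_jitter(width = 0.08, alpha = 0.6, size = 1.5) +
    ggplot2::stat_summary(fun = stats::median, geom = "crossbar",
                          width = 0.4, linewidth = 0.4) +
    ggplot2::labs(y = "% mosquitoes attracted", x = NULL,
                  subtitle = sprintf("Bonferroni p = %.3g, ES = %.2f",
                                     object$p_adj, object$effect_size)) +
    ggplot2::theme_classic()
}

#' Bar chart of round-robin attraction scores
#'
#' @param object A `tournament_result` from [attraction_scores()].
#' @param ... Unused.
#' @return A ggplot of per-subject scores, ranked.
#' @method autoplot tournament_result
#' @export
autoplot.tournament_result <- function(object, ...) {
  df <- dplyr::mutate(object$scores,
                      subject = stats::reorder(.data$subject, .data$score))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$subject, y = .data$score)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "attraction score") +
    ggplot2::theme_classic()
}

#' Volcano plot of one experiment's differential features
#'
#' @param records Differential records from [differential_high_vs_low()]
#'   (one experiment).
#' @param config A [pipeline_config()] supplying the fold and FDR guides.
#' @return A ggplot: log2 fold change (high minus low) against -log10 q.
#' @export
plot_volcano <- function(records, config = pipeline_config()) {
  ggplot2::ggplot(records,
                  ggplot2::aes(x = .data$log2_fold_change,
                               y = -log10(.data$q),
                               colour = .data$passes)) +
    ggplot2::geom_point(alpha = 0.7, size = 1.3) +
    ggplot2::geom_vline(xintercept = c(-1, 1) * log2(config$diff_fold_min),
                        linetype = "dashed", linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = -log10(config$diff_fdr),
                        linetype = "dashed", linewidth = 0.3) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick"),
                                 guide = "none") +
    ggplot2::labs(x = "log2 fold change (high - low)", y = "-log10 q") +
    ggplot2::theme_classic()
}

#' Effect size across a nylon dilution series
#'
#' @param series Output of [dilution_series_analysis()].
#' @param alpha Significance level drawn as the open/closed point distinction.
#' @return A ggplot of effect size versus swatch fraction (log2 x-axis).
#' @export
plot_dilution_series <- function(series, alpha = 0.05) {
  ggplot2::ggplot(series, ggplot2::aes(x = .data$fraction, y = .data$effect_size,
                                       shape = .data$significant)) +
    ggplot2::geom_line(linewidth = 0.3, colour = "grey50") +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::scale_x_continuous(trans = "log2") +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 1, `TRUE` = 16),
                                name = sprintf("p_adj < %.2g", alpha)) +
    ggplot2::labs(x = "swatch fraction of the diluted stimulus",
                  y = "effect size (Z / sqrt(N))") +
    ggplot2::theme_classic()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
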