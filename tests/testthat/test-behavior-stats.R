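test_that("inclusion criteria match the published boundaries", {
  crit <- inclusion_criteria()
  # 9 attracted in total -> excluded by the attracted-total rule
  t1 <- make_trial(5, 4, live = 35, loaded = 40, not_act = 26)
  r1 <- include_trials(t1, crit)
  expect_false(r1$included)
  expect_equal(r1$exclusion_reason, "attracted_total")
  # 29 live -> excluded by the live-count rule even with many attracted
  t2 <- make_trial(12, 8, live = 29, loaded = 40, not_act = 9)
  r2 <- include_trials(t2, crit)
  expect_false(r2$included)
  expect_equal(r2$exclusion_reason, "live_count")
  # both boundaries exactly met -> included
  t3 <- make_trial(6, 4, live = 30, loaded = 40, not_act = 20)
  r3 <- include_trials(t3, crit)
  expect_true(r3$included)
  # single-stimulus: > 14 live required
  s14 <- make_trial(5, NA, live = 14, loaded = 20, assay = "single_stimulus", not_act = 9)
  s15 <- make_trial(5, NA, live = 15, loaded = 20, assay = "single_stimulus", not_act = 10)
  expect_false(include_trials(s14, crit)$included)
  expect_true(include_trials(s15, crit)$included)
})

test_that("a single-stimulus trial carrying a second stimulus is malformed", {
  bad <- make_trial(5, 3, live = 20, assay = "single_stimulus", not_act = 12)
  expect_error(include_trials(bad), class = "hostpref_input_error")
})

test_that("raising any inclusion threshold never admits an excluded trial", {
  set.seed(42)
  trials <- simulate_trials(behavior_sim_config(c(A = 3, B = 1),
                                                n_trials_per_pair = 40,
                                                mortality_rate = 0.2, seed = 42))
  base <- include_trials(trials, inclusion_criteria())
  for (dl in c(0, 2, 5)) for (da in c(0, 3, 6)) {
    stricter <- include_trials(trials, inclusion_criteria(30 + dl, 10 + da, 15))
    expect_true(all(base$included | !stricter$included))  # monotone
  }
})

test_that("percent attracted is the count over the chosen denominator", {
  t <- make_trial(10, 10, live = 40, loaded = 50, not_act = 20)
  p <- percent_attracted(t, "live_end")
  expect_equal(c(p$pct_a, p$pct_b), c(25, 25))
  p2 <- percent_attracted(make_trial(0, 0, live = 30, not_act = 30))
  expect_equal(c(p2$pct_a, p2$pct_b), c(0, 0))
  p3 <- percent_attracted(make_trial(12, 3, live = 30, not_act = 15))
  expect_equal(c(p3$pct_a, p3$pct_b), c(40, 10))
  p4 <- percent_attracted(t, "loaded")
  expect_equal(c(p4$pct_a, p4$pct_b), c(20, 20))
  z <- make_trial(0, 0, live = 0, loaded = 10)
  expect_error(percent_attracted(z, "live_end"), class = "hostpref_input_error")
})

test_that("category breakdown averages per-trial percentages", {
  one <- make_trial(15, 5, act_not = 10, not_act = 10)   # 40 loaded
  expect_equal(unlist(category_breakdown(one)[1, 1:3], use.names = FALSE),
               c(50, 25, 25))
  none <- make_trial(0, 0, act_not = 0, not_act = 40)
  expect_equal(unlist(category_breakdown(none)[1, 1:3], use.names = FALSE),
               c(0, 0, 100))
  two <- make_trials(make_trial(15, 5, act_not = 10, not_act = 10),
                     make_trial(9, 3, act_not = 14, not_act = 14))
  expect_equal(unlist(category_breakdown(two)[1, 1:3], use.names = FALSE),
               c(40, 30, 30))
  expect_error(category_breakdown(make_trial(1, 1)[0, ]),
               class = "hostpref_input_error")
})

test_that("rank-sum test reproduces exact permutation p-values", {
  r <- rank_sum_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$p, 0.1)                   # 2/20 labelings as extreme
  expect_equal(r$method, "exact")
  expect_lt(r$Z, 0)

  same <- rank_sum_test(c(2, 5, 9), c(9, 2, 5))
  expect_equal(same$p, 1)

  tied <- rank_sum_test(c(1, 1, 2), c(1, 2, 2))
  expect_equal(tied$p, oracle_rank_sum_p(c(1, 1, 2), c(1, 2, 2)))

  const <- rank_sum_test(c(3, 3), c(3, 3, 3))
  expect_equal(const$p, 1)
  expect_equal(const$Z, 0)
})

test_that("rank-sum test equals the enumeration oracle over random small samples", {
  set.seed(99)
  for (i in 1:60) {
    nx <- sample(2:6, 1)
    ny <- sample(2:min(6, 12 - nx), 1)
    vals <- if (i %% 2) stats::rnorm(nx + ny) else sample(1:4, nx + ny, replace = TRUE)
    x <- vals[seq_len(nx)]; y <- vals[-seq_len(nx)]
    expect_equal(rank_sum_test(x, y)$p, oracle_rank_sum_p(x, y),
                 info = paste("case", i))
  }
  # untied cases also agree with the classical exact test
  set.seed(100)
  for (i in 1:20) {
    x <- stats::rnorm(5); y <- stats::rnorm(6)
    expect_equal(rank_sum_test(x, y)$p,
                 stats::wilcox.test(x, y, exact = TRUE)$p.value)
  }
})

test_that("large-sample rank-sum approximation tracks wilcox.test", {
  set.seed(7)
  x <- stats::rnorm(30); y <- stats::rnorm(25, 0.8)
  ours <- rank_sum_test(x, y)
  ref <- stats::wilcox.test(x, y, correct = TRUE, exact = FALSE)
  expect_equal(ours$method, "normal")
  expect_equal(ours$p, ref$p.value, tolerance = 1e-10)
})

test_that("Bonferroni adjustment multiplies and caps", {
  expect_equal(bonferroni_adjust(c(0.01, 0.04), 2), c(0.02, 0.08))
  expect_equal(bonferroni_adjust(0.9, 5), 1)
  expect_equal(bonferroni_adjust(c(0.2, 0.5), 1), c(0.2, 0.5))
  p <- c(0.001, 0.03, 0.7)
  expect_true(all(bonferroni_adjust(p, 4) >= p))
  expect_error(bonferroni_adjust(c(0.5, 1.2)), class = "hostpref_input_error")
})

test_that("effect size is Z over the square root of N", {
  expect_equal(rank_effect_size(3, 36), 0.5)
  expect_equal(rank_effect_size(0, 10), 0)
  expect_equal(rank_effect_size(2.5, 25), 0.5)
  expect_error(rank_effect_size(1, 0), class = "hostpref_input_error")
})

test_that("compare_pair detects a strong preference and honors sentinels", {
  # identical percentages in every trial -> p = 1, ES = 0
  flat <- do.call(make_trials, replicate(10, make_trial(8, 8, not_act = 20), simplify = FALSE))
  fit <- compare_pair(flat)
  expect_equal(fit$p, 1)
  expect_equal(fit$effect_size, 0)
  expect_equal(fit$N, 20)

  # synthetic 9:1 pair, 16 trials: significant even after Bonferroni
  cfg <- behavior_sim_config(c(A = 9, B = 1), n_trials_per_pair = 16, seed = 8)
  strong <- compare_pair(simulate_trials(cfg), family_size = 1)
  expect_lt(strong$p_adj, 0.05)
  expect_gt(strong$effect_size, 0)

  # all trials excluded -> sentinel, not an error
  weak <- do.call(make_trials, replicate(4, make_trial(2, 1, live = 35, not_act = 32),
                                         simplify = FALSE))
  sent <- compare_pair(weak)
  expect_equal(sent$n_trials_included, 0)
  expect_true(is.na(sent$p))
})

test_that("compare_pair is invariant to stimulus orientation", {
  cfg <- behavior_sim_config(c(A = 4, B = 1), n_trials_per_pair = 12, seed = 13)
  tr <- simulate_trials(cfg)
  swapped <- tr |>
    dplyr::mutate(subject_a = "B", subject_b = "A",
                  tmp = n_attracted_a, n_attracted_a = n_attracted_b,
                  n_attracted_b = tmp) |>
    dplyr::select(-tmp)
  mixed <- dplyr::bind_rows(tr[1:6, ], swapped[7:12, ])

  f1 <- compare_pair(tr)
  f2 <- compare_pair(swapped)
  f3 <- compare_pair(mixed)
  expect_equal(f2$Z, -f1$Z)
  expect_equal(f2$p, f1$p)
  expect_equal(abs(f2$effect_size), abs(f1$effect_size))
  expect_equal(f3$p, f1$p)                 # orientation-normalised
})

test_that("dilution series orders fractions and flags lost significance", {
  cfg <- behavior_sim_config(c(HI = 16, LO = 1), n_trials_per_pair = 14, seed = 17)
  # equal effective weights at fraction 1/16: preference vanishes there
  tr <- simulate_dilution_trials(cfg, "HI", "LO", fractions = c(1, 1 / 4, 1 / 16))
  res <- dilution_series_analysis(tr)
  expect_equal(res$fraction, sort(res$fraction, decreasing = TRUE))
  # attraction weight scales with the fraction: ES decreases along the series
  expect_gt(res$effect_size[1], res$effect_size[nrow(res)])
  lost <- attr(res, "fraction_significance_lost")
  expect_true(res$significant[1])
  expect_false(res$significant[res$fraction == 1 / 16])
  expect_equal(lost, 1 / 16)

  # equal weights at full size: nonsignificant
  cfg0 <- behavior_sim_config(c(HI = 1, LO = 1), n_trials_per_pair = 12, seed = 18)
  tr0 <- simulate_dilution_trials(cfg0, "HI", "LO", fractions = 1)
  res0 <- dilution_series_analysis(tr0)
  expect_equal(nrow(res0), 1)              # degenerate one-element series
  expect_false(res0$significant)

  expect_error(dilution_series_analysis(dplyr::mutate(tr, fraction_a = NA)),
               class = "hostpref_input_error")
})
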