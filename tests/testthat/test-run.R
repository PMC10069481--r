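test_that("behavioral run ties preferences and tournament together", {
  cfg <- behavior_sim_config(c(S33 = 8, S25 = 2, S28 = 1),
                             n_trials_per_pair = 10, seed = 23)
  trials <- simulate_trials(cfg)
  run <- run_behavior(trials)
  expect_s3_class(run, "behavior_run")
  expect_equal(nrow(run$preferences), 3)
  expect_equal(run$manifest$family_size, 3)
  # the strongest subject tops the tournament
  expect_equal(tidy(run$tournament)$subject[1], "S33")
  # manifest reconciles: included + excluded = input
  expect_equal(sum(run$preferences$n_trials_included) +
                 sum(run$preferences$n_trials_excluded), nrow(trials))
  st <- run$manifest$stages
  expect_equal(st$records_in - st$removed, st$records_out)

  # identical rerun -> identical results
  run2 <- run_behavior(simulate_trials(cfg))
  expect_equal(run$preferences, run2$preferences)
  expect_equal(tidy(run$tournament), tidy(run2$tournament))

  expect_error(run_behavior(trials[0, ]), class = "hostpref_input_error")
})

test_that("metabolomics run recovers planted ground truth with a clean ledger", {
  cfg <- metabo_sim_config(n_features = 120,
                           planted_hits = planted_hits(1:10, log2_effect = 2),
                           seed = 29)
  sim <- simulate_feature_tables(cfg)
  run <- run_metabolomics(sim$tables)

  gt <- sim$ground_truth
  expect_gte(planted_recall(gt, run$hits$feature_id), 0.9)
  expect_true(all(run$hits$feature_id %in% planted_family_ids(gt)))
  expect_true(all(run$hits$direction == "high_enriched"))

  # stage ledger conserves feature counts
  st <- run$manifest$stages
  expect_equal(st$records_in - st$removed, st$records_out)
  expect_equal(st$records_out[-nrow(st)], st$records_in[-1])

  # schema errors are caught
  broken <- sim$tables[[1]]
  broken$samples$group <- NULL
  expect_error(feature_table(broken$features, broken$samples, broken$areas),
               class = "hostpref_input_error")
})

test_that("feature tables survive a CSV round trip", {
  cfg <- metabo_sim_config(n_features = 30, n_experiments = 1, seed = 33)
  ft <- simulate_feature_tables(cfg)$tables[[1]]
  a <- withr::local_tempfile(fileext = ".csv")
  s <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(ft, a, s)
  back <- read_feature_table(a, s)
  expect_equal(back$areas, ft$areas, tolerance = 1e-12)
  expect_equal(back$samples, ft$samples)
  expect_equal(back$features$feature_id, ft$features$feature_id)

  long <- as_tibble(ft)
  expect_equal(nrow(long), nrow(ft$features) * nrow(ft$samples))
  expect_equal(sum(long$observed), sum(ft$mask))
})

test_that("plots build without error", {
  cfg <- behavior_sim_config(c(A = 6, B = 1), n_trials_per_pair = 10, seed = 3)
  fit <- compare_pair(simulate_trials(cfg))
  expect_s3_class(ggplot2::ggplot_build(autoplot(fit))$plot, "ggplot")

  tt <- attraction_scores(build_pair_totals(simulate_trials(cfg)))
  expect_s3_class(ggplot2::ggplot_build(autoplot(tt))$plot, "ggplot")

  mc <- metabo_sim_config(n_features = 40, n_experiments = 1,
                          planted_hits = planted_hits(1:2, 2), seed = 4)
  ft <- simulate_feature_tables(mc)$tables[[1]]
  lg <- log2_transform(impute_half_minimum(prevalence_filter(ft, pipeline_config())))
  rec <- differential_high_vs_low(lg, "exp1")
  expect_s3_class(ggplot2::ggplot_build(plot_volcano(rec))$plot, "ggplot")
})
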