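test_that("trial simulation conserves counts and is reproducible", {
  cfg <- behavior_sim_config(c(A = 2, B = 1, C = 1), n_trials_per_pair = 5,
                             mortality_rate = 0.1, seed = 11)
  tr <- simulate_trials(cfg)
  expect_equal(nrow(tr), 3 * 5)            # 3 pairs x 5 trials
  # behavioral categories plus deaths account for every loaded mosquito
  cats <- tr$n_attracted_a + tr$n_attracted_b +
    tr$n_activated_not_attracted + tr$n_not_activated
  expect_equal(cats, tr$n_live_end)
  expect_true(all(tr$n_live_end <= tr$n_loaded))
  expect_true(all(tr$n_loaded >= 30 & tr$n_loaded <= 40))
  expect_true(all(cats >= 0))

  tr2 <- simulate_trials(cfg)
  expect_identical(tr, tr2)                # same config, byte-identical table

  cfg3 <- behavior_sim_config(c(A = 2, B = 1, C = 1), n_trials_per_pair = 5,
                              mortality_rate = 0.1, seed = 12)
  expect_false(identical(tr, simulate_trials(cfg3)))
})

test_that("equal weights split attracted mosquitoes symmetrically", {
  cfg <- behavior_sim_config(c(A = 1, B = 1), p_activate = 1,
                             p_attract_given_activate = 1, mortality_rate = 0,
                             n_trials_per_pair = 50, seed = 21)
  tr <- simulate_trials(cfg)
  n <- sum(tr$n_loaded)
  frac_a <- sum(tr$n_attracted_a) / n
  se <- sqrt(0.25 / n)
  expect_lt(abs(frac_a - 0.5), 3 * se)
  expect_equal(sum(tr$n_attracted_a + tr$n_attracted_b), n)  # all attracted
})

test_that("a 9:1 weight ratio yields ~90% choices for the stronger stimulus", {
  cfg <- behavior_sim_config(c(A = 9, B = 1), p_activate = 1,
                             p_attract_given_activate = 1, mortality_rate = 0,
                             n_per_trial_range = c(40, 40),
                             n_trials_per_pair = 250, seed = 31)
  tr <- simulate_trials(cfg)                # 10,000 mosquitoes pooled
  n <- sum(tr$n_loaded)
  expect_equal(n, 10000)
  frac_a <- sum(tr$n_attracted_a) / n
  expect_lt(abs(frac_a - 0.9), 3 * sqrt(0.9 * 0.1 / n))
})

test_that("invalid simulator configurations are rejected", {
  expect_error(behavior_sim_config(c(A = 1, B = 1), p_activate = 1.2),
               class = "hostpref_config_error")
  expect_error(behavior_sim_config(c(A = -1, B = 1)),
               class = "hostpref_config_error")
  expect_error(behavior_sim_config(numeric(0)),
               class = "hostpref_config_error")
  expect_error(simulate_trials(behavior_sim_config(c(A = 1))),
               class = "hostpref_config_error")
  expect_error(behavior_sim_config(c(A = 1, B = 1), n_per_trial_range = c(40, 30)),
               class = "hostpref_config_error")
})

test_that("dilution trials scale the diluted stimulus' weight with its fraction", {
  cfg <- behavior_sim_config(c(HI = 8, LO = 1), p_activate = 1,
                             p_attract_given_activate = 1, mortality_rate = 0,
                             n_per_trial_range = c(40, 40),
                             n_trials_per_pair = 100, seed = 5)
  tr <- simulate_dilution_trials(cfg, "HI", "LO", fractions = c(1, 1 / 8))
  frac_full <- with(dplyr::filter(tr, fraction_a == 1),
                    sum(n_attracted_a) / sum(n_loaded))
  frac_dil <- with(dplyr::filter(tr, fraction_a == 1 / 8),
                   sum(n_attracted_a) / sum(n_loaded))
  expect_gt(frac_full, 0.85)               # 8/9 expected
  expect_lt(abs(frac_dil - 0.5), 0.05)     # 1:1 after 8-fold dilution
})
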