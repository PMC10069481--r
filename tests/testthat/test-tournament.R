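pair_row <- function(x, y, tx, ty, n) {
  tibble::tibble(subject_x = x, subject_y = y,
                 total_attracted_x = tx, total_attracted_y = ty, n_trials = n)
}

test_that("margin of victory reproduces the worked example", {
  # 468 vs 35 over 18 trials: difference 433, average margin 24
  m <- margin_of_victory(pair_row("S33", "S28", 468L, 35L, 18L))
  expect_equal(m$winner, "S33")
  expect_equal(m$margin, 24)
  expect_equal(468 - 35, 433)
  expect_equal(margin_of_victory(pair_row("A", "B", 100L, 100L, 7L))$margin, 0)
  expect_true(is.na(margin_of_victory(pair_row("A", "B", 100L, 100L, 7L))$winner))
  expect_equal(margin_of_victory(pair_row("A", "B", 50L, 10L, 4L))$margin, 10)
  # rounding is half away from zero, not banker's
  expect_equal(margin_of_victory(pair_row("A", "B", 5L, 0L, 2L))$margin, 3)
  un <- margin_of_victory(pair_row("S33", "S28", 468L, 35L, 18L), round = FALSE)
  expect_equal(un$margin, 433 / 18)
})

test_that("attraction scores sum awarded margins; losers score zero", {
  # a champion whose 7 awarded margins are the published ones scores 144
  opp <- paste0("O", 1:7)
  margins <- c(15, 18, 20, 21, 23, 23, 24)
  pairs <- dplyr::bind_rows(purrr::map2(opp, margins,
                                        ~ pair_row("S33", .x, .y, 0L, 1L)))
  suppressWarnings(res <- attraction_scores(pairs))
  expect_equal(res$scores$score[res$scores$subject == "S33"], 144)
  expect_equal(res$scores$subject[1], "S33")
  # every opponent lost every shown pair -> score 0
  expect_true(all(res$scores$score[res$scores$subject != "S33"] == 0))

  two <- attraction_scores(pair_row("A", "B", 5L, 0L, 1L))
  expect_equal(tidy(two)$score, c(5, 0))
  expect_equal(tidy(two)$subject, c("A", "B"))

  expect_error(attraction_scores(dplyr::bind_rows(pair_row("A", "B", 5L, 0L, 1L),
                                                  pair_row("B", "A", 1L, 2L, 1L))),
               class = "hostpref_input_error")
})

test_that("scores are order-invariant and unaffected by an always-losing subject", {
  set.seed(61)
  subjects <- LETTERS[1:5]
  combos <- utils::combn(subjects, 2)
  pairs <- purrr::map(seq_len(ncol(combos)), function(k) {
    pair_row(combos[1, k], combos[2, k],
             sample(0:300, 1), sample(0:300, 1), sample(10:20, 1))
  }) |> dplyr::bind_rows()

  s1 <- attraction_scores(pairs)$scores
  s2 <- attraction_scores(pairs[sample(nrow(pairs)), ])$scores
  expect_equal(s1, s2)

  # add subject Z that narrowly loses every pairing (rounded margin 0):
  # existing scores unchanged, Z scores 0
  loser <- purrr::map(subjects, ~ pair_row(.x, "Z", 1L, 0L, 5L)) |> dplyr::bind_rows()
  s3 <- attraction_scores(dplyr::bind_rows(pairs, loser))$scores
  old <- s1[match(subjects, s1$subject), ]
  new <- s3[match(subjects, s3$subject), ]
  expect_equal(new$score, old$score)
  expect_equal(s3$score[s3$subject == "Z"], 0)
  # a decisive loser still scores 0, and each winner gains its margin
  big <- purrr::map(subjects, ~ pair_row(.x, "Z", 50L, 0L, 5L)) |> dplyr::bind_rows()
  s4 <- attraction_scores(dplyr::bind_rows(pairs, big))$scores
  expect_equal(s4$score[match(subjects, s4$subject)], old$score + 10)
  expect_equal(s4$score[s4$subject == "Z"], 0)

  # integer scaling of totals and trials leaves unrounded margins unchanged
  scaled <- dplyr::mutate(pairs,
                          total_attracted_x = total_attracted_x * 3L,
                          total_attracted_y = total_attracted_y * 3L,
                          n_trials = n_trials * 3L)
  expect_equal(margin_of_victory(scaled, round = FALSE)$margin,
               margin_of_victory(pairs, round = FALSE)$margin)
})

test_that("an incomplete round-robin warns but still scores available pairs", {
  pairs <- dplyr::bind_rows(pair_row("A", "B", 10L, 2L, 2L),
                            pair_row("B", "C", 8L, 2L, 2L))
  expect_warning(res <- attraction_scores(pairs), "incomplete")
  expect_equal(res$scores$score[res$scores$subject == "A"], 4)
})

test_that("pair totals regroup mixed trials correctly", {
  t1 <- make_trials(
    make_trial(5, 1, not_act = 30), make_trial(6, 2, not_act = 30),
    make_trial(7, 3, not_act = 30)
  )
  tot <- build_pair_totals(t1)
  expect_equal(tot$total_attracted_x, 18)
  expect_equal(tot$total_attracted_y, 6)
  expect_equal(tot$n_trials, 3)

  expect_equal(nrow(build_pair_totals(t1[0, ])), 0)

  # brute-force regroup over a mixed 5-pair table, with flipped orientations
  set.seed(71)
  subjects <- c("P", "Q", "R", "S")
  combos <- utils::combn(subjects, 2)[, 1:5]
  rows <- purrr::map(1:40, function(i) {
    k <- sample(5, 1)
    a <- combos[1, k]; b <- combos[2, k]
    if (stats::runif(1) < 0.5) { tmp <- a; a <- b; b <- tmp }
    make_trial(sample(0:15, 1), sample(0:15, 1), not_act = 20,
               subject_a = a, subject_b = b, id = paste0("m", i))
  })
  tab <- dplyr::bind_rows(rows)
  got <- build_pair_totals(tab)
  want <- purrr::map(1:5, function(k) {
    a <- combos[1, k]; b <- combos[2, k]
    fwd <- tab[tab$subject_a == a & tab$subject_b == b, ]
    rev <- tab[tab$subject_a == b & tab$subject_b == a, ]
    tibble::tibble(subject_x = min(a, b), subject_y = max(a, b),
                   tx = sum(fwd$n_attracted_a) + sum(rev$n_attracted_b),
                   ty = sum(fwd$n_attracted_b) + sum(rev$n_attracted_a),
                   n = nrow(fwd) + nrow(rev))
  }) |> dplyr::bind_rows() |> dplyr::arrange(subject_x, subject_y)
  expect_equal(got$total_attracted_x, want$tx)
  expect_equal(got$total_attracted_y, want$ty)
  expect_equal(got$n_trials, want$n)

  # non-subject stimuli are skipped with a warning
  ctrl <- make_trial(3, 2, not_act = 30, kind_b = "unworn_nylon", subject_b = NA)
  expect_warning(out <- build_pair_totals(dplyr::bind_rows(t1, ctrl)), "skipping")
  expect_equal(out$n_trials, 3)
})

test_that("expected pair count is n choose 2", {
  expect_equal(expected_pair_count(8), 28)
  expect_equal(expected_pair_count(2), 1)
  expect_equal(expected_pair_count(3), 3)
  expect_error(expected_pair_count(1), class = "hostpref_config_error")
})
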