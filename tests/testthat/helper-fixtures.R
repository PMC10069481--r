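# fixtures are built in code; nothing is read from disk

`%||%` <- function(a, b) if (is.null(a)) b else a

# one two-choice trial row between subject nylons A and B
make_trial <- function(n_a, n_b, live = NULL, loaded = NULL,
                       act_not = 0L, not_act = 0L,
                       subject_a = "A", subject_b = "B",
                       kind_a = "subject_nylon", kind_b = "subject_nylon",
                       assay = "two_choice", fraction_a = 1, id = "t1") {
  live <- live %||% (n_a + n_b + act_not + not_act)
  loaded <- loaded %||% live
  tibble::tibble(
    trial_id = id, assay = assay, genotype = "wild_type",
    subject_a = subject_a, subject_b = subject_b,
    kind_a = kind_a, kind_b = kind_b,
    fraction_a = fraction_a, fraction_b = 1,
    n_loaded = loaded, n_live_end = live,
    n_attracted_a = n_a,
    n_attracted_b = n_b,
    n_activated_not_attracted = act_not, n_not_activated = not_act
  )
}

make_trials <- function(...) {
  rows <- list(...)
  out <- dplyr::bind_rows(rows)
  out$trial_id <- sprintf("t%03d", seq_len(nrow(out)))
  out
}

# small feature table with hand-set areas (features x samples matrix),
# two subject groups of `n_rep` samples plus optional controls
make_ft <- function(areas, mz, rt, groups, classes = NULL, experiment = "exp1") {
  classes <- classes %||% ifelse(groups %in% c("unworn", "solvent"), "none",
                                 ifelse(grepl("^H", groups), "high",
                                        ifelse(grepl("^L", groups), "low", "none")))
  samples <- tibble::tibble(
    sample_id = sprintf("s%02d", seq_along(groups)),
    experiment_id = experiment, group = groups,
    attractor_class = classes,
    replicate = stats::ave(seq_along(groups), groups, FUN = seq_along)
  )
  feature_table(features = tibble::tibble(mz = mz, rt = rt),
                samples = samples, areas = areas)
}

# independent brute-force two-sided rank-sum p-value: counts labelings whose
# rank sum is at least as far from its mean, tail by tail
oracle_rank_sum_p <- function(x, y) {
  nx <- length(x)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(nx)])
  sets <- utils::combn(length(r), nx)
  ws <- apply(sets, 2, function(idx) sum(r[idx]))
  lo <- sum(ws <= w_obs + 1e-9) / length(ws)
  hi <- sum(ws >= w_obs - 1e-9) / length(ws)
  min(1, 2 * min(lo, hi))
}

# naive quadruple-loop CHNO enumeration oracle (masses below `max_mass`)
oracle_formulas <- function(ion_mz, ppm_window, bounds, max_mass = 300) {
  masses <- c(C = 12, H = 1.0078250319, N = 14.0030740052, O = 15.9949146221)
  target <- ion_mz + 1.007276
  out <- list()
  for (C in 0:bounds[["C"]]) for (H in 0:bounds[["H"]]) {
    base_ch <- C * masses[["C"]] + H * masses[["H"]]
    if (base_ch > max_mass) break
    for (N in 0:bounds[["N"]]) for (O in 0:bounds[["O"]]) {
      m <- base_ch + N * masses[["N"]] + O * masses[["O"]]
      if (m >= max_mass) break
      if (C + H + N + O == 0) next
      rdbe <- C - H / 2 + N / 2 + 1
      if (rdbe < 0 || H > 2 * C + N + 2) next
      if (abs(m - target) / target * 1e6 <= ppm_window) {
        out[[length(out) + 1]] <- c(C = C, H = H, N = N, O = O)
      }
    }
  }
  if (length(out) == 0) return(character(0))
  sort(vapply(out, function(v) paste(v, collapse = "/"), character(1)))
}

# compound-level recovery of planted effects: a planted parent counts as
# recovered when it, or any of its fuzzy twins, appears among the hit ids
planted_recall <- function(ground_truth, hit_ids) {
  parents <- ground_truth$feature_id[ground_truth$is_planted &
                                       is.na(ground_truth$parent_id)]
  fam <- function(p) c(p, ground_truth$feature_id[
    !is.na(ground_truth$parent_id) & ground_truth$parent_id == p])
  mean(vapply(parents, function(p) any(fam(p) %in% hit_ids), logical(1)))
}

planted_family_ids <- function(ground_truth) {
  parents <- ground_truth$feature_id[ground_truth$is_planted &
                                       is.na(ground_truth$parent_id)]
  c(parents, ground_truth$feature_id[!is.na(ground_truth$parent_id) &
                                       ground_truth$parent_id %in% parents])
}
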