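#' Configuration for the synthetic GC/QTOF-MS feature-table generator
#'
#' Emulates the statistical structure of a replicated untargeted skin-odor
#' experiment: log-normal peak areas per feature, subject groups with high /
#' low / unclassified attractor status plus unworn-nylon and solvent-blank
#' controls, planted fold-change effects reproduced in every replicate
#' experiment, fuzzy mass/retention-time twin features, detection-limit
#' censoring, exactly constant internal-standard features, and nylon-derived
#' features absent from solvent blanks.
#'
#' @param n_features Number of parent features (twins are added on top).
#' @param n_experiments Number of replicate experiments (default 4).
#' @param subjects Data frame with `subject_id` and `attractor_class`
#'   (`"high"`, `"low"`, `"none"`). Default: 2 high, 2 low, 3 unclassified
#'   subjects.
#' @param n_replicates Samples per group per experiment (default 6).
#' @param planted_hits Tibble with `feature_index`, `log2_effect`,
#'   `direction` (`"high_enriched"` or `"low_enriched"`); `NULL` plants
#'   nothing.
#' @param duplicate_rate Fraction of features that also emit a jittered twin
#'   within the dedup tolerances.
#' @param dup_mass_tol_ppm,dup_rt_tol_min Tolerances the twins are jittered
#'   strictly within (defaults match [pipeline_config()]).
#' @param detection_limit Peak area below which a value is recorded missing.
#' @param cv_target Within-group coefficient of variation of generated areas.
#' @param n_internal_standards Number of constant internal-standard features.
#' @param nylon_rate Fraction of features that are nylon-derived (present in
#'   worn and unworn nylons, absent in solvent blanks).
#' @param background_rate Fraction of features present in all samples
#'   (ambient contaminants); the remainder are human-derived, enriched
#'   `human_enrichment`-fold on worn nylons over controls.
#' @param human_enrichment Fold enrichment of human-derived features on worn
#'   nylons versus controls (default 8).
#' @param seed Integer seed.
#' @return An object of class `metabo_sim_config`.
#' @export
metabo_sim_config <- function(n_features = 200L,
                              n_experiments = 4L,
                              subjects = default_subjects(),
                              n_replicates = 6L,
                              planted_hits = NULL,
                              duplicate_rate = 0.10,
                              dup_mass_tol_ppm = 100,
                              dup_rt_tol_min = 0.05,
                              detection_limit = 4096,
                              cv_target = 0.25,
                              n_internal_standards = 6L,
                              nylon_rate = 0.05,
                              background_rate = 0.20,
                              human_enrichment = 8,
                              seed = 1L) {
  if (duplicate_rate < 0 || duplicate_rate > 1) {
    abort_config("`duplicate_rate` must lie in [0, 1].")
  }
  if (detection_limit < 0) abort_config("`detection_limit` must be >= 0.")
  if (cv_target <= 0) abort_config("`cv_target` must be positive.")
  subjects <- tibble::as_tibble(subjects)
  stopifnot(all(c("subject_id", "attractor_class") %in% names(subjects)),
            all(subjects$attractor_class %in% c("high", "low", "none")))
  if (!is.null(planted_hits)) {
    planted_hits <- tibble::as_tibble(planted_hits)
    stopifnot(all(c("feature_index", "log2_effect", "direction") %in% names(planted_hits)))
    if (any(planted_hits$feature_index > n_features)) {
      abort_config("planted hit indices must be < `n_features`.")
    }
    if (any(!is.finite(planted_hits$log2_effect))) {
      abort_config("planted effect sizes must be finite.")
    }
    stopifnot(all(planted_hits$direction %in% c("high_enriched", "low_enriched")))
  }
  structure(
    list(n_features = check_count(n_features, "n_features", 1L),
         n_experiments = check_count(n_experiments, "n_experiments", 1L),
         subjects = subjects,
         n_replicates = check_count(n_replicates, "n_replicates", 1L),
         planted_hits = planted_hits,
         duplicate_rate = duplicate_rate,
         dup_mass_tol_ppm = dup_mass_tol_ppm,
         dup_rt_tol_min = dup_rt_tol_min,
         detection_limit = detection_limit,
         cv_target = cv_target,
         n_internal_standards = check_count(n_internal_standards, "n_internal_standards"),
         nylon_rate = nylon_rate,
         background_rate = background_rate,
         human_enrichment = human_enrichment,
         seed = check_count(seed, "seed")),
    class = "metabo_sim_config"
  )
}

#' Default subject panel for the simulator
#'
#' Two high attractors, two low attractors and three unclassified subjects,
#' mirroring a 7-subject initial cohort.
#' @return A tibble with `subject_id` and `attractor_class`.
#' @export
default_subjects <- function() {
  tibble::tibble(
    subject_id = c("S33", "S31", "S19", "S28", "S25", "S30", "S32"),
    attractor_class = c("high", "high", "low", "low", "none", "none", "none")
  )
}

#' Declare planted differential features
#'
#' @param feature_index Integer indices of features to plant.
#' @param log2_effect log2 fold change applied in the affected class.
#' @param direction `"high_enriched"` (default) or `"low_enriched"`.
#' @return A tibble suitable for [metabo_sim_config()]'s `planted_hits`.
#' @export
planted_hits <- function(feature_index, log2_effect = 2, direction = "high_enriched") {
  tibble::tibble(feature_index = as.integer(feature_index),
                 log2_effect = log2_effect, direction = direction)
}

# feature-level parameters shared by all experiments (class, mass, RT,
# baseline abundance, twins); caller controls the RNG state
sim_feature_universe <- function(config) {
  n <- config$n_features
  # rejection-sample mass/RT so no two *parent* features collide within the
  # dedup tolerances: collisions are introduced deliberately via twins
  mz <- stats::runif(n, 60, 450)
  rt <- stats::runif(n, 1.5, 15.5)
  repeat {
    d_mz <- abs(outer(mz, mz, "-")) / outer(mz, mz, pmin) * 1e6
    d_rt <- abs(outer(rt, rt, "-"))
    clash <- which(d_mz <= 2 * config$dup_mass_tol_ppm &
                     d_rt <= 2 * config$dup_rt_tol_min & upper.tri(d_mz),
                   arr.ind = TRUE)
    if (nrow(clash) == 0) break
    redraw <- unique(clash[, 2])
    mz[redraw] <- stats::runif(length(redraw), 60, 450)
    rt[redraw] <- stats::runif(length(redraw), 1.5, 15.5)
  }

  class <- rep("human", n)
  n_std <- min(config$n_internal_standards, n)
  n_nyl <- floor(config$nylon_rate * n)
  n_bg <- floor(config$background_rate * n)
  pool <- sample.int(n)
  class[pool[seq_len(n_std)]] <- "standard"
  class[pool[n_std + seq_len(n_nyl)]] <- "nylon"
  class[pool[n_std + n_nyl + seq_len(n_bg)]] <- "background"
  if (!is.null(config$planted_hits)) {
    class[config$planted_hits$feature_index] <- "human"  # hits are human-derived
  }

  base_log2 <- stats::runif(n, 14, 22)          # worn-nylon abundance scale
  base_log2[class == "standard"] <- 18

  features <- tibble::tibble(
    index = seq_len(n), mz = mz, rt = rt, class = class, base_log2 = base_log2,
    is_planted = FALSE, log2_effect = 0, direction = NA_character_,
    parent_index = NA_integer_
  )
  if (!is.null(config$planted_hits)) {
    ph <- config$planted_hits
    features$is_planted[ph$feature_index] <- TRUE
    features$log2_effect[ph$feature_index] <- ph$log2_effect
    features$direction[ph$feature_index] <- ph$direction
  }

  # fuzzy twins: jittered strictly within the merge tolerances, weaker signal
  n_dup <- floor(config$duplicate_rate * n)
  if (n_dup > 0) {
    parents <- sample(which(features$class != "standard"), n_dup)
    twins <- features[parents, ]
    twins$parent_index <- parents
    twins$index <- n + seq_len(n_dup)
    twins$mz <- twins$mz *
      (1 + stats::runif(n_dup, -0.6, 0.6) * config$dup_mass_tol_ppm * 1e-6)
    twins$rt <- pmax(0, twins$rt + stats::runif(n_dup, -0.6, 0.6) * config$dup_rt_tol_min)
    twins$base_log2 <- twins$base_log2 + log2(0.6)   # split detection, weaker
    features <- dplyr::bind_rows(features, twins)
  }
  features$feature_id <- make_feature_id(features$mz, features$rt)
  features
}

sim_sample_sheet <- function(config, exp_idx) {
  exp_id <- sprintf("exp%d", exp_idx)
  groups <- dplyr::bind_rows(
    dplyr::rename(config$subjects, group = "subject_id"),
    tibble::tibble(group = c("unworn", "solvent"), attractor_class = "none")
  )
  tidyr::crossing(groups, replicate = seq_len(config$n_replicates)) |>
    dplyr::mutate(experiment_id = exp_id,
                  sample_id = sprintf("%s_%s_r%d", exp_id, .data$group, .data$replicate)) |>
    dplyr::select("sample_id", "experiment_id", "group", "attractor_class", "replicate")
}

#' Simulate replicate GC/QTOF-MS feature tables with known ground truth
#'
#' Generates one [feature_table()] per replicate experiment under the model
#' described in [metabo_sim_config()]. Planted effects are applied in every
#' experiment, so the ground-truth hit list plus the emitted tables are
#' sufficient to score the recall and false-discovery behavior of the full
#' consensus pipeline without re-simulation.
#'
#' @param config A [metabo_sim_config()].
#' @return A list with `tables` (list of per-experiment `feature_table`s),
#'   `ground_truth` (tibble: `feature_id`, `class`, `is_planted`,
#'   `log2_effect`, `direction`, `parent_id`) and `config`.
#' @export
simulate_feature_tables <- function(config) {
  stopifnot(inherits(config, "metabo_sim_config"))
  old <- globalenv()$.Random.seed
  on.exit(restore_rng(old), add = TRUE)

  set.seed(config$seed)
  universe <- sim_feature_universe(config)
  exp_seeds <- sample.int(.Machine$integer.max - 1L, config$n_experiments)

  sigma <- sqrt(log(1 + config$cv_target^2))   # log-normal sd for target CV
  nf <- nrow(universe)

  tables <- purrr::map(seq_len(config$n_experiments), function(e) {
    set.seed(exp_seeds[e])                     # deterministic per-experiment stream
    sheet <- sim_sample_sheet(config, e)
    ns <- nrow(sheet)

    mu <- matrix(universe$base_log2, nf, ns)   # log2 mean, feature x sample
    worn <- !(sheet$group %in% c("unworn", "solvent"))
    # human-derived signal is enriched on worn nylons over both controls
    mu[universe$class == "human", !worn] <-
      mu[universe$class == "human", !worn] - log2(config$human_enrichment)
    # nylon-derived compounds: shared by worn and unworn nylons, absent in solvent
    mu[universe$class == "nylon", sheet$group == "solvent"] <- -Inf
    # planted attractor-class effects, identical in every experiment
    hi <- sheet$attractor_class == "high"
    lo <- sheet$attractor_class == "low"
    up <- universe$is_planted & universe$direction == "high_enriched"
    dn <- universe$is_planted & universe$direction == "low_enriched"
    mu[up, hi] <- mu[up, hi] + matrix(universe$log2_effect[up], sum(up), sum(hi))
    mu[dn, lo] <- mu[dn, lo] + matrix(universe$log2_effect[dn], sum(dn), sum(lo))

    noise <- matrix(exp(stats::rnorm(nf * ns, 0, sigma)), nf, ns)
    areas <- 2^mu * noise
    areas[universe$class == "standard", ] <- 2^18   # exactly constant standards

    areas[areas < config$detection_limit] <- NA_real_
    feature_table(
      features = universe[c("feature_id", "mz", "rt")],
      samples = sheet, areas = areas
    )
  })

  ground_truth <- universe |>
    dplyr::mutate(parent_id = .data$feature_id[match(.data$parent_index, .data$index)]) |>
    dplyr::select("feature_id", "mz", "rt", "class", "is_planted",
                  "log2_effect", "direction", "parent_id")

  list(tables = tables, ground_truth = ground_truth, config = config)
}
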