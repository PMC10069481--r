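# exact monoisotopic masses (Da)
ELEMENT_MASS <- c(C = 12, H = 1.0078250319, N = 14.0030740052, O = 15.9949146221)
PROTON_MASS <- 1.007276   # m(H atom) - m(electron)
ELECTRON_MASS <- 0.000549

format_formula <- function(C, H, N, O) {
  piece <- function(sym, n) ifelse(n == 0, "", ifelse(n == 1, sym, paste0(sym, n)))
  paste0(piece("C", C), piece("H", H), piece("N", N), piece("O", O))
}

#' Predict CHNO elemental formulas from a deprotonated-ion mass
#'
#' Enumerates all formulas over C, H, N and O within the element bounds whose
#' neutral monoisotopic mass lies within `ppm_window` of the neutral mass
#' implied by the measured \[M-H\]- ion. The neutral mass is recovered as
#' `ion_mz + 1.007276` Da (a proton: the anion's extra electron exactly
#' offsets the electron of the hydrogen atom lost on deprotonation); setting
#' `electron_correction = FALSE` adds the full hydrogen-atom mass instead,
#' ignoring the electron. Candidates must satisfy two plausibility rules:
#' rings-plus-double-bond equivalents `RDBE = C - H/2 + N/2 + 1 >= 0`, and
#' the hydrogen bound `H <= 2C + N + 2`. Results are ranked by absolute ppm
#' error.
#'
#' @param ion_mz Measured \[M-H\]- mass (Da), positive.
#' @param ppm_window Mass tolerance in ppm (default 100).
#' @param bounds Named integer vector of maximum element counts
#'   (default `c(C = 40, H = 80, N = 6, O = 10)`).
#' @param electron_correction Apply the electron-mass bookkeeping described
#'   above (default `TRUE`).
#' @return A tibble ranked by `abs(ppm_error)` with columns `formula`, `C`,
#'   `H`, `N`, `O`, `neutral_mass`, `ppm_error`, `rdbe`. Zero rows is a valid
#'   outcome.
#' @export
predict_formulas <- function(ion_mz, ppm_window = 100,
                             bounds = c(C = 40, H = 80, N = 6, O = 10),
                             electron_correction = TRUE) {
  if (!is.numeric(ion_mz) || length(ion_mz) != 1L || ion_mz <= 0) {
    abort_input("`ion_mz` must be a single positive mass in Da.")
  }
  if (ppm_window <= 0) abort_input("`ppm_window` must be positive.")
  stopifnot(all(c("C", "H", "N", "O") %in% names(bounds)))
  target <- ion_mz + if (electron_correction) PROTON_MASS else ELEMENT_MASS[["H"]]
  tol <- target * ppm_window * 1e-6

  grid <- expand.grid(C = 0:bounds[["C"]], N = 0:bounds[["N"]], O = 0:bounds[["O"]])
  base <- grid$C * ELEMENT_MASS[["C"]] + grid$N * ELEMENT_MASS[["N"]] +
    grid$O * ELEMENT_MASS[["O"]]
  h_lo <- pmax(0L, ceiling((target - tol - base) / ELEMENT_MASS[["H"]]))
  h_hi <- pmin(bounds[["H"]], floor((target + tol - base) / ELEMENT_MASS[["H"]]))
  ok <- which(h_hi >= h_lo)
  if (length(ok) == 0) return(empty_formula_tibble())

  reps <- h_hi[ok] - h_lo[ok] + 1L
  C <- rep(grid$C[ok], reps); N <- rep(grid$N[ok], reps); O <- rep(grid$O[ok], reps)
  H <- unlist(purrr::map2(h_lo[ok], h_hi[ok], seq.int), use.names = FALSE)

  mass <- C * ELEMENT_MASS[["C"]] + H * ELEMENT_MASS[["H"]] +
    N * ELEMENT_MASS[["N"]] + O * ELEMENT_MASS[["O"]]
  ppm_err <- (mass - target) / target * 1e6
  rdbe <- C - H / 2 + N / 2 + 1
  keep <- abs(ppm_err) <= ppm_window & rdbe >= 0 & H <= 2 * C + N + 2 &
    (C + H + N + O) > 0
  out <- tibble::tibble(
    formula = format_formula(C[keep], H[keep], N[keep], O[keep]),
    C = C[keep], H = H[keep], N = N[keep], O = O[keep],
    neutral_mass = mass[keep], ppm_error = ppm_err[keep], rdbe = rdbe[keep]
  )
  dplyr::arrange(out, abs(.data$ppm_error))
}

empty_formula_tibble <- function() {
  tibble::tibble(formula = character(), C = integer(), H = integer(),
                 N = integer(), O = integer(), neutral_mass = numeric(),
                 ppm_error = numeric(), rdbe = numeric())
}

#' Attach formula candidates to consensus hits
#'
#' Pure function of each hit's ion mass and the enumeration settings: every
#' hit gains a list-column of ranked [predict_formulas()] candidates, the
#' best candidate's formula string, and an `unidentified` flag when no CHNO
#' formula matches within the window.
#'
#' @param hits A tibble with at least `feature_id` and `mz` (\[M-H\]- mass)
#'   columns, e.g. [consensus_hits()] joined to the feature keys.
#' @param ppm_window,bounds,electron_correction Passed to [predict_formulas()].
#' @return `hits` with `formulas` (list-column), `top_formula` and
#'   `unidentified` columns.
#' @export
annotate_hits <- function(hits, ppm_window = 100,
                          bounds = c(C = 40, H = 80, N = 6, O = 10),
                          electron_correction = TRUE) {
  stopifnot(all(c("feature_id", "mz") %in% names(hits)))
  cands <- purrr::map(hits$mz, predict_formulas, ppm_window = ppm_window,
                      bounds = bounds, electron_correction = electron_correction)
  dplyr::mutate(
    hits,
    formulas = cands,
    top_formula = purrr::map_chr(cands, ~ if (nrow(.x)) .x$formula[1] else NA_character_),
    unidentified = purrr::map_lgl(cands, ~ nrow(.x) == 0)
  )
}
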