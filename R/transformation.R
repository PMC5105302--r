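# Transformation-efficiency quantification and homology-arm summaries.

#' Convert a DNA mass to femtomoles of a linear fragment
#'
#' Uses an average molecular weight of 650 g/mol per base pair of
#' double-stranded DNA (configurable):
#' `fmol = mass_ug * 1e9 / (fragment_length_bp * mw_per_bp)`.
#'
#' @param dna_mass_ug DNA mass, micrograms (> 0).
#' @param fragment_length_bp Fragment length, bp (> 0).
#' @param mw_per_bp Average molecular weight per bp, g/mol.
#' @return Femtomoles of fragment (vectorized).
#' @examples
#' fmol_from_mass(0.5, 3000) # the standard transformation input
#' @export
fmol_from_mass <- function(dna_mass_ug, fragment_length_bp, mw_per_bp = 650) {
  if (any(dna_mass_ug <= 0) || any(fragment_length_bp <= 0) || mw_per_bp <= 0) {
    abort("dna_mass_ug, fragment_length_bp and mw_per_bp must be positive")
  }
  dna_mass_ug * 1e9 / (fragment_length_bp * mw_per_bp)
}

#' Transformation efficiency of plated observations
#'
#' Efficiency in cfu per fmol of DNA, corrected by the fraction of
#' PCR-screen-positive colonies:
#' `efficiency = cfu * dilution_factor / fmol * (n_positive / n_screened)`.
#'
#' @param obs Tibble of transformation-plate records with columns `cfu`,
#'   `dilution_factor`, `dna_mass_ug`, `fragment_length_bp`, `n_screened`,
#'   `n_positive` (extra columns are carried through).
#' @param mw_per_bp Average molecular weight per bp, g/mol.
#' @return `obs` with `fmol`, `positive_fraction` and `efficiency` columns
#'   appended.
#' @examples
#' obs <- tibble::tibble(
#'   cfu = 100, dilution_factor = 1, dna_mass_ug = 0.1625,
#'   fragment_length_bp = 1000, n_screened = 50, n_positive = 17
#' )
#' transformation_efficiency(obs)
#' @export
transformation_efficiency <- function(obs, mw_per_bp = 650) {
  required <- c("cfu", "dilution_factor", "dna_mass_ug",
                "fragment_length_bp", "n_screened", "n_positive")
  missing_cols <- setdiff(required, names(obs))
  if (length(missing_cols) > 0) {
    abort(paste("missing columns:", paste(missing_cols, collapse = ", ")))
  }
  if (any(obs$n_screened == 0)) {
    abort("n_screened = 0: positive fraction undefined")
  }
  if (any(obs$cfu < 0) || any(obs$n_positive > obs$n_screened) ||
      any(obs$n_positive < 0)) {
    abort("invalid counts (need cfu >= 0 and 0 <= n_positive <= n_screened)")
  }
  obs %>%
    mutate(
      fmol = fmol_from_mass(.data$dna_mass_ug, .data$fragment_length_bp,
                            mw_per_bp),
      positive_fraction = .data$n_positive / .data$n_screened,
      efficiency = .data$cfu * .data$dilution_factor / .data$fmol *
        .data$positive_fraction
    )
}

#' Summarize a homology-arm-length transformation experiment
#'
#' Per (arm length, incubation time) cell: mean and sample SD of the
#' per-plate efficiencies and positive fractions across biological
#' replicates, with monotonicity diagnostics (is mean efficiency
#' non-decreasing in arm length at each incubation time, and in time for
#' each arm length). Diagnostics are retrieved with [glance()].
#'
#' @param obs Transformation-plate tibble with `arm_length_bp` and
#'   `incubation_h` columns (see [transformation_efficiency()] for the
#'   rest).
#' @param mw_per_bp Average molecular weight per bp, g/mol.
#' @return A tibble of class `arm_experiment_summary`, one row per
#'   (arm_length_bp, incubation_h): `n`, `mean_efficiency`,
#'   `sd_efficiency`, `mean_positive_fraction`, `sd_positive_fraction`.
#' @export
summarize_arm_experiment <- function(obs, mw_per_bp = 650) {
  if (nrow(obs) == 0) abort("no observations")
  scored <- transformation_efficiency(obs, mw_per_bp)
  out <- scored %>%
    group_by(.data$arm_length_bp, .data$incubation_h) %>%
    summarise(
      n = dplyr::n(),
      mean_efficiency = mean(.data$efficiency),
      sd_efficiency = if (dplyr::n() >= 2) sd(.data$efficiency) else NA_real_,
      mean_positive_fraction = mean(.data$positive_fraction),
      sd_positive_fraction = if (dplyr::n() >= 2) {
        sd(.data$positive_fraction)
      } else {
        NA_real_
      },
      .groups = "drop"
    ) %>%
    arrange(.data$arm_length_bp, .data$incubation_h)
  by_time <- out %>%
    group_by(.data$incubation_h) %>%
    arrange(.data$arm_length_bp, .by_group = TRUE) %>%
    summarise(monotone = all(diff(.data$mean_efficiency) >= 0),
              .groups = "drop")
  by_arm <- out %>%
    group_by(.data$arm_length_bp) %>%
    arrange(.data$incubation_h, .by_group = TRUE) %>%
    summarise(monotone = all(diff(.data$mean_efficiency) >= 0),
              .groups = "drop")
  attr(out, "diagnostics") <- list(
    efficiency_monotone_in_arm_length = by_time,
    efficiency_monotone_in_time = by_arm
  )
  class(out) <- c("arm_experiment_summary", class(out))
  out
}

#' @exportS3Method generics::glance
glance.arm_experiment_summary <- function(x, ...) {
  d <- attr(x, "diagnostics")
  tibble(
    n_cells = nrow(x),
    monotone_in_arm_length = all(d$efficiency_monotone_in_arm_length$monotone),
    monotone_in_time = all(d$efficiency_monotone_in_time$monotone)
  )
}
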