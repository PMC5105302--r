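# Reporter-fluorescence promoter characterization: wild-type
# normalization, OD-gridded interpolation, strength tiers,
# regulatory-pattern classes, and transcriptome correlation.

#' Normalize strain fluorescence to the wild type at matched OD730
#'
#' Each strain sample's undiluted fluorescence
#' (`fluorescence * dilution_factor`) is divided by the wild-type
#' undiluted fluorescence linearly interpolated at the same OD730.
#' Wild-type replicates are pooled (ties averaged) to form the reference
#' curve. Strain samples whose OD falls outside the wild-type OD range are
#' dropped with a warning; no extrapolation is performed.
#'
#' @param strain Fluorescence series tibble (`strain_id`, `replicate`,
#'   `time_h`, `od730`, `fluorescence`, `dilution_factor`).
#' @param wildtype Wild-type series tibble, same columns.
#' @return `strain` with a `norm_fluor` column appended (out-of-range
#'   samples removed).
#' @export
normalize_to_wildtype <- function(strain, wildtype) {
  if (nrow(wildtype) < 2) abort("wild-type series needs >= 2 samples")
  wt_undiluted <- wildtype$fluorescence * wildtype$dilution_factor
  in_range <- strain$od730 >= min(wildtype$od730) &
    strain$od730 <= max(wildtype$od730)
  if (any(!in_range)) {
    warn(sprintf(
      "%d sample(s) outside the wild-type OD range [%.3g, %.3g] dropped",
      sum(!in_range), min(wildtype$od730), max(wildtype$od730)
    ))
  }
  kept <- strain[in_range, , drop = FALSE]
  wt_at <- approx(wildtype$od730, wt_undiluted, xout = kept$od730,
                  ties = mean, rule = 1)$y
  mutate(kept, norm_fluor = .data$fluorescence * .data$dilution_factor / wt_at)
}

#' Interpolate normalized fluorescence onto the reference OD grid
#'
#' Piecewise-linear interpolation of (OD730, value) measurements at the
#' reference ODs, matching how fluorescence readings are aligned with
#' transcriptomic profiles collected at fixed culture densities. Grid ODs
#' outside the measured range are reported as missing (`NA`), never
#' extrapolated.
#'
#' @param values Tibble with columns `od730` and `value` (one replicate's
#'   measurements).
#' @param od_grid Reference ODs, sorted ascending (default
#'   [reference_ods()]).
#' @return A tibble with columns `od` and `value` (one row per grid OD).
#' @examples
#' interpolate_at_reference_ods(
#'   tibble::tibble(od730 = c(0.2, 0.6), value = c(2, 4)),
#'   od_grid = 0.4
#' )
#' @export
interpolate_at_reference_ods <- function(values, od_grid = reference_ods()) {
  if (is.unsorted(od_grid, strictly = TRUE)) {
    abort("od_grid must be strictly ascending")
  }
  if (nrow(values) < 2) abort("need >= 2 measurements to interpolate")
  y <- approx(values$od730, values$value, xout = od_grid,
              ties = mean, rule = 1)$y
  tibble(od = od_grid, value = y)
}

#' Fit the expression-versus-OD slope
#'
#' Ordinary least squares of replicate-mean normalized fluorescence
#' against the grid OD730 values; missing grid points are skipped.
#'
#' @param profile Tibble with columns `od` and `value`.
#' @return Named numeric vector `c(slope, intercept)`.
#' @export
fit_expression_slope <- function(profile) {
  linear_fit(profile$od, profile$value)
}

#' Classify a promoter's regulatory pattern across growth
#'
#' Evaluates the OLS-fitted line at the lowest and highest grid ODs
#' (`f1`, `f2`) and computes the relative change `rho = (f2 - f1) / f1`.
#' A change of more than `threshold` (default 30%) upward is
#' stationary-phase expression, downward is linear-phase expression, and
#' anything in between is constitutive. Operating on the fitted line makes
#' the class invariant to uniform scaling of the profile.
#'
#' @param profile Tibble with columns `od` and `value` (replicate means on
#'   the reference grid).
#' @param threshold Relative-change threshold (default 0.30).
#' @return One of `"constitutive"`, `"linear_phase"`,
#'   `"stationary_phase"`.
#' @export
classify_regulatory_pattern <- function(profile, threshold = 0.30) {
  keep <- is.finite(profile$value)
  ods <- profile$od[keep]
  fit <- fit_expression_slope(profile[keep, , drop = FALSE])
  f1 <- fit[["intercept"]] + fit[["slope"]] * min(ods)
  f2 <- fit[["intercept"]] + fit[["slope"]] * max(ods)
  if (f1 <= 0) {
    abort("fitted expression at the lowest OD is not positive; relative change undefined")
  }
  rho <- (f2 - f1) / f1
  if (rho > threshold) {
    "stationary_phase"
  } else if (rho < -threshold) {
    "linear_phase"
  } else {
    "constitutive"
  }
}

#' Classify promoter strength from mean fold-change and significance
#'
#' Tiers induced from the observed groupings of the 25 characterized
#' PCC 7002 promoters: promoters not significantly above 1.5-fold over
#' wild type are not useful expression tools; 2- to 10-fold is moderate
#' (the 2- to 6-fold group); 10-fold and above is strong (the >30-fold
#' group). All cuts are configurable.
#'
#' @param mean_norm_fluor Mean normalized fluorescence, fold over wild
#'   type (> 0; vectorized).
#' @param p_value_vs_wt Two-tailed p value against the wild type
#'   (vectorized).
#' @param alpha Significance level (default 0.05).
#' @param cuts Tier boundaries `c(not_significant_max, weak_max,
#'   moderate_max)` (default `c(1.5, 2, 10)`).
#' @return Character vector of tiers: `"not_significant"`, `"weak"`,
#'   `"moderate"`, `"strong"`.
#' @export
classify_strength <- function(mean_norm_fluor, p_value_vs_wt,
                              alpha = 0.05, cuts = c(1.5, 2, 10)) {
  if (any(mean_norm_fluor <= 0)) abort("mean_norm_fluor must be positive")
  dplyr::case_when(
    is.na(p_value_vs_wt) | p_value_vs_wt >= alpha |
      mean_norm_fluor <= cuts[1] ~ "not_significant",
    mean_norm_fluor < cuts[2] ~ "weak",
    mean_norm_fluor < cuts[3] ~ "moderate",
    TRUE ~ "strong"
  )
}

#' Correlate a fluorescence profile with a transcript-abundance profile
#'
#' Pearson product-moment correlation of replicate-mean normalized
#' fluorescence against transcript abundance (counts/total counts) over
#' the shared, non-missing grid ODs.
#'
#' @param fluor Tibble with columns `od`, `value` (fluorescence).
#' @param rna Tibble with columns `od`, `value` (transcript abundance).
#' @return Pearson r in \[-1, 1\], or `NA` when undefined (zero variance)
#'   or fewer than 3 shared points.
#' @export
correlate_profiles <- function(fluor, rna) {
  joined <- dplyr::inner_join(fluor, rna, by = "od",
                              suffix = c("_fluor", "_rna")) %>%
    filter(is.finite(.data$value_fluor), is.finite(.data$value_rna))
  if (nrow(joined) < 3) {
    return(NA_real_)
  }
  pearson_r(joined$value_fluor, joined$value_rna)
}

#' Characterize promoters from plate-reader time courses
#'
#' The full reporter pipeline for a plate of strains: normalize every
#' strain to the wild type at matched OD ([normalize_to_wildtype()]),
#' interpolate each replicate onto the reference OD grid
#' ([interpolate_at_reference_ods()]), average replicates, then fit the
#' expression slope, classify the regulatory pattern and strength tier,
#' test each strain against the wild type (two-sample equal-variance t
#' test on per-replicate mean normalized fluorescence, two-tailed), and,
#' when transcript profiles are supplied, correlate fluorescence with
#' transcript abundance.
#'
#' @param plates Fluorescence tibble for all strains including the wild
#'   type (`strain_id`, `replicate`, `time_h`, `od730`, `fluorescence`,
#'   `dilution_factor`).
#' @param wildtype_id `strain_id` of the wild type.
#' @param od_grid Reference ODs (default [reference_ods()]).
#' @param rnaseq Optional transcript profiles: tibble with columns
#'   `locus`, `od`, `value`, where `locus` matches `strain_id`.
#' @param pattern_threshold Relative-change threshold for
#'   [classify_regulatory_pattern()].
#' @param alpha,cuts Passed to [classify_strength()].
#' @return A tibble of class `promoter_characterization`, one row per
#'   promoter: `promoter_id`, `mean_norm_fluor`, `sd_norm_fluor`,
#'   `slope`, `intercept`, `regulatory_class`, `strength_tier`,
#'   `p_value_vs_wt`, `correlation_r`, `n_replicates`. Per-replicate grid
#'   profiles are attached as attribute `"profiles"`.
#' @export
characterize_promoters <- function(plates, wildtype_id = "WT",
                                   od_grid = reference_ods(), rnaseq = NULL,
                                   pattern_threshold = 0.30, alpha = 0.05,
                                   cuts = c(1.5, 2, 10)) {
  if (!wildtype_id %in% plates$strain_id) {
    abort(sprintf("wild-type strain '%s' not found in plates", wildtype_id))
  }
  wt <- filter(plates, .data$strain_id == wildtype_id)
  # per-strain, per-replicate profiles on the reference grid
  profiles <- plates %>%
    group_by(.data$strain_id, .data$replicate) %>%
    dplyr::group_modify(function(df, key) {
      normed <- normalize_to_wildtype(
        mutate(df, strain_id = key$strain_id, replicate = key$replicate), wt
      )
      interpolate_at_reference_ods(
        rename(normed, value = "norm_fluor"), od_grid
      )
    }) %>%
    ungroup()
  # per-replicate mean normalized fluorescence (for the strain-vs-WT test)
  rep_means <- profiles %>%
    filter(is.finite(.data$value)) %>%
    group_by(.data$strain_id, .data$replicate) %>%
    summarise(rep_mean = mean(.data$value), .groups = "drop")
  wt_rep_means <- filter(rep_means, .data$strain_id == wildtype_id)$rep_mean
  strain_ids <- setdiff(unique(plates$strain_id), wildtype_id)
  rows <- purrr::map(strain_ids, function(sid) {
    prof_mean <- profiles %>%
      filter(.data$strain_id == sid) %>%
      group_by(.data$od) %>%
      summarise(value = mean(.data$value[is.finite(.data$value)]),
                .groups = "drop")
    sm <- filter(rep_means, .data$strain_id == sid)$rep_mean
    p_val <- if (length(sm) >= 2 && length(wt_rep_means) >= 2) {
      # zero pooled variance (noise-free data) is the limiting case:
      # any mean difference is then infinitely many SEs away
      tryCatch(
        two_sample_ttest_equal_var(sm, wt_rep_means)$p_two_tail,
        error = function(e) {
          if (isTRUE(all.equal(mean(sm), mean(wt_rep_means)))) 1 else 0
        }
      )
    } else {
      NA_real_
    }
    fit <- fit_expression_slope(prof_mean)
    corr <- if (!is.null(rnaseq) && sid %in% rnaseq$locus) {
      correlate_profiles(
        prof_mean,
        rnaseq %>% filter(.data$locus == sid) %>% select("od", "value")
      )
    } else {
      NA_real_
    }
    ms <- mean_sd(sm)
    tibble(
      promoter_id = sid,
      mean_norm_fluor = ms[["mean"]],
      sd_norm_fluor = ms[["sd"]],
      slope = fit[["slope"]],
      intercept = fit[["intercept"]],
      regulatory_class = classify_regulatory_pattern(prof_mean,
                                                     pattern_threshold),
      strength_tier = classify_strength(ms[["mean"]],
                                        p_val %||% NA_real_,
                                        alpha, cuts),
      p_value_vs_wt = p_val,
      correlation_r = corr,
      n_replicates = length(sm)
    )
  })
  out <- bind_rows(rows)
  attr(out, "profiles") <- profiles
  attr(out, "wildtype_id") <- wildtype_id
  class(out) <- c("promoter_characterization", class(out))
  out
}
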