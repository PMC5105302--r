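series <- function(strain_id, od, fluor, dilution = 1, replicate = 1) {
  tibble::tibble(
    strain_id = strain_id, replicate = replicate,
    time_h = seq_along(od), od730 = od,
    fluorescence = fluor, dilution_factor = dilution
  )
}

test_that("wild-type normalization divides by the OD-matched interpolated signal", {
  od <- c(0.2, 0.5, 1, 2, 4, 6)
  wt <- series("WT", od, 100 * od)
  # self-normalization is exactly 1
  self <- normalize_to_wildtype(wt, wt)
  expect_equal(self$norm_fluor, rep(1, 6))
  # a constant 31.88-fold strain recovers the fold at every OD
  strain <- series("S", od, 31.88 * 100 * od)
  expect_equal(normalize_to_wildtype(strain, wt)$norm_fluor, rep(31.88, 6))
  # fold recovery is exact off the wild-type sampling points too, because
  # both the wild type and the strain are piecewise-linear in OD
  off <- series("S", c(0.3, 1.5, 5), 7 * 100 * c(0.3, 1.5, 5))
  expect_equal(normalize_to_wildtype(off, wt)$norm_fluor, rep(7, 3))
  # dilution factors undo before normalizing
  diluted <- series("S", od, 31.88 * 100 * od / 10, dilution = 10)
  expect_equal(normalize_to_wildtype(diluted, wt)$norm_fluor, rep(31.88, 6))
  # out-of-range samples are dropped with a warning, never extrapolated
  wide <- series("S", c(0.1, 1, 8), c(10, 100, 800))
  expect_warning(kept <- normalize_to_wildtype(wide, wt), "dropped")
  expect_equal(kept$od730, 1)
})

test_that("reference-OD interpolation is piecewise-linear with no extrapolation", {
  # midpoint
  mid <- interpolate_at_reference_ods(
    tibble::tibble(od730 = c(0.2, 0.6), value = c(2, 4)), od_grid = 0.4
  )
  expect_equal(mid$value, 3)
  # measurements exactly on the grid pass through unchanged
  grid <- reference_ods()
  exact <- interpolate_at_reference_ods(
    tibble::tibble(od730 = grid, value = c(5, 4, 3, 2, 1))
  )
  expect_equal(exact$value, c(5, 4, 3, 2, 1))
  # exact on piecewise-linear truth sampled off-grid
  withr::with_seed(51, {
    for (i in 1:10) {
      slope <- runif(1, -2, 2)
      icpt <- runif(1, 3, 10)
      od <- sort(c(0.1, 6, runif(10, 0.1, 6))) # brackets the whole grid
      got <- interpolate_at_reference_ods(
        tibble::tibble(od730 = od, value = icpt + slope * od)
      )
      expect_equal(got$value, icpt + slope * grid, tolerance = 1e-10)
    }
  })
  # grid points outside the measured range are missing, not extrapolated
  short <- interpolate_at_reference_ods(
    tibble::tibble(od730 = c(0.5, 2), value = c(1, 1))
  )
  expect_true(is.na(short$value[1]) && is.na(short$value[5]))
  expect_error(
    interpolate_at_reference_ods(tibble::tibble(od730 = 1, value = 1)),
    ">= 2"
  )
})

test_that("expression slope is the OLS line over the grid profile", {
  flat <- tibble::tibble(od = reference_ods(), value = 1)
  expect_equal(fit_expression_slope(flat)[["slope"]], 0)
  line <- tibble::tibble(od = reference_ods(), value = 2 * reference_ods())
  expect_equal(fit_expression_slope(line),
               c(slope = 2, intercept = 0), tolerance = 1e-12)
})

test_that("regulatory pattern follows the 30% relative-change rule on the fitted line", {
  grid <- reference_ods()
  flat <- tibble::tibble(od = grid, value = rep(1, 5))
  expect_equal(classify_regulatory_pattern(flat), "constitutive")
  # rising from 1.0 at OD 0.4 to 1.5 at OD 5.0: a 50% relative change
  rising <- tibble::tibble(od = grid, value = 1 + 0.5 * (grid - 0.4) / 4.6)
  expect_equal(classify_regulatory_pattern(rising), "stationary_phase")
  falling <- tibble::tibble(od = grid, value = 2 - 0.8 * (grid - 0.4) / 4.6)
  expect_equal(classify_regulatory_pattern(falling), "linear_phase")
  # scale invariance: the class depends only on relative change
  expect_equal(classify_regulatory_pattern(dplyr::mutate(rising, value = value * 250)),
               "stationary_phase")
  expect_error(
    classify_regulatory_pattern(tibble::tibble(od = grid, value = grid - 3)),
    "not positive"
  )
})

test_that("noise-free synthetic promoters round-trip through the classifier", {
  growth <- simulate_growth(growth_model())
  cfg <- sim_config(seed = 8)
  for (pat in c("constitutive", "linear_phase", "stationary_phase")) {
    tr <- promoter_truth("P", strength = 4, pattern = pat, noise_cv = 0)
    plates <- simulate_fluorescence(tr, growth, cfg)
    res <- characterize_promoters(plates, wildtype_id = "WT")
    expect_equal(res$regulatory_class, pat)
    expect_equal(res$mean_norm_fluor, 4, tolerance = 1e-10)
    expect_equal(res$strength_tier, "moderate")
  }
  # a planted strong stationary-phase promoter is called (strong, stationary)
  strong <- promoter_truth("A2520", strength = 31.88,
                           pattern = "stationary_phase", noise_cv = 0)
  res <- characterize_promoters(simulate_fluorescence(strong, growth, cfg))
  expect_equal(res$strength_tier, "strong")
  expect_equal(res$regulatory_class, "stationary_phase")
})

test_that("strength tiers combine the fold cutoffs with wild-type significance", {
  expect_equal(classify_strength(1.0, 0.001), "not_significant")
  expect_equal(classify_strength(4.153, 0.01), "moderate")
  expect_equal(classify_strength(33.51, 0.01), "strong")
  expect_equal(classify_strength(1.8, 0.01), "weak")
  expect_equal(classify_strength(1.8, 0.2), "not_significant")
  expect_equal(classify_strength(40, NA_real_), "not_significant")
  # the 25 characterized promoters partition into 7 above wild type:
  # 5 moderate and 2 strong
  ref <- pcc7002_promoters()
  tiers <- classify_strength(ref$mean_norm_fluor,
                             ifelse(ref$significant, 0.01, 1))
  expect_equal(sum(tiers != "not_significant"), 7)
  expect_equal(sum(tiers == "moderate"), 5)
  expect_equal(sum(tiers == "strong"), 2)
  expect_equal(ref$locus[tiers == "strong"], c("A2520", "A2579"))
})

test_that("profile correlation is Pearson over shared grid points", {
  grid <- reference_ods()
  rna <- tibble::tibble(od = grid, value = c(1, 2, 3, 5, 8) * 1e-4)
  up <- tibble::tibble(od = grid, value = 3 * rna$value + 0.5)
  down <- tibble::tibble(od = grid, value = -2 * rna$value + 1)
  expect_equal(correlate_profiles(up, rna), 1)
  expect_equal(correlate_profiles(down, rna), -1)
  withr::with_seed(52, {
    for (i in 1:5) {
      x <- rnorm(5)
      y <- rnorm(5)
      fl <- tibble::tibble(od = grid, value = x)
      rn <- tibble::tibble(od = grid, value = y)
      manual <- sum((x - mean(x)) * (y - mean(y))) /
        sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
      expect_equal(correlate_profiles(fl, rn), manual, tolerance = 1e-12)
    }
  })
  # fewer than 3 shared finite points: undefined
  short <- tibble::tibble(od = grid[1:2], value = c(1, 2))
  expect_true(is.na(correlate_profiles(short, rna)))
})

test_that("normalization and grid interpolation commute on piecewise-linear data", {
  od <- c(0.2, 0.5, 1, 2, 4, 6)
  wt <- series("WT", od, 50 + 80 * od)
  strain <- series("S", od, 3 * (50 + 80 * od))
  # route 1: normalize at measured ODs, then interpolate the ratio
  r1 <- interpolate_at_reference_ods(
    dplyr::rename(normalize_to_wildtype(strain, wt), value = norm_fluor)
  )
  # route 2: interpolate strain and wild type separately, then divide
  s_i <- interpolate_at_reference_ods(
    tibble::tibble(od730 = od, value = strain$fluorescence)
  )
  w_i <- interpolate_at_reference_ods(
    tibble::tibble(od730 = od, value = wt$fluorescence)
  )
  r2 <- s_i$value / w_i$value
  expect_equal(r1$value, r2, tolerance = 1e-12)
  expect_equal(r1$value, rep(3, 5), tolerance = 1e-12)
})

test_that("result objects expose tidy, glance and autoplot interfaces", {
  growth <- simulate_growth(growth_model())
  cfg <- sim_config(seed = 9)
  plates <- dplyr::bind_rows(
    simulate_fluorescence(
      promoter_truth("P_strong", 20, "stationary_phase", noise_cv = 0.05),
      growth, cfg
    ),
    dplyr::filter(
      simulate_fluorescence(
        promoter_truth("P_weak", 1.2, "constitutive", noise_cv = 0.05),
        growth, cfg
      ),
      strain_id != "WT"
    )
  )
  rnaseq <- tibble::tibble(
    locus = "P_strong", od = reference_ods(), value = c(1, 2, 3, 5, 8) * 1e-4
  )
  res <- characterize_promoters(plates, rnaseq = rnaseq)
  expect_s3_class(res, "promoter_characterization")
  td <- tidy(res)
  expect_false(inherits(td, "promoter_characterization"))
  expect_equal(nrow(td), 2)
  gl <- glance(res)
  expect_equal(gl$n_promoters, 2)
  expect_true(is.finite(res$correlation_r[res$promoter_id == "P_strong"]))
  expect_true(is.na(res$correlation_r[res$promoter_id == "P_weak"]))
  expect_s3_class(autoplot(res), "ggplot")
  expect_s3_class(plot_fluorescence_series(plates), "ggplot")
})
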