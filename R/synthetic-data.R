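# Synthetic-data generators with planted ground truth.
#
# Every input the pipeline consumes can be generated here, so each analysis
# stage has a generative inverse to test against: growth curves, reporter
# fluorescence plate reads, qPCR C_T tables, genome annotations with planted
# intergenic gaps, and transformation-plate records.

#' Reference OD730 grid for promoter profiling
#'
#' The cell densities at which normalized fluorescence is tabulated,
#' matching the ODs at which the reference transcriptomic profiles of
#' *Synechococcus* sp. PCC 7002 were collected.
#'
#' @return Numeric vector `c(0.4, 0.7, 1.0, 3.0, 5.0)`.
#' @export
reference_ods <- function() c(0.4, 0.7, 1.0, 3.0, 5.0)

#' Growth model: short exponential phase, then linear light-limited phase
#'
#' Batch cultures of *Synechococcus* sp. PCC 7002 under moderate light show
#' a very short exponential phase followed by a long linear, light-limited
#' phase. The model is exponential from `od0` up to `od_switch`, then
#' linear at `linear_rate`, continuous at the switch. The default linear
#' rate is the wild-type mean (0.0334 OD730/h).
#'
#' @param od0 Initial OD730 (> 0).
#' @param mu Exponential specific growth rate, 1/h (>= 0; 0 requires
#'   `od_switch == od0`).
#' @param od_switch OD730 at the exponential-to-linear transition
#'   (>= `od0`).
#' @param linear_rate Linear-phase growth rate, OD730/h (> 0).
#' @param duration Total simulated time, h (> 0).
#' @return A list of class `growth_model`.
#' @examples
#' simulate_growth(growth_model(), times = seq(0, 168, by = 24))
#' @export
growth_model <- function(od0 = 0.05, mu = 0.25, od_switch = 0.4,
                         linear_rate = 0.0334, duration = 240) {
  if (!all(od0 > 0, linear_rate > 0, duration > 0)) {
    abort("od0, linear_rate and duration must be positive")
  }
  if (mu < 0) abort("mu must be non-negative")
  if (od_switch < od0) abort("od_switch must be >= od0")
  if (mu == 0 && od_switch > od0) {
    abort("mu = 0 requires od_switch == od0 (no exponential phase)")
  }
  structure(
    list(od0 = od0, mu = mu, od_switch = od_switch,
         linear_rate = linear_rate, duration = duration),
    class = "growth_model"
  )
}

#' Simulate an OD730 growth trajectory
#'
#' Deterministic evaluation of a [growth_model()] at the sampling times:
#' `od0 * exp(mu * t)` until the culture reaches `od_switch`, then
#' `od_switch + linear_rate * (t - t_switch)`.
#'
#' @param model A [growth_model()].
#' @param times Sampling times in hours, sorted ascending.
#' @return A tibble with columns `time_h`, `od730`.
#' @export
simulate_growth <- function(model, times = seq(0, model$duration, by = 12)) {
  stopifnot(inherits(model, "growth_model"))
  if (is.unsorted(times)) abort("times must be sorted ascending")
  t_switch <- if (model$mu > 0) log(model$od_switch / model$od0) / model$mu else 0
  od <- ifelse(
    times <= t_switch,
    model$od0 * exp(model$mu * times),
    model$od_switch + model$linear_rate * (times - t_switch)
  )
  tibble(time_h = as.numeric(times), od730 = od)
}

#' Planted ground truth for one promoter
#'
#' Describes the promoter a simulation should emulate: its mean normalized
#' fluorescence over the reference OD grid (`strength`, fold over wild
#' type), its regulatory pattern, its light:dark expression ratio, and the
#' coefficient of variation of multiplicative plate-reader noise.
#'
#' @param promoter_id Strain/promoter label.
#' @param strength Mean normalized fluorescence, fold over wild type (> 0).
#' @param pattern One of `"constitutive"`, `"linear_phase"`,
#'   `"stationary_phase"`.
#' @param light_dark_ratio Expression ratio light/dark (> 0).
#' @param noise_cv Coefficient of variation of multiplicative lognormal
#'   fluorescence noise (>= 0).
#' @param pattern_span Relative rise (stationary phase) or fall (linear
#'   phase) of the noise-free normalized profile across the reference OD
#'   range; the default 0.6 sits well beyond the 30% classification rule.
#' @return A list of class `promoter_truth`.
#' @export
promoter_truth <- function(promoter_id, strength = 1,
                           pattern = c("constitutive", "linear_phase",
                                       "stationary_phase"),
                           light_dark_ratio = 1, noise_cv = 0.1,
                           pattern_span = 0.6) {
  pattern <- match.arg(pattern)
  if (strength <= 0) abort("strength must be positive")
  if (light_dark_ratio <= 0) abort("light_dark_ratio must be positive")
  if (noise_cv < 0) abort("noise_cv must be non-negative")
  if (pattern_span <= 0 || pattern_span >= 1 / 0.6) {
    abort("pattern_span must lie in (0, 1.67) so profiles stay positive")
  }
  structure(
    list(promoter_id = promoter_id, strength = strength, pattern = pattern,
         light_dark_ratio = light_dark_ratio, noise_cv = noise_cv,
         pattern_span = pattern_span),
    class = "promoter_truth"
  )
}

#' Simulation configuration
#'
#' @param seed Integer seed; a fixed seed gives byte-identical generator
#'   output.
#' @param n_biological_replicates Biological replicates per strain
#'   (default 2, the qRT-PCR design).
#' @param n_technical_replicates qPCR technical replicates per well
#'   (default 3).
#' @param ct_sd Additive Gaussian C_T noise, cycles (>= 0).
#' @param sampling_times Plate-read sampling times, h.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1, n_biological_replicates = 2,
                       n_technical_replicates = 3, ct_sd = 0.3,
                       sampling_times = seq(0, 240, by = 12)) {
  if (n_biological_replicates < 1 || n_technical_replicates < 1) {
    abort("replicate counts must be >= 1")
  }
  if (ct_sd < 0) abort("ct_sd must be non-negative")
  structure(
    list(seed = as.integer(seed),
         n_biological_replicates = as.integer(n_biological_replicates),
         n_technical_replicates = as.integer(n_technical_replicates),
         ct_sd = ct_sd, sampling_times = sampling_times),
    class = "sim_config"
  )
}

#' Noise-free expected normalized fluorescence of a planted promoter
#'
#' The generative shape behind [simulate_fluorescence()]: linear in OD730,
#' centred so that its mean over the reference grid equals the planted
#' `strength`. Constitutive promoters are flat; stationary-phase promoters
#' rise and linear-phase promoters fall by `pattern_span` (relative to
#' strength) across the reference OD range, so the 30% relative-change
#' classification rule has an exact generative counterpart.
#'
#' @param truth A [promoter_truth()].
#' @param od OD730 values at which to evaluate.
#' @param od_grid Reference grid used for centring (default
#'   [reference_ods()]).
#' @return Numeric vector of expected normalized fluorescence (fold over
#'   wild type) at `od`.
#' @export
expected_normalized_fluorescence <- function(truth, od,
                                             od_grid = reference_ods()) {
  stopifnot(inherits(truth, "promoter_truth"))
  rho <- switch(truth$pattern,
    constitutive = 0,
    stationary_phase = truth$pattern_span,
    linear_phase = -truth$pattern_span
  )
  frac <- (od - min(od_grid)) / (max(od_grid) - min(od_grid))
  frac_centre <- mean((od_grid - min(od_grid)) / (max(od_grid) - min(od_grid)))
  truth$strength * (1 + rho * (frac - frac_centre))
}

# absolute wild-type fluorescence model: proportional to cell density
wildtype_fluorescence <- function(od, per_od = 2000) per_od * od

# plate-reader saturation: dilute by powers of 10 until under range
plate_dilution <- function(fluor, saturation = 65000) {
  ifelse(fluor <= saturation, 1, 10^ceiling(log10(fluor / saturation)))
}

#' Simulate reporter-fluorescence plate reads for one promoter strain
#'
#' Generates plate-reader time courses for `cfg$n_biological_replicates`
#' replicates of the promoter strain plus matched wild-type replicates.
#' Absolute fluorescence is the wild-type signal (proportional to OD730)
#' times the promoter's expected normalized profile, with multiplicative
#' lognormal noise of coefficient of variation `truth$noise_cv`. Samples
#' that would saturate the detector are recorded at a power-of-ten
#' dilution, mirroring how over-range wells are diluted with medium before
#' re-reading; `fluorescence * dilution_factor` recovers the undiluted
#' signal.
#'
#' @param truth A [promoter_truth()].
#' @param growth Growth trajectory tibble (`time_h`, `od730`) spanning at
#'   least OD 0.4-5.0.
#' @param cfg A [sim_config()].
#' @param wildtype_id Strain label for the wild-type series.
#' @return A tibble with columns `strain_id`, `replicate`, `time_h`,
#'   `od730`, `fluorescence`, `dilution_factor`.
#' @export
simulate_fluorescence <- function(truth, growth, cfg = sim_config(),
                                  wildtype_id = "WT") {
  stopifnot(inherits(truth, "promoter_truth"), inherits(cfg, "sim_config"))
  grid <- reference_ods()
  if (min(growth$od730) > min(grid) || max(growth$od730) < max(grid)) {
    abort(sprintf(
      "growth range [%.2f, %.2f] does not cover the reference ODs [%.1f, %.1f]",
      min(growth$od730), max(growth$od730), min(grid), max(grid)
    ))
  }
  sdlog <- sqrt(log(1 + truth$noise_cv^2))
  one_series <- function(strain_id, rep_i, norm_profile, label) {
    with_stream(cfg$seed, paste("fluor", label, strain_id, rep_i), {
      mu <- wildtype_fluorescence(growth$od730) * norm_profile
      noise <- if (sdlog > 0) {
        exp(rnorm(length(mu), mean = -sdlog^2 / 2, sd = sdlog))
      } else {
        rep(1, length(mu))
      }
      undiluted <- mu * noise
      dil <- plate_dilution(undiluted)
      tibble(
        strain_id = strain_id, replicate = rep_i,
        time_h = growth$time_h, od730 = growth$od730,
        fluorescence = undiluted / dil, dilution_factor = dil
      )
    })
  }
  strain_norm <- expected_normalized_fluorescence(truth, growth$od730)
  reps <- seq_len(cfg$n_biological_replicates)
  bind_rows(
    purrr::map(reps, function(r) {
      one_series(truth$promoter_id, r, strain_norm, "strain")
    }),
    purrr::map(reps, function(r) {
      one_series(wildtype_id, r, rep(1, nrow(growth)), "wt")
    })
  )
}

#' Simulate a qPCR C_T table with a planted light:dark ratio
#'
#' Inverse generative model of 2^-ddCT quantification: the target gene's
#' light-condition C_T differs from its dark-condition C_T by
#' `-log2(light_dark_ratio)` in expectation; the reference gene's C_T is
#' identical across conditions in expectation; technical replicates are
#' i.i.d. Gaussian around their cell means with SD `cfg$ct_sd`.
#'
#' @param truth A [promoter_truth()] (uses `promoter_id` and
#'   `light_dark_ratio`).
#' @param cfg A [sim_config()].
#' @param target_gene,reference_gene Gene labels written into the table.
#' @param target_ct_dark,reference_ct Baseline C_T means (cycles).
#' @return A tibble with columns `strain_id`, `gene`, `condition`,
#'   `biological_replicate`, `technical_replicate`, `ct`.
#' @export
simulate_qpcr <- function(truth, cfg = sim_config(),
                          target_gene = "ypet", reference_gene = "rnpA",
                          target_ct_dark = 24, reference_ct = 18) {
  stopifnot(inherits(truth, "promoter_truth"), inherits(cfg, "sim_config"))
  cells <- tidyr::expand_grid(
    gene = c(target_gene, reference_gene),
    condition = c("light", "dark"),
    biological_replicate = seq_len(cfg$n_biological_replicates)
  ) %>%
    mutate(mean_ct = case_when(
      .data$gene == target_gene & .data$condition == "light" ~
        target_ct_dark - log2(truth$light_dark_ratio),
      .data$gene == target_gene ~ target_ct_dark,
      TRUE ~ reference_ct
    ))
  with_stream(cfg$seed, paste("qpcr", truth$promoter_id), {
    cells %>%
      tidyr::expand_grid(technical_replicate = seq_len(cfg$n_technical_replicates)) %>%
      mutate(
        strain_id = truth$promoter_id,
        ct = .data$mean_ct + rnorm(n(), 0, cfg$ct_sd)
      ) %>%
      select("strain_id", "gene", "condition", "biological_replicate",
             "technical_replicate", "ct")
  })
}

#' Generate a genome annotation with planted intergenic gaps
#'
#' Emits gene features that tile a chromosome completely except for the
#' planted gaps plus small inter-feature spaces below the detection
#' threshold, so an intergenic-gap finder run with that threshold must
#' recover exactly the planted gaps.
#'
#' @param n_genes Approximate number of gene features to emit.
#' @param planted_gaps List (or two-column matrix/data frame) of
#'   `(start, end)` 1-based inclusive unannotated ranges; non-overlapping,
#'   within the chromosome, not touching its ends.
#' @param chrom_len Chromosome length, bp.
#' @param seed Integer seed (byte-identical output for a fixed seed).
#' @param chrom Chromosome name.
#' @param max_space Largest inter-feature space emitted outside planted
#'   gaps, bp; must stay below the finder's `min_len`.
#' @param mean_gene Target mean feature length, bp.
#' @param locus_prefix Prefix for generated locus tags.
#' @return A tibble of annotation records (`locus_tag`, `chrom`, `start`,
#'   `end`, `strand`, `feature_type`, `product`).
#' @export
generate_annotation <- function(n_genes, planted_gaps, chrom_len, seed = 1,
                                chrom = "chr", max_space = 200,
                                mean_gene = NULL,
                                locus_prefix = "SYN_A") {
  gaps <- normalize_planted_gaps(planted_gaps, chrom_len)
  # covered segments = complement of the planted gaps
  seg_start <- c(1, gaps$end + 1)
  seg_end <- c(gaps$start - 1, chrom_len)
  segs <- tibble(start = seg_start, end = seg_end) %>%
    filter(.data$end >= .data$start)
  if (is.null(mean_gene)) {
    covered <- sum(segs$end - segs$start + 1)
    mean_gene <- max(200, round(covered / max(n_genes, 1)) - max_space / 2)
  }
  with_stream(seed, "annotation", {
    feats <- purrr::pmap(segs, function(start, end) {
      tile_segment(start, end, mean_gene = mean_gene, max_space = max_space)
    })
    out <- bind_rows(feats) %>% arrange(.data$start)
    out %>%
      mutate(
        locus_tag = sprintf("%s%04d", locus_prefix, row_number()),
        chrom = chrom,
        strand = sample(c("+", "-"), n(), replace = TRUE),
        feature_type = "gene",
        product = "hypothetical protein"
      ) %>%
      select("locus_tag", "chrom", "start", "end", "strand",
             "feature_type", "product")
  })
}

normalize_planted_gaps <- function(planted_gaps, chrom_len) {
  if (is.null(planted_gaps) || length(planted_gaps) == 0) {
    return(tibble(start = integer(), end = integer()))
  }
  if (is.list(planted_gaps) && !is.data.frame(planted_gaps)) {
    planted_gaps <- do.call(rbind, lapply(planted_gaps, function(g) {
      tibble(start = g[[1]], end = g[[2]])
    }))
  }
  gaps <- as_tibble(planted_gaps)
  names(gaps)[1:2] <- c("start", "end")
  gaps <- arrange(gaps, .data$start)
  if (any(gaps$start > gaps$end)) abort("planted gap with start > end")
  if (min(gaps$start) <= 1 || max(gaps$end) >= chrom_len) {
    abort("planted gaps must lie strictly inside the chromosome")
  }
  if (nrow(gaps) > 1 && any(gaps$start[-1] <= gaps$end[-nrow(gaps)] + 1)) {
    abort("planted gaps overlap or touch; they must be separated by >= 1 gene")
  }
  gaps
}

# tile [start, end] with gene features separated by spaces < max_space,
# with the first feature starting at `start` and the last ending at `end`
tile_segment <- function(start, end, mean_gene = 900, max_space = 200) {
  len <- end - start + 1
  n <- max(1L, round(len / (mean_gene + max_space / 2)))
  repeat {
    spaces <- if (n > 1) sample(0:max_space, n - 1, replace = TRUE) else integer()
    body <- len - sum(spaces)
    if (body >= n * 50) break # every gene at least 50 bp
    n <- n - 1L
  }
  # split body bp among n genes, each >= 50
  extra <- body - n * 50
  cuts <- if (n > 1) sort(sample(0:extra, n - 1, replace = TRUE)) else integer()
  gene_len <- 50 + diff(c(0, cuts, extra))
  starts <- start + cumsum(c(0, head(gene_len, -1) + spaces))
  tibble(start = starts, end = starts + gene_len - 1)
}

#' Simulate a transformation-plate observation
#'
#' Colony counts are Poisson around the expectation implied by the
#' transformation-efficiency formula, so the efficiency estimator applied
#' to the output recovers the planted efficiency in expectation; the PCR
#' screen is binomial around the planted positive fraction.
#'
#' @param efficiency Planted transformation efficiency, cfu/fmol (>= 0).
#' @param fmol DNA amount, fmol (> 0).
#' @param dilution Plating dilution factor (>= 1).
#' @param frac_positive Planted fraction of colonies with confirmed
#'   integration, in \[0, 1\] (> 0 unless `efficiency` is 0).
#' @param seed Integer seed.
#' @param n_screened Colonies re-plated for PCR screening (default 50).
#' @param dna_mass_ug,fragment_length_bp Recorded alongside the counts;
#'   defaults chosen so that [fmol_from_mass()] of them equals `fmol`.
#' @param incubation_h,arm_length_bp Experimental condition labels.
#' @return A one-row tibble of transformation-plate fields (`cfu`,
#'   `dilution_factor`, `dna_mass_ug`, `fragment_length_bp`, `n_screened`,
#'   `n_positive`, `incubation_h`, `arm_length_bp`).
#' @export
simulate_transformation <- function(efficiency, fmol, dilution = 1,
                                    frac_positive = 1, seed = 1,
                                    n_screened = 50,
                                    dna_mass_ug = NULL,
                                    fragment_length_bp = 3000,
                                    incubation_h = 4, arm_length_bp = 500) {
  if (efficiency < 0 || fmol <= 0 || dilution <= 0) {
    abort("efficiency must be >= 0; fmol and dilution must be positive")
  }
  if (frac_positive < 0 || frac_positive > 1) {
    abort("frac_positive must lie in [0, 1]")
  }
  if (efficiency > 0 && frac_positive == 0) {
    abort("frac_positive must be positive when efficiency is positive")
  }
  if (is.null(dna_mass_ug)) {
    dna_mass_ug <- fmol * fragment_length_bp * 650 / 1e9
  }
  with_stream(seed, "transformation", {
    lambda <- if (efficiency == 0) 0 else {
      efficiency * fmol / dilution / frac_positive
    }
    cfu <- rpois(1, lambda)
    n_pos <- rbinom(1, n_screened, frac_positive)
    tibble(
      cfu = cfu, dilution_factor = dilution, dna_mass_ug = dna_mass_ug,
      fragment_length_bp = fragment_length_bp, n_screened = n_screened,
      n_positive = n_pos, incubation_h = incubation_h,
      arm_length_bp = arm_length_bp
    )
  })
}
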