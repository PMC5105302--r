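# One-call synthetic study: every pipeline input with a ground-truth
# sidecar, written as plain-text fixtures.

#' Default planted promoter panel for simulated studies
#'
#' A small panel spanning the observed range of promoter behaviour: a
#' wild-type-level constitutive promoter, moderate constitutive and
#' linear-phase promoters, a strong stationary-phase promoter, and
#' light-responsive promoters on both sides of the diurnal convention.
#'
#' @param noise_cv Plate-reader noise CV applied to every panel member.
#' @return A list of [promoter_truth()] objects.
#' @export
default_promoter_panel <- function(noise_cv = 0.1) {
  list(
    promoter_truth("P_base", strength = 1.1, pattern = "constitutive",
                   light_dark_ratio = 1, noise_cv = noise_cv),
    promoter_truth("P_mod_con", strength = 4, pattern = "constitutive",
                   light_dark_ratio = 1.2, noise_cv = noise_cv),
    promoter_truth("P_mod_lin", strength = 3, pattern = "linear_phase",
                   light_dark_ratio = 1.85, noise_cv = noise_cv),
    promoter_truth("P_strong_sta", strength = 31.88,
                   pattern = "stationary_phase",
                   light_dark_ratio = 2.28, noise_cv = noise_cv),
    promoter_truth("P_dark", strength = 2, pattern = "constitutive",
                   light_dark_ratio = 0.75, noise_cv = noise_cv)
  )
}

# transcript profiles consistent with each planted truth, on the
# counts/total-counts scale
simulate_rnaseq_profiles <- function(truths, od_grid = reference_ods(),
                                     scale = 1e-4) {
  bind_rows(purrr::map(truths, function(tr) {
    tibble(
      locus = tr$promoter_id, od = od_grid,
      value = expected_normalized_fluorescence(tr, od_grid, od_grid) * scale
    )
  }))
}

#' Simulate a complete characterization study
#'
#' Generates every input the pipeline consumes, with planted ground
#' truth: a genome annotation with planted intergenic gaps (GFF3), plate
#' reader fluorescence time courses (CSV), qPCR C_T tables (CSV),
#' transformation-plate records (CSV), transcript profiles (TSV), and a
#' YAML ground-truth sidecar. Output is deterministic for a fixed seed
#' (byte-identical files).
#'
#' @param out_dir Directory to write into (created if needed).
#' @param seed Integer master seed.
#' @param truths List of [promoter_truth()] objects (default
#'   [default_promoter_panel()]).
#' @param planted_gaps Planted unannotated ranges for the annotation
#'   (default: the three PCC 7002 neutral sites).
#' @param chrom_len Chromosome length for the annotation, bp.
#' @param n_genes Approximate number of annotation features.
#' @param growth A [growth_model()].
#' @param cfg A [sim_config()] (its `seed` is overridden by `seed`).
#' @param efficiency,fmol,arm_lengths Transformation-experiment settings:
#'   planted efficiency at the longest arms (cfu/fmol), DNA amount, and
#'   the arm lengths tested.
#' @return Invisibly, a named list of the written file paths.
#' @export
simulate_study <- function(out_dir, seed = 1,
                           truths = default_promoter_panel(),
                           planted_gaps = NULL,
                           chrom_len = 3008047, n_genes = 2800,
                           growth = growth_model(),
                           cfg = sim_config(),
                           efficiency = 2, fmol = 256.41,
                           arm_lengths = c(250, 500, 750, 1000, 1250)) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg$seed <- as.integer(seed)
  if (is.null(planted_gaps)) {
    ns <- pcc7002_neutral_sites()
    planted_gaps <- purrr::map2(ns$start, ns$end, c)
  }
  paths <- list(
    annotation = file.path(out_dir, "annotation.gff3"),
    plates = file.path(out_dir, "plates.csv"),
    qpcr = file.path(out_dir, "qpcr.csv"),
    transformation = file.path(out_dir, "transformation.csv"),
    rnaseq = file.path(out_dir, "rnaseq.tsv"),
    truth = file.path(out_dir, "truth.yaml")
  )

  ann <- generate_annotation(n_genes, planted_gaps, chrom_len, seed = seed)
  write_annotation_gff3(ann, paths$annotation, chrom_len = chrom_len)

  curve <- simulate_growth(growth)
  plates <- bind_rows(purrr::map(truths, function(tr) {
    simulate_fluorescence(tr, curve, cfg) %>%
      filter(.data$strain_id != "WT" | tr$promoter_id == truths[[1]]$promoter_id)
  }))
  readr::write_csv(plates, paths$plates)

  qpcr <- bind_rows(purrr::map(truths, simulate_qpcr, cfg = cfg))
  readr::write_csv(qpcr, paths$qpcr)

  # efficiency scales with arm length tier, echoing the arm-length series
  tier_scale <- c(0.05, 0.3, 0.7, 0.9, 1)[seq_along(arm_lengths)]
  frac_pos <- c(0.34, 0.61, 0.86, 0.9, 0.92)[seq_along(arm_lengths)]
  plates_tf <- bind_rows(purrr::pmap(
    list(arm_lengths, tier_scale, frac_pos),
    function(arm, sc, fp) {
      bind_rows(lapply(1:3, function(rep_i) {
        simulate_transformation(
          efficiency * sc, fmol, frac_positive = fp,
          seed = seed + rep_i + arm, arm_length_bp = arm
        )
      }))
    }
  ))
  readr::write_csv(plates_tf, paths$transformation)

  readr::write_tsv(simulate_rnaseq_profiles(truths), paths$rnaseq)

  truth_block <- list(
    seed = as.integer(seed),
    chrom_len = as.integer(chrom_len),
    planted_gaps = purrr::map(planted_gaps, function(g) {
      list(start = as.integer(g[[1]]), end = as.integer(g[[2]]))
    }),
    promoters = purrr::map(truths, function(tr) {
      list(promoter_id = tr$promoter_id, strength = tr$strength,
           pattern = tr$pattern, light_dark_ratio = tr$light_dark_ratio,
           noise_cv = tr$noise_cv)
    }),
    transformation = list(efficiency_at_longest_arms = efficiency,
                          fmol = fmol)
  )
  yaml::write_yaml(truth_block, paths$truth)
  invisible(paths)
}
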