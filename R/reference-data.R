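# Bundled reference characterization tables for Synechococcus sp. PCC 7002.

reference_path <- function(file) {
  system.file("extdata", file, package = "chassiskit", mustWork = TRUE)
}

#' Reference promoter characterization for PCC 7002
#'
#' Characterization of 25 native *Synechococcus* sp. PCC 7002 promoters
#' driving a Ypet reporter under continuous light: mean normalized
#' fluorescence (fold over wild type, with sample SD and a significance
#' flag from a two-tailed wild-type comparison at alpha = 0.05),
#' regulatory classes and expression-versus-OD730 slopes for both the
#' reporter and the reference transcriptomic profiles, and the Pearson
#' correlation between the two across the growth curve.
#'
#' @return A tibble with one row per promoter locus.
#' @examples
#' ref <- pcc7002_promoters()
#' table(classify_strength(ref$mean_norm_fluor,
#'                         ifelse(ref$significant, 0.01, 1)))
#' @export
pcc7002_promoters <- function() {
  readr::read_tsv(reference_path("pcc7002_promoter_reference.tsv"),
                  show_col_types = FALSE)
}

#' Reference diurnal fold-changes for PCC 7002 promoters
#'
#' Signed light:dark fold-changes in reporter transcript level (qRT-PCR,
#' 2^-ddCT against the rnpA reference gene, 6 h into each phase of a
#' 12 h:12 h cycle) for the 25 characterized promoters: positive values
#' are up-regulation in the light, negative values the reciprocal
#' down-regulation, with SD across biological replicates and a
#' significance flag on the light-vs-dark dCT comparison.
#'
#' @return A tibble with columns `strain`, `signed_fold_change`, `sd`,
#'   `significant`.
#' @examples
#' summarize_diurnal(pcc7002_diurnal()$signed_fold_change)
#' @export
pcc7002_diurnal <- function() {
  readr::read_tsv(reference_path("pcc7002_diurnal_reference.tsv"),
                  show_col_types = FALSE)
}

#' Reference neutral integration sites for PCC 7002
#'
#' The three unannotated chromosomal regions longer than 1 kb (NS1-NS3)
#' with their 1-based inclusive coordinates and flanking locus tags.
#'
#' @return A tibble with columns `site`, `start`, `end`, `left_locus`,
#'   `right_locus`.
#' @export
pcc7002_neutral_sites <- function() {
  readr::read_tsv(reference_path("pcc7002_neutral_sites.tsv"),
                  show_col_types = FALSE)
}

#' Reference growth parameters for PCC 7002 neutral-site strains
#'
#' Linear growth rates (OD730/h) and photosynthetic efficiencies
#' (Fv'/Fm', consumed as plain measurements) for the wild type and the
#' two neutral-site integration strains, as mean with sample SD across
#' biological replicates.
#'
#' @return A tibble with columns `strain`, `linear_growth_rate`,
#'   `sd_growth_rate`, `fv_fm`, `sd_fv_fm`.
#' @export
pcc7002_growth <- function() {
  readr::read_tsv(reference_path("pcc7002_growth_reference.tsv"),
                  show_col_types = FALSE)
}
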