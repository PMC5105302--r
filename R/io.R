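# Tabular readers/writers for the pipeline's CSV/TSV schemas.

check_columns <- function(df, required, what) {
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    abort(sprintf("%s is missing column(s): %s", what,
                  paste(missing_cols, collapse = ", ")))
  }
  df
}

#' Read plate-reader fluorescence time courses
#'
#' CSV with columns `strain_id`, `replicate`, `time_h`, `od730`,
#' `fluorescence`, `dilution_factor`.
#'
#' @param path CSV path.
#' @return A tibble.
#' @export
read_plates_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE) %>%
    check_columns(c("strain_id", "replicate", "time_h", "od730",
                    "fluorescence", "dilution_factor"),
                  sprintf("plate file '%s'", path))
}

#' Read a qPCR C_T table
#'
#' CSV with columns `strain_id`, `gene`, `condition`,
#' `biological_replicate`, `technical_replicate`, `ct`.
#'
#' @param path CSV path.
#' @return A tibble.
#' @export
read_qpcr_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE) %>%
    check_columns(c("strain_id", "gene", "condition",
                    "biological_replicate", "technical_replicate", "ct"),
                  sprintf("qPCR file '%s'", path))
}

#' Read transformation-plate records
#'
#' CSV with columns `cfu`, `dilution_factor`, `dna_mass_ug`,
#' `fragment_length_bp`, `n_screened`, `n_positive` (and usually
#' `incubation_h`, `arm_length_bp`).
#'
#' @param path CSV path.
#' @return A tibble.
#' @export
read_transformation_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE) %>%
    check_columns(c("cfu", "dilution_factor", "dna_mass_ug",
                    "fragment_length_bp", "n_screened", "n_positive"),
                  sprintf("transformation file '%s'", path))
}

#' Read transcript-abundance profiles
#'
#' TSV with columns `locus`, `od`, `value` (counts/total counts at each
#' reference OD).
#'
#' @param path TSV path.
#' @return A tibble.
#' @export
read_rnaseq_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE) %>%
    check_columns(c("locus", "od", "value"),
                  sprintf("RNA-seq file '%s'", path))
}
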