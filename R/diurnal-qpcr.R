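# Diurnal qRT-PCR: 2^-ddCT relative quantification, signed fold-change
# convention, and light/dark regulation summaries.

#' Average technical qPCR replicates on the C_T scale
#'
#' Technical replicate C_T values are averaged per (strain, gene,
#' condition, biological replicate) cell before any exponentiation.
#' No-template and no-reverse-transcriptase control rows (strain or gene
#' matching `NTC`/`no-RT`/`no-template`, case-insensitive, or flagged by a
#' logical `is_control` column) are excluded.
#'
#' @param qpcr Tibble with columns `strain_id`, `gene`, `condition`,
#'   `biological_replicate`, `technical_replicate`, `ct`.
#' @return A tibble with one row per cell: `strain_id`, `gene`,
#'   `condition`, `biological_replicate`, `mean_ct`, `n_technical`.
#' @export
mean_technical_ct <- function(qpcr) {
  is_ctrl <- if ("is_control" %in% names(qpcr)) {
    qpcr$is_control %in% TRUE
  } else {
    rep(FALSE, nrow(qpcr))
  }
  ctrl_pattern <- "^(ntc|no[-_ ]?rt|no[-_ ]?template)$"
  is_ctrl <- is_ctrl |
    grepl(ctrl_pattern, qpcr$strain_id, ignore.case = TRUE) |
    grepl(ctrl_pattern, qpcr$gene, ignore.case = TRUE)
  kept <- qpcr[!is_ctrl, , drop = FALSE]
  if (nrow(kept) == 0) abort("no non-control qPCR rows")
  if (any(!is.finite(kept$ct)) || any(kept$ct <= 0)) {
    abort("C_T values must be positive and finite")
  }
  kept %>%
    group_by(.data$strain_id, .data$gene, .data$condition,
             .data$biological_replicate) %>%
    summarise(mean_ct = mean(.data$ct), n_technical = dplyr::n(),
              .groups = "drop")
}

#' Relative expression ratios by the 2^-ddCT method
#'
#' For each (strain, biological replicate):
#' `dCT(cond) = CT_target(cond) - CT_reference(cond)`,
#' `ddCT = dCT(light) - dCT(dark)`, and `ratio = 2^-ddCT`, assuming an
#' amplification efficiency of exactly 2. A missing cell (any of the four
#' target/reference x light/dark combinations) is an error naming the
#' cell.
#'
#' @param means Cell means from [mean_technical_ct()].
#' @param target_gene,reference_gene Gene labels (defaults `"ypet"` and
#'   `"rnpA"`).
#' @param light,dark Condition labels.
#' @return A tibble with one row per (strain, biological replicate):
#'   `strain_id`, `biological_replicate`, `delta_ct_light`,
#'   `delta_ct_dark`, `ddct`, `ratio`.
#' @export
delta_delta_ct <- function(means, target_gene = "ypet",
                           reference_gene = "rnpA",
                           light = "light", dark = "dark") {
  wide <- means %>%
    filter(.data$gene %in% c(target_gene, reference_gene),
           .data$condition %in% c(light, dark)) %>%
    mutate(
      role = ifelse(.data$gene == target_gene, "target", "reference"),
      cond = ifelse(.data$condition == light, "light", "dark")
    ) %>%
    tidyr::pivot_wider(
      id_cols = c("strain_id", "biological_replicate"),
      names_from = c("role", "cond"), values_from = "mean_ct",
      names_sep = "_"
    )
  needed <- c("target_light", "target_dark", "reference_light",
              "reference_dark")
  for (col in setdiff(needed, names(wide))) wide[[col]] <- NA_real_
  incomplete <- wide %>%
    filter(dplyr::if_any(all_of(needed), is.na))
  if (nrow(incomplete) > 0) {
    first <- incomplete[1, ]
    miss <- needed[is.na(unlist(first[needed]))]
    abort(sprintf(
      "missing qPCR cell(s) %s for strain %s, biological replicate %s",
      paste(miss, collapse = ", "), first$strain_id,
      first$biological_replicate
    ))
  }
  wide %>%
    mutate(
      delta_ct_light = .data$target_light - .data$reference_light,
      delta_ct_dark = .data$target_dark - .data$reference_dark,
      ddct = .data$delta_ct_light - .data$delta_ct_dark,
      ratio = 2^(-.data$ddct)
    ) %>%
    select("strain_id", "biological_replicate", "delta_ct_light",
           "delta_ct_dark", "ddct", "ratio")
}

#' Signed fold-change convention
#'
#' Expression ratios below 1 are reported as negative reciprocals:
#' ratio 0.75 becomes -1.33 (down-regulation in the light), ratio 2
#' stays +2 (up-regulation in the light). The mapping is a bijection on
#' the positive ratios, inverted exactly by [signed_to_ratio()].
#'
#' @param ratio Positive expression ratio(s), light/dark.
#' @return Signed fold-change(s) with `|signed| >= 1`.
#' @examples
#' to_signed_fold_change(c(2, 1, 0.75))
#' @export
to_signed_fold_change <- function(ratio) {
  if (any(!is.finite(ratio)) || any(ratio <= 0)) {
    abort("ratios must be positive and finite")
  }
  ifelse(ratio >= 1, ratio, -1 / ratio)
}

#' @rdname to_signed_fold_change
#' @param signed Signed fold-change(s) (`signed >= 1` or `signed <= -1`).
#' @export
signed_to_ratio <- function(signed) {
  if (any(!is.finite(signed)) || any(abs(signed) < 1)) {
    abort("signed fold-changes must satisfy |signed| >= 1")
  }
  ifelse(signed >= 1, signed, -1 / signed)
}

#' Aggregate per-replicate ratios into per-strain diurnal fold-changes
#'
#' Biological replicates are averaged on the signed fold-change scale,
#' with the sample SD as error. Significance is a two-sample
#' equal-variance t test (two-tailed) of the replicate dCT values in the
#' light against those in the dark.
#'
#' @param per_rep Per-replicate table from [delta_delta_ct()].
#' @param alpha Significance level (default 0.05).
#' @return A tibble of class `diurnal_fold_change`, one row per strain:
#'   `strain_id`, `signed`, `sd_signed`, `ratio`, `p_value`,
#'   `significant`, `n_replicates`. With a single replicate `sd_signed`,
#'   `p_value` and `significant` are `NA`.
#' @export
aggregate_biological <- function(per_rep, alpha = 0.05) {
  out <- per_rep %>%
    group_by(.data$strain_id) %>%
    summarise(
      signed = mean(to_signed_fold_change(.data$ratio)),
      sd_signed = if (dplyr::n() >= 2) {
        sd(to_signed_fold_change(.data$ratio))
      } else {
        NA_real_
      },
      p_value = if (dplyr::n() >= 2) {
        # degenerate (zero-variance) replicate sets have no defined p
        tryCatch(
          two_sample_ttest_equal_var(.data$delta_ct_light,
                                     .data$delta_ct_dark)$p_two_tail,
          error = function(e) NA_real_
        )
      } else {
        NA_real_
      },
      n_replicates = dplyr::n(),
      .groups = "drop"
    ) %>%
    mutate(
      ratio = ifelse(.data$signed < 0, -1 / .data$signed, .data$signed),
      significant = !is.na(.data$p_value) & .data$p_value < alpha
    ) %>%
    select("strain_id", "signed", "sd_signed", "ratio", "p_value",
           "significant", "n_replicates")
  class(out) <- c("diurnal_fold_change", class(out))
  out
}

#' Summarize diurnal regulation across promoters
#'
#' Counts promoters with more than a twofold light increase
#' (`signed > 2`), with a 1.5- to 2-fold increase (`1.5 < signed <= 2`),
#' and with reduced light expression (`signed < 0`), and reports the mean
#' and SD of the unsigned ratios (negative signed values converted back
#' via `ratio = 1/|signed|` before averaging, the convention that
#' reproduces the overall light-response mean).
#'
#' @param signed Numeric vector of signed fold-changes, or a
#'   `diurnal_fold_change` tibble (its `signed` column is used).
#' @return A one-row tibble: `n_promoters`, `n_over_2fold`,
#'   `n_1p5_to_2fold`, `n_down`, `mean_ratio`, `sd_ratio`.
#' @export
summarize_diurnal <- function(signed) {
  if (is.data.frame(signed)) signed <- signed$signed
  signed <- signed[is.finite(signed)]
  if (length(signed) == 0) abort("no fold-changes to summarize")
  if (any(signed == 0)) abort("signed fold-changes cannot be 0")
  ratios <- ifelse(signed < 0, -1 / signed, signed)
  tibble(
    n_promoters = length(signed),
    n_over_2fold = sum(signed > 2),
    n_1p5_to_2fold = sum(signed > 1.5 & signed <= 2),
    n_down = sum(signed < 0),
    mean_ratio = mean(ratios),
    sd_ratio = if (length(ratios) >= 2) sd(ratios) else NA_real_
  )
}

#' Full diurnal qPCR pipeline
#'
#' [mean_technical_ct()], [delta_delta_ct()] and [aggregate_biological()]
#' chained: from a raw C_T table to per-strain signed light:dark
#' fold-changes.
#'
#' @inheritParams mean_technical_ct
#' @inheritParams delta_delta_ct
#' @inheritParams aggregate_biological
#' @return A `diurnal_fold_change` tibble (see [aggregate_biological()]).
#' @export
diurnal_fold_changes <- function(qpcr, target_gene = "ypet",
                                 reference_gene = "rnpA",
                                 light = "light", dark = "dark",
                                 alpha = 0.05) {
  qpcr %>%
    mean_technical_ct() %>%
    delta_delta_ct(target_gene, reference_gene, light, dark) %>%
    aggregate_biological(alpha)
}

#' @exportS3Method generics::glance
glance.diurnal_fold_change <- function(x, ...) {
  summarize_diurnal(x)
}
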