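# ggplot2 figures for chassiskit result objects.

#' Plot a promoter characterization
#'
#' Mean normalized fluorescence (log scale) per promoter with replicate-SD
#' error bars, coloured by strength tier.
#'
#' @param object A `promoter_characterization` from
#'   [characterize_promoters()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot promoter_characterization
#' @export
autoplot.promoter_characterization <- function(object, ...) {
  df <- tidy(object) %>%
    mutate(promoter_id = stats::reorder(.data$promoter_id,
                                        .data$mean_norm_fluor))
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$promoter_id, y = .data$mean_norm_fluor,
    fill = .data$strength_tier
  )) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = pmax(.data$mean_norm_fluor - .data$sd_norm_fluor, 1e-3),
      ymax = .data$mean_norm_fluor + .data$sd_norm_fluor
    ), width = 0.3) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::scale_y_log10() +
    ggplot2::coord_flip() +
    ggplot2::labs(
      x = NULL, y = "Normalized fluorescence (fold over wild type)",
      fill = "Strength tier"
    ) +
    ggplot2::theme_minimal()
}

#' Plot diurnal fold-changes
#'
#' Signed light:dark fold-change per strain; significant light responses
#' are highlighted, and the twofold and 1.5-fold guides are drawn.
#'
#' @param object A `diurnal_fold_change` from [diurnal_fold_changes()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot diurnal_fold_change
#' @export
autoplot.diurnal_fold_change <- function(object, ...) {
  df <- tidy(object) %>%
    mutate(strain_id = stats::reorder(.data$strain_id, .data$signed))
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$strain_id, y = .data$signed, fill = .data$significant
  )) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = c(-1.5, 1.5), linetype = "dotted") +
    ggplot2::geom_hline(yintercept = c(-2, 2), linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::labs(
      x = NULL, y = "Signed fold-change (light : dark)",
      fill = "Significant"
    ) +
    ggplot2::theme_minimal()
}

#' Plot fluorescence time courses
#'
#' Undiluted fluorescence versus OD730 per strain and replicate.
#'
#' @param plates Fluorescence series tibble (`strain_id`, `replicate`,
#'   `od730`, `fluorescence`, `dilution_factor`).
#' @return A ggplot object.
#' @export
plot_fluorescence_series <- function(plates) {
  ggplot2::ggplot(plates, ggplot2::aes(
    x = .data$od730, y = .data$fluorescence * .data$dilution_factor,
    colour = .data$strain_id,
    group = interaction(.data$strain_id, .data$replicate)
  )) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "OD730", y = "Fluorescence (a.u., undiluted)",
                  colour = "Strain") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
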