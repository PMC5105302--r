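# broom-style tidiers for chassiskit result objects.

strip_result_class <- function(x, drop) {
  out <- as_tibble(x)
  attr(out, "profiles") <- NULL
  attr(out, "diagnostics") <- NULL
  attr(out, "wildtype_id") <- NULL
  out
}

#' Tidy a promoter characterization
#'
#' @param x A `promoter_characterization` from [characterize_promoters()].
#' @param ... Unused.
#' @return A plain tibble, one row per promoter.
#' @method tidy promoter_characterization
#' @export
tidy.promoter_characterization <- function(x, ...) {
  strip_result_class(x)
}

#' One-row summary of a promoter characterization
#'
#' @inheritParams tidy.promoter_characterization
#' @return A one-row tibble: promoter counts overall and per strength
#'   tier, plus the number significantly above 1.5-fold over wild type.
#' @method glance promoter_characterization
#' @export
glance.promoter_characterization <- function(x, ...) {
  tibble(
    n_promoters = nrow(x),
    n_above_wildtype = sum(x$strength_tier != "not_significant"),
    n_weak = sum(x$strength_tier == "weak"),
    n_moderate = sum(x$strength_tier == "moderate"),
    n_strong = sum(x$strength_tier == "strong")
  )
}

#' @exportS3Method generics::tidy
tidy.diurnal_fold_change <- function(x, ...) {
  strip_result_class(x)
}

#' @exportS3Method generics::tidy
tidy.arm_experiment_summary <- function(x, ...) {
  strip_result_class(x)
}
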