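#' MA plot of one or more arrays
#'
#' Scatter of M against A per array with the lowess trend overlaid; the
#' standard diagnostic for intensity-dependent dye bias before and after
#' normalization.
#'
#' @param ma MA tibble from [ma_transform()] or [lowess_normalize()].
#' @param samples optional character vector restricting which arrays are
#'   shown (default: all, facetted).
#' @param span lowess span for the overlay. Default 0.2.
#' @return a ggplot object.
#' @export
plot_ma <- function(ma, samples = NULL, span = 0.2) {
  check_columns(ma, c("sample_id", "M", "A", "absent"), "MA table")
  d <- ma |> filter(is.finite(.data$M), is.finite(.data$A))
  if (!is.null(samples)) d <- d |> filter(.data$sample_id %in% samples)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$A, y = .data$M)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$absent),
                        alpha = 0.5, size = 0.8) +
    ggplot2::geom_smooth(
      data = d |> filter(!.data$absent),
      method = "loess", span = span, se = FALSE, formula = y ~ x,
      colour = "firebrick", linewidth = 0.6
    ) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::facet_wrap(~sample_id) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30",
                                            `TRUE` = "orange")) +
    ggplot2::labs(x = "A (mean log2 intensity)", y = "M (log2 ratio)",
                  colour = "absent")
}

#' @describeIn run_array_pipeline Volcano plot of the array DE results
#'   (signed log2 fold change against -log10 adjusted p).
#' @param object an `array_de` object.
#' @param ... unused.
#' @method autoplot array_de
#' @export
autoplot.array_de <- function(object, ...) {
  d <- object$results |>
    mutate(log2fc = log2_from_signed_fc(.data$fc_signed))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$log2fc,
                                  y = -log10(.data$p_adj),
                                  colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = -log10(object$meta$alpha),
                        linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 fold change (treated vs control)",
                  y = "-log10 adjusted p", colour = "significant")
}

#' @describeIn run_tlda_pipeline Fold-change plot of the TLDA results
#'   (per-assay signed fold change, significant assays highlighted).
#' @param object a `tlda_de` object.
#' @param ... unused.
#' @method autoplot tlda_de
#' @export
autoplot.tlda_de <- function(object, ...) {
  d <- object$results |>
    mutate(log2fc = log2_from_signed_fc(.data$fc_signed),
           assay_id = stats::reorder(.data$assay_id, .data$log2fc))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$assay_id, y = .data$log2fc,
                                  fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey60",
                                          `TRUE` = "firebrick")) +
    ggplot2::labs(x = NULL, y = "log2 fold change (2^-ddCt scale)",
                  fill = "significant")
}

#' @describeIn standard_curve Dilution series with the fitted line and the
#'   implied amplification efficiency in the subtitle.
#' @param object a `standard_curve` object.
#' @param ... unused.
#' @method autoplot standard_curve
#' @export
autoplot.standard_curve <- function(object, ...) {
  d <- object$fit$model
  ggplot2::ggplot(d, ggplot2::aes(x = .data$log10_dilution, y = .data$ct)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope,
                         intercept = object$intercept,
                         colour = "firebrick") +
    ggplot2::labs(
      x = "log10(dilution)", y = "Ct",
      subtitle = if (object$valid) {
        sprintf("slope %.3f, efficiency %.1f%%, r2 %.4f",
                object$slope, 100 * object$efficiency, object$r2)
      } else {
        "invalid curve (non-negative slope)"
      }
    )
}

#' @describeIn overlap_and_concordance Per-family bar chart of down- and
#'   up-regulated overlapping targets.
#' @param object an `overlap_report` object.
#' @param ... unused.
#' @method autoplot overlap_report
#' @export
autoplot.overlap_report <- function(object, ...) {
  d <- object$summary |>
    filter(.data$family != "overall") |>
    tidyr::pivot_longer(c("n_down", "n_up"), names_to = "direction",
                        values_to = "n") |>
    mutate(direction = sub("^n_", "", .data$direction))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$family, y = .data$n,
                                  fill = .data$direction)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_fill_manual(values = c(down = "steelblue",
                                          up = "firebrick")) +
    ggplot2::labs(x = NULL, y = "overlapping targets", fill = "target\ndirection")
}
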