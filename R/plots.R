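#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Scatter plot of a concordance fit
#'
#' VitroF against VivoF, one point per drug, with the least-squares line
#' and the Pearson r annotated.
#'
#' @param object A [concordance()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.teva_concordance <- function(object, ...) {
  ggplot2::ggplot(object$pairs, ggplot2::aes(x = .data$vitro_f, y = .data$vivo_f)) +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         linetype = "dashed", colour = "grey40") +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::geom_text(ggplot2::aes(label = .data$drug),
                       vjust = -0.8, size = 3) +
    ggplot2::labs(
      x = "VitroF (ex vivo score)", y = "VivoF (in vivo score)",
      title = sprintf("Ex vivo / in vivo concordance (R = %.2f, n = %d)",
                      object$r, object$n)
    ) +
    ggplot2::theme_minimal()
}

#' Tumor growth curves by treatment arm
#'
#' Group mean volume (+/- SEM) over measurement days, the standard
#' efficacy-study display.
#'
#' @param volumes Tibble from [caliper_volumes()].
#' @return A ggplot object.
#' @export
plot_growth_curves <- function(volumes) {
  check_columns(volumes, c("group", "day", "volume_mm3"), "`volumes`")
  summ <- volumes |>
    dplyr::group_by(.data$group, .data$day) |>
    dplyr::summarise(
      mean = mean(.data$volume_mm3),
      sem = stats::sd(.data$volume_mm3) / sqrt(dplyr::n()),
      .groups = "drop"
    )
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$day, y = .data$mean,
                                     colour = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$sem,
                                          ymax = .data$mean + .data$sem),
                             size = 0.3) +
    ggplot2::labs(x = "Day", y = expression(Tumor~volume~(mm^3)),
                  colour = "Arm") +
    ggplot2::theme_minimal()
}

#' Bar chart of per-drug VitroF scores
#'
#' Drugs ordered by score, with bootstrap intervals when present; the
#' dashed line at 1 marks the no-effect score.
#'
#' @param scores Tibble from [vitro_scores()].
#' @return A ggplot object.
#' @export
plot_vitro_scores <- function(scores) {
  check_columns(scores, c("drug", "vitro_f"), "`scores`")
  p <- ggplot2::ggplot(scores,
                       ggplot2::aes(x = stats::reorder(.data$drug, -.data$vitro_f),
                                    y = .data$vitro_f)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "VitroF") +
    ggplot2::theme_minimal()
  if (all(c("vitro_f_lo", "vitro_f_hi") %in% names(scores)) &&
      !all(is.na(scores$vitro_f_lo))) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$vitro_f_lo, ymax = .data$vitro_f_hi),
      width = 0.2
    )
  }
  p
}

#' Grouped bar chart of marker object frequencies
#'
#' Group mean object frequency (+/- SEM) per marker, the explant-assay
#' readout display.
#'
#' @param records Explant staining records.
#' @return A ggplot object.
#' @export
plot_marker_frequencies <- function(records) {
  check_columns(records, c("group", "marker", "positive_count",
                           "tumor_area_mm2"), "`records`")
  summ <- records |>
    dplyr::mutate(frequency = .data$positive_count / .data$tumor_area_mm2) |>
    dplyr::group_by(.data$group, .data$marker) |>
    dplyr::summarise(
      mean = mean(.data$frequency),
      sem = stats::sd(.data$frequency) / sqrt(dplyr::n()),
      .groups = "drop"
    )
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$group, y = .data$mean)) +
    ggplot2::geom_col(fill = "tan3") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sem,
                                        ymax = .data$mean + .data$sem),
                           width = 0.2) +
    ggplot2::facet_wrap(~marker, scales = "free_y") +
    ggplot2::labs(x = NULL, y = expression(Object~frequency~(pcs/mm^2))) +
    ggplot2::theme_minimal()
}
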