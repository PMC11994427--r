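#' Scatter of measured TSH against the population-predicted curve
#'
#' Subjects as points (log TSH axis) over the piecewise log-sigmoid
#' population curve. SH subjects are expected to sit above the curve;
#' euthyroid subjects disperse around it, reflecting individual set-points.
#'
#' @param subjects Tibble with `tsh` and `ft4` columns (optionally `status`
#'   from [assign_strata()] for colouring).
#' @param params A [tsh_curve_params()] object.
#' @return A ggplot object.
#' @export
plot_tsh_vs_predicted <- function(subjects, params = tsh_curve_params()) {
  stopifnot(all(c("tsh", "ft4") %in% names(subjects)))
  grid <- seq(max(min(subjects$ft4) * 0.9, 0.5), max(subjects$ft4) * 1.05,
              length.out = 400)
  curve <- predict_ln_tsh(grid, params)
  p <- ggplot2::ggplot(subjects, ggplot2::aes(x = .data$ft4, y = .data$tsh))
  if ("status" %in% names(subjects)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data$status),
                                 alpha = 0.6, size = 1)
  } else {
    p <- p + ggplot2::geom_point(alpha = 0.6, size = 1)
  }
  p +
    ggplot2::geom_line(data = curve,
                       ggplot2::aes(x = .data$ft4, y = .data$tsh, group = .data$branch),
                       linewidth = 0.8) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "FT4 (pmol/L)", y = "TSH (mIU/L), log scale",
                  colour = NULL,
                  title = "Measured TSH around the population-predicted curve")
}

#' Actual versus predicted secretory capacity by stratum
#'
#' Strip plot of per-subject actual GT with the stratum medians of actual
#' and predicted GT overlaid.
#'
#' @param analysis A `thyro_analysis` from [analyze_cohort()].
#' @return A ggplot object.
#' @export
plot_gt_by_stratum <- function(analysis) {
  stopifnot(inherits(analysis, "thyro_analysis"))
  aug <- analysis$subjects
  med <- analysis$strata[!is.na(analysis$strata$tsh_min), ]
  ggplot2::ggplot(aug, ggplot2::aes(x = .data$stratum, y = .data$gt_actual_pmol_s)) +
    ggplot2::geom_jitter(width = 0.18, alpha = 0.4, size = 0.8) +
    ggplot2::geom_point(data = med,
                        ggplot2::aes(x = .data$stratum, y = .data$gt_actual_median),
                        shape = 18, size = 3) +
    ggplot2::geom_point(data = med,
                        ggplot2::aes(x = .data$stratum, y = .data$gt_predicted_median),
                        shape = 5, size = 3) +
    ggplot2::labs(x = NULL, y = "SPINA-GT (pmol/s)",
                  title = "Actual (filled) vs predicted (open) median GT by stratum")
}
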