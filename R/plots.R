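#' Radar-style plot of group sensory profiles
#'
#' Group mean scores on the five metrics drawn on a polar axis, the
#' conventional radar presentation of panel profiles.
#'
#' @param group_profile Long tibble from [group_sensory_profile()].
#' @return A ggplot.
#' @export
plot_radar <- function(group_profile) {
  ggplot2::ggplot(group_profile,
                  ggplot2::aes(.data$metric, .data$score,
                               group = .data$group, color = .data$group)) +
    ggplot2::geom_polygon(fill = NA, linewidth = 0.8) +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::coord_polar() +
    ggplot2::labs(x = NULL, y = "mean score") +
    ggplot2::theme_minimal()
}

#' Plot an accumulated ion chromatogram
#'
#' @param aic Output of [build_aic()].
#' @return A ggplot of the summed trace.
#' @export
plot_aic <- function(aic) {
  ggplot2::ggplot(aic$trace, ggplot2::aes(.data$rt, .data$intensity)) +
    ggplot2::geom_line(color = "#2b8cbe") +
    ggplot2::labs(x = "retention time (min)", y = "summed intensity") +
    ggplot2::theme_minimal()
}

#' Feature map of abundant ion features
#'
#' m/z vs retention-time scatter of selected features sized by apex
#' intensity.
#'
#' @param scatter `scatter` element of [build_aic()].
#' @return A ggplot.
#' @export
plot_feature_map <- function(scatter) {
  ggplot2::ggplot(scatter,
                  ggplot2::aes(.data$rt, .data$mz,
                               size = .data$apex_intensity)) +
    ggplot2::geom_point(alpha = 0.6, color = "#d95f0e") +
    ggplot2::labs(x = "retention time (min)", y = "m/z", size = "apex") +
    ggplot2::theme_minimal()
}
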