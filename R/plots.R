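#' Plot the distribution of accessibility scores by mode
#'
#' Box plots of community accessibility (m2 of green space per person) for
#' each travel mode and the integrated score, the standard way to compare
#' how mode choice reshapes the accessibility distribution.
#'
#' @param object An [accessibility_scores()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ugs_access
#' @export
autoplot.ugs_access <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object),
                              cols = dplyr::all_of(unname(ACCESS_COLS)),
                              names_to = "mode", values_to = "access") |>
    mutate(mode = factor(names(ACCESS_COLS)[match(.data$mode, ACCESS_COLS)],
                         levels = names(ACCESS_COLS)))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$mode, y = .data$access)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = NULL, y = expression("accessibility (" * m^2 / person * ")")) +
    ggplot2::theme_minimal()
}

#' Plot cumulative trip-frequency curves with estimated thresholds
#'
#' Draws the empirical cumulative share of trips against travel time for
#' each mode and marks the fitted breakpoint (the catchment threshold).
#'
#' @param trips Trip table (`mode`, `minutes`).
#' @param thresholds Optional [estimate_threshold()] result; computed from
#'   `trips` when missing.
#' @return A ggplot object.
#' @export
plot_trip_curve <- function(trips, thresholds = NULL) {
  thresholds <- thresholds %||% estimate_threshold(trips)
  trips <- as_tibble(trips)
  curves <- purrr::map_dfr(unique(trips$mode), function(m) {
    mins <- trips$minutes[trips$mode == m]
    minute <- seq(0, ceiling(max(mins)))
    tibble(mode = m, minute = minute,
           cumulative = vapply(minute, function(t) mean(mins <= t), numeric(1)))
  })
  ggplot2::ggplot(curves,
                  ggplot2::aes(x = .data$minute, y = .data$cumulative,
                               colour = .data$mode)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(
      data = thresholds,
      ggplot2::aes(xintercept = .data$threshold_min, colour = .data$mode),
      linetype = "dashed"
    ) +
    ggplot2::labs(x = "travel time (min)", y = "cumulative trip share") +
    ggplot2::theme_minimal()
}

#' Plot the heterogeneous marginal effects of a KRLS fit
#'
#' Box plots of the pointwise partial derivatives per covariate, with the
#' average effect overlaid: the distribution behind the P25/P50/P75 columns
#' of the effect tables.
#'
#' @param object A [krls()] fit.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot krls
#' @export
autoplot.krls <- function(object, ...) {
  der <- as_tibble(as.data.frame(object$derivatives)) |>
    tidyr::pivot_longer(dplyr::everything(), names_to = "covariate",
                        values_to = "derivative")
  avg <- tibble(covariate = object$covariates, avg = unname(object$avg))
  ggplot2::ggplot(der, ggplot2::aes(x = .data$covariate, y = .data$derivative)) +
    ggplot2::geom_boxplot(outlier.alpha = 0.3) +
    ggplot2::geom_point(data = avg, ggplot2::aes(y = .data$avg),
                        colour = "red", size = 2) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::labs(x = NULL, y = "pointwise marginal effect") +
    ggplot2::theme_minimal()
}

#' Plot a deprivation table
#'
#' Average marginal effect of each SES covariate on accessibility, by mode,
#' with the P25-P75 heterogeneity band.
#'
#' @param object A `deprivation_table`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot deprivation_table
#' @export
autoplot.deprivation_table <- function(object, ...) {
  d <- as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$avg, y = .data$covariate)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$p25, xmax = .data$p75), height = 0.2
    ) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$stars != ""), size = 2) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1),
                                name = "p < 0.05") +
    ggplot2::facet_wrap(~mode) +
    ggplot2::labs(x = "marginal effect on accessibility (m2/person per unit)",
                  y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
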