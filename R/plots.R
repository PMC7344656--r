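# ggplot2 views of the main result types.

#' Map the access index over area centroids
#'
#' @param areas Area tibble with `x_km`, `y_km`, `access_per_1000` (from
#'   [compute_access()]).
#' @return A ggplot object.
#' @export
plot_access_map <- function(areas) {
  assert_columns(areas, c("x_km", "y_km", "access_per_1000"), "areas")
  ggplot2::ggplot(areas, ggplot2::aes(.data$x_km, .data$y_km,
                                      colour = .data$access_per_1000)) +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::scale_colour_viridis_c(name = "GPs per 1000") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (km)", y = "y (km)",
                  title = "2SFCA access to primary care") +
    ggplot2::theme_minimal()
}

#' @describeIn run_ladder Plot the variance ladder: area-level variance,
#'   latent ICC and MOR across the nested models.
#' @param object A `cmrf_ladder`.
#' @export
autoplot.cmrf_ladder <- function(object, ...) {
  long <- object$summary |>
    dplyr::select("model", "tau2", "icc_pct", "mor") |>
    tidyr::pivot_longer(-"model", names_to = "metric") |>
    dplyr::mutate(metric = factor(.data$metric,
                                  levels = c("tau2", "icc_pct", "mor"),
                                  labels = c("tau^2", "ICC (%)", "MOR")))
  ggplot2::ggplot(long, ggplot2::aes(.data$model, .data$value, group = 1)) +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::geom_point(size = 2) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(
      x = NULL, y = NULL,
      title = sprintf("Contextual effect across nested models%s",
                      if (!is.na(object$cmrf)) paste0(" (", object$cmrf, ")") else "")
    ) +
    ggplot2::theme_minimal()
}

#' @describeIn fit_area_glmm Forest plot of the odds ratios (intercept
#'   omitted) with 95% Wald intervals.
#' @param object An `area_glmm` fit.
#' @export
autoplot.area_glmm <- function(object, ...) {
  tbl <- odds_ratios(object) |>
    dplyr::filter(.data$term != "(Intercept)")
  if (nrow(tbl) == 0) {
    stop("Null model has no covariate odds ratios to plot.", call. = FALSE)
  }
  tbl$term <- factor(tbl$term, levels = rev(tbl$term))
  ggplot2::ggplot(tbl, ggplot2::aes(.data$or, .data$term)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey60") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$or_low, xmax = .data$or_high), height = 0.2
    ) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Odds ratio (log scale)", y = NULL,
                  title = "Fixed effects, 95% Wald intervals") +
    ggplot2::theme_minimal()
}
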