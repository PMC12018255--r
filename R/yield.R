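#' Cardinal values of a beta-function crop response
#'
#' The (minimum, optimum, maximum) triple that parameterizes a beta-function
#' response: the response is 1 at the optimum and 0 at or beyond the
#' extremes. Defaults are the published cardinal values for banana in Latin
#' America and the Caribbean: temperature 20.0 / 26.8 / 29.4 degC,
#' precipitation 85.5 / 2646 / 5307 mm.
#'
#' @param x_min,x_opt,x_max Cardinal values; must satisfy
#'   `x_min < x_opt < x_max`.
#' @return An object of class `cardinal_values`.
#' @export
cardinal_values <- function(x_min, x_opt, x_max) {
  if (!is.finite(x_min) || !is.finite(x_opt) || !is.finite(x_max) ||
      !(x_min < x_opt && x_opt < x_max)) {
    stop("cardinal values must satisfy x_min < x_opt < x_max", call. = FALSE)
  }
  structure(list(x_min = x_min, x_opt = x_opt, x_max = x_max),
            class = "cardinal_values")
}

#' @rdname cardinal_values
#' @export
cardinal_temperature <- function() cardinal_values(20.0, 26.8, 29.4)

#' @rdname cardinal_values
#' @export
cardinal_precipitation <- function() cardinal_values(85.5, 2646, 5307)

#' @export
print.cardinal_values <- function(x, ...) {
  cat(sprintf("<cardinal_values> min %.4g, opt %.4g, max %.4g\n",
              x$x_min, x$x_opt, x$x_max))
  invisible(x)
}

#' Beta-function relative response
#'
#' The asymmetric beta response used for climate-dependent relative yield:
#' \deqn{Y(x) = \frac{x_{max}-x}{x_{max}-x_{opt}}
#'   \left(\frac{x-x_{min}}{x_{opt}-x_{min}}\right)^{
#'   \frac{x_{opt}-x_{min}}{x_{max}-x_{opt}}}}
#' for `x` in `[x_min, x_max]` and 0 outside. `Y(x_opt) = 1`; the response is
#' continuous everywhere, strictly increasing below the optimum and strictly
#' decreasing above it. The boundary values are defined as exactly 0.
#'
#' @param x Numeric vector (deg C or mm).
#' @param cardinals A [cardinal_values()] object.
#' @return Response values in \[0, 1\].
#' @examples
#' beta_response(26.8, cardinal_temperature()) # 1
#' beta_response(31.0, cardinal_temperature()) # 0
#' @export
beta_response <- function(x, cardinals) {
  stopifnot(inherits(cardinals, "cardinal_values"))
  xmin <- cardinals$x_min
  xopt <- cardinals$x_opt
  xmax <- cardinals$x_max
  e <- (xopt - xmin) / (xmax - xopt)
  y <- ((xmax - x) / (xmax - xopt)) * ((x - xmin) / (xopt - xmin))^e
  y[x <= xmin | x >= xmax] <- 0
  y[is.na(x)] <- NA_real_
  y
}

#' Combined climate-dependent relative yield
#'
#' The product of the temperature and precipitation beta responses,
#' `Y_C = Y_T * Y_P`: 1 only when both are at their optima, 0 if either
#' predictor is outside its cardinal range.
#'
#' @param temperature Mean annual temperature (deg C), vectorized.
#' @param precipitation Annual precipitation (mm), vectorized.
#' @param cardinals_t,cardinals_p [cardinal_values()] for each predictor.
#' @return Relative yield in \[0, 1\].
#' @export
relative_yield <- function(temperature, precipitation,
                           cardinals_t = cardinal_temperature(),
                           cardinals_p = cardinal_precipitation()) {
  beta_response(temperature, cardinals_t) *
    beta_response(precipitation, cardinals_p)
}

#' Grid of climate-dependent yield change
#'
#' Per-cell difference between future and current climate-dependent relative
#' yield, `Y_Cf - Y_Cc`, each the product of temperature and precipitation
#' beta responses. Values lie in \[-1, 1\]; negative cells lose yield
#' potential under the future climate.
#'
#' @param t_current,p_current,t_future,p_future Aligned climate
#'   [grid_layer()]s.
#' @param cardinals_t,cardinals_p [cardinal_values()].
#' @return A [grid_layer()] of yield change.
#' @export
yield_change_grid <- function(t_current, p_current, t_future, p_future,
                              cardinals_t = cardinal_temperature(),
                              cardinals_p = cardinal_precipitation()) {
  assert_aligned(t_current, p_current, t_future, p_future)
  y_cur <- relative_yield(t_current$values, p_current$values,
                          cardinals_t, cardinals_p)
  y_fut <- relative_yield(t_future$values, p_future$values,
                          cardinals_t, cardinals_p)
  grid_like(t_current, y_fut - y_cur)
}

#' Banana-area-weighted yield-change summary per region
#'
#' For each region, the banana-area-weighted median and interquartile range
#' of the per-cell yield change, with the total banana area and cell count.
#' Regions with fewer than `min_cells` banana-bearing cells are flagged:
#' their summaries rest on too few values to characterise a distribution.
#'
#' @param delta A [yield_change_grid()] result.
#' @param banana_area Banana hectares per cell (the weights).
#' @param regions A [region_labels()] object.
#' @param min_cells Flagging threshold (default 10 cells).
#' @return Tibble with `region`, `name`, `n_cells`, `banana_ha`, `q25`,
#'   `median`, `q75`, `few_cells`.
#' @export
yield_change_summary <- function(delta, banana_area, regions,
                                 min_cells = 10) {
  assert_aligned(delta, banana_area, regions$grid)
  keep <- !is.na(delta$values) & !is.na(banana_area$values) &
    !is.na(regions$grid$values) & banana_area$values > 0
  df <- tibble::tibble(
    region = as.integer(regions$grid$values[keep]),
    delta = delta$values[keep],
    w = banana_area$values[keep]
  )
  out <- df |>
    dplyr::group_by(.data$region) |>
    dplyr::summarise(
      n_cells = dplyr::n(),
      banana_ha = sum(.data$w),
      q25 = weighted_quantile(.data$delta, .data$w, 0.25),
      median = weighted_quantile(.data$delta, .data$w, 0.5),
      q75 = weighted_quantile(.data$delta, .data$w, 0.75)
    ) |>
    dplyr::mutate(few_cells = .data$n_cells < min_cells)
  dplyr::left_join(out, regions$table, by = c(region = "code")) |>
    dplyr::relocate("name", .after = "region")
}

#' Plot per-region yield change
#'
#' @param summary A [yield_change_summary()] tibble.
#' @return A ggplot of the weighted median with interquartile error bars.
#' @export
plot_yield_change <- function(summary) {
  ggplot2::ggplot(summary,
                  ggplot2::aes(x = stats::reorder(.data$name, .data$median),
                               y = .data$median)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$q25,
                                          ymax = .data$q75,
                                          colour = .data$few_cells)) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL,
                  y = "Banana-area-weighted yield change (Y_Cf - Y_Cc)",
                  colour = "< 10 cells") +
    ggplot2::theme_minimal()
}
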