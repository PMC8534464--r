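#' Broom-style accessors for fitted kinetic models
#'
#' `tidy()` returns one row per estimated parameter; `glance()` returns a
#' one-row model summary with fit quality.
#'
#' @param x An `od_fit` object from [fit_peleg()], [fit_azuara()],
#'   [fit_page()] or [fit_crank()].
#' @param ... Unused, for generic consistency.
#' @return A tibble.
#' @method tidy od_fit
#' @export
tidy.od_fit <- function(x, ...) {
  tibble(term = names(x$params), estimate = unname(x$params))
}

#' @rdname tidy.od_fit
#' @method glance od_fit
#' @export
glance.od_fit <- function(x, ...) {
  tibble(
    model = x$model,
    r_squared = x$quality$r_squared,
    rmse = x$quality$rmse,
    n_points = x$quality$n_points,
    equilibrium = x$equilibrium,
    space = x$space,
    flagged = length(x$flags) > 0
  )
}

#' @export
print.od_fit <- function(x, ...) {
  cat(sprintf("<od_fit> %s model (%s space)\n", x$model, x$space))
  cat("  parameters: ",
      paste(sprintf("%s = %.6g", names(x$params), x$params), collapse = ", "),
      "\n", sep = "")
  if (!is.na(x$equilibrium)) {
    cat(sprintf("  equilibrium: %.4f %%\n", x$equilibrium))
  }
  cat(sprintf("  R^2 = %.4f, RMSE = %.4g (n = %d)\n",
              x$quality$r_squared, x$quality$rmse, x$quality$n_points))
  if (length(x$flags) > 0) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Predict from a fitted kinetic model
#'
#' Evaluates the fitted model at new times, in the space the model was fit
#' in (percent for Peleg/Azuara, dimensionless ratio for Page/Crank).
#'
#' @param object An `od_fit`.
#' @param times Times in seconds; defaults to the fitted times.
#' @param ... Unused.
#' @return A numeric vector.
#' @export
predict.od_fit <- function(object, times = object$data$time_s, ...) {
  p <- object$params
  switch(object$model,
    peleg  = peleg_predict(times, p[["k1"]], p[["k2"]]),
    azuara = azuara_predict(times, p[["S"]], p[["y_inf"]]),
    page   = page_ratio(times, p[["A"]], p[["B"]]),
    crank  = crank_ratio(times, p[["De"]], object$radius,
                         n_terms = object$n_terms)
  )
}

#' Plot a fitted kinetic model
#'
#' Observed points and the fitted curve on a dense time grid.
#'
#' @param object An `od_fit`.
#' @param n_grid Number of grid points for the fitted curve.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot od_fit
#' @export
autoplot.od_fit <- function(object, n_grid = 200, ...) {
  grid <- tibble(
    time_s = seq(min(object$data$time_s), max(object$data$time_s),
                 length.out = n_grid)
  )
  grid$fitted <- predict(object, grid$time_s)
  ylab <- if (object$space == "percent") "% of initial mass"
          else "unaccomplished ratio (-)"
  ggplot2::ggplot(object$data, ggplot2::aes(x = time_s / 3600)) +
    ggplot2::geom_point(ggplot2::aes(y = observed)) +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = fitted),
                       colour = "steelblue") +
    ggplot2::labs(x = "time (h)", y = ylab,
                  title = sprintf("%s model fit", object$model)) +
    ggplot2::theme_minimal()
}

#' Plot a model comparison
#'
#' Bar chart of R-squared per model, faceted by treatment and quantity.
#'
#' @param object An `od_model_comparison` from [compare_models()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot od_model_comparison
#' @export
autoplot.od_model_comparison <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = model, y = r_squared, fill = rank == 1)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::facet_grid(treatment ~ quantity) +
    ggplot2::coord_cartesian(ylim = c(min(0.8, min(object$summary$r_squared,
                                                   na.rm = TRUE)), 1)) +
    ggplot2::labs(y = expression(R^2), x = NULL) +
    ggplot2::theme_minimal()
}

#' Plot kinetics series
#'
#' WL, SG and WR trajectories against time, coloured by quantity and
#' faceted by treatment.
#'
#' @param kinetics A kinetics tibble with `treatment`, `time_s` and the
#'   `WL_pct`/`SG_pct`/`WR_pct` columns.
#' @return A ggplot object.
#' @export
plot_kinetics <- function(kinetics) {
  long <- tidyr::pivot_longer(
    kinetics, all_of(c("WL_pct", "SG_pct", "WR_pct")),
    names_to = "quantity", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = time_s / 3600, y = value,
                                     colour = quantity)) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~treatment) +
    ggplot2::labs(x = "time (h)", y = "% of initial mass") +
    ggplot2::theme_minimal()
}
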