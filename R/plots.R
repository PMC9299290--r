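#' Plot the size-at-age spline with its confidence band
#'
#' @param object A [fit_size_at_age_spline()] result.
#' @param points Optional size-at-age points to overlay.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sat_spline <- function(object, points = NULL, ...) {
  grid <- seq(object$domain[1], object$domain[2], length.out = 200)
  pred <- predict(object, grid)
  p <- ggplot(pred, aes(x = .data$age, y = .data$ccl_cm)) +
    geom_ribbon(aes(ymin = .data$lower95, ymax = .data$upper95),
                fill = "grey80") +
    geom_line(linewidth = 0.8) +
    labs(x = "Estimated age (yr)", y = "Back-calculated CCL (cm)",
         title = "Penalized spline size-at-age") +
    theme_minimal()
  if (!is.null(points)) {
    p <- p + geom_point(data = points, aes(x = .data$age, y = .data$ccl_cm),
                        alpha = 0.35, size = 0.8)
  }
  p
}

#' Plot the bootstrapped von Bertalanffy curve and draw spread
#'
#' @param object A [bootstrap_fabens()] result.
#' @param l0 Age-0 anchor length, cm.
#' @param max_age Right edge of the age axis, yr.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.vbgm_fit <- function(object, l0 = 6, max_age = 50, ...) {
  ages <- seq(0, max_age, length.out = 200)
  mean_curve <- tibble(age = ages,
                       ccl_cm = vb_length_at_age(object$k_hat, object$linf_hat,
                                                 ages, l0))
  qs <- apply(
    sapply(seq_len(nrow(object$draws)), function(i) {
      vb_length_at_age(object$draws$k[i], object$draws$linf[i], ages, l0)
    }),
    1, quantile, probs = c(0.025, 0.975)
  )
  band <- tibble(age = ages, lower = qs[1, ], upper = qs[2, ])
  ggplot(mean_curve, aes(x = .data$age, y = .data$ccl_cm)) +
    geom_ribbon(data = band,
                aes(x = .data$age, ymin = .data$lower, ymax = .data$upper),
                inherit.aes = FALSE, fill = "grey80") +
    geom_line(linewidth = 0.8) +
    labs(x = "Age (yr)", y = "CCL (cm)",
         title = "Bootstrapped Fabens von Bertalanffy growth curve") +
    theme_minimal()
}

#' Plot the correction-factor curve over its training points
#'
#' @param object A [correction_factor_model()].
#' @param training Optional tibble with `lag_number`, `lag_diameter_mm`.
#' @param x_max Right edge of the LAG-number axis.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cf_model <- function(object, training = NULL, x_max = 10, ...) {
  grid <- tibble(lag_number = seq(0, x_max, length.out = 200))
  grid$lag_diameter_mm <- cf_eval(object, grid$lag_number)
  p <- ggplot(grid, aes(x = .data$lag_number, y = .data$lag_diameter_mm)) +
    geom_line(linewidth = 0.8) +
    labs(x = "LAG number", y = "LAG diameter (mm)",
         title = sprintf("Correction factor (%s)", object$kind)) +
    theme_minimal()
  if (!is.null(training)) {
    p <- p + geom_point(data = training,
                        aes(x = .data$lag_number, y = .data$lag_diameter_mm))
  }
  p
}

#' Plot mean annual growth by size class
#'
#' @param growth_summary A [summarize_growth()] result.
#' @return A ggplot object.
#' @export
plot_growth_by_class <- function(growth_summary) {
  gs <- growth_summary |> filter(.data$n > 0)
  ggplot(gs, aes(x = .data$class, y = .data$mean_growth)) +
    geom_col(fill = "grey60") +
    geom_errorbar(aes(ymin = .data$mean_growth - .data$se_growth,
                      ymax = .data$mean_growth + .data$se_growth),
                  width = 0.2) +
    labs(x = "Starting size class (cm CCL)", y = "Mean annual growth (cm/yr)") +
    theme_minimal()
}
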