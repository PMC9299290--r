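#' Hatchling anchor measurements
#'
#' The allometric length model is anchored at the smallest hatchling: a bone
#' section diameter of `dop_mm` corresponds exactly to a carapace length of
#' `lop_cm`. The anchors are measured constants (population minima), not free
#' parameters of any fit.
#'
#' @param lop_cm Minimum hatchling curved carapace length (CCL), cm.
#' @param dop_mm Minimum hatchling humerus section diameter, mm.
#' @return An object of class `hatchling_anchors`.
#' @export
#' @examples
#' hatchling_anchors(6, 2.4)
hatchling_anchors <- function(lop_cm = 6, dop_mm = 2.4) {
  if (!is.numeric(lop_cm) || lop_cm <= 0) {
    skel_abort("`lop_cm` must be a positive number.", "skelegrow_value_error")
  }
  if (!is.numeric(dop_mm) || dop_mm <= 0) {
    skel_abort("`dop_mm` must be a positive number.", "skelegrow_value_error")
  }
  structure(list(lop_cm = lop_cm, dop_mm = dop_mm), class = "hatchling_anchors")
}

#' Allometric length model relating bone diameter to carapace length
#'
#' The model is `L = Lop + b * (D - Dop)^c`, where `L` is CCL (cm), `D` is a
#' bone section (or LAG) diameter (mm), and `(Lop, Dop)` are the hatchling
#' anchors, so `L(Dop) = Lop` holds exactly for any `(b, c)`.
#'
#' @param lop_cm,dop_mm Hatchling anchors (see [hatchling_anchors()]).
#' @param b Slope term (> 0).
#' @param c Proportionality exponent (> 0).
#' @param residual_sse Residual sum of squares from a fit, if any (cm^2).
#' @param n Number of observations behind a fit, if any.
#' @param converged Logical convergence flag (fits only).
#' @return An object of class `allometric_model`.
#' @export
#' @examples
#' m <- allometric_model(6, 2.4, b = 3.665, c = 0.928)
#' allometry_length(m, 2.4)  # == 6 by construction
allometric_model <- function(lop_cm = 6, dop_mm = 2.4, b, c,
                             residual_sse = NA_real_, n = NA_integer_,
                             converged = NA) {
  anchors <- hatchling_anchors(lop_cm, dop_mm)
  if (!is.numeric(b) || b <= 0) {
    skel_abort("`b` must be a positive number.", "skelegrow_value_error")
  }
  if (!is.numeric(c) || c <= 0) {
    skel_abort("`c` must be a positive number.", "skelegrow_value_error")
  }
  structure(
    list(anchors = anchors, b = b, c = c, residual_sse = residual_sse,
         n = n, converged = converged),
    class = "allometric_model"
  )
}

#' @export
print.allometric_model <- function(x, ...) {
  cat("Allometric length model: L = Lop + b * (D - Dop)^c\n")
  cat(sprintf("  anchors: Lop = %g cm at Dop = %g mm\n",
              x$anchors$lop_cm, x$anchors$dop_mm))
  cat(sprintf("  b = %.4g, c = %.4g\n", x$b, x$c))
  if (!is.na(x$residual_sse)) {
    cat(sprintf("  residual SSE = %.4g cm^2 on n = %d pairs (converged: %s)\n",
                x$residual_sse, x$n, x$converged))
  }
  invisible(x)
}

#' Evaluate the allometric length model
#'
#' @param model An [allometric_model()].
#' @param d_mm Bone section or LAG diameter(s), mm. Values marginally below
#'   the anchor diameter (measurement noise) are clamped to it with a warning.
#' @return Predicted CCL (cm), vectorized over `d_mm`.
#' @export
allometry_length <- function(model, d_mm) {
  stopifnot(inherits(model, "allometric_model"))
  dop <- model$anchors$dop_mm
  if (any(d_mm < dop)) {
    warn(sprintf("%d diameter(s) below the anchor Dop = %g mm clamped to Dop.",
                 sum(d_mm < dop), dop))
    d_mm <- pmax(d_mm, dop)
  }
  model$anchors$lop_cm + model$b * (d_mm - dop)^model$c
}

#' Invert the allometric length model
#'
#' Returns the section diameter at which the model predicts `l_cm`. Used by
#' the simulator to turn carapace lengths into LAG diameters.
#'
#' @param model An [allometric_model()].
#' @param l_cm CCL value(s), cm; must be `>= Lop`.
#' @return Diameter(s), mm.
#' @export
allometry_diameter <- function(model, l_cm) {
  stopifnot(inherits(model, "allometric_model"))
  lop <- model$anchors$lop_cm
  if (any(l_cm < lop)) {
    skel_abort("`l_cm` must be at least the anchor length Lop.",
               "skelegrow_value_error")
  }
  model$anchors$dop_mm + ((l_cm - lop) / model$b)^(1 / model$c)
}

#' Fit the linear THD to CCL relationship
#'
#' Ordinary least squares of curved carapace length on total humerus section
#' diameter, used to impute body size for specimens recovered without a CCL
#' measurement. Prediction is gated on adjusted r-squared > `gate_r2`.
#'
#' @param data Data frame with columns `thd_mm` and `ccl_cm`.
#' @param gate_r2 Minimum adjusted r-squared required before the model may be
#'   used for prediction (default 0.9).
#' @return An object of class `thd_ccl_fit` with fields `slope` (cm/mm),
#'   `intercept` (cm), `adj_r2`, and `n`.
#' @export
#' @examples
#' d <- tibble::tibble(thd_mm = 1:10, ccl_cm = 2 * (1:10) + 1)
#' fit_thd_ccl(d)
fit_thd_ccl <- function(data, gate_r2 = 0.9) {
  assert_columns(data, c("thd_mm", "ccl_cm"), "THD/CCL pair data")
  data <- data[complete.cases(data[, c("thd_mm", "ccl_cm")]), ]
  if (nrow(data) < 3) {
    skel_abort("At least 3 complete (THD, CCL) pairs are required.",
               "skelegrow_precondition_error")
  }
  if (diff(range(data$thd_mm)) <= 1) {
    skel_abort("THD values must span more than 1 mm to fit the size model.",
               "skelegrow_precondition_error")
  }
  fit <- lm(ccl_cm ~ thd_mm, data = data)
  if (anyNA(coef(fit))) {
    skel_abort("Singular fit: THD values are effectively constant.",
               "skelegrow_fit_error")
  }
  # summary.lm warns on exact fits; the perfect-fit case is legitimate here
  s <- suppressWarnings(summary(fit))
  structure(
    list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         adj_r2 = s$adj.r.squared, n = nrow(data), sigma = s$sigma,
         se = unname(s$coefficients[, "Std. Error"]), gate_r2 = gate_r2),
    class = "thd_ccl_fit"
  )
}

#' @export
print.thd_ccl_fit <- function(x, ...) {
  cat(sprintf("Linear size model: CCL = %.4g * THD + %.4g (adj r2 = %.3f, n = %d)\n",
              x$slope, x$intercept, x$adj_r2, x$n))
  invisible(x)
}

#' @export
tidy.thd_ccl_fit <- function(x, ...) {
  tibble(term = c("intercept", "slope"),
         estimate = c(x$intercept, x$slope),
         std.error = x$se)
}

#' @export
glance.thd_ccl_fit <- function(x, ...) {
  tibble(adj.r.squared = x$adj_r2, sigma = x$sigma, nobs = x$n)
}

#' Predict CCL from total humerus section diameter
#'
#' Refuses to predict when the fit failed its adjusted r-squared gate, since a
#' weak THD-CCL relationship makes imputed body sizes untrustworthy.
#'
#' @param model A [fit_thd_ccl()] result.
#' @param thd_mm Positive diameter value(s), mm.
#' @return Predicted CCL (cm).
#' @export
predict_ccl <- function(model, thd_mm) {
  stopifnot(inherits(model, "thd_ccl_fit"))
  if (model$adj_r2 <= model$gate_r2) {
    skel_abort(
      sprintf("THD-CCL model gate failed (adj r2 = %.3f <= %.2f); refusing to predict.",
              model$adj_r2, model$gate_r2),
      "skelegrow_gate_error"
    )
  }
  if (any(!is.finite(thd_mm)) || any(thd_mm <= 0)) {
    skel_abort("`thd_mm` must be positive.", "skelegrow_value_error")
  }
  model$slope * thd_mm + model$intercept
}

#' Fit the allometric length model by nonlinear least squares
#'
#' Optimizes `(b, c)` in `L = Lop + b (D - Dop)^c` with the hatchling anchors
#' held fixed, minimizing the sum of squared CCL residuals. Multiple starting
#' values of the exponent (`c` in 0.5, 1, 1.5) guard against local minima.
#'
#' @param data Data frame with columns `d_mm` (section diameter) and `ccl_cm`.
#'   Rows with `d_mm < Dop` are rejected; rows at exactly `Dop` contribute
#'   `(L - Lop)^2` to the objective.
#' @param anchors A [hatchling_anchors()] object.
#' @return An [allometric_model()] with `residual_sse`, `n` and `converged` set.
#' @export
fit_allometric <- function(data, anchors = hatchling_anchors()) {
  stopifnot(inherits(anchors, "hatchling_anchors"))
  assert_columns(data, c("d_mm", "ccl_cm"), "diameter/CCL pair data")
  data <- data[complete.cases(data[, c("d_mm", "ccl_cm")]), ]
  if (any(data$d_mm < anchors$dop_mm)) {
    skel_abort("All diameters must be at least the anchor Dop.",
               "skelegrow_precondition_error")
  }
  if (sum(data$d_mm > anchors$dop_mm) < 5) {
    skel_abort("At least 5 pairs with diameter above Dop are required.",
               "skelegrow_precondition_error")
  }
  lop <- anchors$lop_cm
  dop <- anchors$dop_mm
  dd <- data$d_mm - dop
  ll <- data$ccl_cm
  fits <- list()
  for (c0 in c(0.5, 1, 1.5)) {
    b0 <- max(1e-6, coef(lm(I(ll - lop) ~ 0 + I(dd^c0)))[1])
    fit <- tryCatch(
      nls(ll ~ lop + b * dd^c, start = list(b = b0, c = c0),
          algorithm = "port", lower = c(b = 1e-8, c = 1e-8),
          control = list(maxiter = 200, warnOnly = FALSE)),
      error = function(e) NULL
    )
    if (!is.null(fit)) fits[[length(fits) + 1]] <- fit
  }
  if (length(fits) == 0) {
    skel_abort(
      "Allometric fit failed to converge from all starting exponents (0.5, 1, 1.5).",
      "skelegrow_fit_error"
    )
  }
  sse <- map_dbl(fits, function(f) sum(resid(f)^2))
  best <- fits[[which.min(sse)]]
  cf <- coef(best)
  allometric_model(lop, dop, b = unname(cf["b"]), c = unname(cf["c"]),
                   residual_sse = min(sse), n = nrow(data), converged = TRUE)
}

#' @export
tidy.allometric_model <- function(x, ...) {
  tibble(term = c("lop_cm", "dop_mm", "b", "c"),
         estimate = c(x$anchors$lop_cm, x$anchors$dop_mm, x$b, x$c),
         fixed = c(TRUE, TRUE, FALSE, FALSE))
}

#' @export
glance.allometric_model <- function(x, ...) {
  tibble(residual_sse = x$residual_sse, nobs = x$n, converged = x$converged)
}

#' Back-calculate CCL at a LAG under the body proportional hypothesis
#'
#' BPH assumes an individual's length deviates from the population
#' length-structure curve by a constant proportion, giving
#' `L_lag = f(d_lag) * L_final / f(d_final)` with `f` the allometric model.
#' At `d_lag = d_final` the result is exactly `l_final` for any model.
#'
#' @param model An [allometric_model()].
#' @param d_lag LAG diameter(s), mm. Values marginally below the anchor
#'   diameter are clamped with a warning (measurement noise tolerance).
#' @param d_final Final section diameter (bone edge / THD), mm.
#' @param l_final CCL at recovery, cm (> 0).
#' @return Back-calculated CCL (cm), vectorized over `d_lag`.
#' @export
back_calculate_ccl <- function(model, d_lag, d_final, l_final) {
  stopifnot(inherits(model, "allometric_model"))
  if (length(d_final) != 1 || length(l_final) != 1) {
    skel_abort("`d_final` and `l_final` must be scalars.", "skelegrow_value_error")
  }
  if (!is.finite(l_final) || l_final <= 0) {
    skel_abort("`l_final` must be positive.", "skelegrow_value_error")
  }
  if (any(d_lag > d_final + 1e-9)) {
    skel_abort("`d_lag` may not exceed `d_final` (LAGs lie inside the bone edge).",
               "skelegrow_ordering_error")
  }
  dop <- model$anchors$dop_mm
  if (any(d_lag < dop)) {
    warn(sprintf("%d LAG diameter(s) below Dop clamped to Dop = %g mm.",
                 sum(d_lag < dop), dop))
    d_lag <- pmax(d_lag, dop)
  }
  f <- function(d) model$anchors$lop_cm + model$b * (pmax(d - dop, 0))^model$c
  f(d_lag) * l_final / f(d_final)
}
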