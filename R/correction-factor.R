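#' Correction-factor model for LAGs lost to resorption
#'
#' The correction factor (CF) is a fitted relationship `y = f(x)` between LAG
#' number `x` (annulus = 1) and LAG diameter `y` (mm), trained on
#' directly-ageable bones that retain their year-1 annulus. Inverting it at a
#' resorption-core diameter estimates how many yearly LAGs the core has
#' destroyed. Polynomial kinds store coefficients `(a0, a1, ...)` of
#' `y = a0 + a1 x + a2 x^2 + ...`; the `monotone_smoother` kind stores an
#' isotonic-regression-based monotone interpolant.
#'
#' @param coefficients Numeric vector `(a0, a1, ...)` for polynomial kinds.
#' @param kind One of `"poly1"`, `"poly2"`, `"poly3"`, `"monotone_smoother"`.
#' @param r2 Training r-squared.
#' @param training_max_diameter Largest LAG diameter (mm) seen in training;
#'   inversion beyond it is extrapolation and is flagged.
#' @param n_lags,n_turtles Training sample sizes.
#' @param smoother For `kind = "monotone_smoother"`: list with `x`, `y` knots.
#' @return An object of class `cf_model`.
#' @export
#' @examples
#' # the study's published second-order correction factor
#' cf1 <- correction_factor_model(c(5.53, 1.38, 0.227), kind = "poly2",
#'                                r2 = 0.584, training_max_diameter = 12.5,
#'                                n_lags = 23, n_turtles = 15)
#' estimate_lost_lags(cf1, 5.53 + 1.38 + 0.227)  # exactly 1
correction_factor_model <- function(coefficients = NULL,
                                    kind = c("poly2", "poly1", "poly3",
                                             "monotone_smoother"),
                                    r2 = NA_real_,
                                    training_max_diameter = NA_real_,
                                    n_lags = NA_integer_,
                                    n_turtles = NA_integer_,
                                    smoother = NULL) {
  kind <- match.arg(kind)
  if (kind != "monotone_smoother") {
    order <- as.integer(substring(kind, 5))
    if (is.null(coefficients) || length(coefficients) != order + 1) {
      skel_abort(sprintf("`%s` needs %d coefficients (a0..a%d).",
                         kind, order + 1, order),
                 "skelegrow_value_error")
    }
  } else if (is.null(smoother)) {
    skel_abort("`monotone_smoother` kind needs a `smoother` knot list.",
               "skelegrow_value_error")
  }
  structure(
    list(kind = kind, coefficients = coefficients, r2 = r2,
         training_max_diameter = training_max_diameter,
         n_lags = n_lags, n_turtles = n_turtles, smoother = smoother),
    class = "cf_model"
  )
}

#' @export
print.cf_model <- function(x, ...) {
  cat(sprintf("Correction-factor model (%s), r2 = %.3f\n", x$kind, x$r2))
  if (!is.null(x$coefficients)) {
    cat("  y =", paste(sprintf("%.4g%s", x$coefficients,
                               c("", " x", paste0(" x^", seq_len(max(0, length(x$coefficients) - 2)) + 1))[
                                 seq_along(x$coefficients)]),
                       collapse = " + "), "\n")
  }
  cat(sprintf("  trained on %s LAGs from %s turtles, max diameter %.3g mm\n",
              x$n_lags, x$n_turtles, x$training_max_diameter))
  invisible(x)
}

#' @export
tidy.cf_model <- function(x, ...) {
  if (x$kind == "monotone_smoother") {
    tibble(term = sprintf("knot_%d", seq_along(x$smoother$x)),
           x = x$smoother$x, y = x$smoother$y)
  } else {
    tibble(term = paste0("a", seq_along(x$coefficients) - 1),
           estimate = x$coefficients)
  }
}

#' @export
glance.cf_model <- function(x, ...) {
  tibble(kind = x$kind, r.squared = x$r2,
         training_max_diameter = x$training_max_diameter,
         n_lags = x$n_lags, n_turtles = x$n_turtles)
}

# evaluate the CF curve at LAG number x (vectorized); smoothers extend
# linearly beyond their knot range with the boundary segment slopes
cf_eval <- function(model, x) {
  if (model$kind == "monotone_smoother") {
    s <- model$smoother
    fn <- s$fun
    lo <- s$x[1]; hi <- s$x[length(s$x)]
    out <- numeric(length(x))
    inside <- x >= lo & x <= hi
    out[inside] <- fn(x[inside])
    out[x < lo] <- s$y[1] + s$slope_lo * (x[x < lo] - lo)
    out[x > hi] <- s$y[length(s$y)] + s$slope_hi * (x[x > hi] - hi)
    out
  } else {
    a <- model$coefficients
    out <- rep(a[1], length(x))
    for (j in seq_along(a)[-1]) out <- out + a[j] * x^(j - 1)
    out
  }
}

cf_is_monotone <- function(model, x_max) {
  grid <- seq(0, x_max, length.out = 200)
  all(diff(cf_eval(model, grid)) > -1e-9)
}

fit_monotone_smoother <- function(x, y) {
  ord <- order(x)
  iso <- isoreg(x[ord], y[ord])
  # collapse to unique abscissae (isotonic fitted means)
  kx <- sort(unique(x))
  ky <- map_dbl(kx, function(v) mean(iso$yf[x[ord] == v]))
  if (length(kx) >= 3 && all(diff(ky) > 0)) {
    fun <- splinefun(kx, ky, method = "hyman")
  } else {
    fun <- approxfun(kx, ky, rule = 2)
  }
  slope_lo <- if (length(kx) > 1) (ky[2] - ky[1]) / (kx[2] - kx[1]) else 1
  nk <- length(kx)
  slope_hi <- if (nk > 1) (ky[nk] - ky[nk - 1]) / (kx[nk] - kx[nk - 1]) else 1
  list(x = kx, y = ky, fun = fun, slope_lo = max(slope_lo, 1e-9),
       slope_hi = max(slope_hi, 1e-9), fitted = fun(x))
}

#' Fit the correction factor on annulus-retaining bones
#'
#' Builds (LAG number, LAG diameter) training pairs from every
#' annulus-retaining bone (annulus = LAG 1), fits polynomials of order 1 to 3
#' and a monotone smoother (isotonic regression with monotone-cubic
#' interpolation), and returns the highest-r-squared candidate that is
#' monotone increasing over `[0, max LAG number]`. Ties are broken toward the
#' lowest polynomial order, then parametric over nonparametric.
#'
#' @param data Either a cohort tibble (training pairs are extracted from
#'   rows with `has_annulus = TRUE`) or a data frame with columns
#'   `specimen_id`, `lag_number`, `lag_diameter_mm`.
#' @return A [correction_factor_model()] of the selected kind.
#' @export
fit_correction_factor <- function(data) {
  if ("lag_diameters_mm" %in% names(data)) {
    train <- data |>
      filter(.data$has_annulus) |>
      transmute(.data$specimen_id, d = .data$lag_diameters_mm) |>
      mutate(lag_number = map(.data$d, seq_along)) |>
      unnest(c("d", "lag_number")) |>
      rename(lag_diameter_mm = "d")
  } else {
    assert_columns(data, c("specimen_id", "lag_number", "lag_diameter_mm"),
                   "correction-factor training data")
    train <- data
  }
  if (nrow(train) < 5 || length(unique(train$specimen_id)) < 3) {
    skel_abort(
      "Correction factor needs at least 5 (LAG number, diameter) points from at least 3 annulus-retaining turtles.",
      "skelegrow_precondition_error"
    )
  }
  x <- train$lag_number
  y <- train$lag_diameter_mm
  x_max <- max(x)
  sst <- sum((y - mean(y))^2)
  r2_of <- function(fitted) if (sst == 0) 1 else 1 - sum((y - fitted)^2) / sst

  candidates <- list()
  for (ord in 1:3) {
    if (length(unique(x)) < ord + 1) next
    X <- outer(x, 0:ord, `^`)
    cf <- tryCatch(qr.solve(qr(X), y), error = function(e) NULL)
    if (is.null(cf) || anyNA(cf)) next
    m <- correction_factor_model(as.numeric(cf), kind = paste0("poly", ord),
                                 r2 = r2_of(drop(X %*% cf)),
                                 training_max_diameter = max(y),
                                 n_lags = length(y),
                                 n_turtles = length(unique(train$specimen_id)))
    candidates[[length(candidates) + 1]] <- list(model = m, order = ord,
                                                 parametric = TRUE)
  }
  sm <- fit_monotone_smoother(x, y)
  msm <- correction_factor_model(kind = "monotone_smoother",
                                 r2 = r2_of(sm$fitted),
                                 training_max_diameter = max(y),
                                 n_lags = length(y),
                                 n_turtles = length(unique(train$specimen_id)),
                                 smoother = sm)
  candidates[[length(candidates) + 1]] <- list(model = msm, order = 99,
                                               parametric = FALSE)

  ok <- purrr::keep(candidates, function(cand) cf_is_monotone(cand$model, x_max))
  if (length(ok) == 0) {
    skel_abort("No monotone correction-factor candidate could be fitted.",
               "skelegrow_fit_error")
  }
  r2s <- map_dbl(ok, function(cand) cand$model$r2)
  best_r2 <- max(r2s)
  tied <- ok[r2s >= best_r2 - 1e-9]
  orders <- map_dbl(tied, "order")
  tied[[which.min(orders)]]$model
}

# root of cf_eval(model, x) = core on the increasing branch; NA-free scalar
cf_invert <- function(model, core) {
  y0 <- cf_eval(model, 0)
  if (core <= y0) return(0)
  if (model$kind == "poly2") {
    a <- model$coefficients
    if (abs(a[3]) < 1e-12) return((core - a[1]) / a[2])
    disc <- a[2]^2 - 4 * a[3] * (a[1] - core)
    if (disc < 0) {
      # concave quadratic whose maximum lies below the core diameter
      vertex <- -a[2] / (2 * a[3])
      warn(sprintf("Core diameter %.3g mm exceeds the correction factor's maximum; returning the LAG number at its turning point (%.2f).",
                   core, vertex))
      return(vertex)
    }
    roots <- (-a[2] + c(-1, 1) * sqrt(disc)) / (2 * a[3])
    # increasing branch: smaller root for concave, the +sqrt root for convex
    return(if (a[3] > 0) max(roots) else min(roots))
  }
  if (model$kind == "poly1") {
    return((core - model$coefficients[1]) / model$coefficients[2])
  }
  # cubic or smoother: bisection on the increasing branch
  f <- function(x) cf_eval(model, x) - core
  hi <- 1
  repeat {
    if (f(hi) >= 0) break
    nxt <- hi * 2
    if (cf_eval(model, nxt) <= cf_eval(model, hi) || nxt > 1e4) {
      warn(sprintf("Core diameter %.3g mm exceeds the correction factor's maximum; returning the LAG number at its turning point (%.2f).",
                   core, hi))
      return(hi)
    }
    hi <- nxt
  }
  uniroot(f, c(0, hi), tol = 1e-10)$root
}

#' Estimate the number of LAGs destroyed by a resorption core
#'
#' Solves the correction-factor curve `y(x) = core_diameter` for the unique
#' positive LAG number on its increasing branch (closed form for quadratics,
#' bisection otherwise). A core diameter at or below the curve's intercept
#' `y(0)` yields 0. Cores beyond the training maximum diameter are
#' extrapolations and raise a warning.
#'
#' The returned value is the LAG number whose diameter equals the supplied
#' one: fed a true resorption-core boundary it is the count of LAGs inside
#' the core; fed the diameter of the innermost *retained* LAG (the usual
#' observable proxy) it is that LAG's own number, one more than the count of
#' LAGs lost interior to it (see [assign_ages()]).
#'
#' @param model A [correction_factor_model()].
#' @param core_diameter Positive core diameter(s), mm.
#' @param warn_extrapolation Warn when a core exceeds the training maximum.
#' @return Non-negative real LAG number(s), vectorized over `core_diameter`.
#' @export
estimate_lost_lags <- function(model, core_diameter, warn_extrapolation = TRUE) {
  stopifnot(inherits(model, "cf_model"))
  if (any(!is.finite(core_diameter)) || any(core_diameter <= 0)) {
    skel_abort("`core_diameter` must be positive.", "skelegrow_value_error")
  }
  extrap <- !is.na(model$training_max_diameter) &
    core_diameter > model$training_max_diameter
  if (warn_extrapolation && any(extrap)) {
    warn(sprintf("%d core diameter(s) exceed the correction factor's training maximum (%.3g mm); lost-LAG estimates are extrapolations.",
                 sum(extrap), model$training_max_diameter))
  }
  map_dbl(core_diameter, function(cd) cf_invert(model, cd))
}

#' Assign a final age and per-LAG ages to every bone
#'
#' Hatch-mark-only bones are age 0. Annulus-retaining bones are directly
#' aged: one LAG = 1 year, so the final age is the retained LAG count and the
#' LAG ages are 1, 2, .... For bones missing the annulus, the number of lost
#' LAGs is estimated from the innermost retained LAG diameter through the
#' correction factor; the fractional lost count is kept internally and only
#' the final age (retained + lost) is rounded to a whole year. The outermost
#' LAG receives the final age and each LAG inward is one year younger.
#'
#' @param cohort A cohort tibble.
#' @param model A fitted [correction_factor_model()].
#' @param lost_convention `"interior"` (default): the correction factor
#'   inverted at the innermost retained LAG diameter returns that LAG's own
#'   number, so the LAGs lost interior to it are one fewer. `"inclusive"`
#'   counts the inverted LAG number itself as lost (the convention under
#'   which published lost-LAG tallies are usually printed); it ages every
#'   resorbed bone one year older.
#' @return A tibble with one row per bone: `specimen_id`, `lags_retained`,
#'   `lags_lost` (fractional), `final_age` (whole years), `extrapolated`
#'   (core beyond CF training range) and `lag_ages` (list column of
#'   consecutive integer ages, innermost to outermost).
#' @export
assign_ages <- function(cohort, model = NULL,
                        lost_convention = c("interior", "inclusive")) {
  lost_convention <- match.arg(lost_convention)
  needs_cf <- any(!cohort$has_annulus & !cohort$hatch_mark_only &
                    lengths(cohort$lag_diameters_mm) > 0)
  if (needs_cf && !inherits(model, "cf_model")) {
    skel_abort("A correction-factor model is required: the cohort contains bones missing their annulus.",
               "skelegrow_precondition_error")
  }
  rows <- pmap(
    list(cohort$specimen_id, cohort$lag_diameters_mm,
         cohort$has_annulus, cohort$hatch_mark_only),
    function(id, d, annulus, hatch_only) {
      n_ret <- length(d)
      if (hatch_only || n_ret == 0) {
        return(tibble(specimen_id = id, lags_retained = 0L, lags_lost = 0,
                      final_age = 0L, extrapolated = FALSE,
                      lag_ages = list(integer(0))))
      }
      if (annulus) {
        return(tibble(specimen_id = id, lags_retained = n_ret, lags_lost = 0,
                      final_age = n_ret, extrapolated = FALSE,
                      lag_ages = list(seq_len(n_ret))))
      }
      number <- estimate_lost_lags(model, d[1], warn_extrapolation = FALSE)
      lost <- if (lost_convention == "interior") max(number - 1, 0) else number
      final <- max(as.integer(round(n_ret + lost)), n_ret)
      tibble(specimen_id = id, lags_retained = n_ret, lags_lost = lost,
             final_age = final,
             extrapolated = !is.na(model$training_max_diameter) &&
               d[1] > model$training_max_diameter,
             lag_ages = list(seq(final - n_ret + 1L, final)))
    }
  )
  ages <- list_rbind(rows)
  if (any(ages$extrapolated)) {
    inform(sprintf(
      "Correction factor extrapolated beyond its training range for %d bone(s): %s",
      sum(ages$extrapolated),
      paste(ages$specimen_id[ages$extrapolated], collapse = ", ")))
  }
  ages
}
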