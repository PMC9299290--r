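#' Assemble size-at-age points for growth-curve fitting
#'
#' Combines every back-calculated (age, CCL) pair from the reconstructed
#' records with age-0 points for hatch-mark-only bones (their recovery CCL).
#'
#' @param growth A [reconstruct_growth()] result.
#' @param cohort Optional cohort tibble; supplies hatch-mark-only age-0 rows.
#' @return A tibble with `specimen_id`, `age`, `ccl_cm`.
#' @export
size_at_age_points <- function(growth, cohort = NULL) {
  pts <- growth |> select("specimen_id", "age", "ccl_cm")
  if (!is.null(cohort)) {
    hatch <- cohort |>
      filter(.data$hatch_mark_only, !is.na(.data$ccl_cm)) |>
      transmute(.data$specimen_id, age = 0L, .data$ccl_cm)
    pts <- bind_rows(hatch, pts)
  }
  pts
}

#' Penalized cubic spline of size on age with per-animal random intercepts
#'
#' Fits `ccl ~ s(age)` with a penalized cubic regression spline plus a
#' per-animal random intercept (a generalized additive mixed model in its
#' random-effect-smooth form), smoothing parameters chosen by REML with a
#' GCV fallback. The population curve and its pointwise 95% confidence band
#' come from the fit's posterior variance, excluding the random effect.
#'
#' @param points Tibble with `age`, `ccl_cm`, `specimen_id` (at least 20
#'   points from at least 5 animals).
#' @param k Spline basis dimension (default adapts to the number of distinct
#'   ages, at most 10).
#' @return An object of class `sat_spline` with the fitted model, the age
#'   domain, effective degrees of freedom, adjusted r-squared and the
#'   random-intercept standard deviation.
#' @export
fit_size_at_age_spline <- function(points, k = NULL) {
  assert_columns(points, c("age", "ccl_cm", "specimen_id"), "size-at-age points")
  points <- points[complete.cases(points[, c("age", "ccl_cm")]), ]
  if (nrow(points) < 20 || length(unique(points$specimen_id)) < 5) {
    skel_abort("Spline fit needs at least 20 points from at least 5 animals.",
               "skelegrow_precondition_error")
  }
  dat <- tibble(age = points$age, ccl = points$ccl_cm,
                turtle = factor(points$specimen_id))
  k <- k %||% min(10L, length(unique(dat$age)) - 1L)
  if (k < 3) {
    skel_abort("Too few distinct ages for a cubic spline basis.",
               "skelegrow_fit_error")
  }
  fit <- tryCatch(
    gam(ccl ~ s(age, bs = "cr", k = k) + s(turtle, bs = "re"),
        data = dat, method = "REML"),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    fit <- tryCatch(
      gam(ccl ~ s(age, bs = "cr", k = k) + s(turtle, bs = "re"),
          data = dat, method = "GCV.Cp"),
      error = function(e) {
        skel_abort(sprintf("Spline fit failed: %s", conditionMessage(e)),
                   "skelegrow_fit_error")
      }
    )
  }
  sm <- summary(fit)
  vc_out <- utils::capture.output(vc <- mgcv::gam.vcomp(fit, rescale = TRUE))
  re_sd <- tryCatch(unname(vc["s(turtle)", "std.dev"]), error = function(e) NA_real_)
  structure(
    list(fit = fit, domain = range(dat$age), ref_turtle = levels(dat$turtle)[1],
         edf = unname(sm$edf[1]), adj_r2 = sm$r.sq, n = nrow(dat),
         n_turtles = nlevels(dat$turtle), re_sd = re_sd),
    class = "sat_spline"
  )
}

#' @export
print.sat_spline <- function(x, ...) {
  cat(sprintf("Penalized spline size-at-age fit: Edf = %.3f, adj r2 = %.3f\n",
              x$edf, x$adj_r2))
  cat(sprintf("  %d points, %d animals, random-intercept sd = %.3g cm\n",
              x$n, x$n_turtles, x$re_sd))
  cat(sprintf("  age domain [%g, %g] yr\n", x$domain[1], x$domain[2]))
  invisible(x)
}

#' Predict the population size-at-age curve with 95% confidence band
#'
#' @param object A [fit_size_at_age_spline()] result.
#' @param age Ages (yr) inside the fitted domain.
#' @param ... Unused.
#' @return A tibble with `age`, `ccl_cm`, `lower95`, `upper95`.
#' @export
predict.sat_spline <- function(object, age, ...) {
  if (any(age < object$domain[1] - 1e-9 | age > object$domain[2] + 1e-9)) {
    skel_abort(sprintf("Prediction is defined only on the fitted age domain [%g, %g].",
                       object$domain[1], object$domain[2]),
               "skelegrow_domain_error")
  }
  nd <- data.frame(age = age, turtle = factor(object$ref_turtle))
  p <- predict(object$fit, newdata = nd, se.fit = TRUE, exclude = "s(turtle)",
               newdata.guaranteed = TRUE)
  tibble(age = age, ccl_cm = as.numeric(p$fit),
         lower95 = as.numeric(p$fit - 1.96 * p$se.fit),
         upper95 = as.numeric(p$fit + 1.96 * p$se.fit))
}

#' @export
glance.sat_spline <- function(x, ...) {
  tibble(edf = x$edf, adj.r.squared = x$adj_r2, nobs = x$n,
         n_turtles = x$n_turtles, re_sd = x$re_sd)
}

# invert a monotone curve given as function(age) -> value; NA if target
# above the curve's maximum on the domain
invert_curve <- function(fn, target, domain, grid_n = 401) {
  ages <- seq(domain[1], domain[2], length.out = grid_n)
  vals <- fn(ages)
  if (target <= vals[1]) return(domain[1])
  if (target > max(vals)) return(NA_real_)
  idx <- which(vals >= target)[1]
  uniroot(function(a) fn(a) - target, c(ages[idx - 1], ages[idx]),
          tol = 1e-8)$root
}

#' Age at a given size from the spline curve
#'
#' Inverts the mean spline curve by bisection; confidence ages come from
#' inverting the lower and upper 95% bands (the lower band yields the upper
#' age bound and vice versa). Sizes above the curve's maximum are reported
#' out-of-range ("age at or beyond the domain maximum") rather than
#' extrapolated. Queries in a non-monotone region raise an ambiguity error
#' listing the candidate ages.
#'
#' @param fit A [fit_size_at_age_spline()] result.
#' @param ccl_cm Query size(s), cm.
#' @return A tibble with `ccl_cm`, `age`, `lower95`, `upper95`,
#'   `out_of_range`. For an out-of-range query `age` is `NA` and the bounds
#'   refer to the domain maximum.
#' @export
spline_age_at_size <- function(fit, ccl_cm) {
  stopifnot(inherits(fit, "sat_spline"))
  dom <- fit$domain
  grid <- seq(dom[1], dom[2], length.out = 401)
  pred <- predict(fit, grid)
  mean_fn <- function(a) predict(fit, a)$ccl_cm
  lo_fn <- function(a) predict(fit, a)$lower95
  hi_fn <- function(a) predict(fit, a)$upper95
  rows <- map(ccl_cm, function(target) {
    if (target > max(pred$ccl_cm)) {
      return(tibble(ccl_cm = target, age = NA_real_,
                    lower95 = invert_curve(hi_fn, target, dom),
                    upper95 = NA_real_, out_of_range = TRUE))
    }
    # monotonicity over the region up to the first crossing
    idx <- which(pred$ccl_cm >= target)[1]
    region <- pred$ccl_cm[seq_len(max(idx, 2))]
    if (any(diff(region) < -1e-6)) {
      crossings <- which(diff(sign(pred$ccl_cm - target)) != 0)
      skel_abort(
        sprintf("Spline is non-monotone at CCL = %.3g; candidate ages: %s",
                target, paste(round(grid[crossings], 2), collapse = ", ")),
        "skelegrow_ambiguity_error"
      )
    }
    age <- invert_curve(mean_fn, target, dom)
    tibble(ccl_cm = target, age = age,
           lower95 = invert_curve(hi_fn, target, dom),
           upper95 = invert_curve(lo_fn, target, dom),
           out_of_range = FALSE)
  })
  list_rbind(rows)
}

# Fabens model with unit time step is an exact reparameterization of the
# simple linear regression growth = alpha + beta * L, with
# beta = -(1 - exp(-k)) and alpha = Linf * (1 - exp(-k)); the OLS solution
# is therefore the least-squares Fabens fit.
fabens_ols <- function(l_start, growth) {
  vx <- var(l_start)
  if (!is.finite(vx) || vx == 0) return(NULL)
  beta <- stats::cov(l_start, growth) / vx
  alpha <- mean(growth) - beta * mean(l_start)
  if (beta >= 0 || beta <= -1) return(NULL)
  k <- -log(1 + beta)
  linf <- -alpha / beta
  if (!is.finite(k) || !is.finite(linf) || linf <= 0) return(NULL)
  c(k = k, linf = linf)
}

#' Bootstrapped Fabens von Bertalanffy growth model
#'
#' Each bootstrap replicate draws one (starting CCL, annual growth)
#' increment uniformly at random per animal, then least-squares fits the
#' Fabens increment form `growth = (Linf - L)(1 - e^(-k))` (time step fixed
#' at one year, matching annual LAG deposition). Point estimates are the
#' means of the replicate draws; uncertainty is reported both as the draw
#' standard error and as 95% percentile intervals. Replicates whose fit
#' diverges (implied `k` or `Linf` out of range) are dropped and counted;
#' more than 10% drops raises a warning. Every animal appears exactly once
#' per replicate.
#'
#' @param increments A [growth_increments()] result (at least 5 animals with
#'   at least one increment each).
#' @param n_boot Number of bootstrap replicates (default 1000).
#' @param seed Optional integer seed; the same seed reproduces the draws.
#' @return An object of class `vbgm_fit` with `k_hat`, `linf_hat`, draw
#'   tibble `draws`, standard errors, percentile CIs, `n_boot`, `n_dropped`
#'   and `seed`.
#' @export
bootstrap_fabens <- function(increments, n_boot = 1000, seed = NULL) {
  assert_columns(increments, c("specimen_id", "l_start", "growth"),
                 "growth increments")
  inc <- increments[complete.cases(increments[, c("l_start", "growth")]), ]
  split_idx <- split(seq_len(nrow(inc)), inc$specimen_id)
  if (length(split_idx) < 5) {
    skel_abort("Bootstrapped Fabens fit needs increments from at least 5 animals.",
               "skelegrow_precondition_error")
  }
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  ls_all <- inc$l_start
  gr_all <- inc$growth
  draws <- matrix(NA_real_, n_boot, 2)
  dropped <- 0L
  for (b in seq_len(n_boot)) {
    pick <- map_int(split_idx, function(ix) {
      if (length(ix) == 1) ix else ix[sample.int(length(ix), 1)]
    })
    est <- fabens_ols(ls_all[pick], gr_all[pick])
    if (is.null(est)) dropped <- dropped + 1L else draws[b, ] <- est
  }
  draws <- draws[!is.na(draws[, 1]), , drop = FALSE]
  if (dropped > 0.1 * n_boot) {
    warn(sprintf("%d of %d bootstrap replicates dropped (divergent Fabens fits).",
                 dropped, n_boot))
  }
  if (nrow(draws) == 0) {
    skel_abort("All bootstrap replicates diverged; no growth-model fit.",
               "skelegrow_fit_error")
  }
  dr <- tibble(k = draws[, 1], linf = draws[, 2])
  structure(
    list(k_hat = mean(dr$k), linf_hat = mean(dr$linf),
         k_se = sd(dr$k), linf_se = sd(dr$linf),
         k_ci = unname(quantile(dr$k, c(0.025, 0.975))),
         linf_ci = unname(quantile(dr$linf, c(0.025, 0.975))),
         draws = dr, n_boot = n_boot, n_dropped = dropped,
         n_turtles = length(split_idx), seed = seed),
    class = "vbgm_fit"
  )
}

#' @export
print.vbgm_fit <- function(x, ...) {
  cat("Bootstrapped Fabens von Bertalanffy growth model\n")
  cat(sprintf("  Linf = %.1f +/- %.2g cm (95%% CI: %.1f to %.1f)\n",
              x$linf_hat, x$linf_se, x$linf_ci[1], x$linf_ci[2]))
  cat(sprintf("  k    = %.3f +/- %.2g /yr (95%% CI: %.2f to %.2f)\n",
              x$k_hat, x$k_se, x$k_ci[1], x$k_ci[2]))
  cat(sprintf("  %d replicates (%d dropped), %d animals\n",
              x$n_boot, x$n_dropped, x$n_turtles))
  invisible(x)
}

#' @export
tidy.vbgm_fit <- function(x, ...) {
  tibble(term = c("k", "linf"),
         estimate = c(x$k_hat, x$linf_hat),
         std.error = c(x$k_se, x$linf_se),
         conf.low = c(x$k_ci[1], x$linf_ci[1]),
         conf.high = c(x$k_ci[2], x$linf_ci[2]))
}

#' @export
glance.vbgm_fit <- function(x, ...) {
  tibble(n_boot = x$n_boot, n_dropped = x$n_dropped,
         n_turtles = x$n_turtles)
}

#' von Bertalanffy length at age and age at length (closed forms)
#'
#' `vb_length(t) = Linf - (Linf - L0) e^(-k t)`, anchored at the hatchling
#' size `L0` at age 0; `vb_age(L)` is its exact inverse
#' `log((Linf - L0)/(Linf - L)) / k`. The annual-step growth recursion used
#' throughout the package coincides with `vb_length` at whole years, so the
#' forward/inverse round trip is exact.
#'
#' @param k Growth rate (1/yr).
#' @param linf Asymptotic CCL (cm).
#' @param age Age(s), yr.
#' @param ccl_cm Length(s), cm, with `l0 <= ccl_cm < linf`.
#' @param l0 Age-0 anchor length (cm, default 6).
#' @return Numeric vector.
#' @export
vb_length_at_age <- function(k, linf, age, l0 = 6) {
  linf - (linf - l0) * exp(-k * age)
}

#' @rdname vb_length_at_age
#' @export
vb_age <- function(k, linf, ccl_cm, l0 = 6) {
  if (any(ccl_cm < l0)) {
    skel_abort("`ccl_cm` must be at least the age-0 anchor `l0`.",
               "skelegrow_value_error")
  }
  ifelse(ccl_cm >= linf, Inf, log((linf - l0) / (linf - ccl_cm)) / k)
}

#' Age at a given size from the bootstrapped growth model
#'
#' Evaluates the closed-form inverse of the von Bertalanffy curve per
#' bootstrap draw; the point estimate is the mean over draws and the 95% CI
#' the percentile interval of the per-draw ages. Draws whose asymptote lies
#' at or below the query size would give an unbounded age; they are excluded
#' and counted.
#'
#' @param fit A [bootstrap_fabens()] result.
#' @param ccl_cm Query size(s), cm (above `l0`).
#' @param l0 Age-0 anchor length (cm, default 6, the hatchling minimum).
#' @return A tibble with `ccl_cm`, `age`, `lower95`, `upper95`,
#'   `n_unbounded` (excluded draws).
#' @export
vb_age_at_length <- function(fit, ccl_cm, l0 = 6) {
  stopifnot(inherits(fit, "vbgm_fit"))
  if (any(ccl_cm < l0)) {
    skel_abort("`ccl_cm` must be at least `l0`.", "skelegrow_value_error")
  }
  rows <- map(ccl_cm, function(target) {
    ok <- fit$draws$linf > target
    n_ex <- sum(!ok)
    if (!any(ok)) {
      return(tibble(ccl_cm = target, age = Inf, lower95 = Inf, upper95 = Inf,
                    n_unbounded = n_ex))
    }
    ages <- vb_age(fit$draws$k[ok], fit$draws$linf[ok], target, l0)
    ci <- unname(quantile(ages, c(0.025, 0.975)))
    tibble(ccl_cm = target, age = mean(ages), lower95 = ci[1],
           upper95 = ci[2], n_unbounded = n_ex)
  })
  list_rbind(rows)
}
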