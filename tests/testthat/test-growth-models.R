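make_vb_points <- function(n_turtles = 8, ages = 0:25, noise = 0.05,
                           offsets = NULL, seed = 1) {
  set.seed(seed)
  if (is.null(offsets)) {
    offsets <- stats::rnorm(n_turtles, 0, 0.5)
    offsets <- offsets - mean(offsets)
  }
  crossing(turtle = seq_len(n_turtles), age = ages) |>
    mutate(specimen_id = sprintf("S%02d", turtle),
           ccl_cm = vb_length_at_age(0.185, 89.2, age) + offsets[turtle] +
             rnorm(dplyr::n(), 0, noise)) |>
    select(specimen_id, age, ccl_cm)
}

test_that("the spline reproduces a straight line with minimal effective df", {
  set.seed(2)
  pts <- crossing(turtle = 1:6, age = 0:19) |>
    mutate(specimen_id = sprintf("L%02d", turtle),
           ccl_cm = 10 + 2 * age + rnorm(dplyr::n(), 0, 0.01)) |>
    select(specimen_id, age, ccl_cm)
  fit <- fit_size_at_age_spline(pts)
  pred <- predict(fit, 0:19)
  expect_lt(max(abs(pred$ccl_cm - (10 + 2 * (0:19)))), 0.05)
  expect_lt(fit$edf, 2.5)
  expect_true(all(pred$lower95 <= pred$ccl_cm & pred$ccl_cm <= pred$upper95))
})

test_that("the spline tracks a von Bertalanffy curve within 0.1 cm", {
  pts <- make_vb_points(offsets = rep(0, 8), noise = 0.02, seed = 5)
  fit <- fit_size_at_age_spline(pts, k = 20)
  # LAGs are annual marks, so the curve is identified at whole-year ages
  grid <- 0:25
  pred <- predict(fit, grid)
  expect_lt(max(abs(pred$ccl_cm - vb_length_at_age(0.185, 89.2, grid))), 0.1)
  expect_error(predict(fit, 30), class = "skelegrow_domain_error")
})

test_that("an animal duplicated with a size offset produces positive random-intercept variance", {
  pts <- make_vb_points(offsets = rep(0, 8), noise = 0.05, seed = 6)
  shifted <- pts |> filter(specimen_id == "S01") |>
    mutate(specimen_id = "S99", ccl_cm = ccl_cm + 2)
  fit <- fit_size_at_age_spline(bind_rows(pts, shifted))
  expect_gt(fit$re_sd, 0)
})

test_that("spline age-at-size inverts the mean curve and reports out-of-range sizes", {
  pts <- make_vb_points(offsets = rep(0, 8), noise = 0.02, seed = 7)
  fit <- fit_size_at_age_spline(pts)
  target <- predict(fit, 10)$ccl_cm
  inv <- spline_age_at_size(fit, target)
  expect_equal(inv$age, 10, tolerance = 1e-3)
  expect_true(inv$lower95 <= inv$age && inv$age <= inv$upper95)
  # round trip at integer ages of the underlying growth law
  for (t in c(3, 8, 15)) {
    got <- spline_age_at_size(fit, vb_length_at_age(0.185, 89.2, t))
    expect_equal(got$age, t, tolerance = 0.1)
  }
  # beyond the curve's maximum
  oor <- spline_age_at_size(fit, max(predict(fit, seq(0, 25, 0.1))$ccl_cm) + 5)
  expect_true(oor$out_of_range)
  expect_true(is.na(oor$age))
})

test_that("noiseless increments give a degenerate bootstrap at the generating parameters", {
  l <- seq(10, 80, by = 5)
  inc <- tibble(specimen_id = sprintf("T%02d", seq_along(l)),
                from_age = 1L, to_age = 2L, l_start = l,
                growth = (90 - l) * (1 - exp(-0.2)), negative = FALSE)
  fit <- bootstrap_fabens(inc, n_boot = 50, seed = 1)
  expect_equal(fit$k_hat, 0.2, tolerance = 1e-6)
  expect_equal(fit$linf_hat, 90, tolerance = 1e-6)
  expect_lt(diff(fit$k_ci), 1e-8)
  expect_lt(diff(fit$linf_ci), 1e-6)
  expect_equal(fit$n_dropped, 0L)
})

test_that("an animal at the asymptote contributes a zero increment without bias", {
  l <- c(seq(10, 80, by = 10), 90)
  inc <- tibble(specimen_id = sprintf("T%02d", seq_along(l)),
                from_age = 1L, to_age = 2L, l_start = l,
                growth = (90 - l) * (1 - exp(-0.2)), negative = FALSE)
  expect_equal(inc$growth[length(l)], 0)
  fit <- bootstrap_fabens(inc, n_boot = 20, seed = 2)
  expect_equal(fit$k_hat, 0.2, tolerance = 1e-6)
  expect_equal(fit$linf_hat, 90, tolerance = 1e-6)
})

test_that("the closed-form replicate fit equals an independent nonlinear least-squares fit", {
  set.seed(33)
  l <- runif(25, 10, 85)
  g <- (89.2 - l) * (1 - exp(-0.185)) + rnorm(25, 0, 0.4)
  inc <- tibble(specimen_id = sprintf("T%02d", seq_along(l)),
                from_age = 1L, to_age = 2L, l_start = l, growth = g,
                negative = g < 0)
  fit <- bootstrap_fabens(inc, n_boot = 1, seed = 4)  # one animal each: same data every replicate
  oracle <- stats::nls(g ~ (linf - l) * (1 - exp(-k)),
                       start = list(k = 0.3, linf = 80))
  expect_equal(fit$draws$k[1], unname(coef(oracle)["k"]), tolerance = 1e-6)
  expect_equal(fit$draws$linf[1], unname(coef(oracle)["linf"]), tolerance = 1e-6)
})

test_that("bootstrap draws are reproducible under a fixed seed", {
  sim <- recovery_sim(seed = 2, noise = 0.1)
  ages <- truth_ages(sim$truth)
  allom <- fit_cohort_allometry(sim$cohort)
  inc <- growth_increments(reconstruct_growth(sim$cohort, ages, allom))
  f1 <- bootstrap_fabens(inc, n_boot = 40, seed = 123)
  f2 <- bootstrap_fabens(inc, n_boot = 40, seed = 123)
  expect_equal(f1$draws, f2$draws)
  f3 <- bootstrap_fabens(inc, n_boot = 40, seed = 124)
  expect_false(isTRUE(all.equal(f1$draws, f3$draws)))
})

test_that("forward and inverse von Bertalanffy forms round-trip exactly per draw", {
  set.seed(77)
  for (i in 1:25) {
    k <- runif(1, 0.05, 0.4)
    linf <- runif(1, 70, 110)
    t <- runif(1, 0, 40)
    expect_equal(vb_age(k, linf, vb_length_at_age(k, linf, t)), t,
                 tolerance = 1e-10)
  }
})

test_that("age-at-length matches a bisection oracle and handles the asymptote", {
  # closed form against bisection on the forward curve
  cf <- vb_age(0.185, 89.2, 85, l0 = 6)
  bis <- uniroot(function(t) vb_length_at_age(0.185, 89.2, t) - 85,
                 c(0, 200), tol = 1e-12)$root
  expect_equal(cf, bis, tolerance = 1e-8)
  expect_equal(cf, 16.14, tolerance = 0.01)

  l <- seq(10, 80, by = 5)
  inc <- tibble(specimen_id = sprintf("T%02d", seq_along(l)),
                from_age = 1L, to_age = 2L, l_start = l,
                growth = (89.2 - l) * (1 - exp(-0.185)), negative = FALSE)
  fit <- bootstrap_fabens(inc, n_boot = 30, seed = 5)
  # anchor size maps to age zero in every draw
  at0 <- vb_age_at_length(fit, 6)
  expect_equal(at0$age, 0)
  expect_equal(at0$lower95, 0)
  at85 <- vb_age_at_length(fit, 85)
  expect_equal(at85$age, cf, tolerance = 1e-4)
  # sizes at/above every draw's asymptote are unbounded and excluded
  at95 <- vb_age_at_length(fit, 95)
  expect_equal(at95$age, Inf)
  expect_equal(at95$n_unbounded, nrow(fit$draws))
})
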