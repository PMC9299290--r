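test_that("exact quadratic training data recover the generating polynomial", {
  # three turtles contributing LAG numbers 1..4 on the published quadratic
  pts <- tidyr::crossing(specimen_id = c("a", "b", "c"), lag_number = 1:4) |>
    dplyr::mutate(lag_diameter_mm = 5.53 + 1.38 * lag_number +
                    0.227 * lag_number^2)
  fit <- fit_correction_factor(pts)
  expect_equal(fit$kind, "poly2")
  expect_equal(fit$coefficients, c(5.53, 1.38, 0.227), tolerance = 1e-6)
  expect_equal(fit$r2, 1, tolerance = 1e-9)
  expect_equal(fit$n_turtles, 3L)
})

test_that("ties on r-squared break toward the lowest polynomial order", {
  pts <- tidyr::crossing(specimen_id = c("a", "b", "c"), lag_number = 1:5) |>
    dplyr::mutate(lag_diameter_mm = 2 + 3 * lag_number)
  fit <- fit_correction_factor(pts)
  expect_equal(fit$kind, "poly1")
  expect_equal(fit$coefficients, c(2, 3), tolerance = 1e-8)
})

test_that("too few points or turtles is a precondition error", {
  pts <- tibble::tibble(specimen_id = c("a", "a", "b"),
                        lag_number = c(1, 2, 1),
                        lag_diameter_mm = c(6, 9, 6.1))
  expect_error(fit_correction_factor(pts),
               class = "skelegrow_precondition_error")
})

test_that("lost-LAG inversion solves the published quadratic exactly", {
  cf1 <- cf1_model()
  # root at zero: core equal to the intercept
  expect_equal(estimate_lost_lags(cf1, 5.53), 0)
  expect_equal(estimate_lost_lags(cf1, 5.0), 0)
  # evaluating the polynomial at 1 and inverting returns exactly 1
  expect_equal(estimate_lost_lags(cf1, 5.53 + 1.38 + 0.227), 1,
               tolerance = 1e-12)
  # the study's adult core range maps into its printed lost-LAG range
  cores <- seq(16.7, 29.1, length.out = 15)
  lost <- suppressWarnings(round(estimate_lost_lags(cf1, cores)))
  expect_true(all(lost >= 4 & lost <= 8))
  # monotone non-decreasing in core diameter
  raw <- suppressWarnings(estimate_lost_lags(cf1, cores))
  expect_true(all(diff(raw) >= 0))
  # extrapolation beyond the training maximum warns
  expect_warning(estimate_lost_lags(cf1, 20), "extrapolation")
})

test_that("the monotone smoother interpolates noiseless training data and inverts exactly", {
  m <- allometric_model(6, 2.4, b = 3.665, c = 0.928)
  ccl <- vb_length_at_age(0.185, 89.2, 1:12)
  d <- allometry_diameter(m, ccl)
  pts <- tidyr::crossing(specimen_id = c("a", "b", "c"), lag_number = 1:12) |>
    dplyr::mutate(lag_diameter_mm = d[lag_number])
  fit <- fit_correction_factor(pts)
  expect_equal(fit$kind, "monotone_smoother")
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  for (x in c(2, 5, 9, 11)) {
    expect_equal(estimate_lost_lags(fit, d[x]), x, tolerance = 1e-6)
  }
})

test_that("ages are assigned per the one-LAG-one-year rule", {
  cf1 <- cf1_model()
  cohort <- dplyr::bind_rows(
    one_bone("hatch", numeric(0), ccl = 7, thd = 3, hatch = TRUE),
    one_bone("ann5", c(6.9, 9.0, 10.4, 11.5, 12.4), ccl = 36, annulus = TRUE)
  )
  ages <- assign_ages(cohort, cf1)
  expect_equal(ages$final_age, c(0L, 5L))
  expect_equal(ages$lag_ages[[1]], integer(0))
  expect_equal(ages$lag_ages[[2]], 1:5)
  expect_equal(ages$lags_lost, c(0, 0))
})

test_that("a resorbed bone's age sums retained LAGs with those lost interior to its innermost LAG", {
  cf1 <- cf1_model()
  # 20 retained LAGs whose innermost sits at the diameter of LAG number 7:
  # 6 LAGs lost inside it, final age 26, innermost retained LAG age 7
  y <- function(x) 5.53 + 1.38 * x + 0.227 * x^2
  d <- y(7:26)
  bone <- one_bone("adult", d, ccl = 88, thd = max(d))
  ages <- suppressMessages(assign_ages(bone, cf1))
  expect_equal(ages$lags_retained, 20L)
  expect_equal(ages$lags_lost, 6, tolerance = 1e-9)
  expect_equal(ages$final_age, 26L)
  expect_equal(ages$lag_ages[[1]], 7:26)
  expect_true(ages$extrapolated)
  # the printed-arithmetic convention counts the innermost LAG's number itself
  ages_incl <- suppressMessages(
    assign_ages(bone, cf1, lost_convention = "inclusive"))
  expect_equal(ages_incl$final_age, 27L)
})

test_that("per-LAG ages are consecutive integers ending at the final age", {
  sim <- recovery_sim(seed = 12)
  cf <- fit_correction_factor(sim$cohort)
  ages <- suppressMessages(assign_ages(sim$cohort, cf))
  for (i in seq_len(nrow(ages))) {
    la <- ages$lag_ages[[i]]
    if (length(la) == 0) next
    expect_equal(diff(la), rep(1L, length(la) - 1), ignore_attr = TRUE)
    expect_equal(la[length(la)], ages$final_age[i])
    expect_gte(ages$final_age[i], ages$lags_retained[i])
  }
})

test_that("noiseless resorbed-LAG counts invert exactly at true core diameters inside training range", {
  sim <- recovery_sim(seed = 11)
  cf <- fit_correction_factor(sim$cohort)
  adults <- sim$truth[sim$truth$n_resorbed > 0, ]
  in_range <- adults$core_diameter_mm <= cf$training_max_diameter
  expect_gt(sum(in_range), 0)
  est <- suppressWarnings(
    estimate_lost_lags(cf, adults$core_diameter_mm[in_range]))
  expect_equal(as.integer(round(est)), as.integer(adults$n_resorbed[in_range]),
               ignore_attr = TRUE)
})
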