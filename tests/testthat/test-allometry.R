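test_that("the linear size model recovers exact and noisy generating lines", {
  # exact line
  d <- tibble::tibble(thd_mm = seq(1, 10), ccl_cm = 2 * seq(1, 10) + 1)
  fit <- fit_thd_ccl(d)
  expect_equal(fit$slope, 2, tolerance = 1e-10)
  expect_equal(fit$intercept, 1, tolerance = 1e-10)
  expect_equal(fit$adj_r2, 1, tolerance = 1e-10)

  # noisy recovery, checked against the OLS closed form computed by hand
  set.seed(42)
  thd <- runif(59, 3, 30)
  ccl <- 2.845 * thd + 0.367 + rnorm(59, 0, 0.5)
  noisy <- tibble::tibble(thd_mm = thd, ccl_cm = ccl)
  fit2 <- fit_thd_ccl(noisy)
  X <- cbind(1, thd)
  beta_hat <- solve(t(X) %*% X, t(X) %*% ccl)
  expect_equal(fit2$intercept, beta_hat[1], tolerance = 1e-8)
  expect_equal(fit2$slope, beta_hat[2], tolerance = 1e-8)
  expect_lt(abs(fit2$slope - 2.845), 2 * fit2$se[2])
  expect_lt(abs(fit2$intercept - 0.367), 2 * fit2$se[1])
})

test_that("the linear size model enforces its preconditions and prediction gate", {
  expect_error(fit_thd_ccl(tibble::tibble(thd_mm = c(1, 5), ccl_cm = c(2, 3))),
               class = "skelegrow_precondition_error")
  expect_error(fit_thd_ccl(tibble::tibble(thd_mm = rep(2, 5),
                                          ccl_cm = 1:5)),
               class = "skelegrow_precondition_error")
  # identity prediction
  d <- tibble::tibble(thd_mm = 1:10, ccl_cm = as.numeric(1:10))
  fit <- fit_thd_ccl(d)
  expect_equal(predict_ccl(fit, 10), 10, tolerance = 1e-10)
  # published coefficients evaluated at the hatchling diameter
  pub <- structure(list(slope = 2.845, intercept = 0.367, adj_r2 = 0.99,
                        n = 59L, sigma = NA_real_, se = c(NA, NA),
                        gate_r2 = 0.9),
                   class = "thd_ccl_fit")
  expect_equal(predict_ccl(pub, 2.4), 2.845 * 2.4 + 0.367)
  expect_error(predict_ccl(pub, -1), class = "skelegrow_value_error")
  # gate: a weak fit refuses to predict
  set.seed(7)
  weak <- tibble::tibble(thd_mm = runif(30, 1, 20))
  weak$ccl_cm <- 5 + rnorm(30, 0, 50)
  wf <- fit_thd_ccl(weak)
  expect_error(predict_ccl(wf, 5), class = "skelegrow_gate_error")
})

test_that("nonlinear allometric fit recovers exact generating parameters", {
  truth <- allometric_model(6, 2.4, b = 3.665, c = 0.928)
  d <- seq(3, 30, length.out = 25)
  dat <- tibble::tibble(d_mm = d, ccl_cm = allometry_length(truth, d))
  fit <- fit_allometric(dat, hatchling_anchors(6, 2.4))
  expect_equal(fit$b, 3.665, tolerance = 1e-6)
  expect_equal(fit$c, 0.928, tolerance = 1e-6)
  expect_true(fit$converged)
  # anchor identity holds exactly for the fitted model
  expect_equal(allometry_length(fit, 2.4), 6)

  # linear limit: data generated with exponent 1
  lin <- tibble::tibble(d_mm = d, ccl_cm = 6 + 2.5 * (d - 2.4))
  lfit <- fit_allometric(lin, hatchling_anchors(6, 2.4))
  expect_equal(lfit$c, 1, tolerance = 1e-6)

  # a row at exactly Dop contributes only its (L - Lop)^2 residual
  withrow <- dplyr::bind_rows(dat, tibble::tibble(d_mm = 2.4, ccl_cm = 6.5))
  f2 <- fit_allometric(withrow, hatchling_anchors(6, 2.4))
  expect_equal(f2$residual_sse, 0.5^2, tolerance = 1e-6)
})

test_that("BPH back-calculation satisfies its identities and monotonicity", {
  m <- allometric_model(6, 2.4, b = 3.665, c = 0.928)
  # identity at the bone edge, for any model
  expect_equal(back_calculate_ccl(m, 17.3, 17.3, 88.1), 88.1)
  # algebraic reduction at the anchor diameter
  expect_equal(back_calculate_ccl(m, 2.4, 20, 80),
               6 * 80 / (6 + 3.665 * (20 - 2.4)^0.928))
  # direct scalar formula evaluation
  d_lag <- 11.7; d_final <- 25.2; l_final <- 84.3
  f <- function(d) 6 + 3.665 * (d - 2.4)^0.928
  expect_equal(back_calculate_ccl(m, d_lag, d_final, l_final),
               f(d_lag) * l_final / f(d_final), tolerance = 1e-12)
  # monotone increasing in d_lag
  grid <- seq(2.5, 25, length.out = 60)
  vals <- back_calculate_ccl(m, grid, 25.2, 84.3)
  expect_true(all(diff(vals) > 0))
  # ordering error and sub-anchor clamping
  expect_error(back_calculate_ccl(m, 26, 25, 84),
               class = "skelegrow_ordering_error")
  expect_warning(out <- back_calculate_ccl(m, 2.0, 25, 84), "clamped")
  expect_equal(out, back_calculate_ccl(m, 2.4, 25, 84))
})

test_that("inverse allometry composed with back-calculation recovers true size exactly", {
  m <- allometric_model(6, 2.4, b = 3.665, c = 0.928)
  ccl_true <- c(20.1, 31.7, 49.5, 70.3, 84.9)
  d <- allometry_diameter(m, ccl_true)
  got <- back_calculate_ccl(m, d, max(d), max(ccl_true))
  expect_equal(got, ccl_true, tolerance = 1e-9)
})
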