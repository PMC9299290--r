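test_that("the rapprochement detector finds the first qualifying run", {
  expect_equal(detect_rapprochement(c(2.0, 1.1, 0.5, 0.4, 0.3)), 3L,
               ignore_attr = TRUE)
  expect_equal(detect_rapprochement(c(0.4, 0.4, 0.4)), 1L, ignore_attr = TRUE)
  j <- detect_rapprochement(c(1.0, 0.9, 0.8))
  expect_true(is.na(j))
  expect_equal(attr(j, "reason"), "no_run")
  # undetectable (too short) is flagged distinctly from growth still rapid
  j2 <- detect_rapprochement(c(0.1, 0.1))
  expect_true(is.na(j2))
  expect_equal(attr(j2, "reason"), "too_few_increments")
})

test_that("the detector agrees with a brute-force window scan on random series", {
  set.seed(314)
  for (i in 1:300) {
    n <- sample(0:12, 1)
    x <- round(runif(n, 0, 1.2), 2)
    expect_identical(as.integer(detect_rapprochement(x)),
                     brute_rapprochement(x))
  }
})

test_that("lowering the threshold never moves detection earlier", {
  set.seed(99)
  for (i in 1:100) {
    x <- round(runif(8, 0, 1), 2)
    j_loose <- detect_rapprochement(x, threshold = 0.7)
    j_tight <- detect_rapprochement(x, threshold = 0.4)
    if (!is.na(j_loose) && !is.na(j_tight)) expect_gte(j_tight, j_loose)
    if (is.na(j_loose)) expect_true(is.na(j_tight))
  }
})

test_that("maturation age and size are recovered on noiseless simulated adults", {
  sim <- recovery_sim(seed = 11)
  cf <- fit_correction_factor(sim$cohort)
  ages <- suppressMessages(assign_ages(sim$cohort, cf))
  allom <- fit_cohort_allometry(sim$cohort)
  growth <- reconstruct_growth(sim$cohort, ages, allom)
  mat <- estimate_maturity(growth, ages)
  mm <- mat |>
    filter(detected, is.na(excluded_reason)) |>
    left_join(sim$truth, by = "specimen_id", suffix = c("_est", "_true")) |>
    left_join(select(ages, specimen_id, lags_retained), by = "specimen_id")
  expect_gt(nrow(mm), 5)
  # +/- 1 year reflects knife-edge increments exactly at the threshold
  expect_true(all(abs(mm$asm_est - mm$asm_true) <= 1))
  expect_true(all(abs(mm$ssm_est - mm$ssm_true) <= 0.51))
  # reproductive longevity counts the maturation LAG itself
  expect_equal(mm$reproductive_longevity,
               mm$lags_retained - mm$maturation_lag_index + 1L)
})

test_that("juveniles with fast growth are undetected and immature-only records are flagged", {
  g <- tibble(specimen_id = "juv", lag_index = 1:4, age = 1:4,
              lag_diameter_mm = c(6, 9, 11, 12.5),
              ccl_cm = c(20, 31, 40, 48), has_annulus = TRUE,
              ccl_imputed = FALSE)
  a <- tibble(specimen_id = "juv", lags_retained = 4L, lags_lost = 0,
              final_age = 4L, extrapolated = FALSE, lag_ages = list(1:4))
  mat <- estimate_maturity(g, a)
  expect_false(mat$detected)
  expect_equal(mat$note, "no_run")
})

test_that("a bone retaining only post-rapprochement LAGs is excluded from age analysis", {
  # first retained increment already below threshold AND the age needed
  # correction-factor extrapolation: onset not observed
  ccl <- 88 + cumsum(c(0, rep(0.2, 5)))
  g <- tibble(specimen_id = "old", lag_index = 1:6, age = 20:25,
              lag_diameter_mm = seq(32.5, 34, length.out = 6),
              ccl_cm = ccl, has_annulus = FALSE, ccl_imputed = FALSE)
  a <- tibble(specimen_id = "old", lags_retained = 6L, lags_lost = 14,
              final_age = 25L, extrapolated = TRUE, lag_ages = list(20:25))
  mat <- estimate_maturity(g, a)
  expect_true(mat$detected)
  expect_equal(mat$excluded_reason, "onset not observed")
  expect_true(is.na(mat$asm))
  expect_true(is.na(mat$ssm))
})

test_that("nesting histories align with back-calculated years and flag pre-maturation nesting", {
  g <- tibble(specimen_id = "nest", lag_index = 1:10, age = 6:15,
              lag_diameter_mm = seq(15, 28, length.out = 10),
              ccl_cm = seq(70, 88, length.out = 10), has_annulus = FALSE,
              ccl_imputed = FALSE)
  mat <- tibble(specimen_id = "nest", detected = TRUE,
                maturation_lag_index = 5L, asm = 10L, ssm = g$ccl_cm[5],
                reproductive_longevity = 6L, excluded_reason = NA_character_,
                note = NA_character_)
  stranding <- 2020L
  # nesting only in mature years, observed CCL equal to back-calculated
  nh <- tibble(year = c(2017L, 2019L),
               ccl_cm = g$ccl_cm[g$age %in% c(12, 14)])
  cmp <- compare_with_nesting(g, "nest", nh, stranding, maturity = mat)
  expect_equal(cmp$diff, c(0, 0))
  expect_false(any(cmp$pre_maturation))
  # a nesting record two years before the maturation LAG raises one flag
  nh2 <- bind_rows(nh, tibble(year = 2013L, ccl_cm = 75))
  cmp2 <- compare_with_nesting(g, "nest", nh2, stranding, maturity = mat)
  expect_equal(sum(cmp2$pre_maturation), 1)
  # nesting before the estimated hatch year is inconsistent
  nh3 <- tibble(year = 2003L, ccl_cm = 70)
  expect_error(compare_with_nesting(g, "nest", nh3, stranding, maturity = mat),
               class = "skelegrow_consistency_error")
})
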