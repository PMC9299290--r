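# shared fixtures, all generated in code
suppressMessages({
  library(dplyr)
  library(tibble)
  library(tidyr)
  library(purrr)
})

# gap-free ground-truthed cohort: annulus-retaining bones up to age 14 so
# that adult resorption cores fall inside the correction factor's training
# range (the regime in which exact recovery is possible)
recovery_sim <- function(seed, noise = 0, maturity = TRUE) {
  simulate_cohort(
    sim_params(n_turtles = 45, asm_min = 13, maturity_effect = maturity,
               diameter_noise_sd = noise, age_pool = 1:35,
               resorb_min_age = 15),
    seed = seed
  )
}

# age table built from simulator truth (bypasses the correction factor, for
# tests that target downstream stages in isolation)
truth_ages <- function(truth) {
  lagged <- truth[truth$age > 0, ]
  tibble::tibble(
    specimen_id = lagged$specimen_id,
    lags_retained = lagged$age - lagged$n_resorbed,
    lags_lost = as.numeric(lagged$n_resorbed),
    final_age = lagged$age,
    extrapolated = FALSE,
    lag_ages = purrr::map2(lagged$n_resorbed, lagged$age, ~ seq(.x + 1, .y))
  )
}

fit_cohort_allometry <- function(cohort, anchors = hatchling_anchors()) {
  pairs <- cohort[!is.na(cohort$ccl_cm) & !is.na(cohort$thd_mm), ]
  fit_allometric(
    tibble::tibble(d_mm = pairs$thd_mm, ccl_cm = pairs$ccl_cm),
    anchors = anchors
  )
}

# the study's published quadratic correction factor
cf1_model <- function() {
  correction_factor_model(c(5.53, 1.38, 0.227), kind = "poly2", r2 = 0.584,
                          training_max_diameter = 12.5, n_lags = 23L,
                          n_turtles = 15L)
}

# minimal single-bone cohort rows
one_bone <- function(id, d, ccl = NA_real_, thd = max(d, 1),
                     annulus = FALSE, hatch = FALSE) {
  tibble::tibble(
    specimen_id = id, region = "unknown", sex = "unknown",
    ccl_cm = ccl, thd_mm = thd, has_annulus = annulus,
    hatch_mark_only = hatch, lag_diameters_mm = list(d),
    nesting_history = list(tibble::tibble(year = integer(0),
                                          ccl_cm = numeric(0)))
  )
}

map_dbl_or <- function(lst, f, default) {
  vapply(lst, function(x) if (length(x)) f(x) else default, numeric(1))
}

# brute-force rapprochement scan: independent oracle for the detector
brute_rapprochement <- function(x, threshold = 0.5, run_length = 3) {
  n <- length(x)
  if (n < run_length) return(NA_integer_)
  for (j in seq_len(n - run_length + 1)) {
    if (all(x[j:(j + run_length - 1)] <= threshold)) return(j)
  }
  NA_integer_
}

# exhaustive sign-flip enumeration: independent oracle for the paired
# signed-rank p-value (same zero/tie conventions)
enum_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  ws <- signs %*% r
  p_le <- mean(ws <= w + 1e-12)
  p_ge <- mean(ws >= w - 1e-12)
  min(1, 2 * min(p_le, p_ge))
}
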