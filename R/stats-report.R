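#' Coefficient of variation from a reported mean, SE and n
#'
#' CV = SD / mean with SD recovered from the standard error, SD = SE * sqrt(n).
#' Useful for comparing the variability of maturation age and size across
#' populations from published mean +/- SE summaries.
#'
#' @param mean Reported mean (> 0).
#' @param se Reported standard error (>= 0).
#' @param n Sample size (>= 2).
#' @return The dimensionless CV.
#' @export
#' @examples
#' cv_from_moments(16.3, 0.53, 29)  # ~ 0.18
cv_from_moments <- function(mean, se, n) {
  if (any(mean <= 0)) skel_abort("`mean` must be positive.", "skelegrow_value_error")
  if (any(se < 0)) skel_abort("`se` must be non-negative.", "skelegrow_value_error")
  if (any(n < 2)) skel_abort("`n` must be at least 2.", "skelegrow_value_error")
  (se * sqrt(n)) / mean
}

# exact null distribution of the signed-rank statistic W+ over all sign
# assignments, via convolution on doubled (possibly mid-) ranks; returns
# P(W+ <= w) and P(W+ >= w)
signed_rank_exact_p <- function(ranks2, w2) {
  total <- sum(ranks2)
  counts <- numeric(total + 1)  # counts[s + 1] = #assignments with doubled sum s
  counts[1] <- 1
  for (r in ranks2) {
    shifted <- c(rep(0, r), counts[seq_len(length(counts) - r)])
    counts <- counts + shifted
  }
  denom <- 2^length(ranks2)
  p_le <- sum(counts[seq_len(w2 + 1)]) / denom
  p_ge <- sum(counts[seq(w2 + 1, total + 1)]) / denom
  c(p_le = p_le, p_ge = p_ge)
}

#' Paired signed-rank comparison of observed and back-calculated sizes
#'
#' Compares observed nesting CCLs with the back-calculated CCLs of the same
#' calendar years. Repeated pairs within an individual are averaged first so
#' each animal contributes exactly one pair (avoiding pseudoreplication from
#' non-independent repeated measures). Zero differences are dropped before
#' ranking (standard exact-test convention); when every difference is zero
#' the p-value is 1. The two-sided p-value is exact (full enumeration of the
#' sign-flip null via convolution, mid-ranks for ties) for up to 25 non-zero
#' differences and uses the tie-corrected normal approximation above that.
#'
#' @param pairs Tibble with `specimen_id`, `observed`, `back_calculated`
#'   (cm); at least 3 distinct individuals after averaging.
#' @return A one-row tibble with `statistic` (W+, sum of positive ranks),
#'   `p_value`, `n_individuals`, `n_nonzero`, `method`.
#' @export
paired_wilcoxon_by_individual <- function(pairs) {
  assert_columns(pairs, c("specimen_id", "observed", "back_calculated"),
                 "paired size data")
  agg <- pairs |>
    group_by(.data$specimen_id) |>
    summarise(observed = mean(.data$observed),
              back_calculated = mean(.data$back_calculated),
              .groups = "drop")
  n_ind <- nrow(agg)
  if (n_ind < 3) {
    skel_abort("At least 3 distinct individuals are required after averaging.",
               "skelegrow_precondition_error")
  }
  d <- agg$observed - agg$back_calculated
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    return(tibble(statistic = 0, p_value = 1, n_individuals = n_ind,
                  n_nonzero = 0L, method = "all differences zero"))
  }
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (n <= 25) {
    ranks2 <- as.integer(round(2 * r))
    p <- signed_rank_exact_p(ranks2, as.integer(round(2 * w)))
    pval <- min(1, 2 * min(p["p_le"], p["p_ge"]))
    method <- "exact signed rank (sign-flip enumeration)"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (w - mu) / sqrt(sigma2)
    pval <- 2 * pnorm(-abs(z))
    method <- "normal approximation (tie-corrected)"
  }
  tibble(statistic = unname(w), p_value = unname(pval), n_individuals = n_ind,
         n_nonzero = n, method = method)
}

#' Summarize a cohort by life stage and region
#'
#' Life stages: hatchling (hatch mark only), juvenile (annulus retained),
#' adult (LAGs present, annulus resorbed).
#'
#' @param cohort A cohort tibble.
#' @param ages Optional [assign_ages()] result; adds age summaries.
#' @return A tibble with one row per (life stage, region) combination
#'   present, plus an `all` region row per stage.
#' @export
summarize_cohort <- function(cohort, ages = NULL) {
  staged <- cohort |>
    mutate(stage = case_when(
      .data$hatch_mark_only ~ "hatchling",
      .data$has_annulus ~ "juvenile",
      lengths(.data$lag_diameters_mm) > 0 ~ "adult",
      TRUE ~ "unstaged"
    ))
  if (!is.null(ages)) {
    staged <- left_join(staged, select(ages, "specimen_id", "final_age"),
                        by = "specimen_id")
  } else {
    staged$final_age <- NA_integer_
  }
  summarise_block <- function(df) {
    summarise(df,
              n = dplyr::n(),
              ccl_mean = mean(.data$ccl_cm, na.rm = TRUE),
              ccl_se = se_mean(.data$ccl_cm),
              ccl_min = suppressWarnings(min(.data$ccl_cm, na.rm = TRUE)),
              ccl_max = suppressWarnings(max(.data$ccl_cm, na.rm = TRUE)),
              age_mean = mean(.data$final_age, na.rm = TRUE),
              age_se = se_mean(.data$final_age),
              .groups = "drop")
  }
  by_region <- staged |> group_by(.data$stage, .data$region) |> summarise_block()
  overall <- staged |> group_by(.data$stage) |> summarise_block() |>
    mutate(region = "all", .after = "stage")
  bind_rows(overall, by_region) |> arrange(.data$stage, .data$region)
}

#' Summarize maturation estimates
#'
#' Mean, SE, range and coefficient of variation of ASM and SSM over the
#' bones with a detected, non-excluded maturation onset, plus the maximum
#' observed reproductive longevity.
#'
#' @param maturity An [estimate_maturity()] result.
#' @return A one-row tibble; `n_mature = 0` rows carry NA statistics.
#' @export
summarize_maturity <- function(maturity) {
  m <- maturity |> filter(.data$detected, is.na(.data$excluded_reason))
  if (nrow(m) == 0) {
    return(tibble(n_mature = 0L, asm_mean = NA_real_, asm_se = NA_real_,
                  asm_min = NA_real_, asm_max = NA_real_, asm_cv = NA_real_,
                  ssm_mean = NA_real_, ssm_se = NA_real_, ssm_min = NA_real_,
                  ssm_max = NA_real_, ssm_cv = NA_real_,
                  max_reproductive_longevity = NA_real_,
                  n_excluded = sum(!is.na(maturity$excluded_reason))))
  }
  tibble(
    n_mature = nrow(m),
    asm_mean = mean(m$asm), asm_se = se_mean(m$asm),
    asm_min = min(m$asm), asm_max = max(m$asm),
    asm_cv = if (nrow(m) >= 2) sd(m$asm) / mean(m$asm) else NA_real_,
    ssm_mean = mean(m$ssm), ssm_se = se_mean(m$ssm),
    ssm_min = min(m$ssm), ssm_max = max(m$ssm),
    ssm_cv = if (nrow(m) >= 2) sd(m$ssm) / mean(m$ssm) else NA_real_,
    max_reproductive_longevity = max(m$reproductive_longevity),
    n_excluded = sum(!is.na(maturity$excluded_reason))
  )
}

#' Assemble the final report bundle
#'
#' A pure function of the stage outputs: no quantity is recomputed, so the
#' report always matches the stages exactly. Missing stages are listed under
#' `gaps` and their sections set to `NULL` (an empty maturity set is
#' reported as "no mature specimens").
#'
#' @param cohort Cohort tibble (required).
#' @param ages,growth,increments,maturity,growth_summary Stage outputs
#'   (optional; `NULL` marks a gap).
#' @param spline_fit,vbgm_fit Fitted growth models (optional).
#' @param query_ccl Sizes (cm) at which to answer age-at-size queries with
#'   both growth models.
#' @return A list of class `skelegrow_report`.
#' @export
build_report <- function(cohort, ages = NULL, growth = NULL, increments = NULL,
                         maturity = NULL, growth_summary = NULL,
                         spline_fit = NULL, vbgm_fit = NULL,
                         query_ccl = numeric(0)) {
  gaps <- character(0)
  need <- function(x, label) {
    if (is.null(x)) gaps <<- c(gaps, label)
    x
  }
  ages <- need(ages, "ages")
  growth <- need(growth, "growth")
  increments <- need(increments, "increments")
  maturity <- need(maturity, "maturity")
  spline_fit_g <- if (!is.null(spline_fit)) glance(spline_fit) else {
    gaps <- c(gaps, "spline"); NULL
  }
  vb_tidy <- if (!is.null(vbgm_fit)) tidy(vbgm_fit) else {
    gaps <- c(gaps, "vbgm"); NULL
  }
  maturation <- if (!is.null(maturity)) summarize_maturity(maturity) else NULL
  maturation_note <- if (!is.null(maturation) && maturation$n_mature == 0) {
    "no mature specimens"
  } else NA_character_
  age_at_size <- NULL
  if (length(query_ccl) > 0) {
    parts <- list()
    if (!is.null(vbgm_fit)) {
      parts$vbgm <- vb_age_at_length(vbgm_fit, query_ccl) |> mutate(model = "vbgm")
    }
    if (!is.null(spline_fit)) {
      parts$spline <- spline_age_at_size(spline_fit, query_ccl) |>
        mutate(model = "spline", n_unbounded = NA_integer_)
    }
    age_at_size <- list_rbind(parts)
  }
  year1 <- NULL
  if (!is.null(increments)) {
    y1 <- increments |> filter(.data$from_age == 0)
    year1 <- tibble(n = nrow(y1),
                    mean_year1_growth = if (nrow(y1)) mean(y1$growth) else NA_real_,
                    se_year1_growth = se_mean(y1$growth))
  }
  structure(
    list(
      cohort_summary = summarize_cohort(cohort, ages),
      size_age_at_stranding = if (!is.null(ages)) {
        cohort |>
          select("specimen_id", "region", "sex", "ccl_cm") |>
          left_join(select(ages, "specimen_id", "final_age", "lags_retained",
                           "lags_lost", "extrapolated"),
                    by = "specimen_id")
      } else NULL,
      size_at_age_points = if (!is.null(growth)) {
        size_at_age_points(growth, cohort)
      } else NULL,
      growth_by_class = growth_summary,
      year1_growth = year1,
      maturation = maturation,
      maturation_note = maturation_note,
      maturity_detail = maturity,
      spline = spline_fit_g,
      vbgm = vb_tidy,
      age_at_size = age_at_size,
      gaps = gaps
    ),
    class = "skelegrow_report"
  )
}

#' @export
print.skelegrow_report <- function(x, ...) {
  cat("skelegrow report\n")
  cat("  sections:",
      paste(names(x)[!map_lgl(x, is.null)], collapse = ", "), "\n")
  if (length(x$gaps)) cat("  gaps:", paste(x$gaps, collapse = ", "), "\n")
  invisible(x)
}

#' Write a report bundle to disk
#'
#' Tabular sections become CSV files; the whole bundle (scalars included) is
#' also written as a single JSON document.
#'
#' @param report A [build_report()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "skelegrow_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(report)) {
    section <- report[[nm]]
    if (is.data.frame(section) && nrow(section) > 0) {
      write_results(section, file.path(dir, paste0(nm, ".csv")))
    }
  }
  json <- map(unclass(report), function(s) if (is.data.frame(s)) s else s)
  write_json(json, file.path(dir, "report.json"), auto_unbox = TRUE,
             digits = NA, na = "null", pretty = TRUE)
  invisible(dir)
}
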