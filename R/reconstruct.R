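#' Reconstruct each animal's multi-year size-at-age record
#'
#' Back-calculates CCL at every retained LAG under the body proportional
#' hypothesis, anchored to the CCL at recovery (measured, or imputed from
#' total section diameter via the linear size model when missing), and pairs
#' it with the assigned per-LAG ages. Because the outermost LAG diameter
#' equals the bone edge, the back-calculated CCL at the outermost LAG is
#' exactly the CCL at recovery.
#'
#' @param cohort A cohort tibble.
#' @param ages An [assign_ages()] result for the same cohort.
#' @param allom An [allometric_model()].
#' @param size_model Optional [fit_thd_ccl()] result used to impute missing
#'   recovery CCLs from `thd_mm`; without it a bone lacking both CCL and THD
#'   (or lacking CCL when no size model is given) cannot be reconstructed.
#' @return A tibble with one row per (bone, LAG): `specimen_id`,
#'   `lag_index` (1 = innermost retained), `age`, `lag_diameter_mm`,
#'   `ccl_cm`, plus per-bone columns `has_annulus` and `ccl_imputed`.
#' @export
reconstruct_growth <- function(cohort, ages, allom, size_model = NULL) {
  stopifnot(inherits(allom, "allometric_model"))
  joined <- left_join(cohort, ages, by = "specimen_id")
  rows <- pmap(
    list(joined$specimen_id, joined$lag_diameters_mm, joined$lag_ages,
         joined$ccl_cm, joined$thd_mm, joined$has_annulus),
    function(id, d, lag_ages, ccl, thd, annulus) {
      if (length(d) == 0) return(NULL)
      imputed <- FALSE
      if (is.na(ccl)) {
        if (is.null(size_model) || is.na(thd)) {
          skel_abort(
            sprintf("Specimen %s has no recovery CCL and it cannot be imputed (need `size_model` and `thd_mm`).", id),
            "skelegrow_precondition_error"
          )
        }
        ccl <- predict_ccl(size_model, thd)
        imputed <- TRUE
      }
      tibble(
        specimen_id = id, lag_index = seq_along(d), age = lag_ages,
        lag_diameter_mm = d,
        ccl_cm = back_calculate_ccl(allom, d, thd, ccl),
        has_annulus = annulus, ccl_imputed = imputed
      )
    }
  )
  out <- list_rbind(purrr::compact(rows))
  if (nrow(out) == 0) {
    skel_abort("No bone in the cohort has any measurable LAG.",
               "skelegrow_precondition_error")
  }
  out
}

#' Annual growth increments from a reconstructed record
#'
#' Differences between back-calculated CCLs at adjacent LAGs; increment `i`
#' spans LAG `i` to LAG `i + 1` and is labelled by its starting age and
#' starting CCL. For annulus-retaining bones the year-1 increment (hatchling
#' size `lop_cm` to the annulus CCL) is prepended with `from_age = 0`.
#' Negative increments (possible under diameter noise) are kept but flagged.
#'
#' @param growth A [reconstruct_growth()] result.
#' @param lop_cm Minimum hatchling CCL used for year-1 growth; set to `NULL`
#'   to omit year-1 increments.
#' @return A tibble with `specimen_id`, `from_age`, `to_age`, `l_start`
#'   (CCL at the starting LAG, cm), `growth` (cm/yr) and `negative`.
#' @export
growth_increments <- function(growth, lop_cm = 6) {
  inc <- growth |>
    group_by(.data$specimen_id) |>
    arrange(.data$age, .by_group = TRUE) |>
    reframe(
      from_age = head(.data$age, -1),
      to_age = tail(.data$age, -1),
      l_start = head(.data$ccl_cm, -1),
      growth = diff(.data$ccl_cm)
    )
  if (!is.null(lop_cm)) {
    year1 <- growth |>
      filter(.data$has_annulus, .data$age == 1) |>
      transmute(.data$specimen_id, from_age = 0L, to_age = 1L,
                l_start = lop_cm, growth = .data$ccl_cm - lop_cm)
    inc <- bind_rows(year1, inc)
  }
  inc |>
    mutate(negative = .data$growth < 0) |>
    arrange(.data$specimen_id, .data$from_age)
}

#' Summarize growth increments by size or age class
#'
#' Each increment is assigned to the class of its *starting* CCL (or
#' starting age). Empty classes are reported with `n = 0` rather than
#' dropped; the standard error is reported as 0 when `n < 2`.
#'
#' @param increments A [growth_increments()] result.
#' @param breaks Numeric class edges (left-closed, right-open; the last
#'   class is open-ended when `Inf` is included).
#' @param by `"size"` (classes of `l_start`, cm) or `"age"` (classes of
#'   `from_age`, yr).
#' @return A tibble with `class`, `n`, `mean_growth`, `se_growth`.
#' @export
summarize_growth <- function(increments, breaks, by = c("size", "age")) {
  by <- match.arg(by)
  if (nrow(increments) < 1) {
    skel_abort("At least one growth increment is required.",
               "skelegrow_precondition_error")
  }
  val <- if (by == "size") increments$l_start else increments$from_age
  labs <- paste0("[", head(breaks, -1), ",", tail(breaks, -1), ")")
  cls <- cut(val, breaks = breaks, right = FALSE, labels = labs)
  tibble(class = cls, growth = increments$growth) |>
    filter(!is.na(.data$class)) |>
    group_by(.data$class, .drop = FALSE) |>
    summarise(n = dplyr::n(),
              mean_growth = ifelse(dplyr::n() > 0, mean(.data$growth), NA_real_),
              se_growth = se_mean(.data$growth),
              .groups = "drop")
}
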