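#' Detect rapprochement in an ordered series of growth increments
#'
#' Rapprochement — compression of successive LAGs at the outer edge of the
#' bone — marks the growth slowdown at sexual maturation. The rule: the
#' maturation point is the start of the first run of at least `run_length`
#' sequential increments each at or below `threshold` (0.5 cm by default).
#'
#' @param increments Numeric vector of annual growth increments (cm/yr),
#'   ordered oldest to newest.
#' @param threshold Increment threshold, cm (default 0.5).
#' @param run_length Required run length (default 3).
#' @return The 1-based index of the first increment of the first qualifying
#'   run, or `NA` if there is none. When `NA`, the attribute `reason` is
#'   `"too_few_increments"` (fewer than `run_length` increments, maturation
#'   undetectable) or `"no_run"` (growth still above threshold).
#' @export
#' @examples
#' detect_rapprochement(c(2.0, 1.1, 0.5, 0.4, 0.3))  # 3
detect_rapprochement <- function(increments, threshold = 0.5, run_length = 3) {
  n <- length(increments)
  if (n < run_length) {
    return(structure(NA_integer_, reason = "too_few_increments"))
  }
  small <- increments <= threshold
  # run of run_length consecutive TRUEs starting at j
  run <- rep(TRUE, n - run_length + 1)
  for (offset in seq_len(run_length) - 1) {
    run <- run & small[seq_len(n - run_length + 1) + offset]
  }
  j <- which(run)
  if (length(j) == 0) return(structure(NA_integer_, reason = "no_run"))
  j[1]
}

#' Estimate maturation (ASM, SSM) and reproductive longevity per bone
#'
#' Applies the rapprochement rule to each bone's LAG-to-LAG increment series
#' (increment `i` spans LAG `i` to `i + 1`; the maturation LAG is the LAG at
#' the *start* of the first qualifying run). Age at sexual maturation (ASM)
#' is the assigned age of that LAG and size at maturation (SSM) its
#' back-calculated CCL. Minimum reproductive longevity counts the LAGs from
#' the maturation LAG outward to the bone edge, inclusive.
#'
#' A bone whose very first retained increment already qualifies while its
#' age required correction-factor extrapolation retains only
#' post-rapprochement bone: the onset was resorbed away, so the bone is
#' excluded from age-at-maturation analysis (`excluded_reason` is set and
#' ASM/SSM are suppressed; size and growth analyses remain usable).
#'
#' @param growth A [reconstruct_growth()] result.
#' @param ages An [assign_ages()] result.
#' @param threshold,run_length Rapprochement rule parameters.
#' @return A tibble with one row per bone that has at least one LAG:
#'   `specimen_id`, `detected`, `maturation_lag_index` (1-based among
#'   retained LAGs), `asm` (yr), `ssm` (cm), `reproductive_longevity` (yr),
#'   `excluded_reason`, `note` (why undetected, when undetected).
#' @export
estimate_maturity <- function(growth, ages, threshold = 0.5, run_length = 3) {
  recs <- growth |>
    group_by(.data$specimen_id) |>
    arrange(.data$age, .by_group = TRUE) |>
    summarise(ccl = list(.data$ccl_cm), lag_age = list(.data$age),
              .groups = "drop") |>
    left_join(ages, by = "specimen_id")
  rows <- pmap(
    list(recs$specimen_id, recs$ccl, recs$lag_age,
         recs$lags_retained, recs$extrapolated),
    function(id, ccl, lag_age, n_ret, extrap) {
      inc <- diff(ccl)
      j <- detect_rapprochement(inc, threshold, run_length)
      base <- tibble(specimen_id = id, detected = FALSE,
                     maturation_lag_index = NA_integer_, asm = NA_integer_,
                     ssm = NA_real_, reproductive_longevity = NA_integer_,
                     excluded_reason = NA_character_,
                     note = NA_character_)
      if (is.na(j)) {
        base$note <- attr(j, "reason")
        return(base)
      }
      base$detected <- TRUE
      if (j == 1 && isTRUE(extrap)) {
        base$excluded_reason <- "onset not observed"
        return(base)
      }
      base$maturation_lag_index <- as.integer(j)
      base$asm <- as.integer(lag_age[j])
      base$ssm <- ccl[j]
      base$reproductive_longevity <- as.integer(n_ret - j + 1)
      base
    }
  )
  list_rbind(rows)
}

#' Align back-calculated and observed nesting sizes by calendar year
#'
#' Counts LAG ages back from the stranding year (outermost LAG = stranding
#' year), pairs each observed nesting CCL with the back-calculated CCL of
#' the same calendar year, and flags nesting years earlier than the
#' skeletally-assigned maturation year.
#'
#' @param growth A [reconstruct_growth()] result (one or more bones).
#' @param specimen_id The bone to align.
#' @param nesting_history Tibble with `year`, `ccl_cm` of observed nestings.
#' @param stranding_year Calendar year of carcass recovery.
#' @param maturity Optional [estimate_maturity()] result; enables the
#'   pre-maturation flag.
#' @return A tibble with `year`, `age`, `ccl_backcalc`, `ccl_observed`,
#'   `diff` and `pre_maturation`; one row per observed nesting year.
#' @export
compare_with_nesting <- function(growth, specimen_id, nesting_history,
                                 stranding_year, maturity = NULL) {
  if (nrow(nesting_history) == 0) {
    skel_abort("`nesting_history` is empty.", "skelegrow_precondition_error")
  }
  g <- growth[growth$specimen_id == specimen_id, ]
  if (nrow(g) == 0) {
    skel_abort(sprintf("No reconstructed record for specimen %s.", specimen_id),
               "skelegrow_precondition_error")
  }
  final_age <- max(g$age)
  hatch_year <- stranding_year - final_age
  if (any(nesting_history$year < hatch_year)) {
    skel_abort(
      sprintf("Specimen %s has nesting years before its estimated hatch year (%d).",
              specimen_id, hatch_year),
      "skelegrow_consistency_error"
    )
  }
  g$year <- stranding_year - (final_age - g$age)
  asm <- NA_integer_
  if (!is.null(maturity)) {
    m <- maturity[maturity$specimen_id == specimen_id, ]
    if (nrow(m) == 1) asm <- m$asm
  }
  maturation_year <- if (is.na(asm)) NA_integer_ else stranding_year - (final_age - asm)
  nesting_history |>
    left_join(select(g, "year", "age", ccl_backcalc = "ccl_cm"), by = "year") |>
    transmute(.data$year, .data$age, .data$ccl_backcalc,
              ccl_observed = .data$ccl_cm,
              diff = .data$ccl_observed - .data$ccl_backcalc,
              pre_maturation = if (is.na(maturation_year)) NA else
                .data$year < maturation_year)
}
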