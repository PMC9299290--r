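#' @title Cohort tables of per-bone LAG measurements
#' @description A cohort is a tibble with one row per bone and the columns
#' `specimen_id`, `region` (WA, EA, NT, Gulf, unknown), `sex` (F, M, unknown),
#' `ccl_cm` (CCL at recovery, may be NA), `thd_mm` (total section diameter,
#' equals the bone-edge/outermost diameter), `has_annulus`,
#' `hatch_mark_only`, `lag_diameters_mm` (list column of strictly increasing
#' diameters, innermost to outermost) and `nesting_history` (list column of
#' tibbles with `year`, `ccl_cm`, possibly empty). On disk the diameters are
#' a semicolon-separated field and nesting history is encoded
#' `"year:ccl|year:ccl"`.
#' @name cohort-table
NULL

REGION_LEVELS <- c("WA", "EA", "NT", "Gulf", "unknown")
SEX_LEVELS <- c("F", "M", "unknown")

parse_diameters <- function(x) {
  if (is.na(x) || !nzchar(trimws(x))) return(numeric(0))
  as.numeric(strsplit(trimws(x), ";", fixed = TRUE)[[1]])
}

format_diameters <- function(x) {
  if (length(x) == 0) return("")
  paste(format(x, digits = 15, trim = TRUE, scientific = FALSE), collapse = ";")
}

parse_nesting <- function(x) {
  if (is.na(x) || !nzchar(trimws(x))) {
    return(tibble(year = integer(0), ccl_cm = numeric(0)))
  }
  parts <- strsplit(strsplit(trimws(x), "|", fixed = TRUE)[[1]], ":", fixed = TRUE)
  tibble(year = as.integer(map_chr(parts, 1)),
         ccl_cm = as.numeric(map_chr(parts, 2)))
}

format_nesting <- function(tbl) {
  if (is.null(tbl) || nrow(tbl) == 0) return("")
  paste(sprintf("%d:%s", tbl$year,
                format(tbl$ccl_cm, digits = 15, trim = TRUE, scientific = FALSE)),
        collapse = "|")
}

#' Validate a cohort table against the domain invariants
#'
#' Checks, per bone: strictly increasing positive LAG diameters; a
#' hatch-mark-only bone has no LAGs; an annulus-retaining bone has at least
#' one LAG; the total section diameter is at least the largest LAG diameter;
#' specimen ids are unique.
#'
#' @param cohort A cohort tibble (see [cohort-table]).
#' @return A tibble of problems with columns `specimen_id`, `field`,
#'   `problem`; zero rows when the cohort is valid.
#' @export
validate_cohort <- function(cohort) {
  assert_columns(cohort,
                 c("specimen_id", "thd_mm", "has_annulus", "hatch_mark_only",
                   "lag_diameters_mm"),
                 "cohort table")
  problems <- list()
  note <- function(id, field, problem) {
    problems[[length(problems) + 1]] <<- tibble(
      specimen_id = id, field = field, problem = problem)
  }
  dup <- cohort$specimen_id[duplicated(cohort$specimen_id)]
  for (id in unique(dup)) note(id, "specimen_id", "duplicated specimen id")
  for (i in seq_len(nrow(cohort))) {
    id <- cohort$specimen_id[i]
    d <- cohort$lag_diameters_mm[[i]]
    if (anyNA(d)) {
      note(id, "lag_diameters_mm", "non-numeric or missing diameter value")
      next
    }
    if (length(d) > 0 && any(d <= 0)) {
      note(id, "lag_diameters_mm", "diameters must be positive")
    }
    if (length(d) > 1 && any(diff(d) <= 0)) {
      note(id, "lag_diameters_mm",
           "diameters must be strictly increasing innermost to outermost")
    }
    if (isTRUE(cohort$hatch_mark_only[i]) && length(d) > 0) {
      note(id, "hatch_mark_only", "hatch-mark-only bone must have no LAGs")
    }
    if (isTRUE(cohort$has_annulus[i]) && length(d) == 0) {
      note(id, "has_annulus", "annulus-retaining bone must have at least one LAG")
    }
    if (isTRUE(cohort$hatch_mark_only[i]) && isTRUE(cohort$has_annulus[i])) {
      note(id, "has_annulus", "bone cannot be both hatch-mark-only and annulus-retaining")
    }
    if (length(d) > 0 && !is.na(cohort$thd_mm[i]) &&
        cohort$thd_mm[i] < max(d) - 1e-9) {
      note(id, "thd_mm", "total section diameter below largest LAG diameter")
    }
  }
  if (length(problems) == 0) {
    tibble(specimen_id = character(0), field = character(0), problem = character(0))
  } else {
    list_rbind(problems)
  }
}

#' Read a cohort of per-bone LAG measurements from CSV
#'
#' @param path Path to a CSV file with columns `specimen_id`, `region`,
#'   `sex`, `ccl_cm`, `thd_mm`, `has_annulus`, `hatch_mark_only`,
#'   `lag_diameters_mm` (semicolon-separated, innermost first) and optionally
#'   `nesting_history` (`"year:ccl|year:ccl"`).
#' @param validate Validate invariants and fail on violations (default TRUE).
#' @return A cohort tibble (see [cohort-table]).
#' @export
read_cohort <- function(path, validate = TRUE) {
  if (!file.exists(path)) {
    skel_abort(sprintf("Cohort file not found: %s", path), "skelegrow_io_error")
  }
  required <- c("specimen_id", "region", "sex", "ccl_cm", "thd_mm",
                "has_annulus", "hatch_mark_only", "lag_diameters_mm")
  hdr <- names(suppressMessages(
    read_csv(path, n_max = 0, show_col_types = FALSE)))
  assert_columns(setNames(as.list(hdr), hdr), required,
                 sprintf("cohort file '%s'", path))
  raw <- read_csv(path, col_types = cols(
    specimen_id = col_character(),
    region = col_character(),
    sex = col_character(),
    ccl_cm = col_double(),
    thd_mm = col_double(),
    has_annulus = col_logical(),
    hatch_mark_only = col_logical(),
    lag_diameters_mm = col_character(),
    nesting_history = col_character()
  ), show_col_types = FALSE)
  if (!"nesting_history" %in% names(raw)) raw$nesting_history <- NA_character_
  cohort <- raw |>
    mutate(
      region = ifelse(is.na(.data$region) | !(.data$region %in% REGION_LEVELS),
                      "unknown", .data$region),
      sex = ifelse(is.na(.data$sex) | !(.data$sex %in% SEX_LEVELS),
                   "unknown", .data$sex),
      lag_diameters_mm = map(.data$lag_diameters_mm, parse_diameters),
      nesting_history = map(.data$nesting_history, parse_nesting)
    )
  if (validate) {
    probs <- validate_cohort(cohort)
    if (nrow(probs) > 0) {
      skel_abort(
        paste0("Cohort validation failed:\n",
               paste(sprintf("  - specimen %s, field %s: %s",
                             probs$specimen_id, probs$field, probs$problem),
                     collapse = "\n")),
        "skelegrow_validation_error",
        problems = probs
      )
    }
  }
  cohort
}

#' Write a cohort table to CSV
#'
#' The on-disk column names carry units (`ccl_cm`, `thd_mm`,
#' `lag_diameters_mm`); numeric values are written with enough digits that a
#' round-trip read reproduces them to at least 6 significant digits.
#'
#' @param cohort A cohort tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  out <- cohort |>
    mutate(
      lag_diameters_mm = map_chr(.data$lag_diameters_mm, format_diameters),
      nesting_history = map_chr(.data$nesting_history, format_nesting)
    )
  write_csv(out, path)
  invisible(path)
}

#' Write any stage output table to CSV
#'
#' Generic writer for stage outputs (age estimates, growth records, maturity
#' tables, summaries). List columns of numeric vectors are flattened to
#' semicolon-separated fields.
#'
#' @param records A non-empty data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_results <- function(records, path) {
  if (!is.data.frame(records) || nrow(records) == 0) {
    skel_abort("`records` must be a non-empty data frame.",
               "skelegrow_precondition_error")
  }
  flat <- records |>
    mutate(across(where(is.list),
                  ~ map_chr(.x, function(v) {
                    if (is.data.frame(v)) format_nesting(v) else format_diameters(v)
                  })))
  write_csv(flat, path)
  invisible(path)
}
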