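#' Run the full skeletochronology pipeline
#'
#' Orchestrates simulate/load, allometry fits, age assignment, growth
#' reconstruction, maturation detection, growth models and the final report,
#' writing every stage table, a parameter/checksum record and a gate-decision
#' log into a run directory. Identical configuration and seed yield
#' byte-identical result tables. A single seed feeds a named sub-seed per
#' stochastic stage, so changing the bootstrap replicate count does not
#' perturb the simulated cohort.
#'
#' @param config A list; recognized fields (all optional):
#'   \describe{
#'     \item{cohort}{A cohort tibble to analyze.}
#'     \item{cohort_path}{CSV path to read the cohort from (alternative).}
#'     \item{sim}{A [sim_params()] object; when no cohort is supplied, a
#'       study-structured cohort is simulated ([make_stranding_cohort()]).}
#'     \item{anchors}{[hatchling_anchors()] (default 6 cm / 2.4 mm).}
#'     \item{gate_r2}{Adjusted r-squared gate for the THD-CCL model (0.9).}
#'     \item{lost_convention}{See [assign_ages()].}
#'     \item{allow_extrapolation}{If `FALSE`, halt when any bone needs the
#'       correction factor beyond its training range (default `TRUE`).}
#'     \item{maturity_threshold, maturity_run_length}{Rapprochement rule
#'       (0.5 cm, 3).}
#'     \item{n_boot}{Bootstrap replicates (1000).}
#'     \item{query_ccl}{Age-at-size query sizes, cm.}
#'     \item{size_breaks}{Growth-summary size class edges, cm.}
#'   }
#' @param out_dir Run directory (created; default `tempfile("skelegrow_run")`).
#' @param seed Integer master seed (default 1).
#' @return Invisibly, a list with every stage object, the report, and
#'   `out_dir`.
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("skelegrow_run"),
                         seed = 1) {
  defaults <- list(
    cohort = NULL, cohort_path = NULL, sim = sim_params(),
    anchors = hatchling_anchors(), gate_r2 = 0.9,
    lost_convention = "interior", allow_extrapolation = TRUE,
    maturity_threshold = 0.5, maturity_run_length = 3,
    n_boot = 1000, query_ccl = numeric(0),
    size_breaks = c(0, 10, 20, 30, 40, 50, 60, 70, 80, 90, Inf)
  )
  cfg <- modifyList(defaults, config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "log.txt")
  logline <- function(...) {
    cat(sprintf("[%s] %s\n", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                sprintf(...)),
        file = log_path, append = TRUE)
  }
  # named sub-seeds: stable regardless of how much randomness a stage uses
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1, 2)
  names(sub_seeds) <- c("simulate", "bootstrap")

  truth <- NULL
  if (!is.null(cfg$cohort)) {
    cohort <- cfg$cohort
    logline("stage=input cohort supplied in config (n = %d)", nrow(cohort))
  } else if (!is.null(cfg$cohort_path)) {
    cohort <- read_cohort(cfg$cohort_path)
    logline("stage=input cohort read from %s (n = %d, md5 = %s)",
            cfg$cohort_path, nrow(cohort), unname(md5sum(cfg$cohort_path)))
  } else {
    sim <- make_stranding_cohort(seed = sub_seeds[["simulate"]], params = cfg$sim)
    cohort <- sim$cohort
    truth <- sim$truth
    logline("stage=simulate study-structured cohort (n = %d, seed = %d)",
            nrow(cohort), sub_seeds[["simulate"]])
  }
  cohort_file <- file.path(out_dir, "cohort.csv")
  write_cohort(cohort, cohort_file)
  logline("stage=input cohort written, md5 = %s", unname(md5sum(cohort_file)))

  # allometry: linear THD-CCL size model and the anchored allometric model
  pairs <- cohort |> filter(!is.na(.data$ccl_cm), !is.na(.data$thd_mm))
  size_model <- tryCatch(fit_thd_ccl(pairs, gate_r2 = cfg$gate_r2),
                         skelegrow_error = function(e) NULL)
  if (is.null(size_model)) {
    logline("stage=allometry THD-CCL size model not fittable; CCL imputation unavailable")
  } else {
    logline("stage=allometry THD-CCL adj r2 = %.4f (gate %.2f): %s",
            size_model$adj_r2, cfg$gate_r2,
            if (size_model$adj_r2 > cfg$gate_r2) "passed" else "FAILED")
  }
  allom <- fit_allometric(
    pairs |> transmute(d_mm = .data$thd_mm, ccl_cm = .data$ccl_cm),
    anchors = cfg$anchors
  )
  logline("stage=allometry anchored model b = %.4f, c = %.4f, SSE = %.4g",
          allom$b, allom$c, allom$residual_sse)

  # correction factor and age assignment (CF only needed when some bone has
  # lost its annulus)
  needs_cf <- any(!cohort$has_annulus & !cohort$hatch_mark_only &
                    lengths(cohort$lag_diameters_mm) > 0)
  cf <- NULL
  if (needs_cf) {
    cf <- fit_correction_factor(cohort)
    logline("stage=correction_factor kind = %s, r2 = %.4f, training max = %.3g mm",
            cf$kind, cf$r2, cf$training_max_diameter)
  } else {
    logline("stage=correction_factor skipped (no bone missing its annulus)")
  }
  ages <- suppressMessages(
    assign_ages(cohort, cf, lost_convention = cfg$lost_convention))
  if (any(ages$extrapolated)) {
    extrap_ids <- ages$specimen_id[ages$extrapolated]
    logline("stage=ages %d bone(s) required CF extrapolation: %s",
            length(extrap_ids), paste(extrap_ids, collapse = ", "))
    if (!isTRUE(cfg$allow_extrapolation)) {
      skel_abort(
        paste0("Correction-factor extrapolation disabled but required for: ",
               paste(extrap_ids, collapse = ", ")),
        "skelegrow_extrapolation_error"
      )
    }
  }
  write_results(ages |> select(-"lag_ages"), file.path(out_dir, "ages.csv"))

  # growth reconstruction
  lagged <- sum(lengths(cohort$lag_diameters_mm) > 0)
  if (lagged == 0) {
    logline("stage=growth no LAG-bearing bones; growth-model stages skipped")
    report <- build_report(cohort, ages = ages)
    write_report(report, out_dir)
    inform("Cohort contains no LAG-bearing bones; pipeline completed with empty growth-model stages.")
    return(invisible(list(cohort = cohort, truth = truth, ages = ages,
                          size_model = size_model, allometry = allom,
                          correction_factor = cf, report = report,
                          out_dir = out_dir)))
  }
  growth <- reconstruct_growth(cohort, ages, allom, size_model = size_model)
  increments <- growth_increments(growth, lop_cm = cfg$anchors$lop_cm)
  write_results(growth, file.path(out_dir, "growth.csv"))
  write_results(increments, file.path(out_dir, "increments.csv"))
  growth_summary <- summarize_growth(increments, breaks = cfg$size_breaks)
  write_results(growth_summary, file.path(out_dir, "growth_summary.csv"))

  maturity <- estimate_maturity(growth, ages,
                                threshold = cfg$maturity_threshold,
                                run_length = cfg$maturity_run_length)
  excl <- maturity$specimen_id[!is.na(maturity$excluded_reason)]
  if (length(excl)) {
    logline("stage=maturity excluded (onset not observed): %s",
            paste(excl, collapse = ", "))
  }
  write_results(maturity, file.path(out_dir, "maturity.csv"))

  # growth models (need enough animals with increments / points)
  spline_fit <- NULL
  vbgm_fit <- NULL
  pts <- size_at_age_points(growth, cohort)
  if (nrow(pts) >= 20 && length(unique(pts$specimen_id)) >= 5) {
    spline_fit <- fit_size_at_age_spline(pts)
    logline("stage=spline Edf = %.3f, adj r2 = %.4f", spline_fit$edf,
            spline_fit$adj_r2)
  } else {
    logline("stage=spline skipped (insufficient size-at-age points)")
  }
  if (length(unique(increments$specimen_id)) >= 5) {
    vbgm_fit <- bootstrap_fabens(increments, n_boot = cfg$n_boot,
                                 seed = sub_seeds[["bootstrap"]])
    logline("stage=vbgm Linf = %.2f, k = %.4f (%d replicates, %d dropped)",
            vbgm_fit$linf_hat, vbgm_fit$k_hat, vbgm_fit$n_boot,
            vbgm_fit$n_dropped)
  } else {
    logline("stage=vbgm skipped (fewer than 5 animals with increments)")
  }

  report <- build_report(cohort, ages = ages, growth = growth,
                         increments = increments, maturity = maturity,
                         growth_summary = growth_summary,
                         spline_fit = spline_fit, vbgm_fit = vbgm_fit,
                         query_ccl = cfg$query_ccl)
  write_report(report, out_dir)
  params <- list(seed = seed, sub_seeds = as.list(sub_seeds),
                 gate_r2 = cfg$gate_r2, lost_convention = cfg$lost_convention,
                 allow_extrapolation = cfg$allow_extrapolation,
                 maturity_threshold = cfg$maturity_threshold,
                 maturity_run_length = cfg$maturity_run_length,
                 n_boot = cfg$n_boot, query_ccl = cfg$query_ccl,
                 cohort_md5 = unname(md5sum(cohort_file)))
  write_json(params, file.path(out_dir, "params.json"), auto_unbox = TRUE,
             digits = NA, pretty = TRUE)
  logline("stage=done")
  invisible(list(cohort = cohort, truth = truth, ages = ages,
                 size_model = size_model, allometry = allom,
                 correction_factor = cf, growth = growth,
                 increments = increments, growth_summary = growth_summary,
                 maturity = maturity, spline = spline_fit, vbgm = vbgm_fit,
                 report = report, out_dir = out_dir))
}
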