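#' Simulation parameters for synthetic bone-growth cohorts
#'
#' Defaults reproduce the study conditions the analysis targets: annual-step
#' von Bertalanffy somatic growth (`k` = 0.185 / yr, `Linf` = 89.2 cm, from a
#' 6 cm hatchling), per-animal maturation age drawn from a truncated normal
#' (mean 16.3 yr, sd 2.85 yr, at least `asm_min`), residual post-maturity
#' growth of about 0.2 cm/yr truncated to `[0, 0.5]` cm so rapprochement is
#' present in the bones, and diameter measurement noise of 0.1 mm.
#'
#' While an animal is immature its annual increment is floored at
#' `immature_floor` (0.6 cm): rapprochement-grade compression (three or more
#' sequential increments at or below 0.5 cm) is modelled as a consequence of
#' maturation itself, not of the asymptote, so the simulated maturation age
#' is exactly the quantity the rapprochement rule estimates. Setting
#' `maturity_effect = FALSE` turns both the floor and the post-maturity
#' slowdown off, giving pure annual-step von Bertalanffy growth (used to
#' validate the growth-curve estimators under their own model).
#'
#' @param n_turtles Number of LAG-bearing animals to simulate.
#' @param k,linf,l0 Growth-law parameters: rate (1/yr), asymptotic CCL (cm),
#'   hatchling CCL (cm).
#' @param asm_mean,asm_sd,asm_min Maturation-age distribution (yr).
#' @param post_maturity_growth,post_maturity_sd,post_maturity_cap Mean, sd
#'   and cap (cm/yr) of post-maturity annual increments (truncated at 0).
#' @param immature_floor Minimum immature annual increment (cm/yr).
#' @param maturity_effect Apply the maturation slowdown (and immature floor)?
#' @param allometry [allometric_model()] used to map CCL to LAG diameter.
#' @param age_pool Integer ages (yr) from which age at death is drawn.
#' @param n_hatchlings Number of hatch-mark-only bones (age 0) to add.
#' @param resorb Apply resorption of interior LAGs to old animals?
#' @param resorb_min_age Minimum age (yr) at which resorption is applied.
#' @param resorb_lags Inclusive integer range of LAGs destroyed per resorbed
#'   bone (default 4 to 8).
#' @param diameter_noise_sd Gaussian noise sd added to diameters (mm).
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(n_turtles = 40,
                       k = 0.185, linf = 89.2, l0 = 6,
                       asm_mean = 16.3, asm_sd = 2.85, asm_min = 5,
                       post_maturity_growth = 0.2, post_maturity_sd = 0.15,
                       post_maturity_cap = 0.5,
                       immature_floor = 0.6,
                       maturity_effect = TRUE,
                       allometry = allometric_model(6, 2.4, b = 3.665, c = 0.928),
                       age_pool = 1:35,
                       n_hatchlings = 0,
                       resorb = TRUE, resorb_min_age = 13,
                       resorb_lags = c(4, 8),
                       diameter_noise_sd = 0.1) {
  if (k <= 0) skel_abort("`k` must be positive.", "skelegrow_value_error")
  if (l0 >= linf) skel_abort("`l0` must be below `linf`.", "skelegrow_value_error")
  if (diameter_noise_sd < 0) {
    skel_abort("`diameter_noise_sd` must be non-negative.", "skelegrow_value_error")
  }
  structure(as.list(environment()), class = "sim_params")
}

# annual-step VB trajectory with maturation slowdown; returns increments
# inc[t] spanning age (t-1) -> t, t = 1..age; asm is a whole year: the first
# compressed increment leaves the maturation LAG (age == asm)
sim_increments <- function(age, asm, p) {
  inc <- numeric(age)
  L <- p$l0
  for (t in seq_len(age)) {
    from_age <- t - 1
    if (p$maturity_effect && from_age >= asm) {
      g <- min(p$post_maturity_cap,
               max(0, rnorm(1, p$post_maturity_growth, p$post_maturity_sd)))
    } else {
      g <- (p$linf - L) * (1 - exp(-p$k))
      if (p$maturity_effect) g <- max(g, p$immature_floor)
    }
    inc[t] <- g
    L <- L + g
  }
  inc
}

sim_one_turtle <- function(id, age, asm, p, n_lost = NA_integer_) {
  inc <- sim_increments(age, asm, p)
  ccl <- p$l0 + cumsum(inc)                  # CCL at LAG t, t = 1..age
  d <- allometry_diameter(p$allometry, ccl)  # true LAG diameters
  if (is.na(n_lost)) n_lost <- 0L
  n_lost <- min(n_lost, age - 1L)
  core <- NA_real_
  if (n_lost > 0) {
    # resorption front sits just outside the outermost destroyed LAG
    core <- d[n_lost] + runif(1, 0.05, 0.45) * (d[n_lost + 1] - d[n_lost])
    retained <- d[d > core]
  } else {
    retained <- d
  }
  if (p$diameter_noise_sd > 0) {
    retained <- sort(pmax(retained + rnorm(length(retained), 0, p$diameter_noise_sd),
                          p$allometry$anchors$dop_mm + 0.01))
  }
  thd <- if (length(retained) > 0) max(retained) else
    allometry_diameter(p$allometry, ccl[age])
  list(
    sample = tibble(
      specimen_id = id, region = "unknown", sex = "unknown",
      ccl_cm = ccl[age], thd_mm = thd,
      has_annulus = n_lost == 0L && age >= 1L,
      hatch_mark_only = FALSE,
      lag_diameters_mm = list(retained),
      nesting_history = list(tibble(year = integer(0), ccl_cm = numeric(0)))
    ),
    truth = tibble(
      specimen_id = id, age = age, asm = asm,
      matured = age >= asm,
      ssm = if (age >= asm) ccl[asm] else NA_real_,
      n_resorbed = n_lost, core_diameter_mm = core,
      ccl_at_death = ccl[age]
    ),
    lag_truth = tibble(
      specimen_id = id, lag_number = seq_len(age), age_at_lag = seq_len(age),
      ccl_cm = ccl, diameter_mm = d,
      retained = seq_len(age) > n_lost
    )
  )
}

sim_hatchling <- function(id, p) {
  ccl <- p$l0 + min(rgamma_safe(1.5, 2.3), 11)
  thd <- allometry_diameter(p$allometry, ccl)
  if (p$diameter_noise_sd > 0) {
    thd <- max(thd + rnorm(1, 0, p$diameter_noise_sd),
               p$allometry$anchors$dop_mm)
  }
  list(
    sample = tibble(
      specimen_id = id, region = "unknown", sex = "unknown",
      ccl_cm = ccl, thd_mm = thd, has_annulus = FALSE, hatch_mark_only = TRUE,
      lag_diameters_mm = list(numeric(0)),
      nesting_history = list(tibble(year = integer(0), ccl_cm = numeric(0)))
    ),
    truth = tibble(
      specimen_id = id, age = 0L, asm = NA_real_, matured = FALSE,
      ssm = NA_real_, n_resorbed = 0L, core_diameter_mm = NA_real_,
      ccl_at_death = ccl
    ),
    lag_truth = tibble(
      specimen_id = character(0), lag_number = integer(0),
      age_at_lag = integer(0), ccl_cm = numeric(0), diameter_mm = numeric(0),
      retained = logical(0)
    )
  )
}

rgamma_safe <- function(shape, scale) stats::rgamma(1, shape = shape, scale = scale)

#' Simulate a ground-truthed cohort of bones
#'
#' Generates whole-year growth trajectories under the annual-step von
#' Bertalanffy law (one LAG per year), converts CCL at every LAG to a LAG
#' diameter by inverting the allometric model, deletes interior LAGs inside a
#' per-bone resorption core for old animals, and adds Gaussian measurement
#' noise to the retained diameters (re-sorted to keep monotonicity). The
#' same seed always yields an identical cohort.
#'
#' @param params A [sim_params()] list.
#' @param seed Integer seed for reproducibility (optional).
#' @return A list with `cohort` (tibble, see [cohort-table]), `truth` (one
#'   row per animal: true age, maturation age/size, resorbed count, core
#'   diameter) and `lag_truth` (one row per true LAG: age, CCL, diameter,
#'   retained flag).
#' @export
#' @examples
#' sim <- simulate_cohort(sim_params(n_turtles = 5, n_hatchlings = 2), seed = 1)
#' sim$cohort
simulate_cohort <- function(params = sim_params(), seed = NULL) {
  stopifnot(inherits(params, "sim_params"))
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  p <- params
  if (exp(-p$k * max(p$age_pool)) > 0.9) {
    warn("Growth parameters leave the asymptote far out of reach at maximum age.")
  }
  turtles <- list()
  for (i in seq_len(p$n_turtles)) {
    age <- sample(p$age_pool, 1)
    asm <- round(rtruncnorm(1, p$asm_mean, p$asm_sd, lower = p$asm_min))
    n_lost <- if (p$resorb && age >= p$resorb_min_age) {
      sample(seq(p$resorb_lags[1], p$resorb_lags[2]), 1)
    } else 0L
    turtles[[i]] <- sim_one_turtle(sprintf("T%03d", i), age, asm, p, n_lost)
  }
  for (j in seq_len(p$n_hatchlings)) {
    turtles[[p$n_turtles + j]] <- sim_hatchling(sprintf("H%03d", j), p)
  }
  list(
    cohort = list_rbind(map(turtles, "sample")),
    truth = list_rbind(map(turtles, "truth")),
    lag_truth = list_rbind(map(turtles, "lag_truth"))
  )
}

#' Simulate a cohort with the study's observed size structure
#'
#' Reproduces the sampling structure of the stranded-carcass collection the
#' method was developed on: about 27 hatch-mark-only post-hatchlings, about
#' 15 annulus-retaining juveniles below 40 cm CCL, about 32 adults above
#' 70 cm CCL with 4 to 8 interior LAGs lost to resorption, and no animals in
#' the 40 to 70 cm range. Four adult females carry nesting-history records
#' (calendar years counted back from a nominal stranding year of 2020).
#'
#' @param seed Integer seed.
#' @param params A [sim_params()] list; class sizes and ages are imposed on
#'   top of it.
#' @return As [simulate_cohort()]; the truth table carries an attribute
#'   `stranding_year` (2020).
#' @export
make_stranding_cohort <- function(seed = NULL, params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  p <- params
  stranding_year <- 2020L
  turtles <- list()
  idx <- 0
  regions <- function(n) sample(REGION_LEVELS, n, replace = TRUE,
                                prob = c(0.65, 0.17, 0.04, 0.04, 0.10))
  # juveniles: 1-2 LAGs, annulus retained, CCL < 40 cm
  for (i in seq_len(15)) {
    idx <- idx + 1
    age <- sample(1:2, 1)
    asm <- round(rtruncnorm(1, p$asm_mean, p$asm_sd, lower = max(p$asm_min, 10)))
    turtles[[idx]] <- sim_one_turtle(sprintf("J%03d", i), age, asm, p, 0L)
  }
  # adults: mature, 4-8 LAGs resorbed, CCL > 70 cm
  adult_ids <- character(32)
  for (i in seq_len(32)) {
    idx <- idx + 1
    asm <- round(rtruncnorm(1, p$asm_mean, p$asm_sd, lower = max(p$asm_min, 12)))
    age <- asm + sample(4:20, 1)
    n_lost <- sample(seq(p$resorb_lags[1], p$resorb_lags[2]), 1)
    turtles[[idx]] <- sim_one_turtle(sprintf("A%03d", i), age, asm, p, n_lost)
    adult_ids[i] <- sprintf("A%03d", i)
  }
  # hatchlings / post-hatchlings: hatch mark only
  for (i in seq_len(27)) {
    idx <- idx + 1
    turtles[[idx]] <- sim_hatchling(sprintf("H%03d", i), p)
  }
  cohort <- list_rbind(map(turtles, "sample"))
  truth <- list_rbind(map(turtles, "truth"))
  lag_truth <- list_rbind(map(turtles, "lag_truth"))
  cohort$region <- regions(nrow(cohort))
  cohort$sex[cohort$specimen_id %in% adult_ids] <-
    sample(c("F", "M", "unknown"), 32, replace = TRUE, prob = c(0.5, 0.1, 0.4))
  # nesting histories for four adult females: observed CCL = true CCL in
  # post-maturation years, calendar years anchored at the stranding year
  females <- head(cohort$specimen_id[cohort$sex == "F"], 4)
  cohort$sex[cohort$specimen_id %in% females] <- "F"
  for (id in females) {
    tr <- truth[truth$specimen_id == id, ]
    lt <- lag_truth[lag_truth$specimen_id == id, ]
    mature_ages <- lt$age_at_lag[lt$age_at_lag >= tr$asm & lt$retained]
    if (length(mature_ages) < 2) next
    obs_ages <- sort(sample(mature_ages, min(3, length(mature_ages))))
    nh <- tibble(
      year = as.integer(stranding_year - (tr$age - obs_ages)),
      ccl_cm = lt$ccl_cm[match(obs_ages, lt$age_at_lag)]
    )
    cohort$nesting_history[[which(cohort$specimen_id == id)]] <- nh
  }
  attr(truth, "stranding_year") <- stranding_year
  list(cohort = cohort, truth = truth, lag_truth = lag_truth)
}
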