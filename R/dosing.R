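#' Probability of target attainment
#'
#' Fraction of simulated subjects whose AUC over the selected window lies
#' inside the closed therapeutic interval (default 400-650 mg.h/L; with
#' MIC fixed at 1 mg/L, AUC/MIC equals AUC).
#'
#' @param exposures Exposure data frame from [simulate_exposure()].
#' @param window Closed AUC target window, mg.h/L.
#' @param which Exposure metric: `"auc_24_48"` (steady-state proxy) or
#'   `"auc_0_24"` (initial exposure).
#' @return A fraction in `[0, 1]`.
#' @export
pta <- function(exposures, window = c(400, 650), which = "auc_24_48") {
  if (NROW(exposures) == 0L) stop("pta: empty exposure list", call. = FALSE)
  x <- exposures[[which]]
  if (is.null(x)) stop("pta: unknown exposure metric '", which, "'",
                       call. = FALSE)
  mean(x >= window[1] & x <= window[2])
}

#' Lowest dose within 95% of the maximal PTA
#'
#' The dose-selection rule of the escalation simulation: among grid doses
#' whose PTA is at least 95% of the maximum over the grid, pick the
#' lowest (balancing efficacy and toxicity). If every PTA is zero the
#' lowest grid dose is returned with attribute `all_zero = TRUE`.
#'
#' @param doses Ascending dose grid, mg/kg.
#' @param ptas PTA at each grid dose.
#' @param frac Candidate threshold as a fraction of the maximum
#'   (default 0.95).
#' @return Selected dose (with attribute `all_zero` if degenerate).
#' @export
#' @examples
#' select_optimal_dose(c(10, 15, 20, 25), c(0.4, 0.70, 0.72, 0.69))  # 15
select_optimal_dose <- function(doses, ptas, frac = 0.95) {
  stopifnot(length(doses) == length(ptas), length(doses) > 0,
            !is.unsorted(doses))
  m <- max(ptas)
  if (m <= 0) {
    warning("select_optimal_dose: PTA is zero over the whole grid")
    return(structure(doses[1], all_zero = TRUE))
  }
  doses[which(ptas >= frac * m)[1]]
}

# one-arm PTA summary for a subgroup
pta_result <- function(dose_mg_per_kg, exposures, window = c(400, 650),
                       which = "auc_24_48") {
  qs <- stats::quantile(exposures$trough_48, c(0.25, 0.5, 0.75), names = FALSE)
  list(dose = dose_mg_per_kg,
       pta = pta(exposures, window, which),
       median_trough = qs[2], trough_iqr = c(qs[1], qs[3]),
       frac_supra = mean(exposures[[if (which == "auc_24_48")
         "supra_24_48" else "supra_0_24"]]),
       n = nrow(exposures))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Dose-escalation optimization for one subgroup
#'
#' Evaluates the PTA of every grid dose on one simulated subgroup cohort
#' using common random numbers (the same cohort and the same random-effect
#' draws at every dose), then applies the 95%-of-maximum / lowest-dose
#' selection rule.
#'
#' @param pop A [pop_params()] object.
#' @param spec A [subgroup_spec()].
#' @param dose_grid Ascending maintenance doses to test, mg/kg (default
#'   5-30 by 1).
#' @param seed Integer seed (cohort and random effects).
#' @param window Target AUC window, mg.h/L.
#' @param which Exposure metric for the target.
#' @return A list: `best` (selected-dose summary with PTA, median trough
#'   and IQR, supratherapeutic fraction), `curve` (data frame of dose vs
#'   PTA), `cohort`, `draws`, `all_zero` flag.
#' @export
optimize_dose <- function(pop, spec, dose_grid = 5:30, seed = 1L,
                          window = c(400, 650), which = "auc_24_48") {
  stopifnot(length(dose_grid) > 0, !is.unsorted(dose_grid))
  cohort <- sample_cohort(spec, seed)
  draws <- draw_random_effects(pop, nrow(cohort), 1L, seed + 1000003L)
  exps <- lapply(dose_grid, function(d)
    simulate_exposure(pop, cohort, q6h_builder(d), draws = draws,
                      window = window))
  ptas <- vapply(exps, pta, numeric(1), window = window, which = which)
  best_dose <- select_optimal_dose(dose_grid, ptas)
  i <- match(as.numeric(best_dose), dose_grid)
  list(best = pta_result(dose_grid[i], exps[[i]], window, which),
       curve = data.frame(dose = dose_grid, pta = ptas),
       cohort = cohort, draws = draws,
       all_zero = isTRUE(attr(best_dose, "all_zero")))
}

#' Standard and optimized dosing table over subgroups
#'
#' Runs the standard fixed 15 mg/kg q6h arm and the dose-escalation
#' optimizer on every subgroup, mirroring the published dosing-table
#' layout.
#'
#' @param pop A [pop_params()] object.
#' @param specs List of [subgroup_spec()]s (default [default_subgroups()]).
#' @param standard_dose Standard arm dose, mg/kg q6h.
#' @param dose_grid Optimizer grid, mg/kg.
#' @param seed Integer seed; each subgroup uses `seed + its index`.
#' @param window Target AUC window.
#' @return A data frame, one row per subgroup, with standard and
#'   optimized dose, PTA, and trough summaries.
#' @export
dosing_table <- function(pop, specs = default_subgroups(),
                         standard_dose = 15, dose_grid = 5:30, seed = 1L,
                         window = c(400, 650)) {
  rows <- lapply(seq_along(specs), function(k) {
    sp <- specs[[k]]
    sk <- seed + k
    opt <- optimize_dose(pop, sp, dose_grid, seed = sk, window = window)
    std_ex <- simulate_exposure(pop, opt$cohort, q6h_builder(standard_dose),
                                draws = opt$draws, window = window)
    std <- pta_result(standard_dose, std_ex, window)
    data.frame(
      label = sp$label, age_min = sp$age_min, age_max = sp$age_max,
      scr_min = sp$scr_min, scr_max = sp$scr_max, n = nrow(opt$cohort),
      std_dose = std$dose, std_pta = std$pta,
      std_trough_med = std$median_trough,
      std_trough_q1 = std$trough_iqr[1], std_trough_q3 = std$trough_iqr[2],
      opt_dose = opt$best$dose, opt_pta = opt$best$pta,
      opt_trough_med = opt$best$median_trough,
      opt_trough_q1 = opt$best$trough_iqr[1],
      opt_trough_q3 = opt$best$trough_iqr[2])
  })
  do.call(rbind, rows)
}

#' Loading-dose evaluation
#'
#' Simulates, for each subgroup, the optimized maintenance regimen with
#' and without a loading dose replacing the first administration, and
#' summarizes initial (AUC 0-24 h) and steady-state (AUC 24-48 h) target
#' attainment and supratherapeutic fractions. Within a subgroup both arms
#' share the cohort and random-effect draws.
#'
#' @param pop A [pop_params()] object.
#' @param specs List of [subgroup_spec()]s.
#' @param maintenance Maintenance doses, mg/kg: one per subgroup
#'   (recycled if scalar). Typically the optimized doses from
#'   [dosing_table()].
#' @param loading Loading dose, mg/kg (default 25).
#' @param seed Integer seed; subgroup `k` uses `seed + k` (matching
#'   [dosing_table()] cohorts).
#' @param window Target AUC window.
#' @return A list with `per_subgroup` (data frame) and `pooled`
#'   (unweighted means across subgroups).
#' @export
evaluate_loading <- function(pop, specs = default_subgroups(),
                             maintenance, loading = 25, seed = 1L,
                             window = c(400, 650)) {
  maintenance <- rep_len(maintenance, length(specs))
  rows <- lapply(seq_along(specs), function(k) {
    sp <- specs[[k]]
    sk <- seed + k
    cohort <- sample_cohort(sp, sk)
    draws <- draw_random_effects(pop, nrow(cohort), 1L, sk + 1000003L)
    ld <- simulate_exposure(pop, cohort,
                            q6h_builder(maintenance[k],
                                        loading_mg_per_kg = loading),
                            draws = draws, window = window)
    nl <- simulate_exposure(pop, cohort, q6h_builder(maintenance[k]),
                            draws = draws, window = window)
    data.frame(
      label = sp$label, maintenance = maintenance[k], loading = loading,
      pta_0_24_load = pta(ld, window, "auc_0_24"),
      pta_0_24_noload = pta(nl, window, "auc_0_24"),
      pta_24_48_load = pta(ld, window, "auc_24_48"),
      pta_24_48_noload = pta(nl, window, "auc_24_48"),
      supra_0_24_load = mean(ld$supra_0_24),
      supra_0_24_noload = mean(nl$supra_0_24),
      supra_24_48_load = mean(ld$supra_24_48),
      supra_24_48_noload = mean(nl$supra_24_48))
  })
  per <- do.call(rbind, rows)
  num <- vapply(per[, -1], is.numeric, logical(1))
  pooled <- as.list(colMeans(per[, -1][, num]))
  list(per_subgroup = per, pooled = pooled)
}

#' Render the dosing table in the published format
#'
#' Formats a [dosing_table()] result as text columns
#' `"dose (PTA%)"` and `"median (q1-q3)"` for both arms.
#'
#' @param results Data frame from [dosing_table()]; may be empty.
#' @return A character data frame (header-only when `results` is empty).
#' @export
render_dosing_table <- function(results) {
  hdr <- data.frame(age = character(), scr = character(),
                    standard = character(), standard_trough = character(),
                    optimized = character(), optimized_trough = character())
  if (NROW(results) == 0L) return(hdr)
  fmt_reg <- function(d, p) sprintf("%g (%.1f)", d, 100 * p)
  fmt_tr <- function(m, a, b) sprintf("%.2f (%.2f-%.2f)", m, a, b)
  miss <- is.na(results$opt_dose)
  data.frame(
    age = sprintf("%g-%g years", results$age_min, results$age_max),
    scr = sprintf("%g-%g", results$scr_min, results$scr_max),
    standard = fmt_reg(results$std_dose, results$std_pta),
    standard_trough = fmt_tr(results$std_trough_med, results$std_trough_q1,
                             results$std_trough_q3),
    optimized = ifelse(miss, "-",
                       fmt_reg(results$opt_dose, results$opt_pta)),
    optimized_trough = ifelse(miss, "-",
                              fmt_tr(results$opt_trough_med,
                                     results$opt_trough_q1,
                                     results$opt_trough_q3)))
}

#' Parse a rendered dosing table back to numbers
#'
#' Inverse of [render_dosing_table()] for the numeric fields (round-trip
#' to the rendered precision).
#'
#' @param rendered Character data frame from [render_dosing_table()].
#' @return A data frame of the parsed doses, PTAs and trough summaries.
#' @export
parse_dosing_table <- function(rendered) {
  parse_reg <- function(s) {
    m <- regmatches(s, regexec("^([-0-9.]+) \\(([0-9.]+)\\)$", s))
    t(vapply(m, function(x) as.numeric(x[2:3]), numeric(2)))
  }
  parse_tr <- function(s) {
    m <- regmatches(s, regexec(
      "^([0-9.]+) \\(([0-9.]+)-([0-9.]+)\\)$", s))
    t(vapply(m, function(x) as.numeric(x[2:4]), numeric(3)))
  }
  sr <- parse_reg(rendered$standard); st <- parse_tr(rendered$standard_trough)
  or <- parse_reg(rendered$optimized); ot <- parse_tr(rendered$optimized_trough)
  data.frame(std_dose = sr[, 1], std_pta = sr[, 2] / 100,
             std_trough_med = st[, 1], std_trough_q1 = st[, 2],
             std_trough_q3 = st[, 3],
             opt_dose = or[, 1], opt_pta = or[, 2] / 100,
             opt_trough_med = ot[, 1], opt_trough_q1 = ot[, 2],
             opt_trough_q3 = ot[, 3])
}
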