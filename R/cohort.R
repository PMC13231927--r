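#' Simulation subgroup specification
#'
#' An age band, serum-creatinine band and cohort size defining one row of
#' the dosing-simulation design.
#'
#' @param label Subgroup label.
#' @param age_min,age_max Age band, years.
#' @param scr_min,scr_max Serum creatinine band, umol/L.
#' @param n Number of virtual subjects.
#' @return An object of class `subgroup_spec`.
#' @export
subgroup_spec <- function(label, age_min, age_max, scr_min, scr_max,
                          n = 1000L) {
  stopifnot(age_min > 0, age_max > age_min, scr_min > 0, scr_max > scr_min,
            n >= 0)
  structure(list(label = label, age_min = age_min, age_max = age_max,
                 scr_min = scr_min, scr_max = scr_max, n = as.integer(n)),
            class = "subgroup_spec")
}

#' The nine default dosing subgroups
#'
#' Age and serum-creatinine bands of the simulated dosing design: five age
#' groups (3 months-1, 1-4, 4-10, 10-16, 16-18 years) crossed with one or
#' two creatinine bands each, nine subgroups in total.
#'
#' @param n Subjects per subgroup (default 1000).
#' @return A list of [subgroup_spec()] objects.
#' @export
default_subgroups <- function(n = 1000L) {
  d <- list(
    c(0.25, 1, 10, 30), c(1, 4, 10, 30), c(1, 4, 30, 50),
    c(4, 10, 20, 40), c(4, 10, 40, 60), c(10, 16, 30, 60),
    c(10, 16, 60, 80), c(16, 18, 50, 80), c(16, 18, 80, 110))
  lab <- c("3 months-1 year / SCR 10-30", "1-4 years / SCR 10-30",
           "1-4 years / SCR 30-50", "4-10 years / SCR 20-40",
           "4-10 years / SCR 40-60", "10-16 years / SCR 30-60",
           "10-16 years / SCR 60-80", "16-18 years / SCR 50-80",
           "16-18 years / SCR 80-110")
  mapply(function(b, l) subgroup_spec(l, b[1], b[2], b[3], b[4], n = n),
         d, lab, SIMPLIFY = FALSE)
}

# cached monotone interpolant of the packaged median weight-for-age curve
the <- new.env(parent = emptyenv())

#' Median weight for age
#'
#' Smooth median weight-for-age curve used to generate virtual-cohort
#' weights. Anchored to unisex growth-reference medians and interpolated
#' with a monotone Hermite spline; shipped as
#' `extdata/weight_for_age_synthetic.csv` (a synthetic stand-in for the
#' confidential covariate database, overridable via `curve`).
#'
#' @param age Age, years (vectorized; clamped to the tabulated range).
#' @param curve Optional two-column data frame (age years, median kg)
#'   replacing the packaged curve.
#' @return Median weight, kg.
#' @export
#' @examples
#' weight_for_age(c(0.5, 2, 6.8, 12))
weight_for_age <- function(age, curve = NULL) {
  if (is.null(curve)) {
    if (is.null(the$wfa_fun)) {
      path <- system.file("extdata", "weight_for_age_synthetic.csv",
                          package = "pedvanc", mustWork = TRUE)
      tab <- utils::read.csv(path)
      the$wfa_fun <- stats::splinefun(tab[[1]], tab[[2]], method = "monoH.FC")
      the$wfa_range <- range(tab[[1]])
    }
    f <- the$wfa_fun; rng <- the$wfa_range
  } else {
    f <- stats::splinefun(curve[[1]], curve[[2]], method = "monoH.FC")
    rng <- range(curve[[1]])
  }
  f(pmin(pmax(age, rng[1]), rng[2]))
}

#' Sample a virtual covariate cohort
#'
#' Generates `spec$n` subjects with age and serum creatinine uniform on
#' the subgroup bands, weight equal to the median weight-for-age times a
#' lognormal deviate (log-scale SD `wt_sd`), and PMA derived from age
#' assuming term gestation. Deterministic for a given seed.
#'
#' @param spec A [subgroup_spec()].
#' @param seed Integer seed.
#' @param wt_sd Log-scale SD of the weight deviation (default 0.15).
#' @return A data frame with columns `id, age, pma, wt, scr`.
#' @export
sample_cohort <- function(spec, seed, wt_sd = 0.15) {
  stopifnot(inherits(spec, "subgroup_spec"))
  n <- spec$n
  if (n == 0L)
    return(data.frame(id = integer(), age = numeric(), pma = numeric(),
                      wt = numeric(), scr = numeric()))
  set.seed(seed)
  age <- stats::runif(n, spec$age_min, spec$age_max)
  scr <- stats::runif(n, spec$scr_min, spec$scr_max)
  wt <- weight_for_age(age) * exp(stats::rnorm(n, 0, wt_sd))
  data.frame(id = seq_len(n), age = age, pma = pma_from_age(age),
             wt = wt, scr = scr)
}

#' Default regimen policy for synthetic TDM data
#'
#' Returns a function mapping one cohort row to a [regimen()]:
#' `dose_mg_per_kg` q6h 1-h infusions in one or more treatment episodes.
#' Episodes are separated by a 72-h drug-free gap, so each is its own
#' occasion under the 24-h-gap rule.
#'
#' @param dose_mg_per_kg Dose per administration, mg/kg.
#' @param n_occasions Number of treatment episodes.
#' @param doses_per_occasion q6h administrations per episode.
#' @return `function(cov_row) -> regimen`.
#' @export
default_regimen_policy <- function(dose_mg_per_kg = 15, n_occasions = 1,
                                   doses_per_occasion = 8) {
  force(dose_mg_per_kg); force(n_occasions); force(doses_per_occasion)
  function(cov) {
    dose <- round(dose_mg_per_kg * cov$wt)
    t0 <- (seq_len(n_occasions) - 1) * (6 * doses_per_occasion + 72)
    times <- as.vector(vapply(t0, function(s)
      s + seq(0, by = 6, length.out = doses_per_occasion),
      numeric(doses_per_occasion)))
    occ <- rep(seq_len(n_occasions), each = doses_per_occasion)
    regimen(time = times, amt = dose, dur = 1, occ = occ,
            horizon = max(times) + 24)
  }
}

#' Default sparse TDM sampling policy
#'
#' Returns a function drawing 1-6 observation times per subject
#' (probability weights chosen so the median count is 3), trough-weighted:
#' with probability `p_trough` a time just before a later dose, otherwise
#' uniform over the treated interval.
#'
#' @param p_trough Probability that a sample is a trough sample.
#' @param n_probs Probability weights for 1-6 samples per subject.
#' @return `function(reg) -> numeric vector of times (h)`.
#' @export
default_sampling_policy <- function(p_trough = 0.7,
                                    n_probs = c(0.15, 0.2, 0.3, 0.15,
                                                0.1, 0.1)) {
  force(p_trough); force(n_probs)
  function(reg) {
    n <- sample.int(6L, 1L, prob = n_probs)
    later_doses <- reg$time[-1]
    t <- vapply(seq_len(n), function(i) {
      if (length(later_doses) && stats::runif(1) < p_trough) {
        td <- later_doses[sample.int(length(later_doses), 1L)]
        td - stats::runif(1, 0, 0.5)
      } else {
        stats::runif(1, min(reg$time) + reg$dur[1], attr(reg, "horizon"))
      }
    }, numeric(1))
    sort(t)
  }
}

# occasion of an observation time: occasion of the latest dose at or
# before it (1 if none)
obs_occasion <- function(reg, t) {
  vapply(t, function(tt) {
    i <- which(reg$time <= tt + 1e-9)
    if (length(i)) reg$occ[max(i)] else 1L
  }, integer(1))
}

#' Synthesize a sparse TDM dataset from the population model
#'
#' For every cohort subject, draws interindividual and per-occasion
#' random effects, simulates concentrations at policy-drawn sampling
#' times, and applies proportional residual error
#' `DV = f * (1 + sigma_prop * eps)`. Records below the lower limit of
#' quantification and non-positive records are dropped (counted in the
#' `n_blq` attribute); sampling times before the first dose are excluded
#' (counted in `n_excluded`). The generating random effects are kept in
#' the `truth` attribute for recovery tests.
#'
#' @param pop A [pop_params()] object.
#' @param cohort Covariate data frame from [sample_cohort()].
#' @param regimen_policy `function(cov_row) -> regimen`; see
#'   [default_regimen_policy()].
#' @param sampling_policy `function(regimen) -> times`; see
#'   [default_sampling_policy()].
#' @param seed Integer seed.
#' @param lloq Lower limit of quantification, mg/L (default 2).
#' @return A `tdm_dataset` (NONMEM-style event-record data frame; see
#'   [read_tdm()]), with attributes `truth`, `n_blq`, `n_excluded`.
#' @export
synthesize_tdm <- function(pop, cohort,
                           regimen_policy = default_regimen_policy(),
                           sampling_policy = default_sampling_policy(),
                           seed = 1L, lloq = 2) {
  stopifnot(inherits(pop, "pop_params"))
  set.seed(seed)
  rows <- list(); truths <- list()
  n_blq <- 0L; n_excl <- 0L
  for (i in seq_len(nrow(cohort))) {
    cv <- cohort[i, ]
    cov <- subject_covariates(age = cv$age, wt = cv$wt, scr = cv$scr,
                              pma = cv$pma)
    reg <- regimen_policy(cv)
    n_occ <- max(reg$occ)
    ind <- draw_individual(pop, cov, n_occasions = n_occ)
    t_obs <- sampling_policy(reg)
    drop <- t_obs < min(reg$time) + 1e-9
    n_excl <- n_excl + sum(drop)
    t_obs <- t_obs[!drop]
    f <- concentration(ind, reg, t_obs)
    dv <- f * (1 + pop$sigma_prop * stats::rnorm(length(f)))
    ok <- dv >= lloq
    n_blq <- n_blq + sum(!ok)
    t_obs <- t_obs[ok]; dv <- dv[ok]
    occ_obs <- obs_occasion(reg, t_obs)
    dose_rows <- data.frame(
      ID = cv$id, TIME = reg$time, AMT = reg$amt, RATE = reg$amt / reg$dur,
      DUR = reg$dur, DV = NA_real_, EVID = 1L, MDV = 1L, OCC = reg$occ,
      AGE = cv$age, WT = cv$wt, SCR = cv$scr, PMA = cv$pma)
    obs_rows <- if (length(t_obs)) data.frame(
      ID = cv$id, TIME = t_obs, AMT = 0, RATE = 0, DUR = 0,
      DV = dv, EVID = 0L, MDV = 0L, OCC = occ_obs,
      AGE = cv$age, WT = cv$wt, SCR = cv$scr, PMA = cv$pma) else NULL
    sub <- rbind(dose_rows, obs_rows)
    rows[[i]] <- sub[order(sub$TIME, -sub$EVID), ]
    truths[[i]] <- list(id = cv$id, eta_cl = ind$eta_cl,
                        eta_v1 = ind$eta_v1, kappa_cl = ind$kappa_cl,
                        cl = ind$cl, v1 = ind$v1)
  }
  ds <- do.call(rbind, rows)
  rownames(ds) <- NULL
  structure(ds, truth = truths, n_blq = n_blq, n_excluded = n_excl,
            class = c("tdm_dataset", "data.frame"))
}
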