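#' Age-standardized serum creatinine
#'
#' Reference serum creatinine for a child of a given age, from the
#' pediatric creatinine reference polynomial
#' `-2.37330 - 12.91367 * ln(age) + 23.93581 * sqrt(age)`. This is the
#' pivot of the renal covariate effect: a subject whose measured creatinine
#' equals this value has a renal clearance factor of exactly 1.
#'
#' The curve is not globally monotone: it has a shallow interior minimum
#' near 1.2 years and rises steadily for older ages.
#'
#' @param age Age in years (> 0). Vectorized.
#' @param intercept,slope_log,slope_sqrt Polynomial coefficients; exposed
#'   for sensitivity analyses.
#' @return Standard creatinine, umol/L.
#' @export
#' @examples
#' scr_std(1)    # 21.56251 (log term vanishes)
#' scr_std(6.8)  # ~35, near the cohort median creatinine
scr_std <- function(age, intercept = -2.37330, slope_log = -12.91367,
                    slope_sqrt = 23.93581) {
  if (any(!is.finite(age)) || any(age <= 0))
    stop("scr_std: age must be positive and finite", call. = FALSE)
  intercept + slope_log * log(age) + slope_sqrt * sqrt(age)
}

#' Allometric size factor
#'
#' Theory-based allometric scaling of clearance-like parameters to a 70 kg
#' reference with a fixed exponent of 0.75.
#'
#' @param wt Body weight, kg (> 0). Vectorized.
#' @return Unitless factor; 1 at 70 kg.
#' @export
#' @examples
#' f_size(70)    # 1
#' f_size(8.75)  # (1/8)^0.75 = 0.2102
f_size <- function(wt) {
  if (any(!is.finite(wt)) || any(wt <= 0))
    stop("f_size: weight must be positive and finite", call. = FALSE)
  (wt / 70)^0.75
}

#' Sigmoidal maturation of clearance with postmenstrual age
#'
#' Hill-type maturation function `pma^hill / (pma^hill + tm50^hill)`,
#' strictly increasing in PMA, 0.5 at `tm50` and saturating at 1.
#'
#' @param pma Postmenstrual age, weeks (> 0). Vectorized.
#' @param hill Hill coefficient (default the fixed value 3.4).
#' @param tm50 PMA at half-maximal maturation, weeks (default 47.7).
#' @return Unitless fraction of mature clearance in (0, 1).
#' @export
#' @examples
#' f_mat(47.7)               # 0.5 by definition
#' f_mat(2 * 52.1775 + 40)   # well above 0.9 at 2 years of age
f_mat <- function(pma, hill = 3.4, tm50 = 47.7) {
  if (any(!is.finite(pma)) || any(pma <= 0))
    stop("f_mat: pma must be positive and finite", call. = FALSE)
  r <- (pma / tm50)^hill
  r / (1 + r)
}

#' Postnatal-age transition factor
#'
#' Optional first-order transition in postnatal age,
#' `1 - pna_max * exp(-log(2) * pna / pna_t50)`: the factor equals
#' `1 - pna_max` at birth and approaches 1 with half-time `pna_t50` days.
#' It multiplies [f_mat()] in the extended maturation model. The final
#' model does not retain this factor and no default parameter values are
#' shipped; both must be supplied.
#'
#' @param pna Postnatal age, days (>= 0). Vectorized.
#' @param pna_max Transition amplitude in `[0, 1]`.
#' @param pna_t50 Transition half-time, days (> 0).
#' @return Unitless factor in `[1 - pna_max, 1]`.
#' @export
f_mat_pna <- function(pna, pna_max, pna_t50) {
  if (missing(pna_max) || missing(pna_t50) ||
      is.na(pna_max) || is.na(pna_t50))
    stop("f_mat_pna: pna_max and pna_t50 must be supplied (no published ",
         "defaults exist)", call. = FALSE)
  if (pna_max < 0 || pna_max > 1)
    stop("f_mat_pna: pna_max must lie in [0, 1]", call. = FALSE)
  if (pna_t50 <= 0) stop("f_mat_pna: pna_t50 must be positive", call. = FALSE)
  if (any(pna < 0)) stop("f_mat_pna: pna must be non-negative", call. = FALSE)
  1 - pna_max * exp(-log(2) * pna / pna_t50)
}

#' Renal function factor from serum creatinine
#'
#' Exponential covariate effect of the deviation of measured serum
#' creatinine from its age standard: `exp(-theta_scr * (scr - scr_std(age)))`.
#' Equals 1 when creatinine is exactly age-typical and decreases as
#' creatinine rises (reduced renal elimination).
#'
#' @param scr Serum creatinine, umol/L (> 0). Vectorized.
#' @param age Age, years (> 0).
#' @param theta_scr Covariate slope per umol/L (default 0.0188).
#' @param ... Passed to [scr_std()] (alternative polynomial coefficients).
#' @return Unitless positive factor.
#' @export
f_renal <- function(scr, age, theta_scr = 0.0188, ...) {
  if (any(!is.finite(scr)) || any(scr <= 0))
    stop("f_renal: scr must be positive and finite", call. = FALSE)
  exp(-theta_scr * (scr - scr_std(age, ...)))
}

#' Postmenstrual age from postnatal age
#'
#' @param age Age, years. Vectorized.
#' @param ga_weeks Gestational age at birth, weeks (default 40, term).
#' @return PMA in weeks, `age * 52.1775 + ga_weeks`.
#' @export
pma_from_age <- function(age, ga_weeks = 40) {
  age * 52.1775 + ga_weeks
}

#' Subject covariates
#'
#' Bundle of the covariates the model uses for one subject at one occasion.
#' If `pma` is omitted it is derived from `age` assuming term gestation.
#'
#' @param age Age, years (> 0).
#' @param wt Weight, kg (> 0).
#' @param scr Serum creatinine, umol/L (> 0).
#' @param pma Postmenstrual age, weeks (>= 22). Derived from `age` when `NULL`.
#' @param pna Postnatal age, days; defaults to `age * 365.25`.
#' @param ga_window Allowed discrepancy (weeks) between `pma` and the PMA
#'   implied by `age` with gestational ages 22-44 weeks.
#' @return An object of class `subject_covariates`.
#' @export
#' @examples
#' subject_covariates(age = 0.5, wt = 7.6, scr = 20)
subject_covariates <- function(age, wt, scr, pma = NULL, pna = NULL,
                               ga_window = c(22, 44)) {
  stopifnot(length(age) == 1L, length(wt) == 1L, length(scr) == 1L)
  if (!is.finite(age) || age <= 0) stop("age must be positive", call. = FALSE)
  if (!is.finite(wt) || wt <= 0) stop("wt must be positive", call. = FALSE)
  if (!is.finite(scr) || scr <= 0) stop("scr must be positive", call. = FALSE)
  if (is.null(pma)) pma <- pma_from_age(age)
  if (pma < 22) stop("pma must be at least 22 weeks", call. = FALSE)
  implied_ga <- pma - age * 52.1775
  if (implied_ga < ga_window[1] || implied_ga > ga_window[2])
    stop("pma and age are inconsistent: implied gestational age ",
         round(implied_ga, 1), " weeks lies outside [",
         ga_window[1], ", ", ga_window[2], "]", call. = FALSE)
  if (is.null(pna)) pna <- age * 365.25
  structure(list(age = age, wt = wt, scr = scr, pma = pma, pna = pna),
            class = "subject_covariates")
}
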