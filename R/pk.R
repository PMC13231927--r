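## Closed-form two-compartment kinetics with zero-order (infusion) input.
##
## The model is linear and time-invariant, so the concentration under an
## arbitrary sequence of infusions is the superposition of step responses:
## an infusion of rate R starting at t0 with duration T contributes
## R * (S(t - t0) - S(t - t0 - T)) where S is the unit-rate step response
## of the central compartment. Both S and its running integral have closed
## forms in the hybrid rate constants alpha > beta > 0, which is what makes
## exact AUC computation over arbitrary windows possible.

# Hybrid-constant coefficients for one or many parameter sets (vectorized).
# alpha*beta = k10*k21 and alpha+beta = k10+k12+k21; beta is computed as
# p/alpha to avoid catastrophic cancellation when the discriminant is small.
two_cpt_coefs <- function(cl, v1, q, v2) {
  k10 <- cl / v1
  k12 <- q / v1
  k21 <- q / v2
  s <- k10 + k12 + k21
  p <- k10 * k21
  disc <- sqrt(pmax(s * s - 4 * p, 0))
  alpha <- (s + disc) / 2
  beta <- p / alpha
  degen <- (alpha - beta) < 1e-9 * alpha
  # A, B are the central-compartment bolus-response weights divided by V1
  d <- alpha - beta
  d[degen] <- 1 # placeholder, never used on the degenerate branch
  A <- (alpha - k21) / (v1 * d)
  B <- (k21 - beta) / (v1 * d)
  list(alpha = alpha, beta = beta, A = A, B = B, k21 = k21, v1 = v1,
       degen = degen)
}

# Unit-rate step response S(t); elementwise in t (coefs recycled or
# same-length vectors). Zero for t <= 0.
step_response <- function(co, t) {
  pos <- t > 0
  tp <- ifelse(pos, t, 0)
  ea <- exp(-co$alpha * tp)
  eb <- exp(-co$beta * tp)
  out <- co$A * (1 - ea) / co$alpha + co$B * (1 - eb) / co$beta
  if (any(co$degen)) {
    lam <- co$alpha
    sd_ <- ((lam - co$k21) * (1 - (1 + lam * tp) * ea) / lam^2 +
              (1 - ea) / lam) / co$v1
    out <- ifelse(co$degen, sd_, out)
  }
  out * pos
}

# Running integral of the step response, int_0^t S(u) du; zero for t <= 0.
step_response_int <- function(co, t) {
  pos <- t > 0
  tp <- ifelse(pos, t, 0)
  ea <- exp(-co$alpha * tp)
  eb <- exp(-co$beta * tp)
  out <- co$A * (tp - (1 - ea) / co$alpha) / co$alpha +
    co$B * (tp - (1 - eb) / co$beta) / co$beta
  if (any(co$degen)) {
    lam <- co$alpha
    sd_ <- ((lam - co$k21) / lam^2 *
              (tp - (2 - (2 + lam * tp) * ea) / lam) +
              (tp - (1 - ea) / lam) / lam) / co$v1
    out <- ifelse(co$degen, sd_, out)
  }
  out * pos
}

#' Infusion regimen
#'
#' An ordered sequence of zero-order intravenous infusion events. A 1-h
#' infusion has duration 1; a continuous infusion is a single long event.
#' Occasion indices partition events into treatment occasions for
#' interoccasion variability.
#'
#' @param time Event start times, h (non-decreasing, >= 0).
#' @param amt Dose per event, mg (>= 0; a zero dose is allowed and
#'   contributes nothing).
#' @param dur Infusion durations, h (> 0); recycled.
#' @param occ Occasion index per event (positive, non-decreasing); recycled.
#' @param horizon Simulation end time, h; defaults to the last event start
#'   plus 24 h.
#' @return An object of class `regimen`: a data frame of events with a
#'   `horizon` attribute.
#' @export
#' @examples
#' regimen(time = c(0, 6, 12), amt = 120, dur = 1)
regimen <- function(time, amt, dur = 1, occ = 1L, horizon = NULL) {
  n <- length(time)
  amt <- rep_len(amt, n)
  dur <- rep_len(dur, n)
  occ <- rep_len(as.integer(occ), n)
  if (n > 0) {
    if (any(!is.finite(time)) || any(time < 0) || is.unsorted(time))
      stop("regimen: event times must be non-negative and non-decreasing",
           call. = FALSE)
    if (any(!is.finite(amt)) || any(amt < 0))
      stop("regimen: doses must be non-negative", call. = FALSE)
    if (any(!is.finite(dur)) || any(dur <= 0))
      stop("regimen: infusion durations must be positive", call. = FALSE)
    if (any(occ < 1L) || is.unsorted(occ))
      stop("regimen: occasion indices must be positive and non-decreasing",
           call. = FALSE)
  }
  if (is.null(horizon)) horizon <- if (n > 0) max(time) + 24 else 24
  structure(data.frame(time = as.numeric(time), amt = as.numeric(amt),
                       dur = as.numeric(dur), occ = occ),
            horizon = as.numeric(horizon), class = c("regimen", "data.frame"))
}

#' Intermittent q6h infusion regimen
#'
#' Convenience constructor for the simulated dosing pattern: 1-h infusions
#' every 6 h. With the default `n_doses = 9` and `horizon = 48` the last
#' dose starts exactly at 48 h so that the steady-state trough can be read
#' immediately before it.
#'
#' @param dose_mg Maintenance dose per administration, mg.
#' @param n_doses Number of administrations.
#' @param interval Dosing interval, h.
#' @param dur Infusion duration, h.
#' @param loading_mg Optional loading dose replacing the first
#'   administration, mg.
#' @param horizon Simulation end, h.
#' @return A [regimen()].
#' @export
q6h_regimen <- function(dose_mg, n_doses = 9, interval = 6, dur = 1,
                        loading_mg = NULL, horizon = 48) {
  amt <- rep(dose_mg, n_doses)
  if (!is.null(loading_mg)) amt[1] <- loading_mg
  regimen(time = seq(0, by = interval, length.out = n_doses), amt = amt,
          dur = dur, occ = 1L, horizon = horizon)
}

#' Individual pharmacokinetic parameters
#'
#' Subject-level two-compartment parameters, with clearance possibly
#' varying by treatment occasion (interoccasion variability). The
#' log-scale random-effect realizations that generated them are carried
#' along for bookkeeping.
#'
#' @param cl Clearance, L/h; a vector with one value per occasion.
#' @param v1 Central volume, L.
#' @param q Intercompartmental clearance, L/h.
#' @param v2 Peripheral volume, L.
#' @param eta_cl,eta_v1 Log-scale interindividual random effects.
#' @param kappa_cl Log-scale interoccasion random effects (one per
#'   occasion).
#' @return An object of class `individual_params`.
#' @export
individual_params <- function(cl, v1, q, v2, eta_cl = 0, eta_v1 = 0,
                              kappa_cl = numeric(length(cl))) {
  if (any(!is.finite(cl)) || any(cl <= 0) || v1 <= 0 || q <= 0 || v2 <= 0)
    stop("individual_params: cl, v1, q, v2 must all be positive",
         call. = FALSE)
  structure(list(cl = as.numeric(cl), v1 = v1, q = q, v2 = v2,
                 eta_cl = eta_cl, eta_v1 = eta_v1,
                 kappa_cl = as.numeric(kappa_cl)),
            class = "individual_params")
}

#' Typical individual parameters for given covariates
#'
#' Evaluates the covariate model with all random effects at zero:
#' `CL = TVCL * f_size(wt) * f_mat(pma) * f_renal(scr, age)`,
#' `V1 = TVV1 * wt/70`, `Q = TVQ * (wt/70)^0.75`, `V2 = TVV2 * wt/70`.
#' The optional postnatal-age transition factor multiplies the maturation
#' term only when both of its parameters are present in `pop`.
#'
#' @param pop A [pop_params()] object.
#' @param cov A [subject_covariates()] object.
#' @return An [individual_params()] object (single occasion).
#' @export
#' @examples
#' pop <- vanco_params()
#' cov <- subject_covariates(age = 30, wt = 70, scr = scr_std(30),
#'                           pma = pma_from_age(30))
#' typical_params(pop, cov)$cl / 70   # ~0.108 L/h/kg
typical_params <- function(pop, cov) {
  stopifnot(inherits(pop, "pop_params"), inherits(cov, "subject_covariates"))
  fmat <- f_mat(cov$pma, pop$hill, pop$tm50)
  if (!is.na(pop$pna_max) && !is.na(pop$pna_t50))
    fmat <- fmat * f_mat_pna(cov$pna, pop$pna_max, pop$pna_t50)
  cl <- pop$tvcl * f_size(cov$wt) * fmat *
    f_renal(cov$scr, cov$age, pop$theta_scr)
  individual_params(cl = cl,
                    v1 = pop$tvv1 * (cov$wt / 70),
                    q = pop$tvq * f_size(cov$wt),
                    v2 = pop$tvv2 * (cov$wt / 70))
}

# coefs per occasion for an individual; returns list indexed by occasion
ind_coefs <- function(ind, n_occ) {
  cl <- rep_len(ind$cl, n_occ)
  lapply(seq_len(n_occ), function(i)
    two_cpt_coefs(cl[i], ind$v1, ind$q, ind$v2))
}

#' Central-compartment concentration under a regimen
#'
#' Closed-form concentration at arbitrary times by superposition of
#' two-compartment infusion step responses. Each dose event is evaluated
#' with the clearance of its own occasion; the concentration is zero
#' before the first event, continuous and non-negative.
#'
#' @param ind An [individual_params()] object.
#' @param reg A [regimen()].
#' @param t Times, h (vectorized).
#' @return Concentrations, mg/L.
#' @export
concentration <- function(ind, reg, t) {
  stopifnot(inherits(ind, "individual_params"), inherits(reg, "regimen"))
  if (nrow(reg) == 0L) return(numeric(length(t)))
  n_occ <- max(reg$occ)
  cos_ <- ind_coefs(ind, n_occ)
  out <- numeric(length(t))
  for (e in seq_len(nrow(reg))) {
    if (reg$amt[e] == 0) next
    co <- cos_[[reg$occ[e]]]
    rate <- reg$amt[e] / reg$dur[e]
    out <- out + rate * (step_response(co, t - reg$time[e]) -
                           step_response(co, t - reg$time[e] - reg$dur[e]))
  }
  pmax(out, 0)
}

#' Exact area under the concentration-time curve
#'
#' Analytic integral of the superposed closed-form solution over
#' `[t1, t2]` (no quadrature).
#'
#' @inheritParams concentration
#' @param t1,t2 Window bounds, h, with `t1 < t2`. `t2 = Inf` gives the
#'   total remaining exposure.
#' @return AUC, mg.h/L.
#' @export
#' @examples
#' ind <- individual_params(cl = 2, v1 = 10, q = 1.3, v2 = 30)
#' reg <- regimen(0, 500, dur = 1)
#' auc(ind, reg, 0, Inf)  # 500 / 2 = 250
auc <- function(ind, reg, t1, t2) {
  stopifnot(inherits(ind, "individual_params"), inherits(reg, "regimen"))
  if (!(t1 >= 0) || !(t2 > t1))
    stop("auc: need 0 <= t1 < t2", call. = FALSE)
  if (nrow(reg) == 0L) return(0)
  n_occ <- max(reg$occ)
  cos_ <- ind_coefs(ind, n_occ)
  cl_occ <- rep_len(ind$cl, n_occ)
  cum_at <- function(t) {
    tot <- 0
    for (e in seq_len(nrow(reg))) {
      if (reg$amt[e] == 0) next
      co <- cos_[[reg$occ[e]]]
      rate <- reg$amt[e] / reg$dur[e]
      if (is.infinite(t)) {
        # IS(t) - IS(t - dur) -> dur * S(inf) = dur * 1/CL as t -> inf
        tot <- tot + reg$amt[e] / cl_occ[reg$occ[e]]
      } else {
        tot <- tot + rate * (step_response_int(co, t - reg$time[e]) -
                               step_response_int(co, t - reg$time[e] - reg$dur[e]))
      }
    }
    tot
  }
  cum_at(t2) - cum_at(t1)
}

#' Trough concentration before a scheduled dose
#'
#' Concentration at the instant immediately before the infusion starting
#' at `t_dose`. Because the contribution of an infusion is zero at its own
#' start time, this equals the superposed concentration evaluated at
#' `t_dose`.
#'
#' @inheritParams concentration
#' @param t_dose An event start time of `reg`, h.
#' @return Trough concentration, mg/L.
#' @export
trough <- function(ind, reg, t_dose) {
  stopifnot(inherits(reg, "regimen"))
  if (!any(abs(reg$time - t_dose) < 1e-9))
    stop("trough: t_dose (", t_dose, " h) is not an event start time",
         call. = FALSE)
  keep <- reg$time < t_dose - 1e-9
  reg_prior <- regimen(reg$time[keep], reg$amt[keep], reg$dur[keep],
                       reg$occ[keep], horizon = attr(reg, "horizon"))
  concentration(ind, reg_prior, t_dose)
}
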