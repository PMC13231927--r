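## MAP (empirical-Bayes) estimation of one subject's random effects with
## fixed population parameters, and the dose-forecasting layer on top.

# Build a prediction closure for one subject: maps the free random-effect
# vector to concentrations at the observation times. The free vector is
# (eta_cl, eta_v1, kappa_1..K) restricted to components whose variance is
# positive (zero-variance effects are fixed at 0).
# Pop-independent event geometry of one subject, reusable across
# candidate parameter sets: time differences of every observation to
# every event start and end, masked at zero, grouped by occasion.
subject_geometry <- function(subject) {
  reg <- subject$reg; obs <- subject$obs
  n_occ <- if (nrow(reg)) max(reg$occ) else 1L
  dt1 <- outer(obs$time, reg$time, "-")
  dt2 <- outer(obs$time, reg$time + reg$dur, "-")
  rate <- reg$amt / reg$dur
  occ <- lapply(seq_len(n_occ), function(o) {
    cols <- which(reg$occ == o & rate > 0)
    list(d1 = dt1[, cols, drop = FALSE] * (dt1[, cols, drop = FALSE] > 0),
         m1 = (dt1[, cols, drop = FALSE] > 0) * 1,
         d2 = dt2[, cols, drop = FALSE] * (dt2[, cols, drop = FALSE] > 0),
         m2 = (dt2[, cols, drop = FALSE] > 0) * 1,
         rate = rate[cols])
  })
  list(n_occ = n_occ, occ = occ, n_obs = nrow(obs))
}

subject_context <- function(pop, subject, estimate_kappa = TRUE,
                            geom = NULL) {
  obs <- subject$obs
  typ <- typical_params(pop, subject$cov)
  if (is.null(geom)) geom <- subject_geometry(subject)
  n_occ <- geom$n_occ
  use <- c(eta_cl = pop$omega_cl > 0, eta_v1 = pop$omega_v1 > 0,
           kappa = estimate_kappa && pop$omega_iov_cl > 0 && nrow(obs) > 0)
  n_free <- sum(use[1:2]) + if (use[3]) n_occ else 0
  unpack <- function(x) {
    i <- 0L
    eta_cl <- if (use[1]) { i <- i + 1L; x[i] } else 0
    eta_v1 <- if (use[2]) { i <- i + 1L; x[i] } else 0
    kappa <- if (use[3]) x[i + seq_len(n_occ)] else numeric(n_occ)
    list(eta_cl = eta_cl, eta_v1 = eta_v1, kappa = kappa)
  }
  tq <- typ$q; tv2 <- typ$v2; tcl <- typ$cl; tv1 <- typ$v1
  n_obs <- geom$n_obs
  pred <- function(x) {
    p <- unpack(x)
    cl_occ <- tcl * exp(p$eta_cl + p$kappa)
    v1 <- tv1 * exp(p$eta_v1)
    out <- numeric(n_obs)
    for (o in seq_len(n_occ)) {
      g <- geom$occ[[o]]
      if (!length(g$rate)) next
      co <- two_cpt_coefs(cl_occ[o], v1, tq, tv2)
      if (co$degen) {
        s <- step_response(co, g$d1) * g$m1 - step_response(co, g$d2) * g$m2
      } else {
        a <- co$alpha; b <- co$beta; A <- co$A; B <- co$B
        s <- (A * (g$m1 - exp(-a * g$d1) * g$m1) / a +
                B * (g$m1 - exp(-b * g$d1) * g$m1) / b) -
          (A * (g$m2 - exp(-a * g$d2) * g$m2) / a +
             B * (g$m2 - exp(-b * g$d2) * g$m2) / b)
      }
      out <- out + as.vector(s %*% g$rate)
    }
    out
  }
  prior_sd <- c(if (use[1]) pop$omega_cl, if (use[2]) pop$omega_v1,
                if (use[3]) rep(pop$omega_iov_cl, n_occ))
  list(pop = pop, typ = typ, reg = subject$reg, obs = obs, n_occ = n_occ,
       use = use, n_free = n_free, unpack = unpack, pred = pred,
       prior_sd = prior_sd)
}

# MAP objective: -2 log posterior up to a constant, with the interaction
# term log(sigma^2 f^2) retained (FOCE-I-consistent).
map_objective <- function(ctx, x) {
  # keep line searches inside the numerically sane region (|eta| <= 10 is
  # already a factor e^10 on a parameter); gradient pushes back inward
  if (any(!is.finite(x)) || any(abs(x) > 10))
    return(1e16 + 1e10 * sum(pmax(abs(x[is.finite(x)]) - 10, 0)^2))
  f <- ctx$pred(x)
  if (any(!is.finite(f)) || any(f <= 0)) return(1e16)
  s2f2 <- (ctx$pop$sigma_prop * f)^2
  sum((ctx$obs$dv - f)^2 / s2f2 + log(s2f2)) + sum((x / ctx$prior_sd)^2)
}

# inner minimization with optional multistart from 0 and +/- 1 prior SD
map_mode <- function(ctx, start = NULL, multistart = is.null(start)) {
  if (ctx$n_free == 0L || nrow(ctx$obs) == 0L)
    return(list(par = numeric(ctx$n_free),
                value = if (nrow(ctx$obs)) map_objective(ctx, numeric(ctx$n_free)) else 0))
  obj <- function(x) map_objective(ctx, x)
  starts <- if (multistart)
    list(numeric(ctx$n_free), ctx$prior_sd, -ctx$prior_sd)
  else list(start)
  fits <- lapply(starts, function(s)
    stats::optim(s, obj, method = "BFGS",
                 control = list(reltol = 1e-12, maxit = 500)))
  fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
}

#' MAP (empirical Bayes) estimation for one subject
#'
#' Finds the mode of the random-effect posterior given a subject's
#' observed concentrations, with population parameters held fixed (the
#' external-validation / precision-dosing mode: no population
#' re-estimation). The objective is the FOCE-I-consistent
#' `sum[(DV - f)^2 / (sigma f)^2 + log((sigma f)^2)] + eta' Omega^-1 eta
#' + sum(kappa^2) / omega_iov^2`, minimized by quasi-Newton iterations
#' with multistart from 0 and +/- one prior SD.
#'
#' @param pop A [pop_params()] object.
#' @param subject A list with elements `cov` ([subject_covariates()]),
#'   `reg` ([regimen()]) and `obs` (data frame with `time`, `dv`); see
#'   [subject_data()].
#' @param estimate_kappa Estimate per-occasion IOV effects (default) or
#'   fix them at zero.
#' @return An object of class `map_fit`: random-effect modes, objective,
#'   individual parameters, individual predictions `ipred` at the
#'   observation times, and forecast `auc_0_24` / `auc_24_48` under the
#'   subject's regimen. With zero usable observations the prior mode
#'   (all zeros) is returned.
#' @export
map_estimate <- function(pop, subject, estimate_kappa = TRUE) {
  stopifnot(inherits(pop, "pop_params"))
  obs <- subject$obs
  n_rej <- 0L
  if (NROW(obs)) {
    bad <- !is.finite(obs$dv) | obs$dv <= 0
    n_rej <- sum(bad)
    obs <- obs[!bad, , drop = FALSE]
  } else {
    obs <- data.frame(time = numeric(), dv = numeric())
  }
  subject$obs <- obs
  ctx <- subject_context(pop, subject, estimate_kappa)
  fit <- map_mode(ctx)
  p <- ctx$unpack(fit$par)
  ind <- individual_params(cl = ctx$typ$cl * exp(p$eta_cl + p$kappa),
                           v1 = ctx$typ$v1 * exp(p$eta_v1),
                           q = ctx$typ$q, v2 = ctx$typ$v2,
                           eta_cl = p$eta_cl, eta_v1 = p$eta_v1,
                           kappa_cl = p$kappa)
  structure(list(
    eta_cl = p$eta_cl, eta_v1 = p$eta_v1, kappa = p$kappa,
    objective = fit$value, par = fit$par,
    ind = ind,
    ipred = if (nrow(obs)) concentration(ind, subject$reg, obs$time)
            else numeric(0),
    auc_0_24 = if (nrow(subject$reg)) auc(ind, subject$reg, 0, 24) else 0,
    auc_24_48 = if (nrow(subject$reg)) auc(ind, subject$reg, 24, 48) else 0,
    n_rejected = n_rej, pop = pop, subject = subject,
    ctx = ctx), class = "map_fit")
}

#' Daily dose hitting the midpoint of the AUC target
#'
#' For a subject with daily clearance `cl` (L/h), the maintenance dose
#' whose steady-state daily AUC equals the midpoint of the target window:
#' `daily dose = AUC_target * CL` with the default midpoint 525 mg.h/L.
#'
#' @param cl Individual clearance, L/h.
#' @param target Target AUC window, mg.h/L (midpoint is used).
#' @param interval Dosing interval, h.
#' @return List with `daily_mg`, `per_interval_mg`, `target_auc`.
#' @export
#' @examples
#' target_dose(2.0)$daily_mg  # 1050
target_dose <- function(cl, target = c(400, 650), interval = 6) {
  target_auc <- mean(target)
  daily <- target_auc * cl
  list(daily_mg = daily, per_interval_mg = daily * interval / 24,
       target_auc = target_auc)
}

#' Dose recommendation from a MAP fit
#'
#' Converts the MAP clearance estimate (interindividual effect only; IOV
#' is ignored for forecasting future occasions) into the maintenance dose
#' that lands the predicted steady-state AUC on the midpoint of the
#' target window.
#'
#' @param fit A [map_estimate()] result.
#' @param target Target AUC window, mg.h/L.
#' @param interval Dosing interval, h.
#' @return List: `cl` (forecast clearance, L/h), `daily_mg`,
#'   `per_interval_mg`, `mg_per_kg` (per interval), `predicted_auc24`
#'   (equal to the window midpoint by construction), `target`.
#' @export
forecast_and_adjust <- function(fit, target = c(400, 650), interval = 6) {
  stopifnot(inherits(fit, "map_fit"))
  cl_fore <- fit$ctx$typ$cl * exp(fit$eta_cl)
  d <- target_dose(cl_fore, target, interval)
  list(cl = cl_fore, daily_mg = d$daily_mg,
       per_interval_mg = d$per_interval_mg,
       mg_per_kg = d$per_interval_mg / fit$subject$cov$wt,
       predicted_auc24 = d$daily_mg / cl_fore, target = target)
}
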