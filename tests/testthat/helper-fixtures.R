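# Shared fixtures: small parameter sets, subjects and datasets built in
# code at test time.

tab2 <- vanco_params()

# a mid-childhood reference subject
ref_subject <- function() subject_covariates(age = 4, wt = 16.3, scr = 25)

# population with all variability switched off
pop_novar <- function(pop = tab2) {
  pop$omega_cl <- 0; pop$omega_v1 <- 0; pop$omega_iov_cl <- 0
  pop$sigma_prop <- 1e-8
  pedvanc:::validate_pop_params(unclass(pop))
}

pop_with <- function(pop = tab2, ...) {
  mods <- list(...)
  for (nm in names(mods)) pop[[nm]] <- mods[[nm]]
  pedvanc:::validate_pop_params(unclass(pop))
}

# deterministic four-sample design: peak and trough in each of two q6h
# treatment episodes (episodes start at 0 h and 96 h)
peak_trough_sampler <- function(reg) {
  c(1 + stats::runif(1, 0, 0.5), 23 + stats::runif(1, 0, 0.9),
    97 + stats::runif(1, 0, 0.5), 119 + stats::runif(1, 0, 0.9))
}

# small synthetic TDM dataset used across estimation/diagnostic tests
make_tdm <- function(n = 30, seed = 1, pop = tab2, n_occasions = 2,
                     lloq = 0, age_band = c(0.25, 18),
                     scr_band = c(10, 180)) {
  co <- sample_cohort(subgroup_spec("fixture", age_band[1], age_band[2],
                                    scr_band[1], scr_band[2], n = n),
                      seed)
  synthesize_tdm(pop, co,
                 default_regimen_policy(15, n_occasions = n_occasions,
                                        doses_per_occasion = 4),
                 peak_trough_sampler, seed = seed + 7000, lloq = lloq)
}

# independent ODE solution of the two-compartment infusion system
# (requires deSolve; the oracle for the closed-form kinetics)
ode_conc <- function(ind, reg, times, rtol = 1e-10) {
  stopifnot(length(ind$cl) == 1L)
  k10 <- ind$cl / ind$v1; k12 <- ind$q / ind$v1; k21 <- ind$q / ind$v2
  deriv <- function(t, y, p) {
    rate <- sum(reg$amt / reg$dur * (t >= reg$time & t < reg$time + reg$dur))
    list(c(rate - (k10 + k12) * y[1] + k21 * y[2],
           k12 * y[1] - k21 * y[2]))
  }
  tt <- sort(unique(c(0, times, reg$time, reg$time + reg$dur)))
  # cap the step size so the integrator cannot step over an infusion
  # pulse that begins after a long drug-free stretch
  out <- deSolve::ode(c(0, 0), tt, deriv, NULL, rtol = rtol, atol = rtol,
                      maxsteps = 1e6, hmax = 0.1)
  out[match(times, tt), 2] / ind$v1
}
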