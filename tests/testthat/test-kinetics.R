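# Closed-form two-compartment kinetics: superposition, AUC, troughs,
# against independent ODE and quadrature oracles.

test_that("concentration is zero before dosing, continuous, non-negative", {
  ind <- individual_params(cl = 2, v1 = 10, q = 1.3, v2 = 30)
  reg <- regimen(time = c(5, 11), amt = 300, dur = 1)
  expect_identical(concentration(ind, reg, c(0, 2, 4.99)), c(0, 0, 0))
  tt <- seq(0, 30, by = 0.01)
  cc <- concentration(ind, reg, tt)
  expect_true(all(cc >= 0))
  expect_lt(max(abs(diff(cc))), 1.5) # no jumps at event boundaries
})

test_that("closed form matches a stiff ODE integration on random regimens", {
  skip_if_not_installed("deSolve")
  set.seed(101)
  worst <- 0
  for (k in 1:30) {
    ind <- individual_params(cl = runif(1, 0.3, 8), v1 = runif(1, 3, 90),
                             q = runif(1, 0.2, 3), v2 = runif(1, 5, 300))
    nt <- sample(2:5, 1)
    reg <- regimen(time = sort(runif(nt, 0, 40)), amt = runif(nt, 50, 900),
                   dur = runif(nt, 0.5, 6))
    tt <- seq(0.7, 48, by = 1.9)
    rel <- abs(concentration(ind, reg, tt) - ode_conc(ind, reg, tt))
    ref <- pmax(ode_conc(ind, reg, tt), 1e-6)
    worst <- max(worst, max(rel / ref))
  }
  expect_lt(worst, 1e-6)
})

test_that("one-compartment limit as intercompartmental clearance vanishes", {
  cl <- 3; v1 <- 20
  ind <- individual_params(cl = cl, v1 = v1, q = 1e-8, v2 = 50)
  reg <- regimen(0, 400, dur = 2)
  k <- cl / v1; r <- 400 / 2
  tt <- c(0.5, 1.5, 2, 4, 10)
  one_cpt <- ifelse(tt <= 2, r / cl * (1 - exp(-k * tt)),
                    r / cl * (1 - exp(-k * 2)) * exp(-k * (tt - 2)))
  expect_equal(concentration(ind, reg, tt), one_cpt, tolerance = 1e-5)
})

test_that("superposition is linear in dose to machine precision", {
  ind <- individual_params(cl = 1.5, v1 = 12, q = 0.8, v2 = 60)
  r1 <- regimen(time = c(0, 6, 12), amt = 150, dur = 1)
  r2 <- regimen(time = c(0, 6, 12), amt = 300, dur = 1)
  tt <- seq(0.5, 24, by = 0.5)
  expect_equal(2 * concentration(ind, r1, tt), concentration(ind, r2, tt),
               tolerance = 1e-12)
  expect_equal(2 * auc(ind, r1, 3, 20), auc(ind, r2, 3, 20),
               tolerance = 1e-12)
})

test_that("total exposure equals dose over clearance", {
  set.seed(7)
  for (k in 1:10) {
    ind <- individual_params(cl = runif(1, 0.5, 6), v1 = runif(1, 5, 80),
                             q = runif(1, 0.3, 2.5), v2 = runif(1, 10, 250))
    nt <- sample(1:6, 1)
    reg <- regimen(time = sort(runif(nt, 0, 30)), amt = runif(nt, 80, 600),
                   dur = runif(nt, 0.5, 3))
    expect_equal(auc(ind, reg, 0, Inf), sum(reg$amt) / ind$cl,
                 tolerance = 1e-9)
  }
})

test_that("windowed AUC agrees with fine trapezoid quadrature", {
  ind <- individual_params(cl = 2.2, v1 = 18, q = 1.1, v2 = 90)
  reg <- q6h_regimen(320)
  tt <- seq(24, 48, by = 0.001)
  cc <- concentration(ind, reg, tt)
  trap <- sum((cc[-1] + cc[-length(cc)]) / 2) * 0.001
  expect_equal(auc(ind, reg, 24, 48), trap, tolerance = 1e-3)
  expect_error(auc(ind, reg, 30, 20), "t1 < t2")
})

test_that("steady-state interval AUC equals dose over clearance", {
  # parameters with a fast terminal phase so a 600-h run-in reaches
  # steady state to well below the assertion tolerance
  ind <- individual_params(cl = 2, v1 = 15, q = 3, v2 = 30)
  reg <- regimen(time = seq(0, by = 6, length.out = 110), amt = 250,
                 dur = 1, horizon = 700)
  expect_equal(auc(ind, reg, 600, 606), 250 / 2, tolerance = 1e-6)
})

test_that("trough is the concentration just before a scheduled dose", {
  ind <- individual_params(cl = 1.8, v1 = 14, q = 1.0, v2 = 70)
  reg <- q6h_regimen(300)
  expect_identical(trough(ind, reg, 0), 0)
  expect_equal(trough(ind, reg, 48), concentration(ind, reg, 48 - 1e-9),
               tolerance = 1e-6)
  expect_error(trough(ind, reg, 3.14), "not an event start time")
  # after dosing stops the post-treatment troughs decay monotonically
  tr <- concentration(ind, reg, c(54, 60, 66, 72))
  expect_true(all(diff(tr) < 0))
})

test_that("per-occasion clearance drives each event's contribution", {
  # two occasions with different clearances: total exposure splits as
  # dose/CL per occasion
  ind <- individual_params(cl = c(2, 3), v1 = 15, q = 1.2, v2 = 80,
                           kappa_cl = c(0, 0.405))
  reg <- regimen(time = c(0, 6, 100, 106), amt = 200, dur = 1,
                 occ = c(1L, 1L, 2L, 2L), horizon = 400)
  expect_equal(auc(ind, reg, 0, Inf), 400 / 2 + 400 / 3, tolerance = 1e-9)
})

test_that("regimen constructor enforces event ordering and positivity", {
  expect_error(regimen(c(6, 0), 100), "non-decreasing")
  expect_error(regimen(0, -5), "non-negative")
  expect_error(regimen(0, 100, dur = 0), "positive")
  expect_error(regimen(c(0, 6), 100, occ = c(2L, 1L)), "non-decreasing")
  r <- q6h_regimen(100, loading_mg = 250)
  expect_equal(r$amt, c(250, rep(100, 8)))
  expect_equal(attr(r, "horizon"), 48)
})
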