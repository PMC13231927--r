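# Population objective function and estimation machinery.

test_that("without random effects the objective is the exact -2 log likelihood", {
  pop0 <- pop_with(omega_cl = 0, omega_v1 = 0, omega_iov_cl = 0,
                   sigma_prop = 0.2)
  ds <- make_tdm(n = 8, seed = 21, pop = pop0, n_occasions = 1)
  # oracle: proportional-error Gaussian likelihood of the typical model
  m2ll <- 0
  for (id in unique(ds$ID)) {
    sub <- subject_data(ds, id)
    f <- concentration(typical_params(pop0, sub$cov), sub$reg, sub$obs$time)
    m2ll <- m2ll + sum((sub$obs$dv - f)^2 / (0.2 * f)^2 +
                         log(2 * pi * (0.2 * f)^2))
  }
  expect_equal(foce_objective(pop0, ds), m2ll, tolerance = 1e-8)
  expect_equal(foce_objective(pop0, ds, method = "focei"), m2ll,
               tolerance = 1e-8)
})

test_that("Laplace approximation matches brute-force integration", {
  # one subject, two random effects: the marginal likelihood integral is
  # computed on a fine grid as an independent oracle
  ds <- make_tdm(n = 1, seed = 22, n_occasions = 1)
  pop1 <- pop_with(omega_iov_cl = 0) # two-dimensional integral
  sub <- pedvanc:::prepare_subjects(ds)[[1]]
  ctx <- pedvanc:::subject_context(pop1, sub)
  m <- pedvanc:::map_mode(ctx)
  lap <- pedvanc:::laplace_subject(ctx, m$par)
  gr <- seq(-1.4, 1.4, length.out = 241)
  h <- gr[2] - gr[1]
  n <- nrow(sub$obs)
  lj <- outer(gr, gr, Vectorize(function(e1, e2) {
    -0.5 * (pedvanc:::map_objective(ctx, c(e1, e2)) + n * log(2 * pi) +
              sum(log(2 * pi * ctx$prior_sd^2)))
  }))
  integral <- -2 * (log(sum(exp(lj - max(lj)))) + max(lj) + 2 * log(h))
  # the Laplace approximation is exact only for a Gaussian posterior;
  # on this mildly skewed posterior it agrees to a fraction of a percent
  expect_equal(lap, integral, tolerance = 0.01)
})

test_that("objective is lower at the generating parameters than far away", {
  ds <- make_tdm(n = 50, seed = 23)
  wrong <- pop_with(tvcl = 2 * tab2$tvcl)
  expect_lt(foce_objective(tab2, ds), foce_objective(wrong, ds))
})

test_that("objective is additive, order-invariant and origin-invariant", {
  ds <- make_tdm(n = 10, seed = 24)
  o1 <- foce_objective(tab2, ds)
  # duplicating every subject doubles the objective
  dup <- as.data.frame(ds)
  dup2 <- dup; dup2$ID <- dup2$ID + 1000
  both <- as_tdm_dataset(rbind(dup, dup2))
  expect_equal(foce_objective(tab2, both), 2 * o1, tolerance = 1e-6)
  # permuting subject blocks changes nothing
  perm <- do.call(rbind, lapply(rev(unique(dup$ID)),
                                function(i) dup[dup$ID == i, ]))
  expect_equal(foce_objective(tab2, as_tdm_dataset(perm)), o1,
               tolerance = 1e-8)
  # shifting the time origin of doses and samples together changes nothing
  shift <- dup; shift$TIME <- shift$TIME + 13
  expect_equal(foce_objective(tab2, as_tdm_dataset(shift)), o1,
               tolerance = 1e-6)
})

test_that("with every parameter fixed the fit returns the initial values", {
  ds <- make_tdm(n = 6, seed = 25)
  fit <- fit_population(ds, init = tab2, fixed = pedvanc:::fit_par_names)
  expect_equal(fit$estimates, tab2)
  expect_equal(fit$objective, foce_objective(tab2, ds), tolerance = 1e-8)
  expect_true(fit$converged)
  expect_error(fit_population(ds, fixed = "nonsense"), "unknown parameter")
})

test_that("a one-parameter fit moves toward the generating clearance", {
  ds <- make_tdm(n = 40, seed = 26)
  init <- pop_with(tvcl = tab2$tvcl * 1.8)
  fit <- fit_population(ds, init = init,
                        fixed = setdiff(pedvanc:::fit_par_names, "tvcl"))
  expect_lt(abs(fit$estimates$tvcl / tab2$tvcl - 1), 0.15)
  expect_lt(fit$objective, foce_objective(init, ds))
})

test_that("identity resampling reproduces the point fit", {
  ds <- make_tdm(n = 10, seed = 27)
  fx <- setdiff(pedvanc:::fit_par_names, "tvcl")
  bt <- bootstrap_population(ds, n_reps = 1, seed = 1, init = tab2,
                             fixed = fx, resample = function(ids) ids)
  expect_equal(bt$table$median, bt$table$estimate, tolerance = 1e-3)
  expect_equal(bt$n_fail, 0L)
})

test_that("bootstrap intervals widen with sparser sampling", {
  rich <- make_tdm(n = 14, seed = 28)
  fx <- setdiff(pedvanc:::fit_par_names, "tvcl")
  # sparse: keep one observation per subject
  sp <- as.data.frame(rich)
  keep <- !duplicated(paste(sp$ID, sp$EVID)) | sp$EVID == 1
  sparse <- as_tdm_dataset(sp[sp$EVID == 1 | keep, ])
  b_rich <- bootstrap_population(rich, n_reps = 10, seed = 2, init = tab2,
                                 fixed = fx)
  b_sparse <- bootstrap_population(sparse, n_reps = 10, seed = 2,
                                   init = tab2, fixed = fx)
  w_rich <- b_rich$table$hi - b_rich$table$lo
  w_sparse <- b_sparse$table$hi - b_sparse$table$lo
  expect_gt(w_sparse, w_rich)
})
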