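# Virtual cohort generation and synthetic TDM datasets.

test_that("cohort sampling is deterministic and respects the bands", {
  sp <- subgroup_spec("infants", 0.25, 1, 10, 30, n = 500)
  a <- sample_cohort(sp, seed = 42)
  b <- sample_cohort(sp, seed = 42)
  expect_identical(a, b)
  expect_false(identical(a, sample_cohort(sp, seed = 43)))
  expect_true(all(a$age >= 0.25 & a$age <= 1))
  expect_true(all(a$scr >= 10 & a$scr <= 30))
  expect_true(all(a$wt > 0))
  expect_equal(a$pma, pma_from_age(a$age))
  expect_equal(nrow(sample_cohort(subgroup_spec("x", 1, 2, 10, 20, n = 0),
                                  1)), 0)
})

test_that("sample means converge to band midpoints", {
  sp <- subgroup_spec("infants", 0.25, 1, 10, 30, n = 10000)
  co <- sample_cohort(sp, seed = 7)
  expect_equal(mean(co$age), 0.625, tolerance = 0.02)
  expect_equal(mean(co$scr), 20, tolerance = 0.02)
})

test_that("median weight curve is increasing in age and plausible", {
  age <- seq(0.25, 18, by = 0.05)
  w <- weight_for_age(age)
  expect_true(all(diff(w) > 0))
  expect_equal(weight_for_age(6.8), 22.9, tolerance = 0.05) # cohort median
  # user-supplied curve overrides the packaged one
  w2 <- weight_for_age(2, curve = data.frame(a = c(1, 3), w = c(10, 14)))
  expect_equal(w2, 12)
})

test_that("nine default subgroups mirror the dosing-table design", {
  sg <- default_subgroups()
  expect_length(sg, 9)
  expect_equal(sg[[1]]$age_min, 0.25)
  expect_equal(sg[[1]]$scr_max, 30)
  expect_equal(sg[[9]]$age_max, 18)
  expect_equal(sg[[9]]$scr_min, 80)
  expect_true(all(vapply(sg, function(s) s$n, integer(1)) == 1000L))
})

test_that("noise-free synthesis reproduces the typical prediction", {
  pop0 <- pop_novar()
  co <- sample_cohort(subgroup_spec("x", 2, 6, 20, 40, n = 4), 3)
  ds <- synthesize_tdm(pop0, co, default_regimen_policy(15),
                       function(reg) c(2, 7, 23), seed = 5, lloq = 0)
  obs <- ds[ds$EVID == 0, ]
  for (i in unique(obs$ID)) {
    sub <- subject_data(ds, i)
    typ <- typical_params(pop0, sub$cov)
    expect_equal(sub$obs$dv, concentration(typ, sub$reg, sub$obs$time),
                 tolerance = 1e-6)
  }
})

test_that("residual error magnitude is recovered from large samples", {
  co <- sample_cohort(subgroup_spec("x", 2, 10, 20, 40, n = 2500), 11)
  ds <- synthesize_tdm(tab2, co, default_regimen_policy(15),
                       function(reg) c(3, 11.5, 22, 27), seed = 12,
                       lloq = 0)
  obs <- ds[ds$EVID == 0, ]
  ratio <- vapply(unique(obs$ID), function(i) {
    sub <- subject_data(ds, i)
    tr <- attr(ds, "truth")[[match(i, unique(ds$ID))]]
    ind <- individual_params(cl = tr$cl, v1 = tr$v1,
                             q = typical_params(tab2, sub$cov)$q,
                             v2 = typical_params(tab2, sub$cov)$v2)
    f <- concentration(ind, sub$reg, sub$obs$time)
    sub$obs$dv / f
  }, numeric(4))
  expect_equal(stats::sd(ratio - 1), tab2$sigma_prop, tolerance = 0.05)
})

test_that("below-quantification records are dropped and counted", {
  pop0 <- pop_novar()
  co <- sample_cohort(subgroup_spec("x", 2, 6, 20, 40, n = 5), 3)
  # a sample far in the washout tail falls below any realistic LLOQ
  ds <- synthesize_tdm(pop0, co, default_regimen_policy(15),
                       function(reg) c(6, 500), seed = 5, lloq = 2)
  expect_equal(attr(ds, "n_blq"), 5L)
  expect_equal(sum(ds$EVID == 0), 5L)
})

test_that("sampling times before the first dose are excluded with a count", {
  pop0 <- pop_novar()
  co <- sample_cohort(subgroup_spec("x", 2, 6, 20, 40, n = 3), 3)
  pol <- function(cov) regimen(time = c(10, 16), amt = 200, dur = 1,
                               horizon = 40)
  ds <- synthesize_tdm(pop0, co, pol, function(reg) c(5, 12, 20), seed = 2,
                       lloq = 0)
  expect_equal(attr(ds, "n_excluded"), 3L)
  expect_true(all(ds$TIME[ds$EVID == 0] >= 10))
})

test_that("dataset generation is fully reproducible under a seed", {
  co <- sample_cohort(subgroup_spec("x", 1, 8, 15, 50, n = 10), 21)
  d1 <- synthesize_tdm(tab2, co, seed = 31)
  d2 <- synthesize_tdm(tab2, co, seed = 31)
  expect_identical(as.data.frame(d1), as.data.frame(d2))
})

test_that("default sampling policy draws a median of three samples", {
  set.seed(99)
  pol <- default_sampling_policy()
  reg <- q6h_regimen(200)
  n <- replicate(4000, length(pol(reg)))
  expect_equal(stats::median(n), 3)
  expect_true(all(n >= 1 & n <= 6))
})
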