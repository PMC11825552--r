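test_that("without random effects CWRES collapses to the weighted residual", {
  model <- txa_final_model(iiv = character(0))
  truth <- param_set(c(v1 = 12.77, v2 = 6.857, cl1 = 3.263, cl2 = 2.859),
                     beta = c(bw_on_v1 = 0.911, clcr_on_cl1 = 0.752),
                     omega2 = numeric(), sigma = c(add = 1, prop = 0.15))
  ds <- simulate_dataset(cohort_design(n = 8), truth, seed = 71, model = model)
  fit <- evaluate_model(ds, model, truth)
  d <- gof_diagnostics(fit)
  expect_equal(d$cwres, (d$dv - d$pred) / residual_sd(d$pred, truth$sigma),
               tolerance = 1e-10)
  expect_equal(d$ipred, d$pred, tolerance = 1e-12)
})

test_that("IPRED equals PRED when the conditional modes are zero", {
  # vanishing IIV pins every eta-hat at zero
  truth0 <- txa_truth(omega2 = c(cl1 = 1e-14, v1 = 1e-14))
  ds <- simulate_dataset(cohort_design(n = 6), txa_truth(), seed = 72)
  fit <- evaluate_model(ds, txa_final_model(), truth0)
  d <- gof_diagnostics(fit)
  expect_true(all(fit$eta == 0))
  expect_equal(d$ipred, d$pred, tolerance = 1e-12)
})

test_that("CWRES of the generating model are standardized and near-normal", {
  ds <- simulate_dataset(cohort_design(), txa_truth(), seed = 73)
  expect_gte(n_observations(ds), 400)
  fit <- evaluate_model(ds, txa_final_model(), txa_truth())
  d <- gof_diagnostics(fit)
  expect_lt(abs(mean(d$cwres)), 0.1)
  expect_gt(sd(d$cwres), 0.85)
  expect_lt(sd(d$cwres), 1.15)
  expect_lt(abs(sample_skewness(d$cwres)), 0.5)
})

test_that("the VPC is deterministic given a seed and degenerates with the variances", {
  tp <- toy_problem(81, n = 6)
  fit <- evaluate_model(tp$ds, tp$model, tp$truth)
  v1 <- vpc(fit, n_replicates = 40, seed = 5)
  v2 <- vpc(fit, n_replicates = 40, seed = 5)
  expect_identical(v1$bins, v2$bins)
  expect_identical(v1$coverage, v2$coverage)

  # variances -> 0 on a cohort of identical median patients: every
  # replicate is the same deterministic profile and the band width -> 0
  des0 <- cohort_design(n = 6, p_male = 1, bw = rep(61.4, 3),
                        height = rep(161.8, 3), scr = rep(85.7, 3),
                        age = c(69, 69, 69, 26, 84), cpb_min = rep(170, 3),
                        jitter_sd = 0)
  degenerate <- param_set(tp$truth$theta, beta = tp$truth$beta,
                          omega2 = c(cl1 = 0), sigma = c(add = 1e-8, prop = 0))
  ds0 <- simulate_dataset(des0, degenerate,
                          model = txa_final_model(iiv = "cl1"), seed = 5)
  fit0 <- evaluate_model(ds0, txa_final_model(iiv = "cl1"), degenerate)
  v0 <- vpc(fit0, n_replicates = 20, seed = 5)
  expect_lt(max(v0$bins$sim_hi - v0$bins$sim_lo), 1e-6)
})

test_that("bootstrap on identical clones returns a zero-width interval", {
  one <- minimal_table()
  one <- rbind(one, data.frame(ID = 1, TIME = c(2, 4, 8), AMT = NA,
                               DV = c(30, 16, 5), EVID = 0L, MDV = 0L,
                               BW = 60, HT = 165, AGE = 60, SEX = 0, SCR = 80))
  one <- one[order(one$TIME, -one$EVID), ]
  clones <- do.call(rbind, lapply(1:6, function(i) { b <- one; b$ID <- i; b }))
  ds <- pop_dataset(clones)
  model <- pop_model(1, iiv = character(0), effects = list(),
                     error = "additive")
  fit <- fit_population(ds, model, control = fast_ctrl)
  bs <- bootstrap_model(fit, n_replicates = 8, seed = 9)
  expect_equal(bs$n_success, 8)
  expect_lt(max(bs$summary$upper97.5 - bs$summary$lower2.5), 1e-6)
  expect_equal(bs$summary$median, unname(coef(fit)), tolerance = 1e-4,
               ignore_attr = TRUE)

  # determinism contract
  bs2 <- bootstrap_model(fit, n_replicates = 8, seed = 9)
  expect_identical(bs$summary, bs2$summary)
})

test_that("bootstrap medians track the generating value on a synthetic cohort", {
  ds <- simulate_dataset(cohort_design(n = 30), txa_truth(), seed = 91)
  fit <- fit_population(ds, txa_final_model(), control = fast_ctrl)
  bs <- bootstrap_model(fit, n_replicates = 30, seed = 10)
  expect_gte(bs$n_success, 15)
  expect_equal(bs$summary["v1", "median"], 12.77, tolerance = 0.15)
  expect_equal(bs$summary["cl1", "median"], 3.263, tolerance = 0.15)
  # percentile ordering invariant
  expect_true(all(bs$summary$lower2.5 <= bs$summary$median + 1e-12))
  expect_true(all(bs$summary$median <= bs$summary$upper97.5 + 1e-12))
})
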