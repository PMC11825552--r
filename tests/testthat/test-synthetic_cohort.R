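test_that("covariate distributions calibrate to the cohort targets", {
  cov <- sample_covariates(cohort_design(n = 10000), seed = 2)
  expect_gt(median(cov$bw), 59); expect_lt(median(cov$bw), 64)
  expect_gt(median(cov$clcr), 55); expect_lt(median(cov$clcr), 67)
  expect_equal(median(cov$height), 161.8, tolerance = 0.05)
  expect_equal(median(cov$scr), 85.7, tolerance = 0.05)
  expect_equal(median(cov$age), 69, tolerance = 0.05)
  expect_true(all(cov$age >= 26 & cov$age <= 84))
  expect_equal(mean(cov$sex == 0), 51 / 77, tolerance = 0.05)
  # inconsistent quantile targets are rejected
  expect_error(cohort_design(bw = c(50, 54.6, 75.2)), "median")
})

test_that("a zero-variance single-subject design is the deterministic median patient", {
  des <- cohort_design(n = 1, p_male = 1,
                       bw = c(61.4, 61.4, 61.4), height = rep(161.8, 3),
                       scr = rep(85.7, 3), age = c(69, 69, 69, 26, 84),
                       cpb_min = rep(170, 3), jitter_sd = 0)
  cov <- sample_covariates(des, seed = 1)
  expect_equal(cov$bw, 61.4)
  expect_equal(cov$scr, 85.7)
  ev <- build_design_events(cov, des, seed = 1)[[1]]
  expect_equal(ev$doses$time, c(0, 170 / 60), tolerance = 1e-12)
})

test_that("dose-1 samples at or after re-dosing are dropped", {
  des <- cohort_design(n = 1, jitter_sd = 0)
  cov <- sample_covariates(des, seed = 3)
  # CPB 170 min: dose 2 at 2.833 h, the 5-h draw is dropped -> 6 samples
  ev <- build_design_events(cov, des, cpb_min = 170)[[1]]
  expect_equal(ev$doses$time[2], 2.833, tolerance = 1e-3)
  expect_length(ev$times, 6)
  expect_equal(ev$occ, c(1, 2, 3, 5, 6, 7))
  # CPB 360 min: dose 2 at 6 h > 5 h, all 7 retained
  ev2 <- build_design_events(cov, des, cpb_min = 360)[[1]]
  expect_length(ev2$times, 7)
})

test_that("the default 77-subject design yields a realistic observation count and range", {
  ds <- simulate_dataset(cohort_design(), txa_truth(), seed = 1)
  expect_equal(n_subjects(ds), 77)
  n <- n_observations(ds)
  expect_gte(n, 400); expect_lte(n, 539)
  dv <- ds$data$DV[ds$data$EVID == 0]
  expect_true(all(dv > 0))
  # pooled concentrations on the order of the observed study ranges
  expect_gt(mean(dv >= 1 & dv <= 140), 0.95)
  expect_lt(quantile(dv, 0.99), 160)
})

test_that("simulation is reproducible and variance-free truth gives noiseless data", {
  d1 <- simulate_dataset(cohort_design(n = 5), txa_truth(), seed = 12)
  d2 <- simulate_dataset(cohort_design(n = 5), txa_truth(), seed = 12)
  expect_identical(d1$data, d2$data)

  model0 <- txa_final_model(iiv = character(0))
  truth0 <- param_set(txa_truth()$theta, beta = txa_truth()$beta,
                      omega2 = numeric(), sigma = c(add = 1e-9, prop = 0))
  d0 <- simulate_dataset(cohort_design(n = 3), truth0, seed = 13,
                         model = model0)
  s <- subject_records(d0)[[1]]
  typ <- apply_covariates(truth0$theta, model0$effects, s$covariates)
  expect_equal(s$obs$dv, predict_conc(s$obs$time, s$doses, typ, 2),
               tolerance = 1e-6)
})
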