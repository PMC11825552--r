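test_that("macro-constant identities hold for random positive parameters", {
  set.seed(101)
  for (i in 1:50) {
    p <- pk_params(v1 = runif(1, 1, 50), cl1 = runif(1, 0.2, 20),
                   v2 = runif(1, 1, 50), cl2 = runif(1, 0.2, 20))
    m <- macro_constants(p)
    expect_equal(m$coefA + m$coefB, 1, tolerance = 1e-12)
    expect_equal(m$alpha * m$beta, m$k10 * m$k21, tolerance = 1e-12)
    expect_equal(m$alpha + m$beta, m$k10 + m$k12 + m$k21, tolerance = 1e-12)
    expect_true(m$alpha >= m$beta && m$beta > 0)
  }
})

test_that("the final covariate model reproduces the published worked example", {
  truth <- txa_truth()
  model <- txa_final_model()
  eff <- model$effects
  cl1 <- apply_covariates(truth$theta, eff, list(bw = 61.4, clcr = 60))[["cl1"]]
  expect_equal(cl1, 3.223, tolerance = 2e-4)          # 3.223 L/h
  expect_equal(cl1 * 1000 / 60, 53.72, tolerance = 2e-3)  # 53.72 mL/min
  # covariates at their references leave the typical values unchanged
  at_ref <- apply_covariates(truth$theta, eff, list(bw = 61.4, clcr = 61.0))
  expect_equal(at_ref[["v1"]], 12.77)
  expect_equal(at_ref[["cl1"]], 3.263)
  # exponent 0 removes the effect
  e0 <- list(cov_effect("cl1", "clcr", ref = 61, exponent = 0))
  expect_equal(apply_covariates(truth$theta, e0, list(clcr = 15))[["cl1"]], 3.263)
  expect_error(apply_covariates(truth$theta, eff, list(bw = 61.4)), "clcr")
})

test_that("individualize implements the log-normal random-effect model", {
  typ <- pk_params(v1 = 12.77, cl1 = 3.263, v2 = 6.857, cl2 = 2.859)
  expect_equal(individualize(typ, c(cl1 = 0, v1 = 0)), typ)
  expect_equal(individualize(typ, c(cl1 = log(2)))[["cl1"]], 2 * 3.263)
  # geometric mean of individual parameters converges to the typical value
  set.seed(7)
  eta <- rnorm(20000, 0, 0.3)
  gm <- exp(mean(log(typ[["cl1"]] * exp(eta))))
  expect_equal(gm, typ[["cl1"]], tolerance = 0.01)
})

test_that("bolus predictions obey limits, superposition and model collapse", {
  p <- pk_params(v1 = 12.77, cl1 = 3.263, v2 = 6.857, cl2 = 2.859)
  d1000 <- data.frame(time = 0, amt = 1000)
  # t -> 0+ limit equals dose / V1 since coefA + coefB = 1
  expect_equal(predict_conc(1e-9, d1000, p), 1000 / 12.77, tolerance = 1e-6)
  # before the first dose the prediction is zero, not an error
  expect_equal(predict_conc(c(0, 0.5), data.frame(time = 1, amt = 1000), p),
               c(0, 0))
  # cl2 = 0 collapses the two-compartment model onto the one-compartment one
  p0 <- pk_params(v1 = 12.77, cl1 = 3.263, v2 = 6.857, cl2 = 1e-300)
  tt <- c(0.25, 1, 4, 12)
  expect_equal(predict_conc(tt, d1000, p0, 2), predict_conc(tt, d1000, p, 1),
               tolerance = 1e-9)
  # superposition: two 500-mg doses at the same instant = one 1000-mg dose
  d2x500 <- data.frame(time = c(0, 0), amt = c(500, 500))
  expect_equal(predict_conc(tt, d2x500, p), predict_conc(tt, d1000, p),
               tolerance = 1e-12)
  # linearity in dose amount
  d2000 <- data.frame(time = 0, amt = 2000)
  expect_equal(predict_conc(tt, d2000, p), 2 * predict_conc(tt, d1000, p),
               tolerance = 1e-12)
})

test_that("closed-form predictions agree with ODE integration to 1e-6 relative", {
  skip_if_not_installed("deSolve")
  p <- pk_params(v1 = 12.77, cl1 = 3.263, v2 = 6.857, cl2 = 2.859)
  doses <- data.frame(time = c(0, 2.833), amt = c(1000, 1000))
  tt <- c(0.5, 1, 2, 2.5, 3.833, 8.833, 18.833)
  cf <- predict_conc(tt, doses, p)
  ode <- ode_conc(tt, doses, p)
  expect_equal(cf, as.numeric(ode), tolerance = 1e-6)
  expect_gt(cf[1], cf[3])  # decline between doses after distribution
})

test_that("single-bolus AUC equals dose / CL1 (mass balance)", {
  p <- pk_params(v1 = 12.77, cl1 = 3.263, v2 = 6.857, cl2 = 2.859)
  d <- data.frame(time = 0, amt = 1000)
  auc <- stats::integrate(function(t) predict_conc(t, d, p), 0, Inf,
                          rel.tol = 1e-10)$value
  expect_equal(auc, 1000 / 3.263, tolerance = 1e-6)
})

test_that("near-degenerate hybrid roots stay finite and match the collapse limit", {
  # cl2 chosen so alpha ~ beta triggers the repeated-root branch
  v1 <- 10; cl1 <- 2.5; cl2 <- 1e-22
  p <- pk_params(v1 = v1, cl1 = cl1, v2 = cl2 * v1 / cl1, cl2 = cl2)
  tt <- c(0.5, 2, 8)
  pred <- predict_conc(tt, data.frame(time = 0, amt = 1000), p)
  expect_true(all(is.finite(pred)))
  mono <- (1000 / v1) * exp(-cl1 / v1 * tt)
  expect_equal(pred, mono, tolerance = 1e-6)
})
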