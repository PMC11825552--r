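test_that("combined residual SD follows sqrt(sigma1^2 + (Cpred sigma2)^2)", {
  expect_equal(residual_sd(0, c(add = 1, prop = 0.15)), 1)
  expect_equal(residual_sd(250, c(add = 1, prop = 0)), 1)
  expect_equal(residual_sd(100, c(add = 1, prop = 0.15)), sqrt(1 + 225))
  expect_equal(residual_sd(100, c(add = 1, prop = 0.15)), 15.033, tolerance = 1e-4)
  expect_error(residual_sd(10, c(add = 0, prop = 0.1)), "sigma1")
  expect_error(residual_sd(-1, c(add = 1, prop = 0.1)), "cpred")
})

test_that("the subject joint objective matches a hand-expanded toy case", {
  model <- pop_model(1, iiv = "cl1", effects = list())
  params <- param_set(c(v1 = 10, cl1 = 2), omega2 = c(cl1 = 0.09),
                      sigma = c(add = 1, prop = 0.1))
  s <- list(id = 1, covariates = list(),
            doses = data.frame(time = 0, amt = 1000),
            obs = data.frame(time = 2, dv = 60))
  eta <- 0.2
  f <- (1000 / 10) * exp(-(2 * exp(eta) / 10) * 2)
  v <- 1 + (0.1 * f)^2
  by_hand <- (60 - f)^2 / v + log(v) + eta^2 / 0.09 + log(0.09)
  expect_equal(subject_objective(s, model, params, eta), by_hand,
               tolerance = 1e-12)

  # zero observations leave only the eta penalty
  s0 <- s
  s0$obs <- s0$obs[0, ]
  expect_equal(subject_objective(s0, model, params, eta),
               eta^2 / 0.09 + log(0.09), tolerance = 1e-12)

  # eta = 0 and an exact observation leave only the log-variance terms
  s1 <- s
  f0 <- (1000 / 10) * exp(-0.4)
  s1$obs$dv <- f0
  v0 <- 1 + (0.1 * f0)^2
  expect_equal(subject_objective(s1, model, params, 0), log(v0) + log(0.09),
               tolerance = 1e-12)
})

test_that("with omega^2 = 0 the OFV is the fixed-effect weighted deviance", {
  tp <- toy_problem(3, n = 4, iiv = "cl1")
  model0 <- txa_final_model(iiv = "cl1")
  params0 <- param_set(tp$truth$theta, beta = tp$truth$beta,
                       omega2 = c(cl1 = 0), sigma = tp$truth$sigma)
  o <- ofv(tp$ds, model0, params0)
  direct <- sum(vapply(subject_records(tp$ds), function(s) {
    typ <- apply_covariates(tp$truth$theta, model0$effects, s$covariates)
    f <- predict_conc(s$obs$time, s$doses, typ, 2)
    v <- residual_sd(f, tp$truth$sigma)^2
    sum((s$obs$dv - f)^2 / v + log(v) + log(2 * pi))
  }, numeric(1)))
  expect_equal(o, direct, tolerance = 1e-10)
})

test_that("OFV is additive over subjects", {
  tp <- toy_problem(4, n = 3)
  o1 <- ofv(tp$ds, tp$model, tp$truth)
  df <- tp$ds$data
  df2 <- df
  df2$ID <- df2$ID + 100
  dup <- pop_dataset(rbind(df, df2))
  expect_equal(ofv(dup, tp$model, tp$truth), 2 * o1, tolerance = 1e-8)
})

test_that("FOCE OFV agrees with adaptive Gauss-Hermite quadrature", {
  skip_if_not_installed("pracma")
  # one random effect
  tp1 <- toy_problem(11, n = 5, iiv = "cl1")
  expect_lt(abs(ofv(tp1$ds, tp1$model, tp1$truth) -
                  agq_ofv(tp1$ds, tp1$model, tp1$truth)), 0.5)
  # two random effects
  tp2 <- toy_problem(12, n = 5, iiv = c("cl1", "v1"))
  expect_lt(abs(ofv(tp2$ds, tp2$model, tp2$truth) -
                  agq_ofv(tp2$ds, tp2$model, tp2$truth, n_nodes = 11)), 0.5)
  # single sparse subject, single eta: tight agreement
  tr3 <- txa_truth(omega2 = c(cl1 = 0.09))
  m3 <- txa_final_model(iiv = "cl1")
  ds3 <- simulate_dataset(cohort_design(n = 1, offsets1 = 1, offsets2 = 6),
                          tr3, seed = 13, model = m3)
  expect_lt(abs(ofv(ds3, m3, tr3) - agq_ofv(ds3, m3, tr3)), 0.1)
})

test_that("likelihood-ratio bookkeeping matches the chi-squared rule", {
  r <- lrt(3492.0236, 3382.4731, df = 1)
  expect_equal(r$delta_ofv, -109.5505, tolerance = 1e-4)
  expect_equal(round(r$threshold, 3), 6.635)
  expect_true(r$significant)
  expect_false(lrt(100, 94, df = 1)$significant)   # drop of 6.0 < 6.635
  # antisymmetry of the OFV difference
  expect_equal(lrt(3382.4731, 3492.0236, df = 1)$delta_ofv, 109.5505,
               tolerance = 1e-4)
  expect_error(lrt(10, 5, df = 0), "df")
})

test_that("noise-free data recover the generating fixed effects within 1%", {
  model <- txa_final_model(iiv = character(0))
  truth <- param_set(c(v1 = 12.77, v2 = 6.857, cl1 = 3.263, cl2 = 2.859),
                     beta = c(bw_on_v1 = 0.911, clcr_on_cl1 = 0.752),
                     omega2 = numeric(), sigma = c(add = 0.05, prop = 0))
  ds <- simulate_dataset(cohort_design(n = 10), truth, seed = 21,
                         model = model)
  fit_model <- pop_model(2, iiv = character(0), effects = model$effects,
                         error = "additive")
  fit <- fit_population(ds, fit_model, control = fast_ctrl)
  expect_true(fit$convergence$converged)
  est <- fit$params$theta
  expect_equal(unname(est[c("v1", "cl1", "v2", "cl2")]),
               c(12.77, 3.263, 6.857, 2.859), tolerance = 0.01)
  expect_equal(unname(fit$params$beta), unname(truth$beta), tolerance = 0.02)

  # refitting from the optimum is a fixed point
  refit <- fit_population(ds, fit_model, inits = fit$params,
                          control = fast_ctrl)
  expect_lt(abs(refit$ofv - fit$ofv), 0.01)
})

test_that("estimates are invariant to subject relabeling and time-unit rescaling", {
  tight <- fit_control(se = FALSE, outer_rel_tol = 1e-10)
  ds <- simulate_dataset(cohort_design(n = 14), txa_truth(), seed = 31)
  model <- txa_final_model()
  fit <- fit_population(ds, model, control = tight)

  # relabel: reverse the subject order
  df <- ds$data
  df$ID <- max(df$ID) + 1 - df$ID
  df <- df[order(df$ID, df$TIME, -df$EVID), ]
  fit_r <- fit_population(pop_dataset(df), model, control = tight)
  expect_equal(coef(fit_r), coef(fit), tolerance = 1e-4)

  # rescale time to minutes; clearances scale by 1/60, volumes unchanged
  dfm <- ds$data
  dfm$TIME <- dfm$TIME * 60
  init_m <- fit$params
  init_m$theta[c("cl1", "cl2")] <- init_m$theta[c("cl1", "cl2")] / 60
  fit_m <- fit_population(pop_dataset(dfm), model, inits = init_m,
                          control = tight)
  expect_equal(unname(fit_m$params$theta[c("cl1", "cl2")] * 60),
               unname(fit$params$theta[c("cl1", "cl2")]), tolerance = 1e-4)
  expect_equal(unname(fit_m$params$theta[c("v1", "v2")]),
               unname(fit$params$theta[c("v1", "v2")]), tolerance = 1e-4)
})

test_that("standard errors report %RSE = 100 SE / estimate", {
  tp <- toy_problem(41, n = 10)
  fit <- fit_population(tp$ds, tp$model, control = fit_control(se = TRUE))
  expect_true(any(is.finite(fit$se)))
  fin <- is.finite(fit$se)
  expect_equal(fit$rse[fin], 100 * fit$se[fin] / abs(coef(fit)[fin]),
               tolerance = 1e-10)
})
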