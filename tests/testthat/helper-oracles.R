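# Independent oracles used to check the engine:
#  - agq_ofv(): exact -2 log marginal likelihood by adaptive Gauss-Hermite
#    quadrature over the random effects (pracma nodes), built only from the
#    exported structural/error-model primitives.
#  - ode_conc(): two-compartment bolus concentrations by numerical ODE
#    integration (deSolve), independent of the closed-form solution.

oracle_fd_hessian <- function(fn, x, h = 1e-4) {
  p <- length(x)
  H <- matrix(NA_real_, p, p)
  f0 <- fn(x)
  for (i in seq_len(p)) for (j in i:p) {
    if (i == j) {
      xp <- x; xp[i] <- x[i] + h; xm <- x; xm[i] <- x[i] - h
      H[i, i] <- (fn(xp) - 2 * f0 + fn(xm)) / h^2
    } else {
      xpp <- x; xpp[c(i, j)] <- x[c(i, j)] + h
      xpm <- x; xpm[i] <- x[i] + h; xpm[j] <- x[j] - h
      xmp <- x; xmp[i] <- x[i] - h; xmp[j] <- x[j] + h
      xmm <- x; xmm[c(i, j)] <- x[c(i, j)] - h
      H[i, j] <- H[j, i] <- (fn(xpp) - fn(xpm) - fn(xmp) + fn(xmm)) / (4 * h^2)
    }
  }
  H
}

# -2 log of one subject's marginal likelihood, by adaptive GH quadrature
agq_subject <- function(s, model, params, n_nodes = 15) {
  stopifnot(requireNamespace("pracma", quietly = TRUE))
  iiv <- model$iiv
  d <- length(iiv)
  effects <- lapply(model$effects, function(e) {
    e$exponent <- params$beta[[paste0(e$covariate, "_on_", e$param)]]
    e
  })
  full <- c(v1 = NA_real_, v2 = 1, cl1 = NA_real_, cl2 = 0)
  full[names(params$theta)] <- params$theta
  typ <- apply_covariates(full, effects, s$covariates)
  om <- as.numeric(params$omega2[iiv])
  # -log joint density of (y, eta), all constants included
  nlj <- function(eta) {
    p <- individualize(typ, stats::setNames(eta, iiv))
    f <- predict_conc(s$obs$time, s$doses, p, model$n_compartments)
    v <- residual_sd(f, params$sigma)^2
    0.5 * (sum((s$obs$dv - f)^2 / v + log(2 * pi * v)) +
             sum(eta^2 / om + log(2 * pi * om)))
  }
  mode <- stats::nlminb(rep(0, d), nlj)$par
  H <- oracle_fd_hessian(nlj, mode, h = 1e-4)
  C <- t(chol(solve(H)))                       # covariance factor
  gh <- pracma::gaussHermite(n_nodes)
  if (d == 1) {
    z <- matrix(gh$x, ncol = 1)
    w <- gh$w
  } else {
    grid <- expand.grid(seq_len(n_nodes), seq_len(n_nodes))
    z <- cbind(gh$x[grid[, 1]], gh$x[grid[, 2]])
    w <- gh$w[grid[, 1]] * gh$w[grid[, 2]]
  }
  vals <- vapply(seq_len(nrow(z)), function(k) {
    e <- mode + sqrt(2) * as.numeric(C %*% z[k, ])
    exp(sum(z[k, ]^2) - nlj(e))
  }, numeric(1))
  L <- sqrt(2)^d * det(C) * sum(w * vals)
  -2 * log(L)
}

agq_ofv <- function(ds, model, params, n_nodes = 15) {
  sum(vapply(subject_records(ds), agq_subject, numeric(1),
             model = model, params = params, n_nodes = n_nodes))
}

# ODE-integrated two-compartment bolus concentrations (amounts A1, A2)
ode_conc <- function(t, doses, p, n_compartments = 2) {
  stopifnot(requireNamespace("deSolve", quietly = TRUE))
  k10 <- p[["cl1"]] / p[["v1"]]
  k12 <- if (n_compartments == 2) p[["cl2"]] / p[["v1"]] else 0
  k21 <- if (n_compartments == 2) p[["cl2"]] / p[["v2"]] else 0
  rhs <- function(time, y, parms)
    list(c(-(k10 + k12) * y[1] + k21 * y[2], k12 * y[1] - k21 * y[2]))
  ev <- data.frame(var = "A1", time = doses$time, value = doses$amt,
                   method = "add")
  times <- sort(unique(c(0, doses$time, t)))
  out <- deSolve::lsoda(c(A1 = 0, A2 = 0), times, rhs, parms = NULL,
                        events = list(data = ev), rtol = 1e-11, atol = 1e-11)
  out[match(t, out[, "time"]), "A1"] / p[["v1"]]
}

sample_skewness <- function(x) mean((x - mean(x))^3) / stats::sd(x)^3
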