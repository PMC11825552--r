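#' Residual error standard deviation of the combined error model
#'
#' The observation model is
#' `Cobs = Cpred + eps * sqrt(1 + (Cpred * sigma2 / sigma1)^2)` with
#' `eps ~ N(0, sigma1^2)`, so the SD of an observation around its prediction
#' is `sqrt(sigma1^2 + (Cpred * sigma2)^2)`: additive at low concentrations,
#' proportional at high concentrations.
#'
#' @param cpred predicted concentration(s), mg/L, non-negative.
#' @param sigma residual SDs `c(add = sigma1, prop = sigma2)` (`sigma1` mg/L,
#'   must be positive; `sigma2` dimensionless, non-negative).
#' @return SD of the observation around `cpred`, mg/L.
#' @examples
#' residual_sd(100, c(add = 1, prop = 0.15))  # sqrt(1 + 225)
#' @export
residual_sd <- function(cpred, sigma) {
  s1 <- sigma[["add"]]
  s2 <- if ("prop" %in% names(sigma)) sigma[["prop"]] else 0
  if (!is.finite(s1) || s1 <= 0) stop("sigma1 must be positive", call. = FALSE)
  if (s2 < 0) stop("sigma2 must be non-negative", call. = FALSE)
  if (any(cpred < 0)) stop("cpred must be non-negative", call. = FALSE)
  sqrt(s1^2 + (cpred * s2)^2)
}

#' Joint -2 log density of one subject's data and random effects
#'
#' The quantity minimized over `eta` in the conditional (inner) step of the
#' FOCE algorithm:
#' \deqn{\sum_j \left[\frac{(Cobs_j - Cpred_j(\eta))^2}{sd_j^2} + \ln sd_j^2\right]
#'  + \sum_k \left[\frac{\eta_k^2}{\omega_k^2} + \ln \omega_k^2\right]}
#' where `Cpred` individualizes covariate-adjusted typical values by
#' `exp(eta)` and `sd` is [residual_sd()] at `Cpred(eta)`. Additive
#' `log(2*pi)` constants are omitted; [ofv()] includes them.
#'
#' @param subject one element of [subject_records()].
#' @param model a [pop_model()] with resolved covariate references.
#' @param params a [param_set()].
#' @param eta numeric vector of random effects, one per `model$iiv` entry
#'   (named or in `model$iiv` order).
#' @return Scalar joint -2 log density (up to constants).
#' @export
subject_objective <- function(subject, model, params, eta) {
  if (length(eta) != length(model$iiv))
    stop("eta must have one element per IIV-bearing parameter", call. = FALSE)
  eta <- setNames(as.numeric(eta), if (is.null(names(eta))) model$iiv else names(eta))
  effects <- effects_with_beta(model, params)
  full <- c(v1 = NA_real_, v2 = 1, cl1 = NA_real_, cl2 = 0)
  full[names(params$theta)] <- params$theta
  typ <- apply_covariates(full, effects, subject$covariates)
  p <- individualize(typ, eta)
  f <- predict_conc(subject$obs$time, subject$doses, p, model$n_compartments)
  if (any(!is.finite(f)))
    stop("non-finite prediction for subject ", subject$id, " at time(s) ",
         paste(subject$obs$time[!is.finite(f)], collapse = ", "), call. = FALSE)
  v <- residual_sd(f, params$sigma)^2
  om <- params$omega2[names(eta)]
  sum((subject$obs$dv - f)^2 / v + log(v)) + sum(eta^2 / om + log(om))
}

effects_with_beta <- function(model, params) {
  lapply(model$effects, function(e) {
    b <- params$beta[[effect_label(e)]]
    if (!is.null(b)) e$exponent <- b
    e
  })
}

# ---- engine internals -------------------------------------------------------

# pack a dataset + model into the flat arrays consumed by cpp_focei
build_engine <- function(ds, model) {
  subs <- subject_records(ds)
  covdf <- do.call(rbind, lapply(subs, function(s)
    as.data.frame(s$covariates[vapply(s$covariates, is.numeric, logical(1))])))
  model <- resolve_references(model, covdf)
  y <- unlist(lapply(subs, function(s) s$obs$dv), use.names = FALSE)
  obst <- unlist(lapply(subs, function(s) s$obs$time), use.names = FALSE)
  optr <- c(0L, cumsum(vapply(subs, function(s) nrow(s$obs), integer(1))))
  doset <- unlist(lapply(subs, function(s) s$doses$time), use.names = FALSE)
  dosea <- unlist(lapply(subs, function(s) s$doses$amt), use.names = FALSE)
  dptr <- c(0L, cumsum(vapply(subs, function(s) nrow(s$doses), integer(1))))
  eta_idx <- match(model$iiv, c("v1", "v2", "cl1", "cl2")) - 1L
  env <- new.env(parent = emptyenv())
  env$eta_warm <- matrix(0, nrow = length(subs), ncol = length(model$iiv))
  list(model = model, subs = subs, covdf = covdf,
       y = as.numeric(y), obst = as.numeric(obst), optr = as.integer(optr),
       doset = as.numeric(doset), dosea = as.numeric(dosea),
       dptr = as.integer(dptr), eta_idx = as.integer(eta_idx), env = env)
}

engine_eval <- function(eng, params, control, detail = FALSE,
                        warm = TRUE) {
  typ <- typical_matrix(eng$model, params, eng$covdf)
  om <- as.numeric(params$omega2[eng$model$iiv])
  active <- om > 1e-12
  start <- if (warm) eng$env$eta_warm else
    matrix(0, nrow = nrow(typ), ncol = length(om))
  res <- cpp_focei(eng$y, eng$obst, eng$optr, eng$doset, eng$dosea, eng$dptr,
                   typ, eng$eta_idx[active], om[active],
                   params$sigma[["add"]], params$sigma[["prop"]],
                   eng$model$n_compartments,
                   start[, active, drop = FALSE],
                   control$inner_gtol, control$inner_maxit, detail)
  eta <- matrix(0, nrow = nrow(typ), ncol = length(om))
  eta[, active] <- res$eta
  colnames(eta) <- eng$model$iiv
  res$eta <- eta
  if (warm && res$finite) eng$env$eta_warm <- eta
  res
}

#' FOCE-approximated objective function value (-2 log marginal likelihood)
#'
#' Sums over subjects the first-order conditional approximation with
#' interaction: the inner problem locates each subject's conditional mode
#' `eta_hat`; the model is linearized in `eta` around `eta_hat` with the
#' residual SD evaluated at the conditional prediction, giving the marginal
#' covariance `V = F Omega F' + diag(sd^2)` and
#' `OFV_i = n_i log(2 pi) + log|V| + r' V^{-1} r` with
#' `r = y - f(eta_hat) + F eta_hat`. Deterministic given its inputs.
#'
#' @param ds a `pop_dataset`.
#' @param model a [pop_model()].
#' @param params a [param_set()].
#' @param control a [fit_control()].
#' @return Scalar OFV.
#' @export
ofv <- function(ds, model, params, control = fit_control()) {
  eng <- build_engine(ds, model)
  res <- engine_eval(eng, params, control, warm = FALSE)
  if (!res$finite || !is.finite(res$ofv)) {
    bad <- which(!is.finite(res$ofv_i) | !res$inner_ok)
    stop("non-finite objective; flagged subject(s): ",
         paste(unique(ds$data$ID)[bad], collapse = ", "), call. = FALSE)
  }
  res$ofv
}

#' Estimation settings
#'
#' @param outer_iter maximum outer iterations.
#' @param outer_rel_tol relative convergence tolerance of the outer
#'   minimization over log-transformed population parameters.
#' @param inner_gtol gradient tolerance of the inner (conditional mode)
#'   Newton iteration.
#' @param inner_maxit maximum inner Newton iterations.
#' @param se compute standard errors from the inverse finite-difference
#'   Hessian of OFV/2 (adds ~2 p^2 objective evaluations).
#' @param hess_step central-difference step on the transformed scale.
#' @param penalty objective value substituted for non-finite evaluations
#'   during optimization.
#' @return A list of class `fit_control`.
#' @export
fit_control <- function(outer_iter = 500, outer_rel_tol = 1e-6,
                        inner_gtol = 1e-8, inner_maxit = 100,
                        se = TRUE, hess_step = 1e-4, penalty = 1e10) {
  structure(list(outer_iter = outer_iter, outer_rel_tol = outer_rel_tol,
                 inner_gtol = inner_gtol, inner_maxit = inner_maxit,
                 se = se, hess_step = hess_step, penalty = penalty),
            class = "fit_control")
}

# ---- parameter packing (estimation scale) -----------------------------------

pack_names <- function(model) {
  th <- structural_par_names(model$n_compartments)
  bet <- vapply(model$effects, effect_label, character(1))
  om <- if (length(model$iiv)) paste0("omega2_", model$iiv) else character()
  sig <- c("sigma_add", if (model$error == "combined") "sigma_prop")
  list(theta = th, beta = bet, omega2 = om, sigma = sig,
       all = c(th, bet, om, sig))
}

pack_params <- function(params, model) {
  pn <- pack_names(model)
  x <- c(log(params$theta[pn$theta]),
         if (length(pn$beta)) setNames(params$beta[pn$beta], pn$beta),
         if (length(model$iiv)) log(params$omega2[model$iiv]),
         log(params$sigma[["add"]]),
         if (model$error == "combined") log(params$sigma[["prop"]]))
  setNames(as.numeric(x), pn$all)
}

unpack_params <- function(x, model) {
  pn <- pack_names(model)
  theta <- exp(x[seq_along(pn$theta)])
  names(theta) <- pn$theta
  i <- length(pn$theta)
  beta <- setNames(x[i + seq_along(pn$beta)], pn$beta)
  i <- i + length(pn$beta)
  omega2 <- setNames(exp(x[i + seq_along(model$iiv)]), model$iiv)
  i <- i + length(model$iiv)
  sig_add <- exp(x[[i + 1]])
  sig_prop <- if (model$error == "combined") exp(x[[i + 2]]) else 0
  param_set(theta, beta = beta, omega2 = omega2,
            sigma = c(add = sig_add, prop = sig_prop))
}

default_inits <- function(model) {
  full <- c(v1 = 10, v2 = 10, cl1 = 5, cl2 = 5)
  theta <- full[structural_par_names(model$n_compartments)]
  beta <- setNames(vapply(model$effects, `[[`, numeric(1), "exponent"),
                   vapply(model$effects, effect_label, character(1)))
  param_set(theta, beta = beta,
            omega2 = setNames(rep(0.1, length(model$iiv)), model$iiv),
            sigma = c(add = 1, prop = if (model$error == "combined") 0.2 else 0))
}

#' Fit a population PK model by FOCE with interaction
#'
#' Minimizes [ofv()] over log-transformed typical values, `omega^2` and
#' residual SDs (covariate exponents on the natural scale) with `nlminb`,
#' warm-starting each subject's conditional mode across outer iterations.
#' Standard errors come from the inverse central-finite-difference Hessian
#' of OFV/2 on the transformed scale, propagated through the log transform;
#' `%RSE = 100 * SE / estimate`.
#'
#' @param ds a `pop_dataset`.
#' @param model a [pop_model()].
#' @param inits a [param_set()] of starting values (defaults to generic
#'   positive starts).
#' @param control a [fit_control()].
#' @return An object of class `fit_result`: `params` (estimates), `ofv`,
#'   `se`/`rse` (natural scale, `NA` when not computed), `eta` (conditional
#'   modes, subjects x effects), `convergence`, `model` (with resolved
#'   covariate references), `dataset`, `inits`, `control`.
#' @export
fit_population <- function(ds, model, inits = NULL, control = fit_control()) {
  if (is.null(inits)) inits <- default_inits(model)
  eng <- build_engine(ds, model)
  pn <- pack_names(eng$model)
  if (n_observations(ds) < length(pn$theta) + length(pn$beta))
    stop("fewer observations than fixed effects", call. = FALSE)
  obj <- function(x) {
    p <- try(unpack_params(x, eng$model), silent = TRUE)
    if (inherits(p, "try-error")) return(control$penalty)
    res <- engine_eval(eng, p, control)
    if (!res$finite || !is.finite(res$ofv)) control$penalty else res$ofv
  }
  x0 <- pack_params(inits, eng$model)
  opt <- nlminb(x0, obj,
                control = list(iter.max = control$outer_iter,
                               eval.max = 4 * control$outer_iter,
                               rel.tol = control$outer_rel_tol))
  est <- unpack_params(opt$par, eng$model)
  final <- engine_eval(eng, est, control, warm = FALSE)
  se <- rse <- setNames(rep(NA_real_, length(pn$all)), pn$all)
  if (control$se) {
    H <- fd_hessian(obj, opt$par, control$hess_step)
    cov_x <- try(solve(H / 2), silent = TRUE)
    if (!inherits(cov_x, "try-error") && all(diag(cov_x) > 0)) {
      se_x <- sqrt(diag(cov_x))
      nat <- flatten_params(est, eng$model)
      log_scale <- !names(se_x) %in% pn$beta
      se <- ifelse(log_scale, abs(nat) * se_x, se_x)
      names(se) <- pn$all
      rse <- 100 * se / abs(nat)
    }
  }
  converged <- opt$convergence == 0 && final$finite && all(final$inner_ok)
  structure(list(params = est, ofv = final$ofv, se = se, rse = rse,
                 eta = final$eta, inner_ok = final$inner_ok,
                 convergence = list(converged = converged, code = opt$convergence,
                                    message = opt$message,
                                    iterations = opt$iterations,
                                    evaluations = opt$evaluations),
                 model = eng$model, dataset = ds, inits = inits,
                 control = control, evaluated_only = FALSE),
            class = "fit_result")
}

flatten_params <- function(params, model) {
  pn <- pack_names(model)
  out <- c(params$theta[pn$theta],
           if (length(pn$beta)) setNames(params$beta[pn$beta], pn$beta),
           if (length(model$iiv)) setNames(params$omega2[model$iiv],
                                           paste0("omega2_", model$iiv)),
           sigma_add = params$sigma[["add"]],
           if (model$error == "combined") c(sigma_prop = params$sigma[["prop"]]))
  setNames(as.numeric(out), pn$all)
}

fd_hessian <- function(fn, x, h) {
  p <- length(x)
  H <- matrix(NA_real_, p, p, dimnames = list(names(x), names(x)))
  f0 <- fn(x)
  for (i in seq_len(p)) {
    for (j in i:p) {
      if (i == j) {
        xp <- x; xp[i] <- x[i] + h
        xm <- x; xm[i] <- x[i] - h
        H[i, i] <- (fn(xp) - 2 * f0 + fn(xm)) / h^2
      } else {
        xpp <- x; xpp[c(i, j)] <- x[c(i, j)] + h
        xpm <- x; xpm[i] <- x[i] + h; xpm[j] <- x[j] - h
        xmp <- x; xmp[i] <- x[i] - h; xmp[j] <- x[j] + h
        xmm <- x; xmm[c(i, j)] <- x[c(i, j)] - h
        H[i, j] <- H[j, i] <- (fn(xpp) - fn(xpm) - fn(xmp) + fn(xmm)) / (4 * h^2)
      }
    }
  }
  H
}

#' @export
coef.fit_result <- function(object, ...) flatten_params(object$params, object$model)

#' @export
print.fit_result <- function(x, ...) {
  cat("Population PK fit (FOCE with interaction)\n")
  cat("  OFV: ", format(x$ofv, digits = 10), "   converged: ",
      x$convergence$converged, "\n", sep = "")
  est <- flatten_params(x$params, x$model)
  tab <- data.frame(Estimate = signif(est, 4),
                    `RSE%` = signif(x$rse, 4), check.names = FALSE)
  print(tab)
  invisible(x)
}

#' Likelihood-ratio test between nested models
#'
#' `delta_ofv = OFV(extended) - OFV(parent)`; the extension is significant
#' when the OFV decrease exceeds the chi-squared upper quantile
#' (6.635 for 1 df at p < 0.01).
#'
#' @param parent,extended `fit_result` objects or bare OFV values; the
#'   extended model must nest the parent.
#' @param df degrees of freedom (parameter-count difference; inferred when
#'   both arguments are fits).
#' @param p_crit significance level (default 0.01).
#' @return An object of class `lrt_result` with `delta_ofv`, `df`,
#'   `threshold`, `significant`.
#' @examples
#' lrt(3492.0236, 3382.4731, df = 1)
#' @export
lrt <- function(parent, extended, df = NULL, p_crit = 0.01) {
  npar <- function(f) length(pack_names(f$model)$all)
  if (is.null(df)) {
    if (!inherits(parent, "fit_result") || !inherits(extended, "fit_result"))
      stop("df must be given when OFVs are supplied directly", call. = FALSE)
    df <- npar(extended) - npar(parent)
  }
  if (df <= 0) stop("df must be positive", call. = FALSE)
  o_p <- if (inherits(parent, "fit_result")) parent$ofv else as.numeric(parent)
  o_e <- if (inherits(extended, "fit_result")) extended$ofv else as.numeric(extended)
  delta <- o_e - o_p
  thr <- qchisq(1 - p_crit, df)
  structure(list(delta_ofv = delta, df = df, threshold = thr,
                 significant = (-delta) > thr, p_crit = p_crit),
            class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat("Likelihood-ratio test: dOFV = ", format(x$delta_ofv, digits = 7),
      ", df = ", x$df, ", threshold = ", format(x$threshold, digits = 4),
      " -> ", if (x$significant) "significant" else "not significant",
      "\n", sep = "")
  invisible(x)
}

#' Exhaustive ("shotgun") covariate search
#'
#' Fits every subset of the candidate covariate effects on top of the base
#' model (`2^k` fits, `k <= 4`). Each table row reports the OFV and the
#' change versus its parent (the same subset with the last-added effect
#' removed). The selected model is the lowest-OFV converged subset in which
#' every included effect is significant when dropped individually
#' (`OFV(S - e) - OFV(S) > threshold`); ties prefer fewer effects.
#'
#' @param ds a `pop_dataset`.
#' @param model base [pop_model()] (its `effects` must be empty).
#' @param candidates list of [cov_effect()] candidates with distinct
#'   `(parameter, covariate)` pairs, at most 4.
#' @param inits starting [param_set()] for the base model.
#' @param control a [fit_control()]; SEs are off by default here.
#' @param p_crit per-effect significance level (default 0.01; threshold
#'   6.635 at 1 df).
#' @return An object of class `covsearch_result`: `table` (one row per
#'   fitted subset), `selected_no`, `selected_model`, `selected_fit`,
#'   `fits`, `threshold`.
#' @export
shotgun_covariate_search <- function(ds, model, candidates, inits = NULL,
                                     control = fit_control(se = FALSE),
                                     p_crit = 0.01) {
  if (length(model$effects))
    stop("base model must have no covariate effects", call. = FALSE)
  k <- length(candidates)
  if (k > 4) stop("at most 4 candidate effects are supported", call. = FALSE)
  if (k) {
    keys <- vapply(candidates, effect_label, character(1))
    if (anyDuplicated(keys))
      stop("candidate (parameter, covariate) pairs must be distinct", call. = FALSE)
  }
  thr <- qchisq(1 - p_crit, 1)
  masks <- 0:(2^k - 1)
  nbits <- vapply(masks, function(m) sum(bitwAnd(m, 2^(seq_len(k) - 1)) > 0),
                  numeric(1))
  ord <- order(nbits, masks)
  masks <- masks[ord]
  subset_of <- function(m) which(bitwAnd(m, 2^(seq_len(k) - 1)) > 0)
  fits <- vector("list", length(masks))
  rows <- vector("list", length(masks))
  base_fit <- NULL
  for (i in seq_along(masks)) {
    m <- masks[i]
    incl <- subset_of(m)
    mod_i <- pop_model(model$n_compartments, iiv = model$iiv,
                       effects = candidates[incl], error = model$error)
    init_i <- if (m == 0 || is.null(base_fit)) inits else {
      p <- base_fit$params
      param_set(p$theta,
                beta = setNames(vapply(candidates[incl], `[[`, numeric(1),
                                       "exponent"),
                                vapply(candidates[incl], effect_label,
                                       character(1))),
                omega2 = p$omega2, sigma = p$sigma)
    }
    f <- try(fit_population(ds, mod_i, inits = init_i, control = control),
             silent = TRUE)
    failed <- inherits(f, "try-error") || !f$convergence$converged
    if (!inherits(f, "try-error")) fits[[i]] <- f
    if (m == 0 && !failed) base_fit <- f
    desc <- if (m == 0) "Base model" else
      paste("+", paste(vapply(candidates[incl], function(e)
        paste(e$covariate, "on", e$param), character(1)), collapse = " + "))
    rows[[i]] <- data.frame(model_no = i, mask = m, description = desc,
                            n_effects = length(incl),
                            ofv = if (failed) NA_real_ else f$ofv,
                            converged = !failed)
  }
  tab <- do.call(rbind, rows)
  # parent = subset minus its last-added (highest-index) effect
  tab$parent_no <- NA_integer_
  tab$delta_ofv <- NA_real_
  for (i in seq_len(nrow(tab))) {
    m <- tab$mask[i]
    if (m == 0) next
    top <- 2^(max(subset_of(m)) - 1)
    pi <- which(tab$mask == m - top)
    tab$parent_no[i] <- tab$model_no[pi]
    tab$delta_ofv[i] <- tab$ofv[i] - tab$ofv[pi]
  }
  tab$significant <- !is.na(tab$delta_ofv) & (-tab$delta_ofv) > thr
  # leave-one-out qualification
  qualifies <- logical(nrow(tab))
  for (i in seq_len(nrow(tab))) {
    if (!tab$converged[i]) next
    m <- tab$mask[i]
    incl <- subset_of(m)
    ok <- TRUE
    for (e in incl) {
      pi <- which(tab$mask == m - 2^(e - 1))
      if (!tab$converged[pi] || !((tab$ofv[pi] - tab$ofv[i]) > thr)) {
        ok <- FALSE; break
      }
    }
    qualifies[i] <- ok
  }
  tab$qualifies <- qualifies
  cand_rows <- which(qualifies)
  sel <- cand_rows[order(tab$ofv[cand_rows], tab$n_effects[cand_rows])][1]
  structure(list(table = tab[, c("model_no", "description", "n_effects",
                                 "ofv", "parent_no", "delta_ofv",
                                 "significant", "converged", "qualifies")],
                 selected_no = tab$model_no[sel],
                 selected_model = pop_model(model$n_compartments,
                                            iiv = model$iiv,
                                            effects = candidates[subset_of(tab$mask[sel])],
                                            error = model$error),
                 selected_fit = fits[[sel]], fits = fits, threshold = thr),
            class = "covsearch_result")
}

#' @export
print.covsearch_result <- function(x, ...) {
  cat("Shotgun covariate search (threshold ",
      format(x$threshold, digits = 4), ")\n", sep = "")
  tab <- x$table
  tab$ofv <- round(tab$ofv, 4)
  tab$delta_ofv <- round(tab$delta_ofv, 4)
  print(tab, row.names = FALSE)
  cat("Selected: model ", x$selected_no, " (",
      x$table$description[x$table$model_no == x$selected_no], ")\n", sep = "")
  invisible(x)
}
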