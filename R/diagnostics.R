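#' Evaluate a model at fixed parameters (no estimation)
#'
#' Computes the FOCE objective, conditional modes and per-observation
#' diagnostics at a given parameter set, returning a `fit_result` whose
#' estimates are the supplied parameters. Useful for diagnostics at known
#' (e.g. simulation-truth) parameters and as the basis of a VPC.
#'
#' @param ds a `pop_dataset`.
#' @param model a [pop_model()].
#' @param params a [param_set()].
#' @param control a [fit_control()].
#' @return A `fit_result` with `evaluated_only = TRUE` and no SEs.
#' @export
evaluate_model <- function(ds, model, params, control = fit_control(se = FALSE)) {
  eng <- build_engine(ds, model)
  res <- engine_eval(eng, params, control, detail = TRUE, warm = FALSE)
  pn <- pack_names(eng$model)
  na <- setNames(rep(NA_real_, length(pn$all)), pn$all)
  structure(list(params = params, ofv = res$ofv, se = na, rse = na,
                 eta = res$eta, inner_ok = res$inner_ok,
                 convergence = list(converged = res$finite && all(res$inner_ok),
                                    code = NA_integer_,
                                    message = "evaluated at fixed parameters",
                                    iterations = 0L, evaluations = 1L),
                 model = eng$model, dataset = ds, inits = params,
                 control = control, evaluated_only = TRUE,
                 detail = res[c("pred", "ipred", "yhat", "cwres")]),
            class = "fit_result")
}

#' Goodness-of-fit diagnostics (PRED, IPRED, CWRES)
#'
#' One record per non-missing observation. `pred` is the population
#' prediction (random effects at zero, covariates applied); `ipred` the
#' individual prediction at the conditional mode `eta_hat`; `cwres` the
#' conditional weighted residual: the residual about the FOCE-linearized
#' marginal mean, decorrelated by the Cholesky factor of the linearized
#' marginal covariance, so that under the correct model CWRES have mean
#' ~0 and SD ~1.
#'
#' @param fit a `fit_result` from [fit_population()] or [evaluate_model()].
#' @return A data frame: `id`, `time`, `dv`, `pred`, `ipred`, `cwres`.
#' @export
gof_diagnostics <- function(fit) {
  stopifnot(inherits(fit, "fit_result"))
  det <- fit$detail
  if (is.null(det)) {
    eng <- build_engine(fit$dataset, fit$model)
    res <- engine_eval(eng, fit$params, fit$control, detail = TRUE, warm = FALSE)
    if (!res$finite)
      stop("non-finite diagnostics; check convergence", call. = FALSE)
    det <- res[c("pred", "ipred", "yhat", "cwres")]
  }
  subs <- subject_records(fit$dataset)
  data.frame(
    id = unlist(lapply(subs, function(s) rep(s$id, nrow(s$obs)))),
    time = unlist(lapply(subs, function(s) s$obs$time)),
    dv = unlist(lapply(subs, function(s) s$obs$dv)),
    pred = det$pred, ipred = det$ipred, cwres = det$cwres)
}

#' Visual predictive check
#'
#' Simulates `n_replicates` datasets on the observed design (same subjects,
#' covariates, doses and sampling times) with fresh random effects and
#' residual errors drawn from the model, then summarizes per time bin: the
#' simulated lower/median/upper percentile band (median across replicates of
#' each replicate's bin percentiles) and the observed percentiles, and the
#' fraction of observations inside the central `level` band. Bins follow
#' the nominal sampling occasion (`OCC` column) when present, otherwise
#' time quantiles; bins with fewer than 2 observations merge with their
#' neighbor. Simulated concentrations below zero are truncated at zero
#' for percentile computation. Fixing `seed` reproduces the result exactly.
#'
#' @param fit a `fit_result` (fitted or [evaluate_model()]).
#' @param n_replicates number of simulated datasets (>= 1; >= 100 advised
#'   for reporting).
#' @param level central prediction-interval level (default 0.90).
#' @param seed integer seed for the simulation.
#' @param n_bins number of time-quantile bins when no `OCC` column exists.
#' @return An object of class `vpc_result`: `bins` (per-bin summary),
#'   `coverage` (fraction of observations inside the band), `n_replicates`,
#'   `level`, `seed`, `notes`.
#' @export
vpc <- function(fit, n_replicates = 1000, level = 0.90, seed = 1,
                n_bins = 7) {
  stopifnot(inherits(fit, "fit_result"), n_replicates >= 1)
  ds <- fit$dataset
  model <- fit$model
  params <- fit$params
  subs <- subject_records(ds)
  eng <- build_engine(ds, model)
  typ <- typical_matrix(model, params, eng$covdf)
  obs_df <- gof_skeleton(subs)
  notes <- character()

  if (!is.null(obs_df$occ)) {
    bin_id <- as.integer(factor(obs_df$occ, levels = sort(unique(obs_df$occ))))
  } else {
    br <- unique(quantile(obs_df$time, probs = seq(0, 1, length.out = n_bins + 1)))
    bin_id <- as.integer(cut(obs_df$time, br, include.lowest = TRUE))
    notes <- c(notes, "no OCC column: binned by time quantiles")
  }
  # merge sparse bins with their (lower) neighbor
  repeat {
    cnt <- table(bin_id)
    small <- as.integer(names(cnt))[cnt < 2]
    if (!length(small)) break
    tgt <- small[1]
    lev <- sort(unique(bin_id))
    nb <- if (tgt == min(lev)) lev[which(lev == tgt) + 1] else lev[which(lev == tgt) - 1]
    bin_id[bin_id == tgt] <- nb
    notes <- c(notes, paste("merged sparse bin", tgt, "into", nb))
  }
  bins <- sort(unique(bin_id))

  set.seed(seed)
  lo_p <- (1 - level) / 2
  hi_p <- 1 - lo_p
  nsub <- length(subs)
  neta <- length(model$iiv)
  om_sd <- sqrt(as.numeric(params$omega2[model$iiv]))
  qlo <- matrix(NA_real_, n_replicates, length(bins))
  qmed <- matrix(NA_real_, n_replicates, length(bins))
  qhi <- matrix(NA_real_, n_replicates, length(bins))
  for (r in seq_len(n_replicates)) {
    eta <- matrix(rnorm(nsub * neta), nsub, neta) *
      rep(om_sd, each = nsub)
    sim <- numeric(nrow(obs_df))
    pos <- 1L
    for (i in seq_len(nsub)) {
      s <- subs[[i]]
      no <- nrow(s$obs)
      if (no == 0) next
      p <- typ[i, ]
      if (neta) p[model$iiv] <- p[model$iiv] * exp(eta[i, ])
      f <- cpp_conc(s$obs$time, s$doses$time, s$doses$amt,
                    p[["v1"]], p[["v2"]], p[["cl1"]], p[["cl2"]],
                    model$n_compartments)
      sim[pos:(pos + no - 1L)] <- f + rnorm(no) * residual_sd(f, params$sigma)
      pos <- pos + no
    }
    sim <- pmax(sim, 0)
    for (b in seq_along(bins)) {
      v <- sim[bin_id == bins[b]]
      # type 6 percentiles: less tail bias than the default at bin sizes
      # of tens of observations, so the band holds its nominal level
      qlo[r, b] <- quantile(v, lo_p, type = 6)
      qmed[r, b] <- quantile(v, 0.5, type = 6)
      qhi[r, b] <- quantile(v, hi_p, type = 6)
    }
  }
  band <- data.frame(
    bin = bins,
    n_obs = as.integer(table(bin_id)[as.character(bins)]),
    time_median = vapply(bins, function(b) median(obs_df$time[bin_id == b]),
                         numeric(1)),
    sim_lo = apply(qlo, 2, median), sim_med = apply(qmed, 2, median),
    sim_hi = apply(qhi, 2, median),
    obs_lo = vapply(bins, function(b) quantile(obs_df$dv[bin_id == b], lo_p,
                                               type = 6),
                    numeric(1)),
    obs_med = vapply(bins, function(b) median(obs_df$dv[bin_id == b]),
                     numeric(1)),
    obs_hi = vapply(bins, function(b) quantile(obs_df$dv[bin_id == b], hi_p,
                                               type = 6),
                    numeric(1)))
  inside <- obs_df$dv >= band$sim_lo[match(bin_id, band$bin)] &
    obs_df$dv <= band$sim_hi[match(bin_id, band$bin)]
  structure(list(bins = band, coverage = mean(inside),
                 n_replicates = n_replicates, level = level, seed = seed,
                 notes = notes),
            class = "vpc_result")
}

gof_skeleton <- function(subs) {
  out <- data.frame(
    id = unlist(lapply(subs, function(s) rep(s$id, nrow(s$obs)))),
    time = unlist(lapply(subs, function(s) s$obs$time)),
    dv = unlist(lapply(subs, function(s) s$obs$dv)))
  occ <- lapply(subs, function(s) s$obs$occ)
  if (!any(vapply(occ, is.null, logical(1))))
    out$occ <- unlist(occ)
  out
}

#' @export
print.vpc_result <- function(x, ...) {
  cat("Visual predictive check: ", x$n_replicates, " replicates, ",
      round(100 * x$level), "% band\n", sep = "")
  cat("  observations inside band: ", round(100 * x$coverage, 1), "%\n", sep = "")
  print(cbind(x$bins[, c("bin", "n_obs", "time_median")],
              round(x$bins[, -(1:3)], 2)), row.names = FALSE)
  invisible(x)
}

#' Nonparametric bootstrap of a population fit
#'
#' Resamples subjects with replacement (keeping the original cohort size),
#' refits each replicate starting from the original point estimate, and
#' aggregates converged replicates: per-parameter median, 2.5% and 97.5%
#' percentiles, and `%RSE = 100 * SD / median`. Replicates that fail to
#' converge are counted and excluded; more than `max_fail_frac` failures
#' aborts.
#'
#' @param fit a converged `fit_result`.
#' @param n_replicates number of bootstrap datasets (default 1000).
#' @param seed integer seed driving the resampling.
#' @param control optional [fit_control()] for replicate refits (defaults
#'   to the original fit's control without SEs).
#' @param max_fail_frac maximum tolerated fraction of failed replicates.
#' @return An object of class `bootstrap_result`: `summary` (median,
#'   `lower2.5`, `upper97.5`, `rse` per parameter), `estimates` (replicate
#'   matrix), `n_requested`, `n_success`, `seed`.
#' @export
bootstrap_model <- function(fit, n_replicates = 1000, seed = 1,
                            control = NULL, max_fail_frac = 0.5) {
  stopifnot(inherits(fit, "fit_result"))
  ds <- fit$dataset
  if (n_subjects(ds) < 2) stop("bootstrap needs at least 2 subjects", call. = FALSE)
  if (is.null(control)) {
    control <- fit$control
    control$se <- FALSE
  }
  ids <- unique(ds$data$ID)
  n <- length(ids)
  blocks <- split(seq_len(nrow(ds$data)), factor(ds$data$ID, levels = ids))
  set.seed(seed)
  draws <- matrix(sample.int(n, n * n_replicates, replace = TRUE),
                  nrow = n_replicates)
  est <- matrix(NA_real_, n_replicates,
                length(pack_names(fit$model)$all),
                dimnames = list(NULL, pack_names(fit$model)$all))
  fails <- 0L
  for (r in seq_len(n_replicates)) {
    pick <- draws[r, ]
    df <- do.call(rbind, lapply(seq_along(pick), function(j) {
      b <- ds$data[blocks[[pick[j]]], , drop = FALSE]
      b$ID <- j
      b
    }))
    rds <- pop_dataset(df, source = paste0("bootstrap:", r))
    f <- try(fit_population(rds, fit$model, inits = fit$params,
                            control = control), silent = TRUE)
    if (inherits(f, "try-error") || !f$convergence$converged) {
      fails <- fails + 1L
      if (fails > max_fail_frac * n_replicates)
        stop("bootstrap aborted: ", fails, " of ", n_replicates,
             " replicates failed", call. = FALSE)
      next
    }
    est[r, ] <- flatten_params(f$params, fit$model)
  }
  ok <- stats::complete.cases(est)
  summ <- data.frame(
    median = apply(est[ok, , drop = FALSE], 2, median),
    lower2.5 = apply(est[ok, , drop = FALSE], 2, quantile, 0.025),
    upper97.5 = apply(est[ok, , drop = FALSE], 2, quantile, 0.975),
    rse = 100 * apply(est[ok, , drop = FALSE], 2, sd) /
      abs(apply(est[ok, , drop = FALSE], 2, median)))
  structure(list(summary = summ, estimates = est[ok, , drop = FALSE],
                 n_requested = n_replicates, n_success = sum(ok),
                 seed = seed),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat("Nonparametric bootstrap: ", x$n_success, "/", x$n_requested,
      " converged replicates (seed ", x$seed, ")\n", sep = "")
  print(signif(as.matrix(x$summary), 4))
  invisible(x)
}

#' Four-panel goodness-of-fit plot
#'
#' Observed vs PRED, observed vs IPRED, CWRES vs PRED, and a CWRES
#' normal quantile-quantile panel, drawn with base graphics.
#'
#' @param x a `fit_result`.
#' @param ... ignored.
#' @return The diagnostic data frame, invisibly.
#' @export
plot.fit_result <- function(x, ...) {
  d <- gof_diagnostics(x)
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 1.5, 0.5))
  on.exit(graphics::par(op))
  lim <- range(c(d$dv, d$pred, d$ipred))
  plot(d$pred, d$dv, xlab = "PRED (mg/L)", ylab = "Observed (mg/L)",
       xlim = lim, ylim = lim); graphics::abline(0, 1, lty = 2)
  plot(d$ipred, d$dv, xlab = "IPRED (mg/L)", ylab = "Observed (mg/L)",
       xlim = lim, ylim = lim); graphics::abline(0, 1, lty = 2)
  plot(d$pred, d$cwres, xlab = "PRED (mg/L)", ylab = "CWRES")
  graphics::abline(h = 0, lty = 2)
  stats::qqnorm(d$cwres, main = "CWRES Q-Q"); stats::qqline(d$cwres)
  invisible(d)
}
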