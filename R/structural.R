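#' Individual pharmacokinetic parameter set
#'
#' Parameters of the one- or two-compartment disposition model: central
#' volume `v1` (L), peripheral volume `v2` (L), elimination clearance `cl1`
#' (L/h) and intercompartmental clearance `cl2` (L/h). For a one-compartment
#' model `v2`/`cl2` may be `NA`.
#'
#' @param v1,v2,cl1,cl2 parameter values; all supplied values must be > 0.
#' @return A named numeric vector with elements `v1`, `v2`, `cl1`, `cl2`.
#' @export
pk_params <- function(v1, cl1, v2 = NA_real_, cl2 = NA_real_) {
  p <- c(v1 = v1, v2 = v2, cl1 = cl1, cl2 = cl2)
  bad <- !is.na(p) & p <= 0
  if (any(bad))
    stop("pk parameters must be positive: ", paste(names(p)[bad], collapse = ", "),
         call. = FALSE)
  p
}

#' Micro and hybrid rate constants of the two-compartment bolus model
#'
#' Converts clearance/volume parameters to micro rate constants
#' (`k10 = cl1/v1`, `k12 = cl2/v1`, `k21 = cl2/v2`), the hybrid rate
#' constants `alpha >= beta` (roots of `x^2 - (k10+k12+k21) x + k10 k21`),
#' and the bolus coefficients `coefA = (alpha-k21)/(alpha-beta)`,
#' `coefB = (k21-beta)/(alpha-beta)`, which satisfy `coefA + coefB = 1`.
#'
#' @param p parameter vector from [pk_params()] (all four elements required).
#' @return A list with `k10`, `k12`, `k21`, `alpha`, `beta`, `coefA`, `coefB`.
#' @export
macro_constants <- function(p) {
  p <- p[c("v1", "v2", "cl1", "cl2")]
  if (any(is.na(p)) || any(p <= 0))
    stop("macro_constants requires positive v1, v2, cl1, cl2", call. = FALSE)
  k10 <- p[["cl1"]] / p[["v1"]]
  k12 <- p[["cl2"]] / p[["v1"]]
  k21 <- p[["cl2"]] / p[["v2"]]
  s <- k10 + k12 + k21
  rt <- sqrt(max(s^2 - 4 * k10 * k21, 0))
  alpha <- (s + rt) / 2
  beta <- (s - rt) / 2
  list(k10 = k10, k12 = k12, k21 = k21, alpha = alpha, beta = beta,
       coefA = (alpha - k21) / (alpha - beta),
       coefB = (k21 - beta) / (alpha - beta))
}

#' Covariate effect specification
#'
#' A multiplicative power-law covariate effect on a structural parameter:
#' the targeted parameter is multiplied by `(covariate / ref)^exponent`.
#' References default to `NULL`, meaning "resolve to the dataset median when
#' the model is fitted"; the published TXA model uses the cohort medians
#' (61.4 kg body weight, 61.0 mL/min creatinine clearance).
#'
#' @param param target parameter: one of `"v1"`, `"v2"`, `"cl1"`, `"cl2"`.
#' @param covariate covariate name as found in the dataset (lower case),
#'   e.g. `"bw"` or `"clcr"`.
#' @param ref reference (normalizing) covariate value, in the covariate's
#'   units; `NULL` to resolve from data at fit time.
#' @param exponent power exponent (initial value when estimated).
#' @return An object of class `cov_effect`.
#' @export
cov_effect <- function(param, covariate, ref = NULL, exponent = 0) {
  param <- match.arg(param, c("v1", "v2", "cl1", "cl2"))
  if (!is.null(ref) && (!is.finite(ref) || ref <= 0))
    stop("covariate reference must be positive", call. = FALSE)
  structure(list(param = param, covariate = tolower(covariate),
                 ref = ref, exponent = exponent),
            class = "cov_effect")
}

effect_label <- function(e) paste0(e$covariate, "_on_", e$param)

#' Apply covariate effects to typical parameter values
#'
#' Each targeted parameter is multiplied by `(cov/ref)^exponent`;
#' untargeted parameters pass through unchanged. With every covariate at its
#' reference, the output equals the typical values.
#'
#' @param theta named numeric vector of typical values (`v1`, `v2`, `cl1`,
#'   `cl2`).
#' @param effects list of [cov_effect()] objects with resolved references.
#' @param cov named list or vector of the subject's covariates.
#' @return Covariate-adjusted parameter vector (the subject's typical
#'   parameters, random effects at zero).
#' @examples
#' theta <- pk_params(v1 = 12.77, cl1 = 3.263, v2 = 6.857, cl2 = 2.859)
#' eff <- list(cov_effect("cl1", "clcr", ref = 61, exponent = 0.752))
#' apply_covariates(theta, eff, list(clcr = 60))  # 3.223 L/h
#' @export
apply_covariates <- function(theta, effects, cov) {
  for (e in effects) {
    if (!e$param %in% names(theta))
      stop("unknown parameter in covariate effect: ", e$param, call. = FALSE)
    if (is.null(cov[[e$covariate]]))
      stop("covariate not found: ", e$covariate, call. = FALSE)
    if (is.null(e$ref))
      stop("unresolved covariate reference for ", effect_label(e), call. = FALSE)
    theta[e$param] <- theta[e$param] * (cov[[e$covariate]] / e$ref)^e$exponent
  }
  theta
}

#' Individualize typical parameters with log-normal random effects
#'
#' Implements the exponential inter-individual variability model
#' `P_i = TV(P) * exp(eta_i)` for the parameters named in `eta`; parameters
#' without a random effect pass through.
#'
#' @param typical named parameter vector (typical values, possibly
#'   covariate-adjusted).
#' @param eta named numeric vector of random effects (log scale).
#' @return Individual parameter vector.
#' @export
individualize <- function(typical, eta) {
  if (length(eta) == 0) return(typical)
  if (is.null(names(eta)) || any(!names(eta) %in% names(typical)))
    stop("eta must be named by structural parameters", call. = FALSE)
  typical[names(eta)] <- typical[names(eta)] * exp(eta)
  typical
}

#' Predict concentration after intravenous bolus doses
#'
#' Closed-form concentration for superposed instantaneous boluses. The
#' two-compartment solution is
#' \deqn{C(t) = \sum_d \frac{amt_d}{V_1}\left[A e^{-\alpha (t - t_d)} +
#'   B e^{-\beta (t - t_d)}\right]}
#' over doses given at or before `t`; the one-compartment solution is the
#' mono-exponential with `k = cl1/v1`. Times before the first dose predict 0.
#' Near-degenerate hybrid roots (`alpha` approximately `beta`) are evaluated
#' with the repeated-root limit for numerical stability.
#'
#' @param t vector of times (h) at which to predict.
#' @param doses a data frame with columns `time` (h) and `amt` (mg), sorted
#'   by time.
#' @param p parameter vector from [pk_params()].
#' @param n_compartments 1 or 2.
#' @return Concentrations in mg/L (equivalently ug/mL) at `t`.
#' @examples
#' p <- pk_params(v1 = 12.77, cl1 = 3.263, v2 = 6.857, cl2 = 2.859)
#' predict_conc(c(0, 1, 5), data.frame(time = 0, amt = 1000), p)
#' @export
predict_conc <- function(t, doses, p, n_compartments = 2) {
  n_compartments <- as.integer(n_compartments)
  if (!n_compartments %in% c(1L, 2L))
    stop("n_compartments must be 1 or 2", call. = FALSE)
  if (any(t < 0)) stop("prediction times must be >= 0", call. = FALSE)
  doses <- as.data.frame(doses)
  if (is.unsorted(doses$time)) stop("doses must be sorted by time", call. = FALSE)
  if (any(doses$amt <= 0) || any(doses$time < 0))
    stop("dose amounts must be positive and times >= 0", call. = FALSE)
  need <- if (n_compartments == 2L) c("v1", "v2", "cl1", "cl2") else c("v1", "cl1")
  if (any(is.na(p[need])) || any(p[need] <= 0))
    stop("parameters must be positive: ", paste(need, collapse = ", "), call. = FALSE)
  v2 <- if (n_compartments == 2L) p[["v2"]] else 1
  cl2 <- if (n_compartments == 2L) p[["cl2"]] else 0
  cpp_conc(as.numeric(t), as.numeric(doses$time), as.numeric(doses$amt),
           p[["v1"]], v2, p[["cl1"]], if (n_compartments == 2L) cl2 else 0,
           n_compartments)
}
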