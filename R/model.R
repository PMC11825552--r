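#' Population model specification
#'
#' Declares the structural model (number of compartments), which parameters
#' carry log-normal inter-individual variability (IIV), the covariate
#' effects, and the residual error model.
#'
#' @param n_compartments 1 or 2.
#' @param iiv character vector of parameters carrying a random effect
#'   (subset of `v1`, `v2`, `cl1`, `cl2`); default `c("cl1", "v1")`, the two
#'   best-identified parameters under the sparse double-bolus design.
#' @param effects list of [cov_effect()] objects; `(param, covariate)` pairs
#'   must be distinct.
#' @param error residual error model: `"combined"` (additive +
#'   concentration-proportional) or `"additive"`.
#' @return An object of class `pop_model`.
#' @examples
#' txa_final_model()
#' @export
pop_model <- function(n_compartments = 2, iiv = c("cl1", "v1"),
                      effects = list(), error = c("combined", "additive")) {
  n_compartments <- as.integer(n_compartments)
  stopifnot(n_compartments %in% c(1L, 2L))
  pars <- structural_par_names(n_compartments)
  if (any(!iiv %in% pars))
    stop("iiv parameters must be among: ", paste(pars, collapse = ", "),
         call. = FALSE)
  error <- match.arg(error)
  if (length(effects)) {
    stopifnot(all(vapply(effects, inherits, logical(1), "cov_effect")))
    keys <- vapply(effects, effect_label, character(1))
    if (anyDuplicated(keys))
      stop("duplicate (parameter, covariate) effect", call. = FALSE)
    if (any(!vapply(effects, `[[`, character(1), "param") %in% pars))
      stop("covariate effect targets a parameter outside the structural model",
           call. = FALSE)
  }
  structure(list(n_compartments = n_compartments, iiv = iiv,
                 effects = effects, error = error),
            class = "pop_model")
}

structural_par_names <- function(ncmt)
  if (ncmt == 2L) c("v1", "v2", "cl1", "cl2") else c("v1", "cl1")

#' Population parameter set
#'
#' Fixed effects (typical values and covariate exponents), diagonal
#' inter-individual variance matrix, and residual error SDs.
#'
#' @param theta named typical values (`v1`, `v2`, `cl1`, `cl2` in L and L/h;
#'   `v2`/`cl2` may be omitted for a one-compartment model).
#' @param beta named covariate exponents, one per model effect, named as
#'   `<covariate>_on_<param>` (e.g. `bw_on_v1`).
#' @param omega2 named variances of the log-normal random effects
#'   (dimensionless, log scale).
#' @param sigma residual SDs `c(add = sigma1, prop = sigma2)`: `sigma1` in
#'   mg/L, `sigma2` dimensionless; observation SD is
#'   `sqrt(sigma1^2 + (Cpred * sigma2)^2)`.
#' @return An object of class `param_set`.
#' @export
param_set <- function(theta, beta = numeric(), omega2 = numeric(),
                      sigma = c(add = 1, prop = 0)) {
  if (any(theta <= 0)) stop("typical values must be positive", call. = FALSE)
  if (any(omega2 < 0)) stop("omega^2 must be non-negative", call. = FALSE)
  sigma <- c(add = unname(sigma[["add"]]),
             prop = if ("prop" %in% names(sigma)) unname(sigma[["prop"]]) else 0)
  if (sigma[["add"]] <= 0) stop("sigma1 (additive SD) must be positive", call. = FALSE)
  if (sigma[["prop"]] < 0) stop("sigma2 must be non-negative", call. = FALSE)
  structure(list(theta = theta, beta = beta, omega2 = omega2, sigma = sigma),
            class = "param_set")
}

#' The published TXA final-model structure
#'
#' Two-compartment model with body weight on `v1` and Cockcroft-Gault
#' creatinine clearance on `cl1`, normalized at the study cohort medians
#' (61.4 kg; 61.0 mL/min), IIV on `cl1` and `v1`, combined residual error.
#'
#' @param iiv parameters carrying IIV (default `c("cl1", "v1")`).
#' @return A `pop_model`.
#' @export
txa_final_model <- function(iiv = c("cl1", "v1")) {
  pop_model(2, iiv = iiv,
            effects = list(cov_effect("v1", "bw", ref = 61.4, exponent = 0.911),
                           cov_effect("cl1", "clcr", ref = 61.0, exponent = 0.752)))
}

# resolve NULL covariate references to dataset medians (one value per subject)
resolve_references <- function(model, covdf) {
  model$effects <- lapply(model$effects, function(e) {
    if (is.null(e$ref)) {
      if (is.null(covdf[[e$covariate]]))
        stop("covariate not in dataset: ", e$covariate, call. = FALSE)
      e$ref <- stats::median(covdf[[e$covariate]])
    }
    e
  })
  model
}

# n_subjects x 4 matrix of covariate-adjusted typical parameters
typical_matrix <- function(model, params, covdf) {
  n <- nrow(covdf)
  full <- c(v1 = NA_real_, v2 = 1, cl1 = NA_real_, cl2 = 0)
  full[names(params$theta)] <- params$theta
  typ <- matrix(rep(full[c("v1", "v2", "cl1", "cl2")], each = n), nrow = n,
                dimnames = list(NULL, c("v1", "v2", "cl1", "cl2")))
  for (e in model$effects) {
    b <- params$beta[[effect_label(e)]]
    if (is.null(b))
      stop("missing exponent for effect ", effect_label(e), call. = FALSE)
    typ[, e$param] <- typ[, e$param] * (covdf[[e$covariate]] / e$ref)^b
  }
  typ
}

#' @export
print.pop_model <- function(x, ...) {
  cat(x$n_compartments, "-compartment IV-bolus model, ", x$error,
      " residual error\n", sep = "")
  cat("  IIV on: ", if (length(x$iiv)) paste(x$iiv, collapse = ", ") else "(none)",
      "\n", sep = "")
  if (length(x$effects))
    for (e in x$effects)
      cat("  ", e$covariate, " on ", e$param, " (ref ",
          if (is.null(e$ref)) "data median" else e$ref, ")\n", sep = "")
  invisible(x)
}

#' @export
print.param_set <- function(x, ...) {
  cat("theta: ", paste(names(x$theta), signif(x$theta, 4), sep = "=",
                       collapse = ", "), "\n")
  if (length(x$beta))
    cat("beta:  ", paste(names(x$beta), signif(x$beta, 4), sep = "=",
                         collapse = ", "), "\n")
  if (length(x$omega2))
    cat("omega2:", paste(names(x$omega2), signif(x$omega2, 4), sep = "=",
                         collapse = ", "), "\n")
  cat("sigma: ", paste(names(x$sigma), signif(x$sigma, 4), sep = "=",
                       collapse = ", "), "\n")
  invisible(x)
}
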