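# Shared fixtures: everything is generated in code at test time.

fast_ctrl <- fit_control(se = FALSE)

# minimal one-subject event table (one dose, one observation)
minimal_table <- function() {
  data.frame(ID = 1, TIME = c(0, 1), AMT = c(1000, NA), DV = c(NA, 50),
             EVID = c(1L, 0L), MDV = c(1L, 0L),
             BW = 60, HT = 165, AGE = 60, SEX = 0, SCR = 80)
}

# reduced cohorts for fast fitting
small_design <- function(n = 12) cohort_design(n = n)

# tiny dataset + model pairs for likelihood-level checks
toy_problem <- function(seed, n = 5, iiv = "cl1") {
  truth <- txa_truth(omega2 = stats::setNames(rep(0.09, length(iiv)), iiv))
  model <- txa_final_model(iiv = iiv)
  ds <- simulate_dataset(cohort_design(n = n), truth, seed = seed,
                         model = model)
  list(ds = ds, model = model, truth = truth)
}

# add an independent (decoy) covariate column to a simulated dataset
with_decoy_covariate <- function(ds, seed) {
  set.seed(seed)
  ids <- unique(ds$data$ID)
  val <- stats::setNames(stats::rlnorm(length(ids), log(1109), 0.1), ids)
  df <- ds$data
  df$PRIME <- val[as.character(df$ID)]
  pop_dataset(df, source = paste0(ds$source, "+decoy"))
}
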