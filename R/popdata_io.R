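#' Assemble a population PK dataset from an event-record table
#'
#' Builds a validated analysis dataset from a NONMEM-style event-record data
#' frame. Required columns: `ID`, `TIME` (h), `AMT` (mg, dose rows), `DV`
#' (mg/L, observation rows), `EVID` (0 = observation, 1 = dose), `MDV`
#' (1 = missing DV), and the covariates `BW` (kg), `HT` (cm), `AGE` (years),
#' `SEX` (0 = male, 1 = female), `SCR` (umol/L). `CLCR` (mL/min) and `BSA`
#' (m^2) are computed by Cockcroft-Gault and DuBois-DuBois when absent.
#' Additional constant-within-subject numeric columns are carried along as
#' extra covariates (available under their lower-case names); an optional
#' `OCC` column labels nominal sampling occasions.
#'
#' @param data event-record data frame.
#' @param source provenance string recorded on the dataset.
#' @return An object of class `pop_dataset`.
#' @export
pop_dataset <- function(data, source = "in-memory") {
  data <- as.data.frame(data)
  problems <- validate_event_table(data)
  if (length(problems))
    stop("invalid event-record table:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  if (is.null(data$CLCR))
    data$CLCR <- cockcroft_gault(data$AGE, data$BW, scr_umol_to_mgdl(data$SCR),
                                 data$SEX)
  if (is.null(data$BSA))
    data$BSA <- dubois_bsa(data$BW, data$HT)
  structure(list(data = data, source = source), class = "pop_dataset")
}

required_cols <- c("ID", "TIME", "AMT", "DV", "EVID", "MDV",
                   "BW", "HT", "AGE", "SEX", "SCR")
covariate_cols <- c("BW", "HT", "AGE", "SEX", "SCR")

#' Validate an event-record table
#'
#' Returns a character vector of problems (empty when valid), each naming
#' the offending column or row. Checks: required columns present; times
#' non-negative and non-decreasing within subject; dose amounts positive;
#' non-missing observations positive; covariates constant within subject;
#' at least one dose at or before each subject's first observation.
#'
#' @param data event-record data frame.
#' @return Character vector of problem descriptions.
#' @export
validate_event_table <- function(data) {
  probs <- character()
  miss <- setdiff(required_cols, names(data))
  if (length(miss))
    return(paste("missing required column(s):", paste(miss, collapse = ", ")))
  rows <- seq_len(nrow(data))
  if (nrow(data) == 0) return("table has no rows")
  bad <- rows[!is.finite(data$TIME) | data$TIME < 0]
  if (length(bad))
    probs <- c(probs, paste0("negative or missing TIME at row(s) ",
                             paste(bad, collapse = ", ")))
  bad <- rows[data$EVID == 1 & (!is.finite(data$AMT) | data$AMT <= 0)]
  if (length(bad))
    probs <- c(probs, paste0("non-positive dose AMT at row(s) ",
                             paste(bad, collapse = ", ")))
  bad <- rows[data$EVID == 0 & data$MDV == 0 &
                (!is.finite(data$DV) | data$DV <= 0)]
  if (length(bad))
    probs <- c(probs, paste0("non-positive observed DV at row(s) ",
                             paste(bad, collapse = ", ")))
  extra <- setdiff(names(data), c(required_cols, "OCC", "CLCR", "BSA"))
  extra <- extra[vapply(data[extra], is.numeric, logical(1))]
  for (id in unique(data$ID)) {
    sel <- data$ID == id
    if (all(is.finite(data$TIME[sel])) && is.unsorted(data$TIME[sel]))
      probs <- c(probs, paste0("non-monotone TIME within subject ", id,
                               " (rows ", paste(range(rows[sel]), collapse = "-"), ")"))
    for (cc in c(covariate_cols, "CLCR", "BSA", extra)) {
      if (is.null(data[[cc]])) next
      if (length(unique(data[[cc]][sel])) > 1)
        probs <- c(probs, paste0("covariate ", cc, " varies within subject ", id))
    }
    obs_t <- data$TIME[sel & data$EVID == 0 & data$MDV == 0]
    dose_t <- data$TIME[sel & data$EVID == 1]
    if (length(obs_t)) {
      if (length(dose_t) == 0)
        probs <- c(probs, paste0("subject ", id, " has observations but no dose"))
      else if (min(dose_t) > min(obs_t))
        probs <- c(probs, paste0("subject ", id,
                                 ": first observation precedes first dose"))
    }
  }
  probs
}

#' Read an event-record dataset from CSV
#'
#' Reads the comma-separated event-record dialect written by
#' [write_dataset()] (header row, NONMEM column conventions) and assembles a
#' validated [pop_dataset()].
#'
#' @param path path to a CSV file.
#' @return A `pop_dataset`.
#' @export
read_dataset <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  for (cc in intersect(names(df), c("TIME", "AMT", "DV", "BW", "HT", "AGE",
                                    "SCR", "CLCR", "BSA")))
    df[[cc]] <- as.double(df[[cc]])
  pop_dataset(df, source = path)
}

#' Write an event-record dataset to CSV
#'
#' Emits the same dialect [read_dataset()] accepts. Numeric values are
#' written with 17 significant digits so that a write/read round trip
#' reproduces times, doses and concentrations exactly.
#'
#' @param ds a `pop_dataset`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(ds, path) {
  stopifnot(inherits(ds, "pop_dataset"))
  df <- ds$data
  out <- df
  for (cc in names(out)) {
    if (is.double(out[[cc]]))
      out[[cc]] <- ifelse(is.na(df[[cc]]), "",
                          formatC(df[[cc]], digits = 17, format = "g"))
  }
  write.table(out, path, sep = ",", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

#' Split a dataset into per-subject records
#'
#' @param ds a `pop_dataset`.
#' @return A list with one element per subject: `id`, `covariates` (named
#'   list with lower-case names, serum creatinine in both umol/L and mg/dL
#'   views), `doses` (data frame `time`, `amt`), and `obs` (data frame
#'   `time`, `dv`, and `occ` when present).
#' @export
subject_records <- function(ds) {
  stopifnot(inherits(ds, "pop_dataset"))
  df <- ds$data
  extra <- setdiff(names(df), c(required_cols, "OCC", "CLCR", "BSA"))
  extra <- extra[vapply(df[extra], is.numeric, logical(1))]
  lapply(unique(df$ID), function(id) {
    sub <- df[df$ID == id, , drop = FALSE]
    cov <- list(sex = match_sex(sub$SEX[1]), age = sub$AGE[1],
                bw = sub$BW[1], height = sub$HT[1],
                scr = sub$SCR[1], scr_mgdl = scr_umol_to_mgdl(sub$SCR[1]),
                clcr = sub$CLCR[1], bsa = sub$BSA[1])
    for (cc in extra) cov[[tolower(cc)]] <- sub[[cc]][1]
    dose <- sub[sub$EVID == 1, , drop = FALSE]
    obs <- sub[sub$EVID == 0 & sub$MDV == 0, , drop = FALSE]
    o <- data.frame(time = obs$TIME, dv = obs$DV)
    if (!is.null(obs$OCC)) o$occ <- obs$OCC
    list(id = id, covariates = cov,
         doses = data.frame(time = dose$TIME, amt = dose$AMT), obs = o)
  })
}

#' @export
print.pop_dataset <- function(x, ...) {
  ids <- unique(x$data$ID)
  cat("Population PK dataset (", x$source, ")\n", sep = "")
  cat("  subjects:     ", length(ids), "\n", sep = "")
  cat("  doses:        ", sum(x$data$EVID == 1), "\n", sep = "")
  cat("  observations: ", n_observations(x), "\n", sep = "")
  invisible(x)
}

#' Number of subjects in a dataset
#' @param ds a `pop_dataset`.
#' @return Integer count.
#' @export
n_subjects <- function(ds) length(unique(ds$data$ID))

#' Number of non-missing observations in a dataset
#' @param ds a `pop_dataset`.
#' @return Integer count.
#' @export
n_observations <- function(ds) sum(ds$data$EVID == 0 & ds$data$MDV == 0)
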