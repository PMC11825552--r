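#' Cockcroft-Gault creatinine clearance
#'
#' Estimates creatinine clearance (mL/min) from age, actual body weight,
#' serum creatinine and sex:
#' \deqn{CL_{cr} = \frac{(140 - age)\,BW}{72\,S_{cr}} \times (0.85\ \mathrm{if\ female})}
#' with age in years, body weight in kg and serum creatinine in mg/dL.
#'
#' @param age age in years (must be below 140).
#' @param bw actual body weight in kg.
#' @param scr serum creatinine in mg/dL (use [scr_umol_to_mgdl()] to convert
#'   laboratory values reported in umol/L).
#' @param sex `"male"`/`"female"`, or the numeric file coding 0 = male,
#'   1 = female. Recycled against the other arguments.
#' @return Creatinine clearance in mL/min.
#' @examples
#' cockcroft_gault(69, 61.4, scr_umol_to_mgdl(85.7), "male")
#' @export
cockcroft_gault <- function(age, bw, scr, sex) {
  sex <- match_sex(sex)
  n <- max(length(age), length(bw), length(scr), length(sex))
  age <- rep_len(age, n); bw <- rep_len(bw, n)
  scr <- rep_len(scr, n); sex <- rep_len(sex, n)
  if (any(!is.finite(scr)) || any(scr <= 0))
    stop("serum creatinine must be positive", call. = FALSE)
  if (any(!is.finite(bw)) || any(bw <= 0))
    stop("body weight must be positive", call. = FALSE)
  if (any(age >= 140))
    stop("age must be below 140 years", call. = FALSE)
  clcr <- (140 - age) * bw / (scr * 72)
  clcr[sex == "female"] <- 0.85 * clcr[sex == "female"]
  clcr
}

#' DuBois-DuBois body surface area
#'
#' \deqn{BSA = 0.007184\, BW^{0.425}\, height^{0.725}} with body weight in kg,
#' height in cm, and BSA in m^2.
#'
#' @param bw body weight in kg.
#' @param height height in cm.
#' @return Body surface area in m^2.
#' @examples
#' dubois_bsa(61.4, 161.8)
#' @export
dubois_bsa <- function(bw, height) {
  if (any(!is.finite(bw)) || any(bw <= 0) ||
      any(!is.finite(height)) || any(height <= 0))
    stop("body weight and height must be positive", call. = FALSE)
  0.007184 * bw^0.425 * height^0.725
}

#' Convert serum creatinine from umol/L to mg/dL
#'
#' Laboratory serum creatinine is stored in umol/L; the Cockcroft-Gault
#' formula takes mg/dL. The conversion divides by 88.4.
#'
#' @param scr_umol serum creatinine in umol/L.
#' @return Serum creatinine in mg/dL.
#' @export
scr_umol_to_mgdl <- function(scr_umol) scr_umol / 88.4

# normalize sex coding to a character vector "male"/"female"
match_sex <- function(sex) {
  if (is.numeric(sex)) {
    if (any(!sex %in% c(0, 1)))
      stop("numeric sex coding must be 0 (male) or 1 (female)", call. = FALSE)
    return(c("male", "female")[sex + 1L])
  }
  sex <- tolower(as.character(sex))
  if (any(!sex %in% c("male", "female")))
    stop("sex must be 'male' or 'female' (or 0/1)", call. = FALSE)
  sex
}
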