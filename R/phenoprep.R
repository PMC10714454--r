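# Derivation of disease-resilience phenotypes from raw records.
#
# Traits follow the challenge-model conventions: subjective health scores
# collapsed to perfect-health indicators, treatment counts expressed as
# rates per day present, mortality/treated composite codings, residual
# feed intake as the residual of feed intake on growth and body
# composition covariates, and the survivor-dataset rule that masks
# non-mortality traits for animals that did not reach slaughter.

#' Binarize a 1-5 health score
#'
#' @param score integer vector of health scores in 1..5.
#' @return 0/1 vector: 1 for perfect health (score 5), 0 otherwise.
#' @export
binarize_health_score <- function(score) {
  if (any(!is.na(score) & (score < 1 | score > 5 | score != round(score)))) {
    stop("health scores must be integers in 1..5")
  }
  ifelse(is.na(score), NA_integer_, as.integer(score == 5))
}

#' Treatment rate per day present
#'
#' @param n_treatments nonnegative treatment counts.
#' @param days_present positive number of days the animal was present in
#'   the phase.
#' @return treatments per day.
#' @export
treatment_rate <- function(n_treatments, days_present) {
  if (any(!is.na(days_present) & days_present <= 0)) {
    stop("days_present must be positive")
  }
  if (any(!is.na(n_treatments) & n_treatments < 0)) {
    stop("n_treatments must be nonnegative")
  }
  n_treatments / days_present
}

#' Mortality and mortality-or-treated codings
#'
#' MOR is 1 for animals that died in the phase, 0 otherwise.  MT contrasts
#' the extremes: 1 for animals that died, 0 for animals that survived with
#' no individual therapeutic treatment, missing for animals that survived
#' but were treated.
#'
#' @param survived logical vector.
#' @param n_treatments treatment counts per animal.
#' @return data frame with columns `MOR` and `MT`.
#' @export
code_mortality_treated <- function(survived, n_treatments) {
  stopifnot(length(survived) == length(n_treatments))
  mor <- as.integer(!survived)
  mt <- ifelse(!survived, 1L,
               ifelse(n_treatments == 0, 0L, NA_integer_))
  data.frame(MOR = mor, MT = mt)
}

#' Residual feed intake
#'
#' Residual of an ordinary least-squares regression of average daily feed
#' intake on average body weight, finisher average daily gain, and
#' ultrasound backfat thickness, fitted within the supplied cohort.
#'
#' @param adfi average daily feed intake.
#' @param avg_bw average body weight (optionally entered as metabolic
#'   weight, BW^0.75, with `metabolic = TRUE`).
#' @param adg_fin average daily gain in the finisher.
#' @param backfat ultrasound backfat thickness.
#' @param metabolic use metabolic body weight instead of raw weight.
#' @return RFI residuals (mean zero by construction); `NA` where any input
#'   is missing.
#' @export
residual_feed_intake <- function(adfi, avg_bw, adg_fin, backfat,
                                 metabolic = FALSE) {
  bw <- if (metabolic) avg_bw^0.75 else avg_bw
  df <- data.frame(adfi = adfi, bw = bw, adg = adg_fin, bf = backfat)
  cc <- complete.cases(df)
  if (sum(cc) < 10) stop("need at least 10 complete records to fit RFI")
  X <- cbind(1, df$bw[cc], df$adg[cc], df$bf[cc])
  if (qr(X)$rank < ncol(X)) stop("rank-deficient RFI covariates")
  fit <- lm(adfi ~ bw + adg + bf, data = df[cc, ])
  out <- rep(NA_real_, length(adfi))
  out[cc] <- resid(fit)
  out
}

#' Default trait dictionary
#'
#' Trait metadata used by the scan and enrichment stages: type and the
#' favorable direction of an increase in the trait (+1 favorable, -1
#' unfavorable).
#'
#' @return data frame with columns `trait`, `type`, `favorable`,
#'   `is_mortality`.
#' @export
trait_dictionary <- function() {
  data.frame(
    trait = c("qNurHS1", "qNurHS2", "NurHS", "FinHS",
              "NurTRT", "FinTRT", "AllTRT",
              "cNurMOR", "cFinMOR", "AllMOR",
              "cNurMT", "FinMT", "AllMT",
              "qNurADG", "cNurADG", "FinADG",
              "ADFI", "ADFD", "FCR", "RFI",
              "CWT", "DRS", "LYLD", "CBF", "CLD"),
    type = c(rep("binary", 4), rep("rate", 3), rep("binary", 6),
             rep("continuous", 12)),
    favorable = c(rep(1, 4), rep(-1, 3), rep(-1, 6),
                  rep(1, 3), 1, -1, -1, -1, 1, 1, 1, -1, 1),
    is_mortality = c(rep(FALSE, 7), rep(TRUE, 6), rep(FALSE, 12)),
    stringsAsFactors = FALSE
  )
}

#' Apply the survivor-dataset convention
#'
#' Non-mortality traits are set to missing for animals that did not
#' survive to slaughter; mortality traits (MOR/MT) are untouched.
#'
#' @param pheno data frame with one row per animal, a logical `survived`
#'   column, and trait columns.
#' @param mortality_traits character vector of trait columns exempt from
#'   masking; defaults to columns matching MOR/MT naming.
#' @return the masked data frame.
#' @export
survivor_filter <- function(pheno, mortality_traits = NULL) {
  if (nrow(pheno) == 0) return(pheno)
  stopifnot("survived" %in% names(pheno))
  if (is.null(mortality_traits)) {
    mortality_traits <- grep("(MOR|MT)$", names(pheno), value = TRUE)
  }
  trait_cols <- setdiff(names(pheno),
                        c("animal_id", "survived", mortality_traits))
  trait_cols <- trait_cols[vapply(pheno[trait_cols], is.numeric, TRUE)]
  dead <- !pheno$survived
  for (cl in trait_cols) pheno[[cl]][dead] <- NA
  pheno
}
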