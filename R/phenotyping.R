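#' Body mass index from measured weight and height
#'
#' @param weight Weight in kilograms.
#' @param height Height in metres.
#' @return BMI in kg/m^2, the exact quotient `weight / height^2` (no
#'   internal rounding).
#' @examples
#' compute_bmi(80, 1.80)
#' @export
compute_bmi <- function(weight, height) {
  if (any(!is.finite(height) & !is.na(height)) || any(height <= 0, na.rm = TRUE))
    stop("height must be positive", call. = FALSE)
  if (any(weight <= 0, na.rm = TRUE))
    stop("weight must be positive", call. = FALSE)
  weight / height^2
}

#' Adiposity category levels
#'
#' Category levels used throughout the package, in increasing order of
#' adiposity. `adiposity_levels()` returns the composite (BMI + WC)
#' categories; `wc_levels()` and `bmi_levels()` the single-measure ones.
#'
#' @return Character vector of ordered level names.
#' @export
adiposity_levels <- function() c("low", "increased", "high", "very_high")

#' @rdname adiposity_levels
#' @export
wc_levels <- function() c("healthy", "abdominal_overweight", "abdominal_obesity")

#' @rdname adiposity_levels
#' @export
bmi_levels <- function() c("normal", "overweight", "obesity")

#' Classify body mass index (WHO classes)
#'
#' Half-open intervals, lower bound inclusive: normal weight `< 25`,
#' overweight `25 <= bmi < 30`, obesity `>= 30` kg/m^2.
#'
#' @param bmi BMI in kg/m^2.
#' @return Factor with levels [bmi_levels()]; `NA` input stays `NA`.
#' @export
classify_bmi <- function(bmi) {
  if (any(bmi <= 0, na.rm = TRUE)) stop("bmi must be positive", call. = FALSE)
  cut(bmi, breaks = c(0, 25, 30, Inf), labels = bmi_levels(), right = FALSE)
}

#' Classify waist circumference (WHO classes, sex-specific thresholds)
#'
#' Men: healthy `< 94`, abdominal overweight `94 <= wc < 102`, abdominal
#' obesity `>= 102` cm. Women: thresholds 80 and 88 cm. Lower bounds
#' inclusive.
#'
#' @param wc Waist circumference in cm.
#' @param sex `"men"` or `"women"` (recycled against `wc`).
#' @return Factor with levels [wc_levels()].
#' @export
classify_wc <- function(wc, sex) {
  sex <- check_sex(sex, length(wc))
  if (any(wc <= 0, na.rm = TRUE)) stop("wc must be positive", call. = FALSE)
  lo <- ifelse(sex == "men", 94, 80)
  hi <- ifelse(sex == "men", 102, 88)
  out <- ifelse(wc < lo, 1L, ifelse(wc < hi, 2L, 3L))
  factor(wc_levels()[out], levels = wc_levels())
}

check_sex <- function(sex, n = length(sex)) {
  sex <- as.character(sex)
  if (length(sex) == 1L) sex <- rep(sex, n)
  if (!all(sex %in% c("men", "women")))
    stop("sex must be 'men' or 'women'", call. = FALSE)
  sex
}

#' Default composite adiposity mapping
#'
#' The 3 x 3 grid (BMI class x WC class) collapsed to four composite
#' adiposity categories.  The mapping is reconstructed so that composite
#' category prevalences equal the arithmetic of the published single-measure
#' marginals in both sexes: `very_high` is BMI obesity at any WC,
#' `high` is abdominal obesity below BMI 30, `increased` is abdominal
#' overweight below BMI 30 or BMI overweight with a healthy WC, and
#' `low` is normal BMI with a healthy WC.  Discordant normal-BMI /
#' abdominal-obesity phenotypes therefore land in `high`.
#'
#' @return A 3 x 3 character matrix, rows [bmi_levels()], columns
#'   [wc_levels()], entries in [adiposity_levels()]. Pass a modified copy
#'   to [classify_adiposity()] to audit alternative mappings.
#' @export
adiposity_mapping <- function() {
  m <- matrix(
    c("low",       "increased", "high",
      "increased", "increased", "high",
      "very_high", "very_high", "very_high"),
    nrow = 3, byrow = TRUE,
    dimnames = list(bmi_levels(), wc_levels())
  )
  m
}

#' Composite adiposity category from BMI and WC classes
#'
#' @param bmi_cat Factor/character in [bmi_levels()].
#' @param wc_cat Factor/character in [wc_levels()].
#' @param mapping 3 x 3 mapping matrix, defaults to [adiposity_mapping()].
#' @return Factor with levels [adiposity_levels()].
#' @export
classify_adiposity <- function(bmi_cat, wc_cat, mapping = adiposity_mapping()) {
  b <- as.character(bmi_cat); w <- as.character(wc_cat)
  stopifnot(all(b %in% bmi_levels() | is.na(b)),
            all(w %in% wc_levels() | is.na(w)))
  out <- rep(NA_character_, length(b))
  ok <- !is.na(b) & !is.na(w)
  out[ok] <- mapping[cbind(b[ok], w[ok])]
  factor(out, levels = adiposity_levels())
}

#' Comorbidity classifiers
#'
#' Deterministic flags following the cohort's clinical definitions:
#' hypertension is systolic >= 140 mmHg and/or diastolic >= 90 mmHg and/or
#' antihypertensive medication; diabetes is random plasma glucose
#' >= 11.1 mmol/L or self-report; hypercholesterolaemia is total
#' cholesterol >= 6.5 mmol/L or lipid-lowering therapy; low HDL is
#' < 1.03 mmol/L for men and < 1.29 mmol/L for women.
#'
#' @param sbp,dbp Systolic / diastolic blood pressure, mmHg.
#' @param on_meds,self_report,on_lipid_meds Logical flags.
#' @param glucose Random plasma glucose, mmol/L.
#' @param tc,hdl Total and HDL cholesterol, mmol/L.
#' @param sex `"men"` or `"women"`.
#' @return Logical vector(s); `classify_lipids()` returns a data.frame
#'   with columns `hypercholesterolaemia` and `low_hdl`.
#' @name comorbidity
NULL

#' @rdname comorbidity
#' @export
classify_hypertension <- function(sbp, dbp, on_meds = FALSE) {
  if (any(sbp < 0 | dbp < 0, na.rm = TRUE))
    stop("blood pressures must be non-negative", call. = FALSE)
  (sbp >= 140) | (dbp >= 90) | (on_meds %in% TRUE)
}

#' @rdname comorbidity
#' @export
classify_diabetes <- function(glucose, self_report = FALSE) {
  if (any(glucose < 0, na.rm = TRUE))
    stop("glucose must be non-negative", call. = FALSE)
  (glucose >= 11.1) | (self_report %in% TRUE)
}

#' @rdname comorbidity
#' @export
classify_lipids <- function(tc, hdl, on_lipid_meds = FALSE, sex) {
  sex <- check_sex(sex, length(tc))
  if (any(tc < 0 | hdl < 0, na.rm = TRUE))
    stop("lipids must be non-negative", call. = FALSE)
  data.frame(
    hypercholesterolaemia = (tc >= 6.5) | (on_lipid_meds %in% TRUE),
    low_hdl = hdl < ifelse(sex == "men", 1.03, 1.29)
  )
}

#' Append exposure category columns to a wave table
#'
#' Recomputes BMI from measured height and weight (any supplied `bmi`
#' column more than 0.5 kg/m^2 off is recomputed with a warning) and adds
#' `bmi`, `bmi_cat`, `wc_cat` and the composite `adiposity` columns.
#'
#' @param waves Data frame with one row per participant-wave: columns
#'   `sex`, `height`, `weight`, `wc` (others are carried through).
#' @param mapping Composite mapping, see [classify_adiposity()].
#' @return `waves` with phenotype columns appended.
#' @export
phenotype_waves <- function(waves, mapping = adiposity_mapping()) {
  stopifnot(all(c("sex", "height", "weight", "wc") %in% names(waves)))
  ok <- !is.na(waves$height) & !is.na(waves$weight)
  bmi <- rep(NA_real_, nrow(waves))
  bmi[ok] <- compute_bmi(waves$weight[ok], waves$height[ok])
  if ("bmi" %in% names(waves)) {
    off <- which(ok & !is.na(waves$bmi) & abs(waves$bmi - bmi) > 0.5)
    if (length(off))
      warning(length(off), " supplied bmi values disagree with weight/height",
              " by > 0.5 kg/m^2; recomputed", call. = FALSE)
  }
  waves$bmi <- bmi
  waves$bmi_cat <- classify_bmi(waves$bmi)
  waves$wc_cat <- classify_wc(waves$wc, waves$sex)
  waves$adiposity <- classify_adiposity(waves$bmi_cat, waves$wc_cat, mapping)
  waves
}
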