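#' Body-mass index and waist-to-height ratio from raw measurements
#'
#' Computes BMI (weight in kilograms divided by squared height in metres) and
#' WHtR (waist circumference divided by height, both in centimetres) from
#' measured anthropometry. Inputs are vectorized and recycled to a common
#' length.
#'
#' @param height_cm Standing height in centimetres.
#' @param weight_kg Body weight in kilograms.
#' @param waist_cm Waist circumference in centimetres.
#'
#' @return A data frame with columns `height_cm`, `weight_kg`, `waist_cm`,
#'   `bmi` (kg/m^2) and `whtr` (dimensionless).
#' @examples
#' compute_bmi_whtr(175, 70, 87.5)
#' @export
compute_bmi_whtr <- function(height_cm, weight_kg, waist_cm) {
  n <- max(length(height_cm), length(weight_kg), length(waist_cm))
  height_cm <- rep_len(height_cm, n)
  weight_kg <- rep_len(weight_kg, n)
  waist_cm <- rep_len(waist_cm, n)
  check_measure(height_cm, "height_cm")
  check_measure(weight_kg, "weight_kg")
  check_measure(waist_cm, "waist_cm")
  # plausibility: catch unit mistakes (metres passed as cm, grams as kg)
  if (any(height_cm < 50 | height_cm > 272))
    stop("height_cm outside plausible range [50, 272] cm; metres passed as cm?")
  if (any(weight_kg < 10 | weight_kg > 650))
    stop("weight_kg outside plausible range [10, 650] kg")
  if (any(waist_cm < 20 | waist_cm > 400))
    stop("waist_cm outside plausible range [20, 400] cm")
  data.frame(
    height_cm = height_cm, weight_kg = weight_kg, waist_cm = waist_cm,
    bmi = weight_kg / (height_cm / 100)^2,
    whtr = waist_cm / height_cm
  )
}

check_measure <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0))
    stop(sprintf("'%s' must be positive and finite", name))
  invisible(TRUE)
}

#' Body Roundness Index
#'
#' BRI = 364.2 - 365.5 * sqrt(1 - ((WC / 2pi)^2 / (0.5 H)^2)) with waist
#' circumference WC and height H in metres (Thomas et al. 2013, Obesity
#' 21:2264-71). Arguments are taken in centimetres and converted.
#'
#' @param waist_cm Waist circumference, cm.
#' @param height_cm Height, cm.
#' @return BRI (dimensionless). Errors, rather than returning `NaN`, when the
#'   eccentricity argument is negative (waist/2pi must be below half height).
#' @export
body_roundness_index <- function(waist_cm, height_cm) {
  check_measure(waist_cm, "waist_cm")
  check_measure(height_cm, "height_cm")
  wc <- waist_cm / 100
  h <- height_cm / 100
  arg <- 1 - (wc / (2 * pi))^2 / (0.5 * h)^2
  if (any(arg < 0))
    stop("BRI undefined: waist/(2*pi) exceeds half the height")
  364.2 - 365.5 * sqrt(arg)
}

#' Weight-Adjusted Waist Index
#'
#' WWI = WC / sqrt(weight) with waist in centimetres and weight in kilograms
#' (Park et al. 2018, Sci Rep 8:16753).
#'
#' @param waist_cm Waist circumference, cm.
#' @param weight_kg Weight, kg.
#' @return WWI in cm/sqrt(kg).
#' @export
weight_adjusted_waist_index <- function(waist_cm, weight_kg) {
  check_measure(waist_cm, "waist_cm")
  check_measure(weight_kg, "weight_kg")
  waist_cm / sqrt(weight_kg)
}

#' A Body Shape Index
#'
#' ABSI = WC / (BMI^(2/3) * H^(1/2)) with waist circumference and height in
#' metres and BMI in kg/m^2 (Krakauer & Krakauer 2012, PLoS ONE 7:e39504).
#' Arguments are taken in centimetres and converted.
#'
#' @param waist_cm Waist circumference, cm.
#' @param bmi Body-mass index, kg/m^2.
#' @param height_cm Height, cm.
#' @return ABSI (m^(11/6) kg^(-2/3)).
#' @export
a_body_shape_index <- function(waist_cm, bmi, height_cm) {
  check_measure(waist_cm, "waist_cm")
  check_measure(bmi, "bmi")
  check_measure(height_cm, "height_cm")
  (waist_cm / 100) / (bmi^(2 / 3) * (height_cm / 100)^(1 / 2))
}

#' Functional and comorbidity scores
#'
#' Builds deficit counts for activities of daily living (5 items: bathing,
#' eating, transferring, toileting, walking across a room) and instrumental
#' activities of daily living (4 items: managing money, taking medication,
#' shopping, preparing meals), dichotomizes self-rated health, and counts
#' self-reported diagnoses out of seven chronic conditions (hypertension,
#' diabetes, myocardial infarction, stroke, cancer, chronic lung disease,
#' arthritis). Multimorbidity is two or more conditions.
#'
#' @param adl_items Logical vector of exactly 5 entries (difficulty present).
#' @param iadl_items Logical vector of exactly 4 entries.
#' @param srh_level Self-rated health, integer 1 (excellent) to 5 (poor).
#' @param diagnoses Logical vector of exactly 7 entries.
#' @param srh_cut `"poor"` (level 5 only, default) or `"fair_or_poor"`
#'   (levels 4-5).
#'
#' @return A list with `adl` (0-5), `iadl` (0-4), `poor_srh`,
#'   `comorbidity_count` (0-7) and `multimorbidity`.
#' @export
score_functionality <- function(adl_items, iadl_items, srh_level, diagnoses,
                                srh_cut = c("poor", "fair_or_poor")) {
  srh_cut <- match.arg(srh_cut)
  if (length(adl_items) != 5L) stop("adl_items must have exactly 5 entries")
  if (length(iadl_items) != 4L) stop("iadl_items must have exactly 4 entries")
  if (length(diagnoses) != 7L) stop("diagnoses must have exactly 7 entries")
  if (length(srh_level) != 1L || !srh_level %in% 1:5)
    stop("srh_level must be a single integer in 1..5")
  cc <- sum(as.logical(diagnoses))
  list(
    adl = sum(as.logical(adl_items)),
    iadl = sum(as.logical(iadl_items)),
    poor_srh = if (srh_cut == "poor") srh_level == 5 else srh_level >= 4,
    comorbidity_count = cc,
    multimorbidity = cc >= 2
  )
}

# eligibility bounds used in the validation analyses (NHANES development
# ranges); inclusive on both ends
eligibility_bounds <- list(
  age = c(50, 94), height_cm = c(125, 200), weight_kg = c(30, 150),
  waist_cm = c(50, 160), bmi = c(10, 60)
)

#' Apply eligibility filters to a panel
#'
#' Keeps rows aged 50-94 with complete mortality follow-up and anthropometry
#' within the ranges the models were developed on (height 125-200 cm, weight
#' 30-150 kg, waist 50-160 cm, BMI 10-60 kg/m^2; all bounds inclusive).
#' Each dropped row is tagged with the first rule it violates, checked in the
#' order: missing mortality data, missing anthropometry, age, height, weight,
#' waist, BMI.
#'
#' @param panel Data frame with columns `age`, `height_cm`, `weight_kg`,
#'   `waist_cm`, `follow_up_years`, `event`; `bmi` is computed when absent.
#' @return A list with `kept` and `dropped` data frames partitioning the
#'   input; `dropped` carries a `reason` column with codes
#'   `mortality_missing`, `anthro_missing`, `age_range`, `height_range`,
#'   `weight_range`, `waist_range`, `bmi_range`.
#' @export
apply_eligibility <- function(panel) {
  req <- c("age", "height_cm", "weight_kg", "waist_cm",
           "follow_up_years", "event")
  miss <- setdiff(req, names(panel))
  if (length(miss))
    stop("panel is missing required column(s): ", paste(miss, collapse = ", "))
  if (!"bmi" %in% names(panel))
    panel$bmi <- panel$weight_kg / (panel$height_cm / 100)^2
  b <- eligibility_bounds
  in_rng <- function(x, r) !is.na(x) & x >= r[1] & x <= r[2]
  reason <- rep(NA_character_, nrow(panel))
  flag <- function(reason, cond, code) ifelse(is.na(reason) & cond, code, reason)
  reason <- flag(reason, is.na(panel$follow_up_years) | is.na(panel$event),
                 "mortality_missing")
  reason <- flag(reason, is.na(panel$height_cm) | is.na(panel$weight_kg) |
                   is.na(panel$waist_cm) | is.na(panel$bmi), "anthro_missing")
  reason <- flag(reason, !in_rng(panel$age, b$age), "age_range")
  reason <- flag(reason, !in_rng(panel$height_cm, b$height_cm), "height_range")
  reason <- flag(reason, !in_rng(panel$weight_kg, b$weight_kg), "weight_range")
  reason <- flag(reason, !in_rng(panel$waist_cm, b$waist_cm), "waist_range")
  reason <- flag(reason, !in_rng(panel$bmi, b$bmi), "bmi_range")
  dropped <- panel[!is.na(reason), , drop = FALSE]
  dropped$reason <- reason[!is.na(reason)]
  list(kept = panel[is.na(reason), , drop = FALSE], dropped = dropped)
}
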