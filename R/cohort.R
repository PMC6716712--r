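#' Weekly alcohol intake in grams from standard drinking units
#'
#' Sums regular weekly consumption in standard drinking units: a glass of
#' wine and a bottle of beer each carry about 10 g of ethanol, a unit of
#' spirits about 20 g.
#'
#' @param wine_glasses,beers,spirits nonnegative weekly counts (vectorized).
#' @return Grams of ethanol per week.
#' @examples
#' alcohol_grams_per_week(7, 0, 0)   # 70
#' alcohol_grams_per_week(0, 0, 14)  # 280
#' @export
alcohol_grams_per_week <- function(wine_glasses, beers, spirits) {
  .check_number(wine_glasses, "wine_glasses", lower = 0)
  .check_number(beers, "beers", lower = 0)
  .check_number(spirits, "spirits", lower = 0)
  10 * wine_glasses + 10 * beers + 20 * spirits
}

#' Drinking category from weekly grams of alcohol
#'
#' Abstainers and occasional drinkers (0 g/wk of regular consumption) form
#' one group; 1–140 g/wk are light, 141–279 g/wk moderate and >= 280 g/wk
#' heavy drinkers.
#'
#' @param grams grams of ethanol per week (vectorized, >= 0).
#' @return Factor with levels `abstainer_occasional`, `light`, `moderate`,
#'   `heavy`.
#' @examples
#' alcohol_category(c(0, 140, 141, 350))
#' @export
alcohol_category <- function(grams) {
  .check_number(grams, "grams", lower = 0)
  lev <- c("abstainer_occasional", "light", "moderate", "heavy")
  out <- ifelse(grams >= 280, "heavy",
         ifelse(grams >= 141, "moderate",
         ifelse(grams >= 1, "light", "abstainer_occasional")))
  factor(out, levels = lev)
}

#' Smoking status
#'
#' Current consumers of at least one cigarette per day are smokers; people
#' who quit within the preceding year (including exactly one year ago) are
#' still counted as smokers; quitting more than a year before assessment
#' makes an ex-smoker; everyone else who never smoked is `never`.
#'
#' @param cigarettes_per_day nonnegative daily count (vectorized).
#' @param years_since_quit years since quitting, `NA` when never quit or
#'   never smoked.
#' @param ever_smoked logical.
#' @return Factor with levels `never`, `ex_smoker`, `smoker`.
#' @examples
#' smoking_category(c(1, 0, 0, 0), c(NA, 0.5, 2, NA), c(TRUE, TRUE, TRUE, FALSE))
#' @export
smoking_category <- function(cigarettes_per_day, years_since_quit, ever_smoked) {
  .check_number(cigarettes_per_day, "cigarettes_per_day", lower = 0)
  n <- max(length(cigarettes_per_day), length(years_since_quit),
           length(ever_smoked))
  cigarettes_per_day <- rep_len(cigarettes_per_day, n)
  years_since_quit <- rep_len(years_since_quit, n)
  ever_smoked <- rep_len(as.logical(ever_smoked), n)
  if (any(cigarettes_per_day >= 1 & !ever_smoked)) {
    .stop_invalid("current smokers must have ever_smoked = TRUE")
  }
  if (any(!is.na(years_since_quit) & years_since_quit > 0 & !ever_smoked)) {
    .stop_invalid("a quit date implies ever_smoked = TRUE")
  }
  out <- ifelse(cigarettes_per_day >= 1, "smoker",
         ifelse(ever_smoked & !is.na(years_since_quit) & years_since_quit <= 1,
                "smoker",
         ifelse(ever_smoked, "ex_smoker", "never")))
  factor(out, levels = c("never", "ex_smoker", "smoker"))
}

#' Body mass index and weight class
#'
#' BMI is weight (kg) divided by squared height (m). Classes: normal weight
#' below 25 kg/m2, overweight 25–30 kg/m2 (inclusive at both printed
#' endpoints), obese above 30 kg/m2.
#'
#' @param weight kg, > 0 (vectorized).
#' @param height m, > 0.
#' @return A data frame with columns `bmi` and `bmi_class` (factor
#'   `normal`/`overweight`/`obese`).
#' @examples
#' bmi_and_class(80, 1.79)
#' @export
bmi_and_class <- function(weight, height) {
  .check_number(weight, "weight", lower = .Machine$double.xmin)
  .check_number(height, "height", lower = .Machine$double.xmin)
  bmi <- weight / height^2
  cls <- ifelse(bmi > 30, "obese", ifelse(bmi >= 25, "overweight", "normal"))
  data.frame(bmi = bmi,
             bmi_class = factor(cls, levels = c("normal", "overweight", "obese")))
}

#' ATP-III metabolic syndrome classification
#'
#' Counts the five Adult Treatment Panel III criteria: abdominal obesity
#' (waist > 102 cm in males, > 88 cm in females); fasting triglycerides
#' >= 150 mg/dL; low HDL cholesterol (< 40 mg/dL males, < 50 mg/dL females);
#' raised blood pressure (>= 130 systolic or >= 85 diastolic, or current
#' antihypertensive medication); and hyperglycemia (fasting glucose
#' >= 110 mg/dL or current antidiabetic therapy). Metabolic syndrome is
#' present when at least three criteria are met.
#'
#' @param sex `"male"`/`"female"` (vectorized).
#' @param waist cm.
#' @param triglycerides,hdl,glucose mg/dL.
#' @param systolic_bp,diastolic_bp mm Hg.
#' @param on_antihypertensives,on_antidiabetics logical.
#' @return A data frame with columns `metsyn_criteria_count` (0–5) and
#'   `metabolic_syndrome` (logical).
#' @examples
#' metabolic_syndrome("male", waist = 103, triglycerides = 150, hdl = 39,
#'                    systolic_bp = 120, diastolic_bp = 80,
#'                    on_antihypertensives = FALSE, glucose = 100,
#'                    on_antidiabetics = FALSE)
#' @export
metabolic_syndrome <- function(sex, waist, triglycerides, hdl,
                               systolic_bp, diastolic_bp,
                               on_antihypertensives, glucose,
                               on_antidiabetics) {
  args <- list(waist = waist, triglycerides = triglycerides, hdl = hdl,
               systolic_bp = systolic_bp, diastolic_bp = diastolic_bp,
               on_antihypertensives = on_antihypertensives,
               glucose = glucose, on_antidiabetics = on_antidiabetics)
  for (nm in names(args)) {
    if (is.null(args[[nm]]) || anyNA(args[[nm]])) {
      .stop_missing(sprintf("metabolic syndrome component `%s` is missing", nm))
    }
  }
  sex <- as.character(sex)
  if (!all(sex %in% c("male", "female"))) {
    .stop_invalid("`sex` must be \"male\" or \"female\"")
  }
  male <- sex == "male"
  c1 <- ifelse(male, waist > 102, waist > 88)
  c2 <- triglycerides >= 150
  c3 <- ifelse(male, hdl < 40, hdl < 50)
  c4 <- systolic_bp >= 130 | diastolic_bp >= 85 | as.logical(on_antihypertensives)
  c5 <- glucose >= 110 | as.logical(on_antidiabetics)
  count <- c1 + c2 + c3 + c4 + c5
  data.frame(metsyn_criteria_count = as.integer(count),
             metabolic_syndrome = count >= 3)
}

# MET coefficients of the IPAQ short-form scoring protocol
.ipaq_met <- c(walking = 3.3, moderate = 4.0, vigorous = 8.0)

#' IPAQ short-form physical-activity score and category
#'
#' Weekly MET-minutes are the intensity-weighted sum over the three IPAQ
#' short-form activity types (walking 3.3 MET, moderate 4.0 MET, vigorous
#' 8.0 MET), each contributing days/week times minutes/day. The category is
#' `high` when vigorous activity occurs on at least 3 days and the total
#' reaches 1500 MET-min/wk, or any combination of activities spans 7 days
#' and reaches 3000 MET-min/wk; `moderate` when vigorous activity occurs on
#' at least 3 days for at least 20 min/day, or moderate activity or walking
#' on at least 5 days for at least 30 min/day, or any combination on at
#' least 5 days totals 600 MET-min/wk; otherwise `low`. High takes
#' precedence over moderate. Activity-days are counted additively across
#' types.
#'
#' @param vigorous_days,moderate_days,walking_days days per week, 0–7
#'   (vectorized).
#' @param vigorous_min,moderate_min,walking_min minutes per day, >= 0.
#' @return A data frame with columns `met_min_per_week` and
#'   `activity_category` (factor `low`/`moderate`/`high`).
#' @examples
#' ipaq_classify(3, 0, 0, 20, 0, 0)   # moderate
#' ipaq_classify(3, 0, 0, 80, 0, 0)   # 1920 MET-min/wk, high
#' @export
ipaq_classify <- function(vigorous_days, moderate_days, walking_days,
                          vigorous_min, moderate_min, walking_min) {
  .check_number(vigorous_days, "vigorous_days", 0, 7)
  .check_number(moderate_days, "moderate_days", 0, 7)
  .check_number(walking_days, "walking_days", 0, 7)
  .check_number(vigorous_min, "vigorous_min", lower = 0)
  .check_number(moderate_min, "moderate_min", lower = 0)
  .check_number(walking_min, "walking_min", lower = 0)
  met <- .ipaq_met[["vigorous"]] * vigorous_days * vigorous_min +
    .ipaq_met[["moderate"]] * moderate_days * moderate_min +
    .ipaq_met[["walking"]] * walking_days * walking_min
  total_days <- vigorous_days + moderate_days + walking_days
  high <- (vigorous_days >= 3 & met >= 1500) |
    (total_days >= 7 & met >= 3000)
  moderate <- (vigorous_days >= 3 & vigorous_min >= 20) |
    (moderate_days >= 5 & moderate_min >= 30) |
    (walking_days >= 5 & walking_min >= 30) |
    (total_days >= 5 & met >= 600)
  cat_ <- ifelse(high, "high", ifelse(moderate, "moderate", "low"))
  data.frame(met_min_per_week = met,
             activity_category = factor(cat_, levels = c("low", "moderate", "high")))
}

# fields required to derive the full covariate set
.required_fields <- c(
  "id", "age", "sex", "wine_glasses_per_week", "beers_per_week",
  "spirits_per_week", "cigarettes_per_day", "ever_smoked",
  "vigorous_days", "moderate_days", "walking_days",
  "vigorous_min_per_day", "moderate_min_per_day", "walking_min_per_day",
  "weight", "height", "waist", "triglycerides", "hdl",
  "systolic_bp", "diastolic_bp", "on_antihypertensives", "on_antidiabetics",
  "glucose", "hemoglobin", "mcv", "esr")

#' Derive lifestyle and metabolic covariates for a cohort
#'
#' Applies all deterministic classification rules (alcohol grams and
#' category, smoking status, IPAQ MET-minutes and activity category, BMI and
#' class, ATP-III metabolic syndrome) to a table of raw participant records.
#' Rows with missing required fields (other than `years_since_quit`, where
#' absence means never quit) are dropped complete-case style with a message
#' reporting the count.
#'
#' @param data data frame with one row per participant; see [read_cohort]
#'   for the expected columns.
#' @return The input joined to the derived columns; attribute `n_dropped`
#'   records how many incomplete rows were excluded.
#' @examples
#' cohort <- simulate_cohort(cohort_config(n_per_stratum = 5), seed = 1)
#' head(derive_covariates(cohort))
#' @export
derive_covariates <- function(data) {
  miss <- setdiff(.required_fields, names(data))
  if (length(miss) > 0) {
    .stop_missing(paste("missing required columns:", paste(miss, collapse = ", ")))
  }
  if (!"years_since_quit" %in% names(data)) data$years_since_quit <- NA_real_
  complete <- stats::complete.cases(data[, setdiff(.required_fields, "id")])
  n_drop <- sum(!complete)
  if (n_drop > 0) {
    message(sprintf("derive_covariates: dropped %d incomplete row(s)", n_drop))
    data <- data[complete, , drop = FALSE]
  }
  .check_number(data$age, "age", 18, 120)
  .check_number(data$esr, "esr", lower = 0)
  grams <- alcohol_grams_per_week(data$wine_glasses_per_week,
                                  data$beers_per_week, data$spirits_per_week)
  bmi <- bmi_and_class(data$weight, data$height)
  ipaq <- ipaq_classify(data$vigorous_days, data$moderate_days,
                        data$walking_days, data$vigorous_min_per_day,
                        data$moderate_min_per_day, data$walking_min_per_day)
  ms <- metabolic_syndrome(data$sex, data$waist, data$triglycerides,
                           data$hdl, data$systolic_bp, data$diastolic_bp,
                           data$on_antihypertensives, data$glucose,
                           data$on_antidiabetics)
  out <- cbind(
    data,
    data.frame(alcohol_g_per_week = grams,
               alcohol_category = alcohol_category(grams),
               smoking_category = smoking_category(data$cigarettes_per_day,
                                                   data$years_since_quit,
                                                   data$ever_smoked)),
    bmi, ipaq, ms)
  attr(out, "n_dropped") <- n_drop
  out
}

#' Read and write cohort tables
#'
#' Thin CSV wrappers: one row per participant, header names matching the
#' raw-record fields, `sex` coded `"male"`/`"female"`, logical flags coded
#' 0/1.
#'
#' @param path file path.
#' @param data cohort data frame.
#' @return `read_cohort` returns a data frame; `write_cohort` writes and
#'   returns `path` invisibly.
#' @export
read_cohort <- function(path) {
  data <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("ever_smoked", "on_antihypertensives", "on_antidiabetics")) {
    if (col %in% names(data)) data[[col]] <- as.logical(data[[col]])
  }
  data
}

#' @rdname read_cohort
#' @export
write_cohort <- function(data, path) {
  out <- data
  for (col in names(out)) {
    if (is.logical(out[[col]])) out[[col]] <- as.integer(out[[col]])
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
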