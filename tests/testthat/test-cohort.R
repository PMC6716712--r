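test_that("weekly alcohol grams follow the standard-unit masses", {
  expect_equal(alcohol_grams_per_week(7, 0, 0), 70)
  expect_equal(alcohol_grams_per_week(0, 0, 0), 0)
  expect_equal(alcohol_grams_per_week(0, 0, 14), 280)
  expect_equal(alcohol_grams_per_week(2, 3, 1), 70)
  expect_error(alcohol_grams_per_week(-1, 0, 0), class = "esr_invalid_input")
})

test_that("drinking categories have their boundaries exactly at 0/140/141/279/280", {
  expect_equal(as.character(alcohol_category(c(0, 1, 140, 141, 279, 280, 350))),
               c("abstainer_occasional", "light", "light", "moderate",
                 "moderate", "heavy", "heavy"))
  expect_error(alcohol_category(-5), class = "esr_invalid_input")
  # monotone non-decreasing in grams
  g <- seq(0, 600, by = 7)
  expect_true(all(diff(as.integer(alcohol_category(g))) >= 0))
})

test_that("smoking status handles quitting boundaries and partitions all consistent inputs", {
  expect_equal(as.character(smoking_category(1, NA, TRUE)), "smoker")
  expect_equal(as.character(smoking_category(0, 0.5, TRUE)), "smoker")
  expect_equal(as.character(smoking_category(0, 1, TRUE)), "smoker")  # quit exactly a year ago
  expect_equal(as.character(smoking_category(0, 2, TRUE)), "ex_smoker")
  expect_equal(as.character(smoking_category(0, NA, FALSE)), "never")
  expect_error(smoking_category(5, NA, FALSE), class = "esr_invalid_input")
  # exhaustive & exclusive over a consistent input grid
  grid <- expand.grid(cigs = c(0, 1, 20), ysq = c(NA, 0.2, 1, 1.5, 10),
                      ever = c(TRUE, FALSE))
  ok <- !(grid$cigs >= 1 & !grid$ever) & !(!is.na(grid$ysq) & !grid$ever)
  res <- smoking_category(grid$cigs[ok], grid$ysq[ok], grid$ever[ok])
  expect_false(anyNA(res))
  expect_true(all(res %in% c("never", "ex_smoker", "smoker")))
})

test_that("BMI classes honour both printed interval endpoints", {
  r <- bmi_and_class(80, 1.79)
  expect_equal(r$bmi, 80 / 1.79^2, tolerance = 1e-12)
  expect_lt(abs(r$bmi - 24.97), 0.005)
  expect_equal(as.character(r$bmi_class), "normal")
  expect_equal(as.character(bmi_and_class(25 * 4, 2)$bmi_class), "overweight")
  expect_equal(as.character(bmi_and_class(30 * 4, 2)$bmi_class), "overweight")
  expect_equal(as.character(bmi_and_class(30.5 * 4, 2)$bmi_class), "obese")
  expect_error(bmi_and_class(80, 0), class = "esr_invalid_input")
})

test_that("metabolic syndrome counts the five ATP-III criteria at their printed thresholds", {
  r <- metabolic_syndrome("male", waist = 103, triglycerides = 150, hdl = 39,
                          systolic_bp = 120, diastolic_bp = 80,
                          on_antihypertensives = FALSE, glucose = 100,
                          on_antidiabetics = FALSE)
  expect_equal(r$metsyn_criteria_count, 3L)
  expect_true(r$metabolic_syndrome)
  # waist 88 is not > 88: a female at every threshold's safe side scores 0
  r <- metabolic_syndrome("female", waist = 88, triglycerides = 100, hdl = 60,
                          systolic_bp = 110, diastolic_bp = 70,
                          on_antihypertensives = FALSE, glucose = 90,
                          on_antidiabetics = FALSE)
  expect_equal(r$metsyn_criteria_count, 0L)
  expect_false(r$metabolic_syndrome)
  r <- metabolic_syndrome("male", waist = 110, triglycerides = 200, hdl = 30,
                          systolic_bp = 150, diastolic_bp = 95,
                          on_antihypertensives = TRUE, glucose = 130,
                          on_antidiabetics = TRUE)
  expect_equal(r$metsyn_criteria_count, 5L)
  expect_true(r$metabolic_syndrome)
  expect_error(
    metabolic_syndrome("male", waist = NA, triglycerides = 100, hdl = 50,
                       systolic_bp = 120, diastolic_bp = 80,
                       on_antihypertensives = FALSE, glucose = 90,
                       on_antidiabetics = FALSE),
    class = "esr_missing_data")
})

test_that("metabolic syndrome agrees with an independent brute-force evaluation on random records", {
  set.seed(77)
  n <- 200
  sex <- sample(c("male", "female"), n, TRUE)
  waist <- runif(n, 60, 130); tg <- runif(n, 40, 400)
  hdl <- runif(n, 20, 90); sbp <- runif(n, 90, 190); dbp <- runif(n, 50, 110)
  ah <- runif(n) < 0.2; glu <- runif(n, 60, 220); ad <- runif(n) < 0.1
  got <- metabolic_syndrome(sex, waist, tg, hdl, sbp, dbp, ah, glu, ad)
  # independent re-implementation, one record at a time
  for (i in seq_len(n)) {
    crit <- c(
      if (sex[i] == "male") waist[i] > 102 else waist[i] > 88,
      tg[i] >= 150,
      if (sex[i] == "male") hdl[i] < 40 else hdl[i] < 50,
      sbp[i] >= 130 || dbp[i] >= 85 || ah[i],
      glu[i] >= 110 || ad[i])
    expect_equal(got$metsyn_criteria_count[i], sum(crit))
    expect_equal(got$metabolic_syndrome[i], sum(crit) >= 3)
  }
})

test_that("IPAQ scoring applies the MET coefficients and the category precedence", {
  r <- ipaq_classify(3, 0, 0, 20, 0, 0)
  expect_equal(as.character(r$activity_category), "moderate")
  r <- ipaq_classify(3, 0, 0, 80, 0, 0)
  expect_equal(r$met_min_per_week, 3 * 80 * 8.0)
  expect_equal(as.character(r$activity_category), "high")
  r <- ipaq_classify(0, 0, 0, 0, 0, 0)
  expect_equal(r$met_min_per_week, 0)
  expect_equal(as.character(r$activity_category), "low")
  # 7 days of combined activity totalling >= 3000 MET-min/wk
  r <- ipaq_classify(0, 3, 4, 0, 120, 120)
  expect_gte(r$met_min_per_week, 3000)
  expect_equal(as.character(r$activity_category), "high")
  expect_error(ipaq_classify(8, 0, 0, 10, 0, 0), class = "esr_invalid_input")
})

test_that("IPAQ categories are exhaustive and never low when the 600 MET-min rule fires", {
  set.seed(13)
  g <- data.frame(vd = sample(0:7, 400, TRUE), md = sample(0:7, 400, TRUE),
                  wd = sample(0:7, 400, TRUE), vm = sample(0:120, 400, TRUE),
                  mm = sample(0:120, 400, TRUE), wm = sample(0:120, 400, TRUE))
  r <- ipaq_classify(g$vd, g$md, g$wd, g$vm, g$mm, g$wm)
  expect_false(anyNA(r$activity_category))
  fires600 <- (g$vd + g$md + g$wd) >= 5 & r$met_min_per_week >= 600
  expect_false(any(fires600 & r$activity_category == "low"))
})

test_that("derive_covariates validates inputs and drops incomplete rows with a count", {
  cohort <- simulate_cohort(cohort_config(n_per_stratum = 10), seed = 2)
  expect_error(derive_covariates(cohort[, -which(names(cohort) == "esr")]),
               class = "esr_missing_data")
  cohort$hdl[3] <- NA
  expect_message(d <- derive_covariates(cohort), "dropped 1 incomplete")
  expect_equal(attr(d, "n_dropped"), 1L)
  expect_equal(nrow(d), nrow(cohort) - 1)
})

test_that("cohort CSV round-trips through the readers", {
  cohort <- simulate_cohort(cohort_config(n_per_stratum = 5), seed = 8)
  path <- tempfile(fileext = ".csv")
  write_cohort(cohort, path)
  back <- read_cohort(path)
  expect_equal(back$esr, cohort$esr, tolerance = 1e-12)
  expect_identical(back$ever_smoked, cohort$ever_smoked)
  expect_identical(back$sex, cohort$sex)
  unlink(path)
})
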