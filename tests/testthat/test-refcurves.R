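test_that("percentile curves are ordered in p and follow a positive age effect", {
  cfg <- female_config(150, age_effect = list(type = "linear", coef = 0.012))
  ch <- derive_quiet(simulate_cohort(cfg, seed = 81))
  f <- fit_esr(ch, model_spec(mu = c(age = "linear")))
  grid <- seq(20, 88, by = 4)
  c90 <- percentile_curve(f, "female", age_grid = grid, p = 0.90)
  c975 <- percentile_curve(f, "female", age_grid = grid, p = 0.975)
  expect_true(all(c975$value > c90$value))
  c50 <- percentile_curve(f, "female", age_grid = grid, p = 0.5)
  expect_true(all(diff(c50$value) >= 0))
  expect_error(percentile_curve(f, "female", age_grid = grid, p = 1.2),
               class = "esr_domain_error")
})

test_that("the median curve of a calibrated zero-effect cohort sits near the printed female median", {
  cfg <- female_config(400)
  ch <- derive_quiet(simulate_cohort(cfg, seed = 83))
  f <- fit_esr(ch, model_spec())
  c50 <- percentile_curve(f, "female", age_grid = 45, p = 0.5)
  expect_lt(abs(c50$value - 12), 0.8)  # Monte-Carlo tolerance at n = 2800
})

test_that("reference tables are monotone across percentiles and match a truth-averaged oracle", {
  cfg <- female_config(250)
  ch <- derive_quiet(simulate_cohort(cfg, seed = 85))
  f <- fit_esr(ch, model_spec())
  rt <- reference_table(f, ch)
  rows <- rt[rt$n > 0, ]
  expect_true(all(rows$P90 <= rows$P95 & rows$P95 <= rows$P97.5))
  expect_equal(sum(rt$n), nrow(ch))
  # oracle: every female shares the calibrated truth parameters, so the
  # cell average equals the truth quantile up to estimation error
  truth <- calibrated_female()
  for (p in c(0.90, 0.95, 0.975)) {
    qt <- qgig(p, truth$mu, truth$sigma, truth$nu)
    col <- paste0("P", format(100 * p, drop0trailing = TRUE))
    expect_lt(max(abs(rows[[col]] - qt)) / qt, 0.06)
  }
})

test_that("reference tables are invariant to row order and handle single-member and empty cells", {
  cfg <- cohort_config(n_per_stratum = 80)
  ch <- derive_quiet(simulate_cohort(cfg, seed = 87))
  f <- fit_esr(ch, model_spec(mu = c(sex = "linear", age = "linear")))
  rt1 <- reference_table(f, ch)
  set.seed(3)
  rt2 <- reference_table(f, ch[sample(nrow(ch)), ])
  expect_equal(rt1[order(rt1$sex, rt1$age_group), ],
               rt2[order(rt2$sex, rt2$age_group), ],
               tolerance = 1e-10, ignore_attr = TRUE)
  # one subject per cell reproduces that subject's own predicted quantiles
  one <- ch[ch$sex == "female", ][1, ]
  pr <- predict(f, one)
  rt_one <- suppressWarnings(reference_table(f, one))
  row <- rt_one[rt_one$n == 1, ]
  expect_equal(row$P97.5, round(qgig(0.975, pr$mu, pr$sigma, pr$nu), 1))
  expect_warning(reference_table(f, one), "empty reference cell")
  expect_true(all(is.na(rt_one$P95[rt_one$n == 0])))
})

test_that("exceedance counting uses sex-specific thresholds with strict inequality", {
  cohort <- data.frame(
    sex = c(rep("male", 3), rep("female", 3)),
    esr = c(20, 20.5, 5, 30, 31, 12))
  r <- count_exceedances(cohort)
  expect_equal(r$count, 2)  # 20 and 30 sit exactly at threshold: not counted
  expect_equal(r$percent, 33.3)
  r0 <- count_exceedances(data.frame(sex = rep("male", 4), esr = rep(1, 4)))
  expect_equal(r0$count, 0)
  expect_equal(r0$percent, 0)
  expect_error(count_exceedances(data.frame(esr = 1)),
               class = "esr_missing_data")
})

test_that("Mann-Whitney U matches exact enumeration and the established implementation", {
  r <- mann_whitney(c(1, 2, 3), c(4, 5, 6), alternative = "less")
  expect_equal(r$U, 0)
  expect_equal(r$p.value, 0.05)  # 1 of choose(6,3) = 20 orderings
  expect_true(r$exact)
  # identical groups under midranks: U = n1 n2 / 2
  r2 <- mann_whitney(c(2, 2, 2), c(2, 2, 2))
  expect_equal(r2$U, 4.5)
  # agreement with wilcox.test across all sizes n1 + n2 <= 12 (no ties)
  set.seed(91)
  for (n1 in 2:5) {
    for (n2 in 2:min(6, 12 - n1)) {
      x <- rnorm(n1); y <- rnorm(n2)
      ours <- mann_whitney(x, y)
      ref <- wilcox.test(x, y, exact = TRUE)
      expect_equal(ours$U, unname(ref$statistic))
      expect_equal(ours$p.value, ref$p.value, tolerance = 1e-12)
    }
  }
  # large-sample normal approximation with ties
  set.seed(92)
  x <- sample(1:10, 60, TRUE); y <- sample(3:12, 50, TRUE)
  ours <- mann_whitney(x, y)
  ref <- suppressWarnings(wilcox.test(x, y, correct = TRUE))
  expect_false(ours$exact)
  expect_equal(ours$p.value, ref$p.value, tolerance = 1e-6)
})

test_that("group summaries report quartiles per level and rank tests against the reference level", {
  cfg <- cohort_config(n_per_stratum = 120)
  ch <- derive_quiet(simulate_cohort(cfg, seed = 93))
  gs <- group_summaries(ch, "sex")
  expect_setequal(gs$level, c("male", "female"))
  expect_true(is.na(gs$p_vs_ref[1]))
  expect_lt(gs$p_vs_ref[2], 0.001)  # 2-fold sex difference is obvious
  fem <- gs[gs$level == "female", ]
  expect_equal(fem$median, median(ch$esr[ch$sex == "female"]))
  d <- derive_quiet(simulate_cohort(cohort_config(n_per_stratum = 40), seed = 94))
  gs3 <- group_summaries(d, "alcohol_category")
  expect_equal(nrow(gs3), nlevels(d$alcohol_category))
  expect_warning(group_summaries(ch[ch$sex == "male", ], "sex"),
                 "single-level")
})
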