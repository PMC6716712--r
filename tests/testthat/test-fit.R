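test_that("intercept-only fit recovers the generating parameters within 3 standard errors", {
  truth <- gig_params(11, 1.05, -0.35)
  y <- rgig(1e4, truth$mu, truth$sigma, truth$nu, seed = 101)
  f <- fit_esr(data.frame(esr = y), model_spec())
  est <- c(unname(f$coefficients$mu), unname(f$coefficients$sigma), f$nu)
  nll <- function(th) -sum(dgig(y, exp(th[1]), exp(th[2]), th[3], log = TRUE))
  H <- fd_hessian(nll, est)
  se <- sqrt(diag(solve(H)))
  tr <- c(log(truth$mu), log(truth$sigma), truth$nu)
  expect_true(all(abs(est - tr) < 3 * se))
})

test_that("the P-spline collapses to the linear fit as smoothing grows and beats it as smoothing vanishes", {
  cfg <- female_config(120, age_effect = list(type = "linear", coef = 0.012))
  ch <- derive_quiet(simulate_cohort(cfg, seed = 41))
  f_lin <- fit_esr(ch, model_spec(mu = c(age = "linear")))
  f_inf <- fit_esr(ch, model_spec(mu = c(age = "pspline")),
                   lambda = c(mu.age = 1e10))
  expect_lt(abs(f_inf$loglik - f_lin$loglik), 1e-4)
  f_0 <- fit_esr(ch, model_spec(mu = c(age = "pspline")),
                 lambda = c(mu.age = 1e-2))
  expect_gte(f_0$loglik, f_lin$loglik - 1e-6)
})

test_that("adding a term never decreases the unpenalized log-likelihood", {
  cfg <- cohort_config(n_per_stratum = 100)
  ch <- derive_quiet(simulate_cohort(cfg, seed = 43))
  f0 <- fit_esr(ch, model_spec())
  f1 <- fit_esr(ch, model_spec(mu = c(sex = "linear")))
  f2 <- fit_esr(ch, model_spec(mu = c(sex = "linear", age = "linear")))
  expect_gte(f1$loglik, f0$loglik - 1e-6)
  expect_gte(f2$loglik, f1$loglik - 1e-6)
})

test_that("BIC follows its defining formula and penalizes extra df", {
  mock <- structure(list(loglik = -100, edf = 3, n = 100), class = "esr_fit")
  expect_equal(BIC(mock), 200 + 3 * log(100), tolerance = 1e-10)
  cfg <- female_config(60)
  ch <- derive_quiet(simulate_cohort(cfg, seed = 47))
  f <- fit_esr(ch, model_spec(mu = c(age = "linear")))
  expect_equal(f$bic, -2 * f$loglik + f$edf * log(f$n), tolerance = 1e-10)
  mock2 <- structure(list(loglik = -100, edf = 5, n = 100), class = "esr_fit")
  expect_gt(BIC(mock2), BIC(mock))
})

test_that("the fit is invariant to row order and to recoding of the categorical dummies", {
  cfg <- cohort_config(n_per_stratum = 60)
  ch <- derive_quiet(simulate_cohort(cfg, seed = 53))
  f1 <- fit_esr(ch, model_spec(mu = c(sex = "linear", age = "linear")))
  set.seed(1)
  f2 <- fit_esr(ch[sample(nrow(ch)), ],
                model_spec(mu = c(sex = "linear", age = "linear")))
  expect_lt(abs(f1$loglik - f2$loglik), 1e-6)
  # flip the reference level of sex: same maximized likelihood
  ch_flip <- ch
  ch_flip$sex <- factor(ch_flip$sex, levels = c("male", "female"))
  f3 <- fit_esr(ch_flip, model_spec(mu = c(sex = "linear", age = "linear")))
  expect_lt(abs(f1$loglik - f3$loglik), 1e-6)
  expect_equal(unname(f1$coefficients$mu["sexmale"]),
               -unname(f3$coefficients$mu["sexfemale"]), tolerance = 1e-4)
})

test_that("rank deficiency is reported with the collinear terms named", {
  cfg <- female_config(30)
  ch <- derive_quiet(simulate_cohort(cfg, seed = 59))
  ch$age_copy <- ch$age
  err <- tryCatch(
    fit_esr(ch, model_spec(mu = c(age = "linear", age_copy = "linear"))),
    error = function(e) e)
  expect_s3_class(err, "esr_invalid_input")
  expect_match(conditionMessage(err), "age_copy")
})

test_that("model selection returns a single candidate trivially and ranks by BIC", {
  cfg <- female_config(60)
  ch <- derive_quiet(simulate_cohort(cfg, seed = 61))
  s1 <- select_model(ch, list(only = model_spec()))
  expect_equal(s1$ranking$model, "only")
  expect_s3_class(s1$best, "esr_fit")
  s2 <- select_model(ch, list(a = model_spec(), b = model_spec(mu = c(age = "linear"))))
  expect_equal(s2$ranking$bic, sort(s2$ranking$bic))
  expect_equal(s2$best$bic, min(s2$ranking$bic))
  expect_error(select_model(ch, list()), class = "esr_invalid_input")
})

test_that("quantile residuals are clamped, centred under the truth and flag gross misspecification", {
  cfg <- female_config(200)
  ch <- derive_quiet(simulate_cohort(cfg, seed = 67))
  f <- fit_esr(ch, model_spec())
  r <- quantile_residuals(f)
  expect_length(r, f$n)
  expect_true(all(is.finite(r)))
  expect_lt(abs(mean(r)), 0.1)
  expect_gt(var(r), 0.8); expect_lt(var(r), 1.2)
  # an ignored 2-fold sex effect leaves a clear signature in the residuals
  eff_cfg <- cohort_config(n_per_stratum = 200)
  ch2 <- derive_quiet(simulate_cohort(eff_cfg, seed = 68))
  f2 <- fit_esr(ch2, model_spec())  # omits sex
  r2 <- quantile_residuals(f2)
  expect_lt(mann_whitney(r2[ch2$sex == "male"],
                         r2[ch2$sex == "female"])$p.value, 1e-10)
})

test_that("worm plot geometry: null data inside the band, shifts show up, bands shrink with n", {
  set.seed(71)
  # single worms drift as a whole (order statistics are correlated), so the
  # null coverage is assessed as an average over replicates
  inside <- mean(replicate(20, {
    w <- worm_plot_data(rnorm(1e4))
    mean(w$deviation >= w$lower & w$deviation <= w$upper)
  }))
  expect_gte(inside, 0.90)
  z <- rnorm(1e4)
  w <- worm_plot_data(z)
  w_shift <- worm_plot_data(z + 1)
  expect_gt(mean(w_shift$deviation > 0), 0.99)
  w_small <- worm_plot_data(rnorm(100))
  expect_gt(mean(w_small$upper - w_small$lower),
            mean(w$upper - w$lower))
  expect_error(worm_plot_data(rnorm(10)), class = "esr_invalid_input")
  w_thin <- worm_plot_data(z, n_points = 50)
  expect_lte(nrow(w_thin), 50)
})

test_that("per-subject parameter prediction matches training fits and names missing covariates", {
  cfg <- cohort_config(n_per_stratum = 50)
  ch <- derive_quiet(simulate_cohort(cfg, seed = 73))
  f <- fit_esr(ch, model_spec(mu = c(age = "linear", sex = "linear")))
  pr <- predict(f, ch)
  expect_equal(pr$mu, f$fitted$mu, tolerance = 1e-10)
  err <- tryCatch(predict(f, data.frame(age = 40)), error = function(e) e)
  expect_s3_class(err, "esr_missing_data")
  expect_match(conditionMessage(err), "sex")
})
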