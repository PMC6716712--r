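# Shared oracles and fixture builders. Everything is generated in code at
# test time; no stored data.

# Textbook inverse-Gaussian density with mean m and shape l: the closed-form
# limit of the mean-parameterized GIG at nu = -1/2 (shape = mu / sigma^2).
ig_density <- function(y, m, l) {
  sqrt(l / (2 * pi * y^3)) * exp(-l * (y - m)^2 / (2 * m^2 * y))
}

# Central-difference Hessian of a scalar function (independent of the
# package's internals).
fd_hessian <- function(fn, x, h = 1e-4) {
  p <- length(x)
  H <- matrix(NA_real_, p, p)
  for (i in seq_len(p)) {
    for (j in seq_len(i)) {
      hi <- h * max(1, abs(x[i])); hj <- h * max(1, abs(x[j]))
      xpp <- x; xpp[i] <- xpp[i] + hi; xpp[j] <- xpp[j] + hj
      xpm <- x; xpm[i] <- xpm[i] + hi; xpm[j] <- xpm[j] - hj
      xmp <- x; xmp[i] <- xmp[i] - hi; xmp[j] <- xmp[j] + hj
      xmm <- x; xmm[i] <- xmm[i] - hi; xmm[j] <- xmm[j] - hj
      H[i, j] <- H[j, i] <- (fn(xpp) - fn(xpm) - fn(xmp) + fn(xmm)) /
        (4 * hi * hj)
    }
  }
  H
}

# Effect vector with every covariate effect switched off.
zero_effects <- function() {
  stats::setNames(numeric(11),
    c("smoking_ex_smoker", "smoking_smoker", "alcohol_light",
      "alcohol_moderate", "alcohol_heavy", "activity_moderate",
      "activity_high", "bmi_overweight", "bmi_obese", "metsyn",
      "hemoglobin"))
}

# A single-sex cohort configuration under which the constant-shape GIG
# family is exactly specified (each sex has its own calibrated nu).
female_config <- function(n_per_stratum, age_effect = list(type = "none"),
                          effects_mu = zero_effects(), ...) {
  cohort_config(n_per_stratum = n_per_stratum, male_fraction = 0,
                age_effect = age_effect, effects_mu = effects_mu, ...)
}

derive_quiet <- function(x) suppressMessages(derive_covariates(x))

# calibrated baselines are deterministic; cache them for the whole suite
calibrated_female <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- gig_calibrate_quantiles(c(.25, .5, .75), c(7, 12, 21))
    val
  }
})
calibrated_male <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- gig_calibrate_quantiles(c(.25, .5, .75), c(3, 6, 12))
    val
  }
})
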