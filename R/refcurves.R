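#' Percentile curve of ESR over age
#'
#' Evaluates the fitted GIG p-quantile along an age grid for one sex and a
#' fixed profile of any further model covariates:
#' `q_p(age) = qgig(p; mu(age, sex, profile), sigma(.), nu)`.
#'
#' @param fitted an `esr_fit`.
#' @param sex `"male"` or `"female"`.
#' @param covariate_profile one-row data frame (or named list) supplying
#'   every remaining model covariate; may be empty when the model uses only
#'   age and sex.
#' @param age_grid numeric vector of ages.
#' @param p a single probability in (0, 1).
#' @return Data frame with columns `age`, `sex`, `p`, `value` (mm/h).
#' @export
percentile_curve <- function(fitted, sex, covariate_profile = list(),
                             age_grid = 18:90, p = 0.5) {
  stopifnot(inherits(fitted, "esr_fit"))
  if (length(p) != 1 || p <= 0 || p >= 1) {
    .stop_domain("`p` must be a single probability in (0, 1)")
  }
  nd <- as.data.frame(covariate_profile, stringsAsFactors = FALSE)
  if (nrow(nd) == 0) nd <- data.frame(row.names = 1)
  nd <- nd[rep(1, length(age_grid)), , drop = FALSE]
  nd$age <- age_grid
  nd$sex <- sex
  par <- predict(fitted, nd)
  q <- qgig(p, par$mu, par$sigma, fitted$nu)
  data.frame(age = age_grid, sex = sex, p = p, value = q)
}

#' Age-and-sex percentile reference table
#'
#' For each (sex, age-bin) cell, computes every member's predicted
#' p-quantile from their fitted per-subject GIG parameters and averages
#' within the cell — the "average predicted value within each age-and-sex
#' group". The alternative `method = "midpoint"` evaluates the quantiles at
#' the bin midpoint age under a supplied reference covariate profile
#' instead of averaging members.
#'
#' @param fitted an `esr_fit`.
#' @param cohort data frame of the cohort the table describes; must contain
#'   `sex`, `age` and the model covariates.
#' @param age_breaks increasing break points partitioning the cohort age
#'   range; default bins 18–35, 36–50, 51–65, >65.
#' @param ps probabilities reported as columns (default 0.90, 0.95, 0.975).
#' @param method `"average"` (default) or `"midpoint"`.
#' @param profile reference covariate profile for `method = "midpoint"`.
#' @return Data frame of class `"reference_table"` keyed by (sex,
#'   age_group) with `n` and one column per percentile (mm/h, reported to
#'   one decimal). Empty cells yield `n = 0`, `NA` percentiles and a
#'   warning.
#' @export
reference_table <- function(fitted, cohort,
                            age_breaks = c(18, 35, 50, 65, Inf),
                            ps = c(0.90, 0.95, 0.975),
                            method = c("average", "midpoint"),
                            profile = list()) {
  stopifnot(inherits(fitted, "esr_fit"))
  method <- match.arg(method)
  if (is.unsorted(age_breaks, strictly = TRUE)) {
    .stop_invalid("`age_breaks` must be strictly increasing")
  }
  if (min(cohort$age) < age_breaks[1] || max(cohort$age) > age_breaks[length(age_breaks)]) {
    .stop_invalid("`age_breaks` must span the cohort age range")
  }
  grp <- cut(cohort$age, age_breaks, include.lowest = TRUE, right = TRUE)
  par <- predict(fitted, cohort)
  cells <- expand.grid(sex = c("male", "female"), age_group = levels(grp),
                       stringsAsFactors = FALSE)
  qcols <- paste0("P", format(100 * ps, trim = TRUE, drop0trailing = TRUE))
  out <- cells
  out$n <- 0L
  for (qc in qcols) out[[qc]] <- NA_real_
  qhat <- matrix(unlist(lapply(ps, function(p)
    qgig(rep(p, nrow(par)), par$mu, par$sigma, fitted$nu))), nrow = nrow(par))
  for (i in seq_len(nrow(cells))) {
    idx <- which(cohort$sex == cells$sex[i] & grp == cells$age_group[i])
    out$n[i] <- length(idx)
    if (length(idx) == 0) {
      warning(sprintf("empty reference cell: %s, %s",
                      cells$sex[i], cells$age_group[i]))
      next
    }
    if (method == "average") {
      vals <- colMeans(qhat[idx, , drop = FALSE])
    } else {
      b <- which(levels(grp) == cells$age_group[i])
      hi <- if (is.finite(age_breaks[b + 1])) age_breaks[b + 1] else
        max(cohort$age)
      mid <- (age_breaks[b] + hi) / 2
      nd <- as.data.frame(profile, stringsAsFactors = FALSE)
      if (nrow(nd) == 0) nd <- data.frame(row.names = 1)
      nd$age <- mid; nd$sex <- cells$sex[i]
      pp <- predict(fitted, nd)
      vals <- vapply(ps, function(p) qgig(p, pp$mu, pp$sigma, fitted$nu),
                     numeric(1))
    }
    out[i, qcols] <- round(vals, 1)
  }
  structure(out, class = c("reference_table", "data.frame"))
}

#' Count ESR values above the sex-specific laboratory threshold
#'
#' Counts members whose ESR strictly exceeds their sex's routine laboratory
#' upper reference limit (default 20 mm/h for males, 30 mm/h for females).
#'
#' @param cohort data frame with columns `esr` and `sex`.
#' @param male_threshold,female_threshold upper limits in mm/h.
#' @return List with `count` and `percent` (one decimal).
#' @examples
#' cohort <- data.frame(sex = c("male", "female"), esr = c(25, 25))
#' count_exceedances(cohort)
#' @export
count_exceedances <- function(cohort, male_threshold = 20,
                              female_threshold = 30) {
  if (is.null(cohort$sex) || anyNA(cohort$sex)) {
    .stop_missing("`sex` is missing")
  }
  if (is.null(cohort$esr) || anyNA(cohort$esr)) {
    .stop_missing("`esr` is missing")
  }
  thr <- ifelse(cohort$sex == "male", male_threshold, female_threshold)
  count <- sum(cohort$esr > thr)
  list(count = count, percent = round(100 * count / nrow(cohort), 1))
}

#' Mann-Whitney rank-sum test
#'
#' The U statistic from midranks, with the exact p-value by full
#' enumeration of all group assignments when `n1 + n2 <= exact_max`, and
#' the tie-corrected normal approximation (with continuity correction)
#' otherwise.
#'
#' @param x,y numeric samples.
#' @param alternative `"two.sided"`, `"less"` or `"greater"` (of `x`
#'   relative to `y`).
#' @param exact_max largest combined sample size for which the permutation
#'   distribution is fully enumerated (default 12).
#' @return List with `U` (for the first sample), `p.value`, `exact`.
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6), alternative = "less")
#' @export
mann_whitney <- function(x, y, alternative = c("two.sided", "less", "greater"),
                         exact_max = 12) {
  alternative <- match.arg(alternative)
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1 || n2 < 1) .stop_invalid("both samples must be non-empty")
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (n1 + n2 <= exact_max) {
    combs <- utils::combn(n1 + n2, n1)
    Us <- apply(combs, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
    p_le <- mean(Us <= U)
    p_ge <- mean(Us >= U)
    p <- switch(alternative,
                less = p_le, greater = p_ge,
                two.sided = min(1, 2 * min(p_le, p_ge)))
    list(U = U, p.value = p, exact = TRUE)
  } else {
    m <- n1 * n2 / 2
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / ((n1 + n2) * (n1 + n2 - 1))
    v <- n1 * n2 / 12 * (n1 + n2 + 1 - tie_term)
    zl <- (U + 0.5 - m) / sqrt(v)
    zg <- (U - 0.5 - m) / sqrt(v)
    p <- switch(alternative,
                less = stats::pnorm(zl),
                greater = stats::pnorm(zg, lower.tail = FALSE),
                two.sided = min(1, 2 * min(stats::pnorm(zl),
                                           stats::pnorm(zg, lower.tail = FALSE))))
    list(U = U, p.value = p, exact = FALSE)
  }
}

#' Group summaries with rank tests
#'
#' Median, quartiles and group size of a numeric variable per level of a
#' grouping covariate. With exactly two non-empty levels a Mann-Whitney
#' comparison is reported; with more levels each level is compared against
#' the first (reference) level. A single-level grouping returns summaries
#' only, with a warning.
#'
#' @param cohort data frame.
#' @param grouping name of the grouping column.
#' @param variable name of the numeric column (default `"esr"`).
#' @return Data frame with one row per level: `n`, `median`, `q25`, `q75`
#'   and `p_vs_ref` (NA for the reference level).
#' @export
group_summaries <- function(cohort, grouping, variable = "esr") {
  g <- cohort[[grouping]]
  v <- cohort[[variable]]
  if (is.null(g)) .stop_missing(sprintf("grouping `%s` not found", grouping))
  if (is.null(v)) .stop_missing(sprintf("variable `%s` not found", variable))
  g <- if (is.factor(g)) droplevels(g) else factor(g)
  lev <- levels(g)
  out <- data.frame(
    level = lev,
    n = as.integer(table(g)[lev]),
    median = vapply(lev, function(l) stats::median(v[g == l]), numeric(1)),
    q25 = vapply(lev, function(l) unname(stats::quantile(v[g == l], 0.25)),
                 numeric(1)),
    q75 = vapply(lev, function(l) unname(stats::quantile(v[g == l], 0.75)),
                 numeric(1)),
    p_vs_ref = NA_real_,
    row.names = NULL)
  if (length(lev) < 2) {
    warning("single-level grouping: rank test skipped")
    return(out)
  }
  for (i in seq_along(lev)[-1]) {
    out$p_vs_ref[i] <- mann_whitney(v[g == lev[i]], v[g == lev[1]])$p.value
  }
  out
}
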