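#' Model specification for GIG distributional regression
#'
#' Describes how the location (`mu`) and scale (`sigma`) of the
#' mean-parameterized GIG response depend on covariates. Both parameters are
#' linked through logs, which keeps them positive for any coefficient
#' values; the shape `nu` is a single constant. Each covariate enters a
#' predictor as one of three forms: `"constant"` (excluded — the parameter
#' does not vary with it), `"linear"` (a linear term; factors become
#' treatment-coded dummies), or `"pspline"` (a cubic B-spline with equally
#' spaced interior knots and a difference penalty on adjacent coefficients;
#' continuous covariates only). The spline smoothing parameter is chosen by
#' minimizing BIC over a log-spaced grid.
#'
#' @param response response column name (default `"esr"`).
#' @param mu,sigma named character vectors mapping covariate names to forms,
#'   e.g. `c(age = "pspline", sex = "linear")`. Empty means intercept-only.
#' @param knots number of interior spline knots (default 20).
#' @param degree B-spline degree (default 3, cubic).
#' @param penalty_order order of the difference penalty (default 2).
#' @param lambda_grid log-spaced candidate smoothing parameters.
#' @return An object of class `"esr_spec"`.
#' @examples
#' model_spec(mu = c(age = "pspline", sex = "linear"))
#' @export
model_spec <- function(response = "esr", mu = character(), sigma = character(),
                       knots = 20, degree = 3, penalty_order = 2,
                       lambda_grid = 10^seq(-2, 6, length.out = 7)) {
  mu <- unlist(mu); sigma <- unlist(sigma)
  for (trm in list(mu, sigma)) {
    if (length(trm) > 0) {
      if (is.null(names(trm)) || any(names(trm) == "")) {
        .stop_invalid("model terms must be named: c(covariate = form)")
      }
      if (!all(trm %in% c("constant", "linear", "pspline"))) {
        .stop_invalid("term forms must be constant, linear or pspline")
      }
      if (anyDuplicated(names(trm))) {
        .stop_invalid("each covariate may appear at most once per predictor")
      }
    }
  }
  structure(list(response = response, mu = mu, sigma = sigma,
                 knots = knots, degree = degree,
                 penalty_order = penalty_order, lambda_grid = lambda_grid),
            class = "esr_spec")
}

#' @export
print.esr_spec <- function(x, ...) {
  fmt <- function(tr) if (length(tr) == 0) "1 (intercept only)" else
    paste(sprintf("%s(%s)", tr, names(tr)), collapse = " + ")
  cat("GIG distributional regression spec\n")
  cat("  response:", x$response, "\n")
  cat("  log(mu) ~", fmt(x$mu), "\n")
  cat("  log(sigma) ~", fmt(x$sigma), "\n")
  cat("  nu ~ 1\n")
  invisible(x)
}

# Build a design matrix plus penalty bookkeeping for one predictor.
# Spline bases are column-centred through a QR null-space reparameterization
# so they are identifiable next to the intercept.
.build_design <- function(data, terms, spec) {
  n <- nrow(data)
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  penalties <- list()
  info <- list()
  for (nm in names(terms)) {
    form <- terms[[nm]]
    if (form == "constant") next
    if (!nm %in% names(data)) {
      .stop_missing(sprintf("model covariate `%s` not found in data", nm))
    }
    v <- data[[nm]]
    if (form == "linear") {
      if (is.character(v)) v <- factor(v)
      if (is.factor(v) || is.logical(v)) {
        if (is.logical(v)) v <- factor(v, levels = c(FALSE, TRUE))
        mm <- stats::model.matrix(~v)[, -1, drop = FALSE]
        colnames(mm) <- paste0(nm, sub("^v", "", colnames(mm)))
        X <- cbind(X, mm)
        info[[nm]] <- list(form = "linear", levels = levels(v))
      } else {
        # optimize on the standardized column (raw clinical covariates are
        # near-collinear with the intercept); coefficients are mapped back
        # to the original scale after the fit
        ctr <- mean(v); scl <- stats::sd(v)
        if (!is.finite(scl) || scl == 0) scl <- 1
        X <- cbind(X, (v - ctr) / scl)
        colnames(X)[ncol(X)] <- nm
        info[[nm]] <- list(form = "linear", center = ctr, scale = scl)
      }
    } else { # pspline
      if (!is.numeric(v)) {
        .stop_invalid(sprintf("pspline term `%s` requires a continuous covariate", nm))
      }
      rng <- range(v)
      # equally spaced knots extended degree steps past the boundary
      # (Eilers-Marx construction): the difference-penalty null space is
      # then exactly the polynomials of degree penalty_order - 1
      h <- (rng[2] - rng[1]) / (spec$knots + 1)
      kn <- seq(rng[1] - spec$degree * h, rng[2] + spec$degree * h, by = h)
      B <- splines::splineDesign(kn, v, ord = spec$degree + 1, outer.ok = TRUE)
      D <- diff(diag(ncol(B)), differences = spec$penalty_order)
      P <- crossprod(D)
      Cc <- matrix(colSums(B), ncol = 1)
      Z <- qr.Q(qr(Cc), complete = TRUE)[, -1, drop = FALSE]
      Pz <- t(Z) %*% P %*% Z
      # reparameterize to the penalty eigenbasis with penalized directions
      # rescaled to a unit (ridge) penalty: keeps the optimization
      # well-conditioned across the whole smoothing-parameter grid
      eg <- eigen((Pz + t(Pz)) / 2, symmetric = TRUE)
      pen <- eg$values > max(eg$values) * 1e-9
      scl <- ifelse(pen, 1 / sqrt(pmax(eg$values, 1e-300)), 1)
      Tm <- eg$vectors %*% diag(scl, length(scl))
      BZ <- B %*% Z %*% Tm
      colnames(BZ) <- paste0(nm, ".ps", seq_len(ncol(BZ)))
      idx <- ncol(X) + seq_len(ncol(BZ))
      X <- cbind(X, BZ)
      penalties[[nm]] <- list(idx = idx, pen = pen)
      info[[nm]] <- list(form = "pspline", knots = kn, Z = Z %*% Tm)
    }
  }
  r <- qr(X)
  if (r$rank < ncol(X)) {
    drop_cols <- colnames(X)[r$pivot[(r$rank + 1):ncol(X)]]
    .stop_invalid(paste("design matrix is rank deficient; collinear terms:",
                        paste(drop_cols, collapse = ", ")))
  }
  list(X = X, penalties = penalties, info = info)
}

# Per-observation log-likelihood derivative helpers. Returns the derivative
# of the GIG log density with respect to the log-mu and log-sigma linear
# predictors, using Bessel recurrences; the nu derivative is taken by
# central finite differences by the caller.
.gig_eta_grad <- function(y, mu, sigma, nu) {
  omega <- 1 / sigma^2
  lb <- .log_bK_orders(c(nu, nu + 1, nu - 1, nu + 2), omega)
  lK <- lb[[1]]
  R <- exp(lb[[2]] - lK)
  rm_ <- exp(lb[[3]] - lK)
  r2 <- exp(lb[[4]] - lK)
  d_eta_mu <- -nu + (omega / 2) * (R * y / mu - mu / (R * y))
  dlogK <- -(rm_ + R) / 2
  Rp <- (-(1 + r2) + R * (rm_ + R)) / 2
  d_omega <- nu * Rp / R - dlogK - 0.5 * (R * y / mu + mu / (R * y)) -
    (omega / 2) * Rp * (y / mu - mu / (R^2 * y))
  d_eta_sigma <- d_omega * (-2 * omega)
  list(mu = d_eta_mu, sigma = d_eta_sigma)
}

# Penalized maximum likelihood for fixed smoothing parameters.
.fit_inner <- function(y, Xm, Xs, Pm, Ps, start, nu_bounds = c(-40, 40)) {
  pm <- ncol(Xm); ps <- ncol(Xs)
  unpack <- function(th) list(bm = th[seq_len(pm)],
                              bs = th[pm + seq_len(ps)],
                              nu = th[pm + ps + 1])
  loglik <- function(th) {
    u <- unpack(th)
    mu <- exp(drop(Xm %*% u$bm)); sigma <- exp(drop(Xs %*% u$bs))
    if (!all(is.finite(mu)) || !all(is.finite(sigma))) return(-Inf)
    ll <- tryCatch(sum(dgig(y, mu, sigma, u$nu, log = TRUE)),
                   error = function(e) -Inf)
    if (!is.finite(ll)) -Inf else ll
  }
  penalty <- function(th) {
    u <- unpack(th)
    0.5 * (drop(t(u$bm) %*% Pm %*% u$bm) + drop(t(u$bs) %*% Ps %*% u$bs))
  }
  negpen <- function(th) {
    ll <- loglik(th)
    if (!is.finite(ll)) return(1e10)
    -ll + penalty(th)
  }
  grad_unpen <- function(th) {
    u <- unpack(th)
    mu <- exp(drop(Xm %*% u$bm)); sigma <- exp(drop(Xs %*% u$bs))
    g <- .gig_eta_grad(y, mu, sigma, u$nu)
    h <- 1e-4
    dnu <- (sum(dgig(y, mu, sigma, u$nu + h, log = TRUE)) -
              sum(dgig(y, mu, sigma, u$nu - h, log = TRUE))) / (2 * h)
    c(-drop(crossprod(Xm, g$mu)), -drop(crossprod(Xs, g$sigma)), -dnu)
  }
  gradpen <- function(th) {
    u <- unpack(th)
    g <- tryCatch(grad_unpen(th), error = function(e) rep(NA_real_, length(th)))
    if (!all(is.finite(g))) return(rep(0, length(th)))
    g + c(drop(Pm %*% u$bm), drop(Ps %*% u$bs), 0)
  }
  lower <- c(rep(-Inf, pm + ps), nu_bounds[1])
  upper <- c(rep(Inf, pm + ps), nu_bounds[2])
  # quasi-Newton with restarts: convergence is declared when a restart
  # improves the penalized objective by less than 1e-6
  history <- numeric(0)
  par <- start
  opt <- NULL
  converged <- FALSE
  iterations <- 0L
  for (round in 1:6) {
    opt <- stats::nlminb(par, negpen, gradient = gradpen,
                         lower = lower, upper = upper,
                         control = list(iter.max = 800, eval.max = 1600,
                                        rel.tol = 1e-10))
    iterations <- iterations + opt$iterations
    history <- c(history, opt$objective)
    improved <- length(history) > 1 &&
      history[length(history) - 1] - opt$objective < 1e-6
    par <- opt$par
    if (opt$convergence == 0 || improved) {
      converged <- TRUE
      break
    }
  }
  list(par = opt$par, objective = opt$objective, converged = converged,
       iterations = iterations, message = opt$message, history = history,
       loglik = loglik(opt$par), unpack = unpack,
       grad_unpen = grad_unpen)
}

# Effective degrees of freedom: trace of (H + S)^{-1} H with H the observed
# information of the unpenalized log-likelihood and S the penalty, both at
# the converged estimates. Unpenalized coefficients contribute one df each.
.edf <- function(inner, Pfull) {
  H <- .fd_jacobian(inner$grad_unpen, inner$par)
  H <- (H + t(H)) / 2
  ridge <- 0
  repeat {
    M <- tryCatch(solve(H + Pfull + diag(ridge, nrow(H)), H),
                  error = function(e) NULL)
    if (!is.null(M)) break
    ridge <- if (ridge == 0) 1e-8 * mean(abs(diag(H))) else ridge * 10
    if (ridge > 1e6) .stop_convergence("information matrix is singular")
  }
  M
}

#' Fit a GIG distributional regression
#'
#' Maximizes the GIG log-likelihood, penalized by the P-spline roughness
#' penalties, jointly over the log-location coefficients, log-scale
#' coefficients and the constant shape `nu`, by quasi-Newton iteration with
#' analytic predictor gradients. For each spline term the smoothing
#' parameter is selected by minimizing BIC over `spec$lambda_grid`
#' (warm-starting successive fits). Effective degrees of freedom are the
#' trace of the smoother influence matrix at convergence, and
#' `BIC = -2 loglik + edf * log(n)` with the unpenalized log-likelihood.
#'
#' @param data data frame containing the response and all model covariates
#'   (typically the output of [derive_covariates]).
#' @param spec a [model_spec].
#' @param lambda optional named vector fixing the smoothing parameter of
#'   specific spline terms instead of grid selection.
#' @return An object of class `"esr_fit"` with components `coefficients`
#'   (per predictor), `nu`, `fitted` (per-subject `mu`, `sigma`), `loglik`,
#'   `edf`, `edf_terms`, `bic`, `lambda`, `converged` and the design
#'   information needed by [predict.esr_fit].
#' @examples
#' cohort <- derive_covariates(simulate_cohort(cohort_config(n_per_stratum = 60),
#'                                             seed = 3))
#' fit <- fit_esr(cohort, model_spec(mu = c(sex = "linear")))
#' fit$bic
#' @export
fit_esr <- function(data, spec, lambda = NULL) {
  stopifnot(inherits(spec, "esr_spec"))
  y <- data[[spec$response]]
  if (is.null(y)) .stop_missing(sprintf("response `%s` not found", spec$response))
  if (any(y <= 0) || anyNA(y)) {
    .stop_invalid("response must be positive and complete")
  }
  n <- length(y)
  dm <- .build_design(data, as.list(spec$mu), spec)
  ds <- .build_design(data, as.list(spec$sigma), spec)
  pm <- ncol(dm$X); ps <- ncol(ds$X)

  spline_terms <- c(lapply(dm$penalties, function(p) c(list(pred = "mu"), p)),
                    lapply(ds$penalties, function(p) c(list(pred = "sigma"), p)))
  names(spline_terms) <- c(
    if (length(dm$penalties)) paste0("mu.", names(dm$penalties)),
    if (length(ds$penalties)) paste0("sigma.", names(ds$penalties)))

  # Rescale each spline term's penalized columns per candidate lambda so the
  # optimizer always sees well-conditioned coordinates: the column divisor
  # q_j = max(sqrt(lambda), ||x_j|| / sqrt(n)) absorbs sqrt(lambda) when the
  # penalty dominates and normalizes the column when the likelihood does;
  # the ridge weight lambda / q_j^2 keeps the penalized objective identical.
  tnorm <- sqrt(n)
  qcol <- function(nm, lam) {
    st <- spline_terms[[nm]]
    X0 <- if (st$pred == "mu") dm$X else ds$X
    nrm <- sqrt(colSums(X0[, st$idx[st$pen], drop = FALSE]^2))
    pmax(sqrt(lam[[nm]]), nrm / tnorm)
  }
  assemble <- function(lam) {
    Xm <- dm$X; Xs <- ds$X
    pm_diag <- numeric(pm); ps_diag <- numeric(ps)
    for (nm in names(spline_terms)) {
      st <- spline_terms[[nm]]
      cols <- st$idx[st$pen]
      q <- qcol(nm, lam)
      if (st$pred == "mu") {
        Xm[, cols] <- sweep(Xm[, cols, drop = FALSE], 2, q, "/")
        pm_diag[cols] <- lam[[nm]] / q^2
      } else {
        Xs[, cols] <- sweep(Xs[, cols, drop = FALSE], 2, q, "/")
        ps_diag[cols] <- lam[[nm]] / q^2
      }
    }
    list(Xm = Xm, Xs = Xs, Pm = diag(pm_diag, pm), Ps = diag(ps_diag, ps))
  }

  start <- c(base::log(mean(y)), rep(0, pm - 1),
             base::log(max(stats::sd(y) / mean(y), 0.1)), rep(0, ps - 1),
             -0.5)

  fit_at <- function(lam, start) {
    A <- assemble(lam)
    inner <- .fit_inner(y, A$Xm, A$Xs, A$Pm, A$Ps, start)
    Pfull <- rbind(cbind(A$Pm, matrix(0, pm, ps + 1)),
                   cbind(matrix(0, ps, pm), A$Ps, matrix(0, ps, 1)),
                   matrix(0, 1, pm + ps + 1))
    M <- .edf(inner, Pfull)
    edf <- sum(diag(M))
    list(inner = inner, M = M, edf = edf, A = A, lam = lam,
         bic = -2 * inner$loglik + edf * base::log(n))
  }

  # coefficient conversion between the lambda-scaled optimization basis and
  # the fixed (eigen-reparameterized) design basis
  rescale_par <- function(par, lam_from, lam_to) {
    for (nm in names(spline_terms)) {
      st <- spline_terms[[nm]]
      off <- if (st$pred == "mu") 0 else pm
      cols <- off + st$idx[st$pen]
      par[cols] <- par[cols] * qcol(nm, lam_to) / qcol(nm, lam_from)
    }
    par
  }

  lam <- stats::setNames(rep(1, length(spline_terms)), names(spline_terms))
  if (!is.null(lambda)) {
    for (nm in names(lambda)) lam[[nm]] <- lambda[[nm]]
    fixed <- names(lambda)
  } else {
    fixed <- character(0)
  }
  if (length(spline_terms) == 0) {
    best <- fit_at(lam, start)
  } else if (all(names(spline_terms) %in% fixed)) {
    # warm-start cascade from heavier smoothing: low-lambda surfaces are
    # too flat to optimize reliably from a cold start
    st_start <- start
    st_lam <- lam
    for (fac in 10^seq(6, 0, by = -1)) {
      cur <- lam
      for (nm in names(spline_terms)) cur[[nm]] <- lam[[nm]] * fac
      best <- fit_at(cur, rescale_par(st_start, st_lam, cur))
      st_start <- best$inner$par
      st_lam <- cur
    }
  } else {
    # descend the grid from smoothest to wiggliest, warm-starting each fit
    best <- NULL
    for (nm in setdiff(names(spline_terms), fixed)) {
      st_start <- start
      st_lam <- lam
      for (lg in sort(spec$lambda_grid, decreasing = TRUE)) {
        lam[[nm]] <- lg
        cand <- fit_at(lam, rescale_par(st_start, st_lam, lam))
        st_start <- cand$inner$par
        st_lam <- lam
        if (is.null(best) || cand$bic < best$bic) {
          best <- cand
          best_lam <- lam
        }
      }
      lam <- best_lam
    }
  }
  inner <- best$inner
  if (!inner$converged) {
    .stop_convergence("penalized likelihood optimization did not converge",
                      history = list(objective = inner$history,
                                     iterations = inner$iterations,
                                     message = inner$message))
  }
  # express coefficients in the fixed design basis (undo the sqrt(lambda)
  # column scaling) so fitted values and prediction use dm$X / ds$X directly
  par_design <- inner$par
  for (nm in names(spline_terms)) {
    st <- spline_terms[[nm]]
    off <- if (st$pred == "mu") 0 else pm
    cols <- off + st$idx[st$pen]
    par_design[cols] <- par_design[cols] / qcol(nm, best$lam)
  }
  u <- inner$unpack(par_design)
  mu_hat <- exp(drop(dm$X %*% u$bm))
  sigma_hat <- exp(drop(ds$X %*% u$bs))
  # map standardized linear-term coefficients back to the covariate scale
  unstandardize <- function(b, info, X) {
    for (nm in names(info)) {
      ii <- info[[nm]]
      if (!is.null(ii$center)) {
        j <- match(nm, colnames(X))
        b[1] <- b[1] - b[j] * ii$center / ii$scale
        b[j] <- b[j] / ii$scale
      }
    }
    b
  }
  u$bm <- unstandardize(u$bm, dm$info, dm$X)
  u$bs <- unstandardize(u$bs, ds$info, ds$X)
  edf_terms <- vapply(names(spline_terms), function(nm) {
    st <- spline_terms[[nm]]
    off <- if (st$pred == "mu") 0 else pm
    sum(diag(best$M)[off + st$idx])
  }, numeric(1))
  structure(list(
    spec = spec,
    coefficients = list(mu = stats::setNames(u$bm, colnames(dm$X)),
                        sigma = stats::setNames(u$bs, colnames(ds$X))),
    nu = u$nu,
    fitted = data.frame(mu = mu_hat, sigma = sigma_hat),
    y = y,
    loglik = inner$loglik,
    edf = best$edf,
    edf_terms = edf_terms,
    bic = best$bic,
    lambda = lam,
    n = n,
    converged = inner$converged,
    iterations = inner$iterations,
    design = list(mu = dm$info, sigma = ds$info, spec = spec)
  ), class = "esr_fit")
}

#' @export
print.esr_fit <- function(x, ...) {
  cat("GIG distributional regression fit\n")
  cat(sprintf("  n = %d, logLik = %.3f, edf = %.2f, BIC = %.3f\n",
              x$n, x$loglik, x$edf, x$bic))
  cat(sprintf("  nu = %.4f\n", x$nu))
  cat("  log(mu) coefficients:\n")
  print(round(x$coefficients$mu, 4))
  cat("  log(sigma) coefficients:\n")
  print(round(x$coefficients$sigma, 4))
  invisible(x)
}

#' @export
logLik.esr_fit <- function(object, ...) {
  structure(object$loglik, df = object$edf, nobs = object$n,
            class = "logLik")
}

#' Bayesian Information Criterion of a fitted model
#'
#' `-2 loglik + edf * log(n)`, where the effective degrees of freedom count
#' one per unpenalized coefficient (including `nu`) plus the influence-trace
#' of each spline term.
#'
#' @param object an `esr_fit`.
#' @param ... unused.
#' @return The BIC as a single number.
#' @export
BIC.esr_fit <- function(object, ...) {
  -2 * object$loglik + object$edf * base::log(object$n)
}

# rebuild design columns for new data from stored term info
.predict_design <- function(info, terms, newdata, spec) {
  n <- nrow(newdata)
  X <- matrix(1, n, 1)
  for (nm in names(terms)) {
    form <- terms[[nm]]
    if (form == "constant") next
    if (!nm %in% names(newdata)) {
      .stop_missing(sprintf("covariate profile is missing `%s`", nm))
    }
    v <- newdata[[nm]]
    if (form == "linear") {
      lv <- info[[nm]]$levels
      if (!is.null(lv)) {
        v <- factor(as.character(v), levels = lv)
        if (anyNA(v)) .stop_invalid(sprintf("unknown level in `%s`", nm))
        mm <- stats::model.matrix(~v)[, -1, drop = FALSE]
        X <- cbind(X, mm)
      } else {
        X <- cbind(X, v)
      }
    } else {
      B <- splines::splineDesign(info[[nm]]$knots, v, ord = spec$degree + 1,
                                 outer.ok = TRUE)
      X <- cbind(X, B %*% info[[nm]]$Z)
    }
  }
  X
}

#' Predict per-subject GIG parameters
#'
#' @param object an `esr_fit`.
#' @param newdata data frame with the model covariates; defaults to the
#'   training fitted values.
#' @param ... unused.
#' @return Data frame with columns `mu`, `sigma`, `nu`.
#' @export
predict.esr_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    return(cbind(object$fitted, nu = object$nu))
  }
  spec <- object$spec
  Xm <- .predict_design(object$design$mu, as.list(spec$mu), newdata, spec)
  Xs <- .predict_design(object$design$sigma, as.list(spec$sigma), newdata, spec)
  data.frame(mu = exp(drop(Xm %*% object$coefficients$mu)),
             sigma = exp(drop(Xs %*% object$coefficients$sigma)),
             nu = object$nu)
}

#' Fit candidate specifications and rank them by BIC
#'
#' Fits every candidate specification to the same data, ranks by ascending
#' BIC (ties broken by fewer effective degrees of freedom) and returns the
#' winner together with the full ranking table.
#'
#' @param data data frame.
#' @param candidates list of [model_spec] objects (optionally named).
#' @return List with elements `best` (the lowest-BIC `esr_fit`), `ranking`
#'   (data frame of BIC, logLik, edf per candidate) and `fits`.
#' @export
select_model <- function(data, candidates) {
  if (length(candidates) < 1) .stop_invalid("at least one candidate is required")
  if (is.null(names(candidates)) || any(names(candidates) == "")) {
    names(candidates) <- paste0("model", seq_along(candidates))
  }
  fits <- lapply(candidates, function(sp) {
    tryCatch(fit_esr(data, sp), error = function(e) e)
  })
  ok <- !vapply(fits, inherits, logical(1), "error")
  if (!any(ok)) {
    .stop_convergence(paste("all candidate fits failed:",
                            paste(vapply(fits, conditionMessage, character(1)),
                                  collapse = " | ")))
  }
  tab <- data.frame(
    model = names(fits)[ok],
    logLik = vapply(fits[ok], function(f) f$loglik, numeric(1)),
    edf = vapply(fits[ok], function(f) f$edf, numeric(1)),
    bic = vapply(fits[ok], function(f) f$bic, numeric(1)))
  tab <- tab[order(tab$bic, tab$edf), ]
  rownames(tab) <- NULL
  list(best = fits[[tab$model[1]]], ranking = tab, fits = fits[ok])
}

#' Normalized quantile residuals
#'
#' `z_i = qnorm(F_GIG(y_i; mu_i, sigma_i, nu))` with the fitted cumulative
#' probabilities clamped into `[1/(2n), 1 - 1/(2n)]` (half-count
#' continuity) before the normal inverse. Under a correctly specified model
#' the residuals are standard normal.
#'
#' @param fitted an `esr_fit`.
#' @return Numeric vector of residuals, one per subject.
#' @export
quantile_residuals <- function(fitted) {
  stopifnot(inherits(fitted, "esr_fit"))
  n <- fitted$n
  u <- vapply(seq_len(n), function(i) {
    .pgig1(fitted$y[i], fitted$fitted$mu[i], fitted$fitted$sigma[i], fitted$nu)
  }, numeric(1))
  u <- pmin(pmax(u, 1 / (2 * n)), 1 - 1 / (2 * n))
  stats::qnorm(u)
}

#' Worm-plot coordinates with pointwise acceptance band
#'
#' Detrended normal Q-Q data for quantile residuals: ordered residuals
#' minus the theoretical normal quantiles, with the approximate 95%
#' pointwise band `+/- 1.96 sqrt(p(1-p)/n) / dnorm(qnorm(p))`. Flat worms
#' inside the band indicate an adequate fit; bends signal misfit in
#' location, scale, skewness or kurtosis.
#'
#' @param residuals numeric vector of quantile residuals (at least 20).
#' @param n_points optional thinning: keep this many evenly spaced order
#'   statistics.
#' @return Data frame with columns `z` (theoretical quantile), `deviation`
#'   (ordered residual minus `z`), `lower`, `upper` (band).
#' @export
worm_plot_data <- function(residuals, n_points = NULL) {
  residuals <- residuals[is.finite(residuals)]
  n <- length(residuals)
  if (n < 20) .stop_invalid("worm plots need at least 20 residuals")
  p <- stats::ppoints(n)
  z <- stats::qnorm(p)
  dev <- sort(residuals) - z
  se <- sqrt(p * (1 - p) / n) / stats::dnorm(z)
  out <- data.frame(z = z, deviation = dev,
                    lower = -1.96 * se, upper = 1.96 * se)
  if (!is.null(n_points) && n_points < n) {
    keep <- unique(round(seq(1, n, length.out = n_points)))
    out <- out[keep, ]
    rownames(out) <- NULL
  }
  out
}
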