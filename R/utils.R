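# Internal condition helpers: every user-facing validation failure is signalled
# with a classed condition so callers (and tests) can discriminate input errors
# from numerical failures.

.esr_stop <- function(class, msg, ...) {
  extra <- list(...)
  cond <- structure(
    class = c(class, "esrref_error", "error", "condition"),
    c(list(message = msg, call = sys.call(-1)), extra)
  )
  stop(cond)
}

.stop_invalid <- function(msg, ...) .esr_stop("esr_invalid_input", msg, ...)
.stop_domain <- function(msg, ...) .esr_stop("esr_domain_error", msg, ...)
.stop_missing <- function(msg, ...) .esr_stop("esr_missing_data", msg, ...)
.stop_convergence <- function(msg, ...) .esr_stop("esr_convergence_error", msg, ...)

.check_number <- function(x, name, lower = -Inf, upper = Inf,
                          allow_na = FALSE) {
  if (!is.numeric(x)) .stop_invalid(sprintf("`%s` must be numeric", name))
  bad <- !is.na(x) & (x < lower | x > upper)
  if (any(bad)) {
    .stop_invalid(sprintf("`%s` must lie in [%s, %s]", name,
                          format(lower), format(upper)))
  }
  if (!allow_na && anyNA(x)) {
    .stop_missing(sprintf("`%s` contains missing values", name))
  }
  invisible(x)
}

# Central finite-difference gradient; step scaled to parameter magnitude.
.fd_grad <- function(fn, x, h = 1e-6, ...) {
  g <- numeric(length(x))
  for (i in seq_along(x)) {
    hi <- h * max(1, abs(x[i]))
    xp <- x; xp[i] <- x[i] + hi
    xm <- x; xm[i] <- x[i] - hi
    g[i] <- (fn(xp, ...) - fn(xm, ...)) / (2 * hi)
  }
  g
}

# Jacobian of a vector-valued function by central differences (used for the
# observed information at the optimum).
.fd_jacobian <- function(fn, x, h = 1e-5) {
  f0 <- fn(x)
  J <- matrix(NA_real_, length(f0), length(x))
  for (i in seq_along(x)) {
    hi <- h * max(1, abs(x[i]))
    xp <- x; xp[i] <- x[i] + hi
    xm <- x; xm[i] <- x[i] - hi
    J[, i] <- (fn(xp) - fn(xm)) / (2 * hi)
  }
  J
}

# Run an expression with a locally-set RNG seed, restoring the caller's
# RNG state afterwards, so optional `seed` arguments never disturb the
# global stream.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}
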