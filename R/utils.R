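# Internal helpers shared across modules.

HOURS_PER_YEAR <- 8760
DAYS_PER_YEAR <- 365

# Condition constructors: every user-facing validation failure is a classed
# error so callers (and tests) can distinguish bad input from fit failures.
stop_invalid <- function(...) {
  stop(errorCondition(paste0(...), class = c("soildeg_invalid_input",
                                             "soildeg_error")))
}

stop_fit <- function(...) {
  stop(errorCondition(paste0(...), class = c("soildeg_fit_error",
                                             "soildeg_error")))
}

stop_schema <- function(...) {
  stop(errorCondition(paste0(...), class = c("soildeg_schema_error",
                                             "soildeg_error")))
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_lower = TRUE, allow_upper = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_invalid("`", name, "` must be a single finite number")
  lo_ok <- if (allow_lower) x >= lower else x > lower
  hi_ok <- if (allow_upper) x <= upper else x < upper
  if (!lo_ok || !hi_ok)
    stop_invalid("`", name, "` = ", format(x), " is outside the valid range ",
                 if (allow_lower) "[" else "(", lower, ", ", upper,
                 if (allow_upper) "]" else ")")
  invisible(x)
}

check_numeric_vector <- function(x, name, lower = -Inf) {
  if (!is.numeric(x) || length(x) == 0L || anyNA(x) || any(!is.finite(x)))
    stop_invalid("`", name, "` must be a non-empty finite numeric vector")
  if (any(x < lower))
    stop_invalid("`", name, "` must be >= ", lower)
  invisible(x)
}

# R-squared of observed vs fitted on the natural scale.
r_squared <- function(observed, fitted) {
  ss_res <- sum((observed - fitted)^2)
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) return(if (ss_res == 0) 1 else 0)
  1 - ss_res / ss_tot
}

# Levenberg-Marquardt fit with progressively looser convergence tolerances.
# Very tight tolerances recover noise-free parameters to high relative
# accuracy, but can occasionally drive the iterates into a numerically
# singular corner of the parameter space; retry with looser settings before
# giving up, and let the caller translate the final error.
nlslm_retry <- function(...) {
  last <- NULL
  for (tol in c(1e-15, 1e-10, sqrt(.Machine$double.eps))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(..., control = minpack.lm::nls.lm.control(
        maxiter = 1000, ftol = tol, ptol = tol)),
      error = function(e) e)
    if (!inherits(fit, "error")) return(fit)
    last <- fit
  }
  stop(last)
}

# Evaluate an expression with a temporary RNG seed, restoring the caller's
# RNG state afterwards so generators never perturb the global stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_seed) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (has_seed) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}
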