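# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

.assert <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) .stopf(fmt, ...)
  invisible(TRUE)
}

# population (1/n) standard deviation
.pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

# sample skewness (method-of-moments)
.skewness <- function(x) {
  x <- x[is.finite(x)]
  m <- mean(x)
  s <- .pop_sd(x)
  mean((x - m)^3) / s^3
}

# OLS residuals of y (vector or column matrix) on design X (intercept added);
# rank-deficient columns are dropped by lm.fit's pivoting.
.ols_residuals <- function(y, X) {
  X <- cbind(`(Intercept)` = 1, X)
  fit <- lm.fit(X, y)
  fit$residuals
}
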