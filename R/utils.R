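# Internal validation helpers shared across modules.

stop_input <- function(msg, ...) rlang::abort(sprintf(msg, ...), class = "senescreen_input_error")
stop_config <- function(msg, ...) rlang::abort(sprintf(msg, ...), class = "senescreen_config_error")

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop_config("`%s` must be a single number", name)
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok)
    stop_config("`%s` = %g is outside its allowed range %s%g, %g%s", name, x,
                if (strict_lower) "(" else "[", lower, upper,
                if (strict_upper) ")" else "]")
  invisible(x)
}

check_count <- function(x, name, lower = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) || x < lower)
    stop_config("`%s` must be an integer >= %d", name, lower)
  invisible(as.integer(x))
}

as_expression_matrix <- function(x, arg = "x") {
  if (is.data.frame(x)) {
    first <- x[[1L]]
    if (is.character(first) || is.factor(first)) {
      m <- as.matrix(x[-1L])
      rownames(m) <- as.character(first)
    } else {
      m <- as.matrix(x)
    }
  } else if (is(x, "Matrix")) {
    m <- as.matrix(x)
  } else if (is.matrix(x)) {
    m <- x
  } else {
    stop_input("`%s` must be a matrix or a data frame", arg)
  }
  if (!is.numeric(m)) stop_input("`%s` must be numeric", arg)
  m
}

#' @importFrom methods is
NULL

# Value at the k-th largest position where k = ceiling(q * n); cells with
# value >= this threshold are the "top q" fraction (ties pass inclusively).
top_quantile_threshold <- function(x, top_quantile) {
  n <- length(x)
  k <- max(1L, ceiling(top_quantile * n))
  sort(x, decreasing = TRUE)[k]
}

# Newton solve of trigamma(x) = y, vectorised; used by the empirical-Bayes
# variance-prior estimator.
trigamma_inverse <- function(y) {
  if (length(y) == 0L) return(numeric(0))
  out <- numeric(length(y))
  big <- y > 1e7
  small <- y < 1e-6
  out[big] <- 1 / sqrt(y[big])
  out[small] <- 1 / y[small]
  mid <- !(big | small)
  if (any(mid)) {
    x <- 0.5 + 1 / y[mid]
    for (i in seq_len(50L)) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / y[mid]) / psigamma(x, deriv = 2L)
      x <- x + dif
      if (max(-dif / x) < 1e-10) break
    }
    out[mid] <- x
  }
  out
}
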