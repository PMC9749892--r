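# internal helpers shared across modules

# evaluate `code` under `seed` without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}

#' Standard error of the mean
#'
#' @param x numeric vector; `NA`s are dropped.
#' @return `sd(x)/sqrt(n)`; `NA` when fewer than two observations remain.
#' @export
sem <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# stop() with a field path, used by constructors and the config validator
stop_field <- function(field, msg) {
  stop(sprintf("`%s` %s", field, msg), call. = FALSE)
}

check_number <- function(x, field, min = -Inf, max = Inf,
                         strict_min = FALSE, strict_max = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x))
    stop_field(field, "must be a single finite number")
  lo_ok <- if (strict_min) x > min else x >= min
  hi_ok <- if (strict_max) x < max else x <= max
  if (!lo_ok || !hi_ok)
    stop_field(field, sprintf("must be in %s%g, %g%s (got %g)",
                              if (strict_min) "(" else "[", min, max,
                              if (strict_max) ")" else "]", x))
  x
}

check_count <- function(x, field, min = 1) {
  check_number(x, field, min = min)
  if (x != round(x)) stop_field(field, "must be an integer")
  as.integer(x)
}

is_nonneg_int_vector <- function(x) {
  is.numeric(x) && all(is.finite(x)) && all(x >= 0) && all(x == round(x))
}

# mean-parameterized lognormal draws with a given coefficient of variation;
# cv = 0 degenerates to the mean exactly
rlnorm_mean_cv <- function(n, mean, cv) {
  if (cv == 0) return(rep(mean, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}
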