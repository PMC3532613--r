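#' Round half away from zero
#'
#' Base \code{round()} rounds half to even; printed clinical tables
#' conventionally round half up. Used only for display-scale values.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return numeric vector rounded half away from zero.
#' @export
roundHalfUp <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Derive a stream of child seeds from a base seed, all < 2^31.
# Distinct streams (e.g. per GP run) stay reproducible and independent
# of execution order.
deriveSeed <- function(seed, index) {
  (as.integer(seed) %% 1000003L) * 2047L + 7919L * as.integer(index) %% 2047L +
    as.integer(index)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_prob <- function(x, name, open = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop(sprintf("'%s' must be a single numeric value", name), call. = FALSE)
  lo <- if (open) x > 0 else x >= 0
  hi <- if (open) x < 1 else x <= 1
  if (!lo || !hi)
    stop(sprintf("'%s' must lie in %s", name,
                 if (open) "(0, 1)" else "[0, 1]"), call. = FALSE)
  invisible(x)
}
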