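#' Extended-real values: finite part plus symbolic infinities
#'
#' The model's horizon sums can contain two qualitatively different
#' infinities: a *hard* infinity, contributed by a single term whose clock
#' age is zero (the first, unlived objective unit after a birth or social
#' birth), and a *soft* infinity, the divergence of an infinite series of
#' shrinking terms. Neither is representable as an IEEE `Inf` without losing
#' information -- a past horizon can contain *two* hard infinities and still
#' have a meaningful finite part. `extended_value` keeps the three pieces
#' separate: a finite part (in subjective units, Uo), a count of hard
#' infinities, and a divergence flag.
#'
#' Addition acts componentwise: finite parts add, hard-infinity counts add,
#' divergence flags OR together. An `extended_value` with zero hard
#' infinities and `divergent = FALSE` is an ordinary finite number.
#'
#' @param finite Finite part, a single real number (units of Uo).
#' @param hard Non-negative integer count of hard-infinity terms.
#' @param divergent Logical flag: `TRUE` if the value contains a divergent
#'   (soft-infinite) series.
#' @return An object of class `extended_value`.
#' @examples
#' extended_value(3.598, hard = 1)          # a 20-year-old's past horizon
#' extended_value(0.4472)                   # a finite future horizon
#' extended_value(3.995) + extended_value(0.088, hard = 2)
#' @export
extended_value <- function(finite = 0, hard = 0L, divergent = FALSE) {
  if (!is.numeric(finite) || length(finite) != 1L || !is.finite(finite))
    stop_domain("'finite' must be a single finite number")
  if (!is.numeric(hard) || length(hard) != 1L || hard < 0 || hard != round(hard))
    stop_domain("'hard' must be a single non-negative integer")
  if (!is.logical(divergent) || length(divergent) != 1L || is.na(divergent))
    stop_domain("'divergent' must be TRUE or FALSE")
  structure(
    list(finite = as.numeric(finite), hard = as.integer(hard),
         divergent = divergent),
    class = "extended_value"
  )
}

#' @rdname extended_value
#' @param x An object.
#' @export
is_extended_value <- function(x) inherits(x, "extended_value")

#' Accessors for extended values
#'
#' @param x An `extended_value` (or an object carrying one, such as a
#'   [horizon_result]).
#' @return `finite_part()` the finite part in Uo; `hard_infinities()` the
#'   integer count of hard-infinity terms; `is_divergent()` the soft-infinity
#'   flag.
#' @seealso [extended_value()], [classify_infinity()]
#' @export
finite_part <- function(x) as_extended_value(x)$finite

#' @rdname finite_part
#' @export
hard_infinities <- function(x) as_extended_value(x)$hard

#' @rdname finite_part
#' @export
is_divergent <- function(x) as_extended_value(x)$divergent

# Coerce plain numbers and horizon results to the value algebra.
as_extended_value <- function(x) {
  if (is_extended_value(x)) return(x)
  if (inherits(x, "horizon_result")) return(x$value)
  if (inherits(x, "subjective_unit")) return(x$value)
  if (is.numeric(x) && length(x) == 1L) return(extended_value(x))
  stop_domain("cannot interpret object of class '", paste(class(x), collapse = "/"),
              "' as an extended value")
}

#' @export
Ops.extended_value <- function(e1, e2) {
  if (.Generic != "+")
    stop_domain("only '+' is defined for extended_value objects")
  e1 <- as_extended_value(e1)
  e2 <- as_extended_value(e2)
  extended_value(e1$finite + e2$finite,
                 e1$hard + e2$hard,
                 e1$divergent || e2$divergent)
}

#' Render an extended value
#'
#' Finite values print as plain numbers; hard infinities append `k x Inf`;
#' the qualitative class (`hard`, `soft`, `mixed`) is appended in brackets
#' whenever any infinity is present.
#'
#' @param x An `extended_value`.
#' @param digits Number of decimals for the finite part.
#' @param ... Unused.
#' @export
format.extended_value <- function(x, digits = 4, ...) {
  out <- formatC(x$finite, format = "f", digits = digits)
  if (x$hard > 0L) out <- paste0(out, " + ", x$hard, "×∞")
  if (x$divergent) out <- paste0(out, " + ∞(series)")
  cls <- classify_infinity(x)
  if (cls != "none") out <- paste0(out, " [", cls, "]")
  out
}

#' @export
print.extended_value <- function(x, ...) {
  cat("<extended value> ", format(x, ...), " Uo\n", sep = "")
  invisible(x)
}

# zero element of the algebra
ev_zero <- function() extended_value(0, 0L, FALSE)

# internal: classed domain errors, so callers can distinguish bad input
stop_domain <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("subjtime_domain_error", "subjtime_error")))
}

stop_singular <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("subjtime_singular_current", "subjtime_error")))
}
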