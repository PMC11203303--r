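#' Harmonic numbers
#'
#' `harmonic_number(n)` returns `H_n = sum(1/k, k = 1..n)`, the discrete
#' backbone of every subjective duration and horizon in the model
#' (`H_0 = 0`, the empty sum). Computed through the digamma function,
#' `H_n = digamma(n + 1) - digamma(1)`, which is machine-precision and O(1)
#' in `n`.
#'
#' `gen_harmonic(n, a)` returns the generalized sum
#' `sum(1/t^a, t = 1..n)` for a power-law exponent `a` in \[0, 1\]; it
#' reduces to `harmonic_number(n)` at `a = 1` and to `n` at `a = 0`.
#'
#' @param n Non-negative integer (vectorized for `harmonic_number`).
#' @param a Power-law exponent in \[0, 1\].
#' @return The (generalized) harmonic number, a plain numeric.
#' @examples
#' harmonic_number(20)        # ~ 3.598
#' gen_harmonic(4, 0.5)       # 1 + 1/sqrt(2) + 1/sqrt(3) + 1/2
#' @export
harmonic_number <- function(n) {
  if (!is.numeric(n) || length(n) < 1L || anyNA(n) ||
      any(n < 0) || any(n != round(n)))
    stop_domain("'n' must be non-negative integer(s)")
  digamma(n + 1) - digamma(1)
}

#' @rdname harmonic_number
#' @export
gen_harmonic <- function(n, a) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 0 || n != round(n))
    stop_domain("'n' must be a single non-negative integer")
  check_exponent(a)
  if (n == 0) return(0)
  if (a == 0) return(as.numeric(n))
  if (a == 1) return(harmonic_number(n))
  # sum smallest terms first for accuracy
  sum(seq.int(n, 1)^(-a))
}

#' The subjective mirror of one objective unit of time
#'
#' After `t` completed objective units, one further objective unit is
#' perceived as `1 / t^a` subjective units. During the very first unit
#' (`t = 0`) the perception is infinite: time is discretized in whole
#' units, so the age stays 0 until the first unit completes and the
#' mirror unit diverges. That singular unit is returned as a symbolic
#' *hard* infinity, never as a floating-point `Inf` (the value algebra
#' must be able to count several of them). The hard infinity is attached
#' to the age-0 unit for every exponent, since it is the discretization
#' -- not the exponent -- that produces it.
#'
#' @param t Non-negative integer age (completed objective units).
#' @param a Power-law exponent in \[0, 1\] (default 1, the pure
#'   inverse-proportional model).
#' @return An object of class `subjective_unit` wrapping an
#'   [extended_value()].
#' @examples
#' subjective_unit(1)          # 1 Uo: the first lived year is one's whole life
#' subjective_unit(20)         # 0.05 Uo
#' subjective_unit(0)          # hard infinity
#' subjective_unit(4, a = 0.5) # 0.5 Uo
#' @export
subjective_unit <- function(t, a = 1) {
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t < 0 || t != round(t))
    stop_domain("age 't' must be a single non-negative integer")
  check_exponent(a)
  value <- if (t == 0) extended_value(0, hard = 1L)
           else extended_value(t^(-a))
  new_subjective_unit(value, ages = as.integer(t), exponent = a)
}

#' The stacked subjective unit under multiple clocks
#'
#' Each ritual socialization starts an additional counting clock; the
#' clocks multiply, so with activated ages `t_0, ..., t_L` the subjective
#' unit is `1 / prod(t_i^a)` Uo. Only clocks whose start date is
#' `<= eval_date` participate (piecewise activation); every activated
#' clock sitting at age 0 contributes one hard infinity.
#'
#' @param clock A [person_clock()].
#' @param eval_date Integer evaluation date, `>= birth_date`.
#' @return A `subjective_unit`.
#' @examples
#' p <- person_clock(2004, events = 2024)
#' subjective_unit_stacked(p, 2034)  # 1/(30*10) Uo
#' subjective_unit_stacked(p, 2024)  # hard infinity: the social birth year
#' @export
subjective_unit_stacked <- function(clock, eval_date) {
  starts <- activated_clocks(clock, eval_date)
  ages <- eval_date - starts
  new_subjective_unit(unit_value(ages, clock$exponent),
                      ages = as.integer(ages), exponent = clock$exponent)
}

# value of one unit given the activated clock ages (integers >= 0)
unit_value <- function(ages, a) {
  zero <- sum(ages == 0L)
  if (zero > 0L) extended_value(0, hard = zero)
  else extended_value(prod(ages^(-a)))
}

new_subjective_unit <- function(value, ages, exponent) {
  structure(list(value = value, ages = ages, exponent = exponent),
            class = "subjective_unit")
}

#' @export
print.subjective_unit <- function(x, ...) {
  cat("<subjective unit> ", format(x$value, ...), " Uo",
      "  (ages ", paste(x$ages, collapse = ", "),
      "; a = ", format(x$exponent), ")\n", sep = "")
  invisible(x)
}

#' @export
format.subjective_unit <- function(x, ...) format(x$value, ...)
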