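#' Past horizon: the backward sum of all lived subjective units
#'
#' Looking back from the evaluation date, a person adds up the subjective
#' unit of every objective unit already lived, down to birth. With the
#' birth clock alone the sum is `sum(1/(t-k)^a, k = 0..t)` Uo: a finite
#' part (the harmonic-type sum down to age 1) plus the age-0 birth term,
#' which is a *hard* infinity -- the divergence arrives in a single jump
#' from 1.
#'
#' With stacked clocks the backward sum is assembled segment by segment
#' between consecutive clock starts. Within a segment, the unit of each
#' year is the product `1/prod(t_i^a)` over the clocks activated *in that
#' segment*. Each segment includes its own start year, whose newest clock
#' sits at age 0: every clock start crossed on the way back therefore
#' contributes one hard infinity, and the start year of segment `i + 1`
#' is also counted (finitely) as the top year of segment `i` -- for a
#' person born 2004 with a social birth 2034 evaluated 2044 this yields
#' finite parts `H_30 = 3.995` and `sum(1/(k(k+30)), k=1..10) = 0.088`
#' plus two hard infinities.
#'
#' @param clock A [person_clock()].
#' @param eval_date Integer evaluation date `>= birth_date`.
#' @return A `horizon_result`: list with `value` (an [extended_value()]),
#'   `direction = "past"`, `m = "unbounded"` (the whole lived past),
#'   `ages` (activated clock ages at evaluation) and `segments`, a
#'   data.frame with one row per clock segment (columns `start`, `upper`,
#'   `n_clocks`, `finite`, `hard`) whose `finite`/`hard` columns sum to
#'   the total.
#' @examples
#' past_horizon(person_clock(2004), 2024)                 # {3.598 + 1x∞}
#' past_horizon(person_clock(2004, events = 2034), 2044)  # {4.083 + 2x∞}
#' @export
past_horizon <- function(clock, eval_date) {
  starts <- activated_clocks(clock, eval_date)
  a <- clock$exponent
  n_seg <- length(starts)
  seg <- data.frame(start = integer(n_seg), upper = integer(n_seg),
                    n_clocks = integer(n_seg), finite = numeric(n_seg),
                    hard = integer(n_seg))
  total <- ev_zero()
  for (i in seq_len(n_seg)) {
    upper <- if (i < n_seg) starts[i + 1L] else as.integer(eval_date)
    finite <- 0
    hard <- 0L
    for (y in seq.int(upper, starts[i])) {
      v <- unit_value(y - starts[seq_len(i)], a)
      finite <- finite + v$finite
      hard <- hard + v$hard
    }
    seg[i, ] <- list(starts[i], upper, i, finite, hard)
    total <- total + extended_value(finite, hard)
  }
  new_horizon(total, direction = "past", m = "unbounded",
              ages = eval_date - starts, segments = seg)
}

#' Future horizon: the forward sum of coming subjective units
#'
#' Looking `m` objective units ahead from the evaluation date, a person
#' adds up the subjective unit of each coming year:
#' `sum(1/prod(t_i + k)^a, k = 1..m)` Uo over the activated clock ages
#' `t_i`. All future denominators are at least 1, so a future horizon
#' never contains a hard infinity. The default convention starts at
#' `k = 1` (the current, partly lived unit is excluded);
#' `include_current = TRUE` starts at `k = 0`, the convention of the
#' worked 20-year-old example (`1/20 + ... + 1/30 ~ 0.4472` Uo).
#'
#' With `m = "unbounded"` the sum runs forever. It diverges -- a *soft*
#' infinity, blurred and unlocalized -- exactly when the total term
#' exponent (number of activated clocks times `a`) is `<= 1`; a lone
#' birth clock at `a = 1` therefore anticipates an infinite life. A
#' second clock makes the terms fall like `1/t^2` and the horizon becomes
#' finite: the first socialization ends subjective eternity. Convergent
#' limits are evaluated by partial summation to a cutoff plus a
#' midpoint-rule integral tail whose residual is below 1e-10.
#'
#' @param clock A [person_clock()].
#' @param eval_date Integer evaluation date. Every activated clock must
#'   have age `>= 1`: at age 0 the *current* unit is itself infinite and
#'   the condition is signalled (class `subjtime_singular_current`), not
#'   summed over.
#' @param m Positive integer lookahead, 0, or `"unbounded"`.
#' @param include_current Logical; include the current unit (`k = 0`)?
#' @return A `horizon_result` with `direction = "future"`; its `value` is
#'   divergent (soft infinity) or finite, never hard-infinite.
#' @examples
#' p <- person_clock(2004)
#' future_horizon(p, 2024, m = 10, include_current = TRUE)  # ~ 0.4472 Uo
#' future_horizon(p, 2024, m = "unbounded")                 # soft infinity
#' future_horizon(person_clock(2004, events = 2034), 2044,
#'                m = "unbounded")                          # finite: ~ 0.0450
#' @export
future_horizon <- function(clock, eval_date, m, include_current = FALSE) {
  starts <- activated_clocks(clock, eval_date)
  ages <- eval_date - starts
  if (any(ages == 0))
    stop_singular("an activated clock is at age 0 on ", eval_date,
                  ": the current subjective unit is itself infinite ",
                  "(hard); there is no finite future sum to report")
  a <- clock$exponent
  unbounded <- identical(m, "unbounded") || identical(m, Inf)
  if (!unbounded) {
    if (!is.numeric(m) || length(m) != 1L || is.na(m) || m < 0 || m != round(m))
      stop_domain("'m' must be a non-negative integer or \"unbounded\"")
    k0 <- if (include_current) 0L else 1L
    value <- if (m < k0) ev_zero()
             else extended_value(sum(term_product(ages, seq.int(k0, m), a)))
    return(new_horizon(value, "future", as.integer(m), ages))
  }
  p <- length(ages) * a  # total decay exponent of the summed terms
  if (p <= 1)
    return(new_horizon(extended_value(0, divergent = TRUE),
                       "future", "unbounded", ages))
  k0 <- if (include_current) 0L else 1L
  cutoff <- 1e5
  head_sum <- sum(rev(term_product(ages, seq.int(k0, cutoff), a)))
  f <- function(x) {
    r <- rep(1, length(x))
    for (t_i in ages) r <- r / (t_i + x)^a
    r
  }
  # tail integral over [cutoff + 1/2, Inf) via the substitution u = 1/x,
  # which turns the infinite range into (0, 1/x0] with an integrable
  # endpoint and lets the quadrature reach near machine precision even
  # for decay exponents barely above 1
  x0 <- cutoff + 0.5
  tail_int <- stats::integrate(function(u) f(1 / u) / u^2, 0, 1 / x0,
                               rel.tol = 1e-12, abs.tol = 1e-13,
                               subdivisions = 200L)$value
  # midpoint-rule correction: sum_{k>cutoff} f(k) = int f - f'(x0)/24 + ...
  correction <- -f(x0) * sum(a / (ages + x0)) / 24
  new_horizon(extended_value(head_sum + tail_int - correction),
              "future", "unbounded", ages)
}

# per-year product terms 1/prod(t_i + k)^a for a vector of offsets k
term_product <- function(ages, k, a) {
  r <- rep(1, length(k))
  for (t_i in ages) r <- r / (t_i + k)^a
  r
}

#' Classify the infinities in a horizon
#'
#' `"hard"`: one or more localized zero-age singularities (every past
#' horizon has at least the birth one); `"soft"`: a divergent series with
#' no localized term (the unbounded single-clock future); `"mixed"`: both;
#' `"none"`: an ordinary finite value.
#'
#' @param result A `horizon_result` or [extended_value()].
#' @return One of `"none"`, `"hard"`, `"soft"`, `"mixed"`.
#' @export
classify_infinity <- function(result) {
  v <- as_extended_value(result)
  if (v$hard > 0L && v$divergent) "mixed"
  else if (v$hard > 0L) "hard"
  else if (v$divergent) "soft"
  else "none"
}

new_horizon <- function(value, direction, m, ages, segments = NULL) {
  structure(list(value = value, direction = direction, m = m,
                 ages = as.integer(ages), segments = segments),
            class = "horizon_result")
}

#' @export
print.horizon_result <- function(x, digits = 4, ...) {
  cat("<", x$direction, " horizon> ", format(x$value, digits = digits),
      " Uo\n", sep = "")
  cat("  clock ages: ", paste(x$ages, collapse = ", "),
      if (!identical(x$m, "unbounded") || x$direction == "past") ""
      else "", sep = "")
  if (x$direction == "future")
    cat("; lookahead m = ", as.character(x$m), sep = "")
  cat("\n")
  if (!is.null(x$segments)) {
    cat("  segments (newest first):\n")
    s <- x$segments[rev(seq_len(nrow(x$segments))), ]
    for (i in seq_len(nrow(s)))
      cat(sprintf("    years %d..%d (%d clock%s): %s + %d×∞\n",
                  s$upper[i], s$start[i], s$n_clocks[i],
                  if (s$n_clocks[i] > 1) "s" else "",
                  formatC(s$finite[i], format = "f", digits = digits),
                  s$hard[i]))
  }
  invisible(x)
}
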