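#' Seeded synthetic person timelines
#'
#' Generates reproducible sets of plausible [person_clock()] timelines for
#' property testing and demonstrations. The defaults encode the model's
#' stated life-course regularities: ritual socializations are few (0 to 4
#' per person) and concentrated in the first thirty years of life, so
#' event ages are drawn uniformly from 1..30 by default. Birth years
#' default to 1940..2010; the exponent range defaults to the degenerate
#' `[1, 1]` (the pure inverse-proportional model).
#'
#' @param count Number of persons to generate.
#' @param birth_range Integer range `c(lo, hi)` of birth years.
#' @param n_events_range Integer range of events per person, within 0..4.
#' @param event_age_range Integer range of ages (since birth) at which
#'   events may occur.
#' @param exponent_range Numeric range of exponents, within \[0, 1\].
#' @param seed Integer RNG seed; identical seeds give identical fixtures.
#' @return `fixture_spec()`: an object of class `fixture_spec`.
#' @examples
#' generate_fixtures(fixture_spec(count = 3, seed = 1))
#' @export
fixture_spec <- function(count, birth_range = c(1940L, 2010L),
                         n_events_range = c(0L, 4L),
                         event_age_range = c(1L, 30L),
                         exponent_range = c(1, 1), seed = 1L) {
  check_integerish(count, "count")
  if (count < 1) stop_domain("'count' must be a positive integer")
  for (r in list(birth_range, n_events_range, event_age_range,
                 exponent_range))
    if (length(r) != 2L || anyNA(r) || r[2] < r[1])
      stop_domain("ranges must be c(lo, hi) with lo <= hi")
  if (n_events_range[1] < 0 || n_events_range[2] > 4)
    stop_domain("'n_events_range' must lie within 0..4")
  if (event_age_range[1] < 1)
    stop_domain("event ages must be >= 1 (an event in the birth year is ",
                "not a distinct social birth)")
  if (exponent_range[1] < 0 || exponent_range[2] > 1)
    stop_domain("'exponent_range' must lie within [0, 1]")
  check_integerish(seed, "seed")
  structure(list(count = as.integer(count),
                 birth_range = as.integer(birth_range),
                 n_events_range = as.integer(n_events_range),
                 event_age_range = as.integer(event_age_range),
                 exponent_range = as.numeric(exponent_range),
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

#' @rdname fixture_spec
#' @param spec A `fixture_spec`.
#' @return `generate_fixtures()`: a list of [person_clock()] objects.
#' @export
generate_fixtures <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  n_ages <- spec$event_age_range[2] - spec$event_age_range[1] + 1L
  if (spec$n_events_range[2] > n_ages)
    stop_domain("event_age_range too narrow for up to ",
                spec$n_events_range[2], " distinct event ages")
  with_preserved_rng({
    set.seed(spec$seed)
    lapply(seq_len(spec$count), function(i) {
      birth <- sample_range(spec$birth_range)
      k <- sample_range(spec$n_events_range)
      ages <- if (k > 0)
        sort(sample(seq.int(spec$event_age_range[1], spec$event_age_range[2]),
                    k, replace = FALSE))
      else integer()
      a <- stats::runif(1, spec$exponent_range[1], spec$exponent_range[2])
      person_clock(birth, birth + ages, a)
    })
  })
}

sample_range <- function(r) {
  if (r[1] == r[2]) r[1] else sample(seq.int(r[1], r[2]), 1L)
}

# run code under the generator's own RNG stream without disturbing the
# caller's .Random.seed
with_preserved_rng <- function(code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  force(code)
}

#' @export
print.fixture_spec <- function(x, ...) {
  cat("<fixture spec> ", x$count, " persons, births ",
      x$birth_range[1], "..", x$birth_range[2], ", ",
      x$n_events_range[1], "-", x$n_events_range[2],
      " events at ages ", x$event_age_range[1], "..",
      x$event_age_range[2], ", a in [",
      format(x$exponent_range[1]), ", ", format(x$exponent_range[2]),
      "], seed ", x$seed, "\n", sep = "")
  invisible(x)
}
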