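#' A person's timeline of counting clocks
#'
#' The model's only free inputs: a birth date, an ordered list of dates of
#' ritualized life-course events ("social births": weddings, graduations,
#' communions, ...), and the power-law damping exponent `a` in \[0, 1\].
#' Dates are plain integers in one shared calendar (CE years by default);
#' the model works in whole objective units, so no calendar arithmetic
#' beyond subtraction is ever needed. At an evaluation date `T` the birth
#' clock has age `t = T - T0` and each activated event clock has age
#' `t_i = T - T_i`; the subjective unit of time is `1 / prod(t_i^a)` Uo
#' over the activated clocks.
#'
#' @param birth_date Integer calendar unit of birth (T0).
#' @param events Strictly increasing integer vector of event dates,
#'   each `>= birth_date`. May be empty.
#' @param exponent Power-law damping exponent `a` in \[0, 1\]. `a = 1` is
#'   the pure inverse-proportional model; `a = 0` abolishes shrinking.
#' @param unit_name Name of the objective unit (cosmetic; default "year").
#' @return An object of class `person_clock`.
#' @examples
#' person_clock(2004)                      # birth clock only
#' person_clock(2004, events = 2034)       # a social birth at age 30
#' person_clock(1990, events = c(2000, 2020), exponent = 0.5)
#' @export
person_clock <- function(birth_date, events = integer(), exponent = 1,
                         unit_name = "year") {
  check_integerish(birth_date, "birth_date")
  if (length(events)) {
    for (d in events) check_integerish(d, "events")
    if (any(diff(events) <= 0))
      stop_domain("event dates must be strictly increasing")
    if (any(events < birth_date))
      stop_domain("every event date must be >= birth_date")
  }
  check_exponent(exponent)
  structure(
    list(birth_date = as.integer(birth_date),
         event_dates = as.integer(events),
         exponent = as.numeric(exponent),
         unit_name = as.character(unit_name)[1L]),
    class = "person_clock"
  )
}

#' @rdname person_clock
#' @param x An object.
#' @export
is_person_clock <- function(x) inherits(x, "person_clock")

#' @export
print.person_clock <- function(x, ...) {
  cat("<person clock> born ", x$birth_date, sep = "")
  if (length(x$event_dates))
    cat(", social births at ", paste(x$event_dates, collapse = ", "), sep = "")
  cat(", exponent a = ", format(x$exponent), ", unit = ", x$unit_name, "\n",
      sep = "")
  invisible(x)
}

#' Start dates of all clocks activated by a given date
#'
#' The birth clock plus every event clock whose start date is `<= eval_date`.
#' Clocks not yet started do not exist for the model (their factor is 1).
#'
#' @param clock A [person_clock()].
#' @param eval_date Integer evaluation date, `>= birth_date`.
#' @return Integer vector of start dates, birth first.
#' @export
activated_clocks <- function(clock, eval_date) {
  stopifnot(is_person_clock(clock))
  check_integerish(eval_date, "eval_date")
  if (eval_date < clock$birth_date)
    stop_domain("eval_date (", eval_date, ") precedes birth_date (",
                clock$birth_date, ")")
  c(clock$birth_date, clock$event_dates[clock$event_dates <= eval_date])
}

#' Read a person clock from a config file
#'
#' Accepts YAML or JSON (chosen by file extension, `.json` vs anything
#' else) with keys `birth_date` (int), `events` (list of int, optional),
#' `exponent` (float, default 1.0), `unit_name` (string, default "year").
#'
#' @param path Path to the config file.
#' @return A [person_clock()].
#' @export
read_person_config <- function(path) {
  if (!file.exists(path)) stop_domain("config file not found: ", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(cfg$birth_date)) stop_domain("config is missing 'birth_date'")
  person_clock(
    birth_date = cfg$birth_date,
    events = if (is.null(cfg$events)) integer() else unlist(cfg$events),
    exponent = if (is.null(cfg$exponent)) 1 else cfg$exponent,
    unit_name = if (is.null(cfg$unit_name)) "year" else cfg$unit_name
  )
}

check_integerish <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x))
    stop_domain("'", name, "' must be a single integer calendar unit")
  invisible(x)
}

check_exponent <- function(a) {
  if (!is.numeric(a) || length(a) != 1L || is.na(a) || a < 0 || a > 1)
    stop_domain("exponent 'a' must be a single number in [0, 1]")
  invisible(a)
}
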