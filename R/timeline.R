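#' Year-by-year timeline report for a person
#'
#' One row per evaluation age from `from_age` to `to_age`: the subjective
#' unit of that year, the cumulative subjective age (the running sum of
#' units over completed years 1..t, so it telescopes exactly row to row),
#' the past-horizon finite part and hard-infinity count, and optionally a
#' future-horizon column for a fixed lookahead. Singular rows -- years in
#' which a clock starts -- carry the symbolic hard-infinity count in the
#' `*_hard` columns with a finite part of 0, never a numeric overflow;
#' the future column is `NA` on such rows (the current unit is itself
#' infinite there).
#'
#' @param clock A [person_clock()].
#' @param from_age,to_age Integer ages, `0 <= from_age <= to_age`.
#' @param lookahead Optional positive integer: adds a future-horizon
#'   column over the next `lookahead` objective units (current unit
#'   excluded).
#' @return A `timeline_report`: a data.frame with columns `age`,
#'   `eval_date`, `unit_finite`, `unit_hard`, `cum_finite`, `cum_hard`,
#'   `past_finite`, `past_hard` and (optionally) `future_finite`, plus
#'   attributes `clock`, `exponent` and `lookahead`.
#' @examples
#' build_timeline(person_clock(2004), 1, 30)
#' build_timeline(person_clock(2000, events = 2020), 18, 23, lookahead = 10)
#' @export
build_timeline <- function(clock, from_age, to_age, lookahead = NULL) {
  stopifnot(is_person_clock(clock))
  check_integerish(from_age, "from_age")
  check_integerish(to_age, "to_age")
  if (from_age < 0 || to_age < from_age)
    stop_domain("ages must satisfy 0 <= from_age <= to_age")
  if (!is.null(lookahead)) {
    check_integerish(lookahead, "lookahead")
    if (lookahead < 1) stop_domain("'lookahead' must be a positive integer")
  }

  ages <- seq.int(from_age, to_age)
  # cumulative subjective age telescopes over completed years 1..t (the
  # age-0 unit is the unlived first one and is excluded, so with a single
  # clock the cumulative age at t is exactly H_t)
  cum <- ev_zero()
  cum_done <- 0L
  cum_at <- function(t) {
    while (cum_done < t) {
      cum_done <<- cum_done + 1L
      cum <<- cum +
        subjective_unit_stacked(clock, clock$birth_date + cum_done)$value
    }
    cum
  }

  n <- length(ages)
  rows <- data.frame(age = ages, eval_date = clock$birth_date + ages,
                     unit_finite = numeric(n), unit_hard = integer(n),
                     cum_finite = numeric(n), cum_hard = integer(n),
                     past_finite = numeric(n), past_hard = integer(n))
  if (!is.null(lookahead)) rows$future_finite <- NA_real_
  for (i in seq_len(n)) {
    t <- ages[i]
    d <- clock$birth_date + t
    u <- subjective_unit_stacked(clock, d)$value
    rows$unit_finite[i] <- u$finite
    rows$unit_hard[i] <- u$hard
    c_t <- if (t == 0) ev_zero() else cum_at(t)
    rows$cum_finite[i] <- c_t$finite
    rows$cum_hard[i] <- c_t$hard
    p <- past_horizon(clock, d)$value
    rows$past_finite[i] <- p$finite
    rows$past_hard[i] <- p$hard
    if (!is.null(lookahead))
      rows$future_finite[i] <- tryCatch(
        finite_part(future_horizon(clock, d, m = lookahead)),
        subjtime_singular_current = function(e) NA_real_)
  }
  structure(rows, clock = clock, exponent = clock$exponent,
            lookahead = lookahead,
            class = c("timeline_report", "data.frame"))
}

#' @export
print.timeline_report <- function(x, digits = 4, ...) {
  clock <- attr(x, "clock")
  cat("<timeline report> ", nrow(x), " rows, a = ",
      format(attr(x, "exponent")), "\n", sep = "")
  print(clock)
  df <- as.data.frame(x)
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], round, digits = digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Write and re-read timeline reports
#'
#' Serialization is round-trip safe: finite parts are written as full
#' precision (17 significant digits) decimal strings, hard-infinity
#' counts as integer columns -- never the string `"inf"` inside a numeric
#' field -- so a report written and re-read compares equal field by
#' field. CSV is comma-separated, header row, UTF-8, `.` decimal point;
#' JSON carries the clock metadata alongside the rows.
#'
#' @param report A [build_timeline()] report.
#' @param path Output/input file path.
#' @param format `"csv"` or `"json"`.
#' @return `write_timeline()` returns `path` invisibly; `read_timeline()`
#'   returns a `timeline_report`.
#' @export
write_timeline <- function(report, path, format = c("csv", "json")) {
  format <- match.arg(format)
  stopifnot(inherits(report, "timeline_report"))
  df <- as.data.frame(report)
  if (format == "csv") {
    out <- df
    dbl <- vapply(out, is.double, logical(1))
    out[dbl] <- lapply(out[dbl], function(v)
      ifelse(is.na(v), "NA", formatC(v, format = "g", digits = 17)))
    utils::write.table(out, path, sep = ",", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8", eol = "\n")
  } else {
    clock <- attr(report, "clock")
    payload <- list(
      metadata = list(birth_date = clock$birth_date,
                      events = clock$event_dates,
                      exponent = clock$exponent,
                      unit_name = clock$unit_name,
                      lookahead = attr(report, "lookahead")),
      rows = df)
    jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                         na = "null", pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_timeline
#' @param clock For `read_timeline()` from CSV, the [person_clock()] the
#'   report was built from (CSV carries no metadata); ignored for JSON.
#' @export
read_timeline <- function(path, format = c("csv", "json"), clock = NULL) {
  format <- match.arg(format)
  if (format == "csv") {
    df <- utils::read.csv(path, colClasses = NA)
    for (col in intersect(c("unit_hard", "cum_hard", "past_hard"), names(df)))
      df[[col]] <- as.integer(df[[col]])
    lookahead <- NULL
  } else {
    payload <- jsonlite::read_json(path, simplifyVector = TRUE)
    df <- as.data.frame(payload$rows)
    for (col in intersect(c("unit_hard", "cum_hard", "past_hard"), names(df)))
      df[[col]] <- as.integer(df[[col]])
    meta <- payload$metadata
    clock <- person_clock(meta$birth_date,
                          if (length(meta$events)) unlist(meta$events)
                          else integer(),
                          meta$exponent, meta$unit_name)
    lookahead <- meta$lookahead
  }
  structure(df, clock = clock,
            exponent = if (!is.null(clock)) clock$exponent else NA_real_,
            lookahead = lookahead,
            class = c("timeline_report", "data.frame"))
}
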