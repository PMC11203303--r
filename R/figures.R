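#' Regenerate the numeric series behind the model's standard figures
#'
#' Each supported id returns the plot-ready table for one of the model's
#' canonical illustrations, computed from the package's own functions:
#'
#' * `2` -- subjective unit `1/t` over the first 30 years (`t`, `unit`).
#' * `3` -- discrete vs continuous subjective duration from `t1 = 1` and
#'   their gap, plus the objective duration (`t2`, `ds_discrete`,
#'   `ds_continuous`, `gap`, `objective`).
#' * `4` -- subjective speeds and durations from `t1 = 1`; the objective
#'   speed column is constantly 1.
#' * `5` -- a 20-year-old's single past-year contributions `1/t`, newest
#'   first, growing toward the (omitted) birth singularity.
#' * `6` -- a 20-year-old's next-ten-years contributions `1/(20+k)`,
#'   `k = 0..10` (the current year included).
#' * `7` -- figures 5 and 6 joined, with a `direction` column.
#' * `8` -- power-law units `1/t^a` for
#'   `a = 1, 0.5, 0.4, 0.3, 0.2, 0.1, 0` in long format (`a`, `t`, `unit`).
#' * `9` -- the square-root case `a = 0.5` over 30 years, with the `a = 1`
#'   inset column.
#' * `10` -- two clocks, social birth at age 20, `a = 1`, ages 1..50:
#'   `1/t` before, singular at 20, `1/(t(t-20))` after (`unit_hard`
#'   marks the singular row).
#' * `11` -- stacked piecewise units with social births at ages 10 and
#'   30, `a = 0.2`, ages 1..50.
#'
#' @param figure_id Integer in 2..11.
#' @return A data.frame (see above), with attribute `figure_id`.
#' @examples
#' figure_data(2)[20, ]   # unit 0.05 Uo at t = 20
#' figure_data(9)[4, ]    # 1/sqrt(4) = 0.5 Uo
#' @export
figure_data <- function(figure_id) {
  if (!is.numeric(figure_id) || length(figure_id) != 1L ||
      !(figure_id %in% 2:11))
    stop_domain("'figure_id' must be one of 2..11")
  df <- switch(as.character(figure_id),
    "2" = data.frame(t = 1:30,
                     unit = vapply(1:30, function(t)
                       finite_part(subjective_unit(t)), numeric(1))),
    "3" = {
      t2 <- 2:100
      data.frame(
        t2 = t2,
        ds_discrete = vapply(t2, function(x) discrete_duration(1, x)$value,
                             numeric(1)),
        ds_continuous = vapply(t2, function(x) continuous_duration(1, x)$value,
                               numeric(1)),
        gap = vapply(t2, discrete_continuous_gap, numeric(1)),
        objective = t2 - 1)
    },
    "4" = {
      t2 <- 2:100
      data.frame(
        t2 = t2,
        vs_discrete = vapply(t2, function(x)
          subjective_speed(1, x, mode = "discrete")$value, numeric(1)),
        vs_continuous = vapply(t2, function(x)
          subjective_speed(1, x, mode = "continuous")$value, numeric(1)),
        ds_discrete = vapply(t2, function(x) discrete_duration(1, x)$value,
                             numeric(1)),
        ds_continuous = vapply(t2, function(x) continuous_duration(1, x)$value,
                               numeric(1)),
        objective_speed = 1)
    },
    "5" = data.frame(t = 20:1,
                     contribution = vapply(20:1, function(t)
                       finite_part(subjective_unit(t)), numeric(1))),
    "6" = data.frame(k = 0:10, contribution = 1 / (20 + 0:10)),
    "7" = rbind(
      cbind(direction = "past",
            data.frame(step = 1:20, contribution = 1 / (20:1))),
      cbind(direction = "future",
            data.frame(step = 1:10, contribution = 1 / (20 + 1:10)))),
    "8" = {
      grid <- expand.grid(t = 1:30, a = c(1, 0.5, 0.4, 0.3, 0.2, 0.1, 0))
      grid$unit <- mapply(function(t, a)
        finite_part(subjective_unit(t, a)), grid$t, grid$a)
      grid[c("a", "t", "unit")]
    },
    "9" = data.frame(t = 1:30,
                     unit = vapply(1:30, function(t)
                       finite_part(subjective_unit(t, 0.5)), numeric(1)),
                     unit_a1 = vapply(1:30, function(t)
                       finite_part(subjective_unit(t, 1)), numeric(1))),
    "10" = piecewise_units(person_clock(0, events = 20, exponent = 1), 1:50),
    "11" = piecewise_units(person_clock(0, events = c(10, 30),
                                        exponent = 0.2), 1:50)
  )
  structure(df, figure_id = as.integer(figure_id))
}

# per-age stacked units for a clock whose birth date is age 0
piecewise_units <- function(clock, ages) {
  u <- lapply(ages, function(t)
    subjective_unit_stacked(clock, clock$birth_date + t)$value)
  data.frame(t = ages,
             unit = vapply(u, function(v)
               if (v$hard > 0L) NA_real_ else v$finite, numeric(1)),
             unit_hard = vapply(u, function(v) v$hard, integer(1)))
}
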