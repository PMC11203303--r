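test_that("a 20-year-old's past horizon is H_20 plus one hard infinity", {
  h <- past_horizon(person_clock(2004), 2024)
  expect_equal(round(finite_part(h), 3), 3.598)
  expect_identical(hard_infinities(h), 1L)
  expect_false(is_divergent(h))
  expect_identical(classify_infinity(h), "hard")
  # the finite part is exactly the harmonic number of the age
  expect_equal(finite_part(h), harmonic_number(20))
})

test_that("the two-clock past horizon decomposes into its printed segments", {
  h <- past_horizon(person_clock(2004, events = 2034), 2044)
  expect_identical(hard_infinities(h), 2L)
  seg <- h$segments
  expect_identical(nrow(seg), 2L)
  # birth-clock segment: the 30 years before the social birth, H_30
  expect_equal(round(seg$finite[seg$n_clocks == 1], 3), 3.995)
  expect_equal(seg$finite[seg$n_clocks == 1], harmonic_number(30))
  # product segment: the 10 years lived on two clocks
  expect_equal(round(seg$finite[seg$n_clocks == 2], 3), 0.088)
  two_clock_oracle <- 0
  for (k in 1:10) two_clock_oracle <- two_clock_oracle + 1 / (k * (k + 30))
  expect_equal(seg$finite[seg$n_clocks == 2], two_clock_oracle)
  # each segment carries exactly one clock-start hard infinity
  expect_identical(seg$hard, c(1L, 1L))
  expect_equal(finite_part(h), sum(seg$finite))
  expect_equal(round(finite_part(h), 3), 3.995 + 0.088)
})

test_that("evaluating at birth leaves only the hard birth term", {
  h <- past_horizon(person_clock(1970), 1970)
  expect_identical(finite_part(h), 0)
  expect_identical(hard_infinities(h), 1L)
  h05 <- past_horizon(person_clock(1970, exponent = 0.5), 1970)
  expect_identical(hard_infinities(h05), 1L)
  expect_error(past_horizon(person_clock(1970), 1969),
               class = "subjtime_domain_error")
})

test_that("past horizons damp uniformly under the power-law exponent", {
  h <- past_horizon(person_clock(0, exponent = 0.5), 20)
  expect_equal(finite_part(h), gen_harmonic(20, 0.5))
  expect_identical(hard_infinities(h), 1L)
})

test_that("the bounded future horizon matches the worked example", {
  p <- person_clock(2004)
  expect_equal(round(finite_part(future_horizon(p, 2024, 10,
                                                include_current = TRUE)), 4),
               0.4472)
  # default convention excludes the current unit (sum starts at k = 1)
  expect_equal(round(finite_part(future_horizon(p, 2024, 10)), 4), 0.3972)
  expect_equal(finite_part(future_horizon(p, 2024, 10)),
               harmonic_number(30) - harmonic_number(20))
  expect_identical(classify_infinity(future_horizon(p, 2024, 10)), "none")
})

test_that("future horizons carry no hard infinities and handle edge cases", {
  p <- person_clock(2000, events = 2010)
  h <- future_horizon(p, 2030, 15)
  expect_identical(hard_infinities(h), 0L)
  # m = 0 without the current unit is the empty sum, not an error
  expect_identical(finite_part(future_horizon(p, 2030, 0)), 0)
  # m = 0 with the current unit is just the current unit
  expect_equal(finite_part(future_horizon(p, 2030, 0, include_current = TRUE)),
               1 / (30 * 20))
  # an age-0 clock makes the current unit singular: signalled, not summed
  expect_error(future_horizon(p, 2010, 5),
               class = "subjtime_singular_current")
})

test_that("adding one year of lookahead adds exactly the next term", {
  for (clock in list(person_clock(0), person_clock(0, events = 8),
                     person_clock(0, events = 8, exponent = 0.4))) {
    ages <- 25 - activated_clocks(clock, 25)
    for (m in c(1, 5, 11)) {
      step <- finite_part(future_horizon(clock, 25, m + 1)) -
        finite_part(future_horizon(clock, 25, m))
      expect_equal(step, prod(1 / (ages + m + 1)^clock$exponent),
                   tolerance = 1e-14)
    }
  }
})

test_that("unbounded future horizons diverge iff total exponent <= 1", {
  # one clock, a = 1: soft infinity (an anticipated endless life)
  h1 <- future_horizon(person_clock(2004), 2024, "unbounded")
  expect_true(is_divergent(h1))
  expect_identical(classify_infinity(h1), "soft")
  # two clocks, a = 1: convergent -- the first socialization ends eternity
  h2 <- future_horizon(person_clock(2004, events = 2034), 2044, "unbounded")
  expect_false(is_divergent(h2))
  expect_identical(classify_infinity(h2), "none")
  # two clocks, a = 0.5: the harmonic boundary case is divergent
  h3 <- future_horizon(person_clock(0, events = 10, exponent = 0.5),
                       30, "unbounded")
  expect_true(is_divergent(h3))
  # three clocks, a = 0.5: total exponent 1.5, convergent
  h4 <- future_horizon(person_clock(0, events = c(5, 10), exponent = 0.5),
                       30, "unbounded")
  expect_false(is_divergent(h4))
})

test_that("the convergent two-clock limit matches its telescoping closed form", {
  # sum_{k>=1} 1/((t+k)(u+k)) = (H_t - H_u)/(t - u), and brute-force
  # partial sums approach the same limit from below
  cases <- list(c(40, 10), c(25, 5), c(33, 32))
  for (cs in cases) {
    t <- cs[1]; u <- cs[2]
    clock <- person_clock(0, events = t - u)
    h <- future_horizon(clock, t, "unbounded")
    closed <- (loop_power_sum(t) - loop_power_sum(u)) / (t - u)
    expect_equal(finite_part(h), closed, tolerance = 1e-9)
    partial <- loop_two_clock_future(t, u, 5000)
    expect_lt(partial, finite_part(h))
    expect_lt(finite_part(h) - partial, 1e-3)
  }
  # the worked value: ages 40 and 10 give ~0.0450 Uo
  expect_equal(round(finite_part(future_horizon(person_clock(0, events = 30),
                                                40, "unbounded")), 4),
               0.045)
})

test_that("infinity classification distinguishes hard, soft, mixed, none", {
  expect_identical(classify_infinity(past_horizon(person_clock(0), 20)), "hard")
  expect_identical(
    classify_infinity(future_horizon(person_clock(0), 20, "unbounded")),
    "soft")
  expect_identical(
    classify_infinity(future_horizon(person_clock(0), 20, 10)), "none")
  expect_identical(
    classify_infinity(extended_value(1, hard = 1, divergent = TRUE)), "mixed")
})

test_that("every past horizon of a generated person is hard-infinite", {
  clocks <- generate_fixtures(fixture_spec(count = 25, seed = 7,
                                           exponent_range = c(0, 1)))
  for (p in clocks) {
    eval_date <- p$birth_date + 45L
    h <- past_horizon(p, eval_date)
    crossed <- 1L + sum(p$event_dates <= eval_date)
    expect_gte(hard_infinities(h), 1L)
    expect_identical(hard_infinities(h), crossed)
    expect_true(classify_infinity(h) %in% c("hard", "mixed"))
    # and the single-clock unbounded future stays soft
    single <- person_clock(p$birth_date, exponent = 1)
    expect_identical(
      classify_infinity(future_horizon(single, eval_date, "unbounded")),
      "soft")
  }
})
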