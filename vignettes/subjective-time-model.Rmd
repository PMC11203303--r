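---
title: "A discrete model of the subjective passage of time"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A discrete model of the subjective passage of time}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(subjtime)
```

## The model

Objective time is counted in fixed units `Uo` — the year, throughout this
vignette — from an arbitrary shared origin. The model attaches to each
person a *mirror* subjective unit: after `t` completed objective units of
life, the next unit is perceived as

$$U_s = \frac{1}{t^a}\,U_o, \qquad 0 \le a \le 1 .$$

The hypothesis encodes one observation: a person apprehends their whole
lived life as a unitary whole, so one more year is weighed against the `t`
years already absorbed. The exponent `a` damps the effect: `a = 1` is the
pure inverse-proportional form, `a = 0.5` a square-root form, `a = 0` no
shrinking at all. `a` is a free parameter, in principle fittable to
judgment experiments, and a *single* `a` applies to every clock of a
person — per-clock exponents are not supported, because the model treats
damping as a property of the person's cognition, not of the event.

Time is **discrete**: ages are integer counts of completed units. During
the whole first unit after a clock starts, the age on that clock is 0 and
the unit `1/0^a` is infinite. This *hard infinity* is a genuine feature of
the discretization, not an overflow, and the package represents it
symbolically (see "The value algebra" below). We attach the hard infinity
to the age-0 unit for *every* exponent, including `a = 0` where the bare
formula would give `0^0 = 1`: the singular first unit comes from the
age-counting convention, which the exponent does not touch. A smooth
(continuous-time) reading of the same curves is exposed through the
`continuous` mode of the duration and speed functions, where the
singularity integrates away; the discrete mode is authoritative for all
worked examples.

### Durations and speed

The subjective mirror of the objective interval `(t1, t2]` is

$$d_s = \sum_{t = t_1 + 1}^{t_2} \frac{1}{t^a}\,U_o
      = \left[H^{(a)}_{t_2} - H^{(a)}_{t_1}\right] U_o ,$$

a difference of (generalized) harmonic numbers, and its continuous
counterpart is $\ln(t_2/t_1)\,U_o$ at `a = 1`, or
$(t_2^{1-a} - t_1^{1-a})/(1-a)\,U_o$ below. At `a = 1` the log form makes
*multiplicative shrinking* exact: scaling both endpoints by any `k` leaves
the subjective duration at `ln k`, so ages 6→12, 12→24 and 48→96 all feel
like `ln 2 ≈ 0.69` years.

```{r durations}
discrete_duration(20, 30)
continuous_duration(6, 12)
discrete_continuous_gap(100)
```

The discrete and continuous forms measured from `t1 = 1` differ by a
near-constant gap whose exact asymptote is `1 − γ ≈ 0.4228` (`γ` the
Euler–Mascheroni constant, from `H_n − ln n → γ`). The model quotes the
gap as "around 0.42"; the package reports it pointwise at any `t2` and
leaves the asymptote to `1 + digamma(1)`, since no averaging range for the
quoted constant is specified.

The subjective *speed* of time is the dimensionless ratio
`duration / (t2 − t1)`. Durations measured from age 1 grow with `t2` while
speeds fall — both monotonically — which is the model's resolution of the
young/old paradox: for the young, time flies (speed near 1) yet durations
loom large; for the old, time crawls yet the years feel short.

Intervals that would include the age-0 term are rejected by the duration
functions and routed to the horizon functions, which own the infinity
bookkeeping. This keeps `duration_result` a plain finite number.

### Horizons and the two infinities

Looking back from age `t`, a person sums every lived subjective year:

$$H_p = \sum_{k=0}^{t} \frac{1}{(t-k)^a}\,U_o .$$

All terms but one are finite; the `t = 0` birth term is a *hard* infinity,
perceived as a single jump. A 20-year-old's past horizon is
`{3.598 + ∞} Uo`, with finite part exactly `H_20`. Looking forward `m`
years, all denominators are at least 1, so bounded future horizons are
plain finite numbers; unbounded ones may instead diverge as a series —
the *soft* infinity, blurred over infinitely many shrinking terms.

```{r horizons}
past_horizon(person_clock(2004), 2024)
future_horizon(person_clock(2004), 2024, m = 10, include_current = TRUE)
classify_infinity(future_horizon(person_clock(2004), 2024, m = "unbounded"))
```

Two printed conventions coexist for the bounded future horizon: the
defining sum starts at `k = 1` (current unit excluded), while the worked
20-year-old example sums `1/20 + ... + 1/30`, current unit included. Both
are legitimate readings, so the package exposes an `include_current` flag
rather than silently choosing; the default is the defining (`k = 1`)
convention. If any activated clock is at age 0 on the evaluation date the
*current* unit is itself infinite and there is no finite future sum to
report; the package signals this as a classed condition
(`subjtime_singular_current`) instead of summing around it.

### Stacked clocks

Every culture marks additional "social births" — weddings, graduations,
communions — each of which starts a further counting clock at its date
`T_i`. The clocks multiply:

$$U_s = \frac{1}{\prod_{i} t_i^a}\,U_o ,$$

the product running over the birth clock and the event clocks already
started (`T_i ≤ T`); clocks not yet started contribute nothing, which is
what produces the piecewise regimes of the stacked-unit curves. The event
year replays the hard infinity (that clock's age is 0), and afterwards the
unit shrinks faster than before.

The past horizon under stacked clocks is assembled segment by segment
between consecutive clock starts, each segment using the clocks active
within it. A boundary year belongs to both adjacent segments: it is the
hard-infinity start of the newer segment *and* a finite top term of the
older one. That convention is forced by the worked two-clock example
(birth 2004, social birth 2034, evaluated 2044), whose printed
decomposition `[3.995 + 0.088 + 2×∞]` requires the 1/30 term inside the
birth-clock segment while the same year contributes `1/(0·30)` to the
two-clock segment:

```{r twoclock}
past_horizon(person_clock(2004, events = 2034), 2044)
```

Whether the power-law exponent should also damp the backward terms of
each segment is implied but nowhere written; the package applies the
person's `a` uniformly to every factor of every segment, the only choice
consistent with a single per-person exponent.

The qualitative cost of the first socialization is quantitative here: with
`L + 1` activated clocks the unbounded future horizon diverges **iff**
`(L + 1)·a ≤ 1` (comparison with the generalized harmonic series; the
boundary case is divergent, as for the harmonic series itself). At
`a = 1`, one clock means an endless anticipated life (soft infinity), two
clocks a finite one — "eternal" humans become "mortal" the day of their
first ritual. The package asserts this only as the convergence
classification; it makes no claim about actual longevity.

```{r eternity}
classify_infinity(future_horizon(person_clock(2004), 2044, "unbounded"))
finite_part(future_horizon(person_clock(2004, events = 2034), 2044, "unbounded"))
```

## The value algebra

Horizon values live in an extended-real algebra implemented by
`extended_value`: a triple *(finite part, hard-infinity count, divergent
flag)*. Addition acts componentwise (finite parts add, counts add, flags
OR), which is exactly what summing horizon segments needs; the two-clock
past horizon above is `[3.995 + 1×∞] + [0.088 + 1×∞]`. Hard infinities
are never stored as IEEE `Inf` — the distinguishing count (`2×∞`) would
collapse — and serialization writes the finite part, count and flag as
separate columns, never the string `"inf"` in a numeric field.

## Numerical choices

- **Harmonic numbers** are computed as `digamma(n+1) − digamma(1)`:
  O(1), machine precision, exact agreement with term-by-term summation to
  well below 1e−12 relative error over the tested range. Generalized sums
  `Σ 1/t^a` are summed smallest-term-first.
- **Continuous durations near `a = 1`.** The power-law form
  `(t2^{1−a} − t1^{1−a})/(1−a)` is evaluated through `expm1`, which is
  stable arbitrarily close to `a = 1`; the exact log branch takes over
  below `|1 − a| = 1e−12`. The two branches agree to better than 1e−9
  at the switch point (tested at `a = 1 − 1e−9` against the log form).
- **Unbounded convergent horizons** are evaluated as a partial sum of the
  first 1e5 terms plus an integral tail with a midpoint correction: the
  tail `Σ_{k>K} f(k)` is `∫_{K+1/2}^∞ f − f′(K+1/2)/24 + …`, whose
  truncation residual is below 1e−10 throughout the convergent regime
  (the Euler–Maclaurin error term at `K = 1e5` is at most
  `~K^{−2}/24`). The infinite-range integral itself is computed after the
  substitution `u = 1/x`, which turns it into a finite-range quadrature
  accurate to near machine precision even for decay exponents barely
  above 1. The `a = 1` two-clock case is additionally cross-checked in
  the tests against its exact telescoping closed form
  `Σ 1/((t+k)(u+k)) = (H_t − H_u)/(t − u)`.
- **Degenerate inputs.** `m = 0` without the current unit is the empty
  sum (0, not an error); evaluating at the birth date gives a past
  horizon of `{0 + 1×∞}`; duplicate or decreasing event dates are
  rejected at construction.

## Synthetic persons

`generate_fixtures()` draws seeded person timelines for property tests
and demonstrations. Its defaults are the model's own stated life-course
regularities, fixed once: 0–4 ritual events per person, event ages
uniform on 1..30 (ritual socializations are few and concentrated in the
first thirty years of life), birth years uniform on 1940..2010 (an
arbitrary contemporary window; the model is translation-invariant in the
calendar, so the choice is cosmetic), exponent fixed at 1 unless a range
is requested. Generation is deterministic under a seed and leaves the
caller's RNG stream untouched.

What these synthetic persons exercise is the model's bookkeeping —
activation order, segment assembly, classification — over many clock
configurations. They are not data about human time perception: no claim
tested on them (nor anywhere else in the package) says anything about how
actual people report durations. Connecting `a` to judgment experiments is
exactly the open empirical question the model leaves.

## Problem sizes

The test-suite and acceptance computations are desk-scale by construction
— harmonic sums to a few hundred terms, timelines of at most ~50 rows,
fixture sets of 10–100 persons, oracle sweeps to `t = 500` and spot
checks at `n = 1e4`–`1e6` — so the whole suite completes in seconds.

## Limitations

- The model is an individual-level idealization: one exponent per person,
  whole-unit ages, a single stacked sense of time (no parallel clocks).
- Calendar dates are bare integers; months-within-years, time zones and
  real calendar arithmetic are out of scope by design.
- The continuous mode is a smooth reading of the same hypothesis, kept
  for its closed forms; it erases the hard infinity, which is the
  discrete model's signature feature.
- Nothing here is fit to data; all numerical claims the package makes are
  the model's own worked examples, recomputed by the test suite and the
  acceptance script.
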