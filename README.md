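# subjtime

Quantifying the subjective passage of time, one person at a time.

A year is the same length for everyone — and yet it is not. For a
one-year-old, a year is their whole life; for a fifty-year-old it is 2% of
it. `subjtime` implements a discrete sociophysics-style model of this
asymmetry: after `t` completed objective units (years, say), the next one is
perceived as a *subjective* unit

```
U_s = (1 / t^a) U_o,        0 ≤ a ≤ 1,
```

where `U_o` is the objective unit and `a` is a power-law damping exponent
(`a = 1` is the pure inverse-proportional model, `a = 0` switches the effect
off). Everything else in the package follows from this single hypothesis:

- **Durations.** The subjective mirror of the objective interval `(t1, t2]`
  is the harmonic-type sum `Σ_{t=t1+1..t2} 1/t^a = H_{t2} − H_{t1}` Uo in
  discrete time, and `ln(t2/t1)` Uo (or `(t2^{1−a} − t1^{1−a})/(1−a)` Uo)
  in continuous time. The two modes differ by a near-constant gap ≈ 0.42 Uo
  at `a = 1` (exact asymptote `1 − γ`, with `γ` the Euler–Mascheroni
  constant). Doubling intervals are perceived as equal: ages 6→12, 12→24,
  24→48 all last `ln 2 ≈ 0.69` subjective years.
- **Speed of time.** `v = duration / (t2 − t1)`, dimensionless. Duration
  since birth grows with age while the speed falls — the model's account of
  "time flies when young, freezes when old".
- **Horizons.** Looking back, a person sums every subjective year down to
  birth: a finite part (`H_20 ≈ 3.598` Uo for a 20-year-old) plus the age-0
  birth term, a *hard* infinity that arrives in a single jump. Looking
  forward without a deadline, the series `Σ 1/(t+k)` diverges — a blurred
  *soft* infinity. Both are tracked symbolically, never as floating `Inf`.
- **Stacked clocks.** Ritualized life-course events ("social births":
  weddings, graduations, ...) each start another counting clock; the clocks
  multiply, `U_s = 1/(t · t_1 ⋯ t_L)^a` Uo over the activated ages. The
  event year replays the hard infinity, and with two or more clocks at
  `a = 1` the unbounded future horizon becomes *finite*: the first
  socialization ends subjective eternity. The convergence rule is exact:
  the unbounded future horizon diverges iff (number of clocks) × `a` ≤ 1.

## Worked example

A person born in 1990, with social births in 2015 and 2020, evaluated in
2026 (ages 36, 11 and 6 on their three clocks):

```r
library(subjtime)
me <- person_clock(1990, events = c(2015, 2020), exponent = 1)

subjective_unit_stacked(me, 2026)
#> <subjective unit> 0.0004 Uo  (ages 36, 11, 6; a = 1)

past_horizon(me, 2026)
#> <past horizon> 3.9108 + 3×∞ [hard] Uo
#>   clock ages: 36, 11, 6
#>   segments (newest first):
#>     years 2026..2020 (3 clocks): 0.0107 + 1×∞
#>     years 2020..2015 (2 clocks): 0.0842 + 1×∞
#>     years 2015..1990 (1 clock): 3.8160 + 1×∞

future_horizon(me, 2026, m = "unbounded")
#> <future horizon> 0.0023 Uo
#>   clock ages: 36, 11, 6; lookahead m = unbounded
```

Read: the current year feels like 0.0004 objective years; the lived past is
a finite 3.91 Uo plus three localized infinities, one per clock start
crossed on the way back; and the entire unbounded future amounts to a
finite 0.0023 Uo — with three clocks running, the series `Σ 1/((36+k)(11+k)(6+k))`
converges. Per-year tables come from `build_timeline()`, the canonical
illustration series from `figure_data(2:11)`, and seeded synthetic persons
from `generate_fixtures()`.

A thin command-line wrapper is installed as `exec/subjtime`:

```sh
subjtime horizon --birth 2004 --now 2024 --direction past
# 3.5977 + 1×∞ [hard] Uo
subjtime timeline --birth 1990 --events 2015,2020 --from 1 --to 50 --out report.csv
```

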