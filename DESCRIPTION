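Package: subjtime
Title: Subjective Passage-of-Time Calculator with Stacked Life-Course Clocks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Calculator and simulator for a discrete model of the subjective
    passage of time. Each person carries a mirror subjective unit of time that
    shrinks as an inverse power of the number of objective units (years)
    already lived, optionally rescaled by additional clocks started at
    ritualized life-course events ("social births"). The package computes
    per-age subjective units, discrete (harmonic-number) and continuous
    (logarithmic/power-law) subjective durations, the subjective speed of
    time, and past/future horizons under an extended-real value algebra that
    tracks localized ("hard") singularities and divergent-series ("soft")
    infinities symbolically. Includes timeline reports, figure-series
    regeneration, seeded synthetic-person fixtures, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
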