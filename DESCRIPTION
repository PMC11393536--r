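Package: lerkit
Title: Later Eating Rhythm Variables from Timed Child Food Diaries
Version: 0.1.0
Authors@R: person("LER", "Maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: Derives later-eating-rhythm (LER) variables from time-stamped
    3-day child food diaries and parent-reported usual bedtimes: eating
    occasions and meal/snack classification, 13 timing / evening energy /
    meal-frequency variables per child and day-type stratum, night-eating
    classification and threshold calibration against half-hour energy-intake
    profiles, and a descriptive and correlation summary layer with
    week-vs-weekend comparisons. Includes a synthetic cohort generator that
    emulates the trimodal eating-time density, coarse historical meal-slot
    coding, sentinel time codes and missingness patterns of such diary data,
    so the whole pipeline is exercisable without access to managed cohort
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table (>= 1.14),
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
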