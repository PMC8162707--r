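Package: puffinGLS
Title: Threshold Light-Level Geolocation and Migration Metrics for
    High-Arctic Seabirds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing archival light-logger (geolocator, GLS)
    deployments on high-Arctic seabirds: a solar ephemeris and
    threshold-method geolocation engine (twilight detection, sun-elevation
    angle calibration against a known deployment site, twice-daily position
    estimation), track quality control (spherical moving-average smoothing,
    equinox-window removal, speed and inland filters), migration metrics
    (tri-monthly median locations, great-circle migration distances with
    land-avoidance rerouting around southern Greenland, farthest-location
    and monthly-distance statistics, return-migration onset), sex-grouped
    cohort summaries, and a synthetic light-data generator that simulates
    clipped, shaded light series along known tracks so the whole pipeline
    can be validated end-to-end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    geosphere,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
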