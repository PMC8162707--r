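---
title: "Threshold geolocation and migration metrics for high-Arctic seabirds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Threshold geolocation and migration metrics for high-Arctic seabirds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(puffinGLS)
```

## The problem

Archival light loggers (geolocators, GLS tags) record ambient light on a
clipped integer scale at a fixed interval. From the times the light trace
crosses a fixed threshold, one sunset and one sunrise are obtained per
night, and from each pair a position follows: **longitude** from the timing
of local solar midnight (or noon) against UTC, corrected by the equation of
time; **latitude** from the night (or day) length through the sunrise
equation,

$$\cos H = \frac{\sin a - \sin\varphi \sin\delta}{\cos\varphi \cos\delta},$$

where $\varphi$ is latitude, $\delta$ solar declination, $H$ the hour angle
at sunset and $a$ the *sun elevation angle* — the solar altitude at which
the tag's light reading crosses the threshold, calibrated per deployment
from control data recorded at a known site.

`puffinGLS` implements this threshold method together with the
quality-control filters, migration-distance metrics, and sex-grouped cohort
statistics used to describe differential migration of Atlantic puffins
(*Fratercula arctica naumanni*) breeding in high-Arctic northwest Greenland
(colony at 76.47° N, 70.22° W), and a synthetic light-data generator so
that every stage can be validated end to end without raw tag records.

## The processing model

The pipeline mirrors standard GLS practice for this kind of study:

1. **Twilight detection** (`detect_twilights`): threshold 10 on a 0–64
   light scale; crossing times linearly interpolated between the two
   bounding samples; dark periods shorter than 4 h discarded outright, so
   brief shading dips never masquerade as nights. Constant series (polar
   day, polar night) simply yield no events.
2. **Position estimation** (`positions_from_twilights`): both daily
   estimates are computed — a midnight position from each sunset–sunrise
   pair and a noon position from each sunrise–sunset pair — and carry their
   provenance, since tag firmware conventions differ and neither is
   privileged. Latitude is found by bisection of the sunrise equation on
   $\varphi \in [-89.5°, 89.5°]$ to 0.01°; bisection handles $a \neq 0$
   uniformly where the textbook closed form does not. When the equation
   flattens (near equinoxes) the root is ill-conditioned; positions whose
   local derivative $|\partial f / \partial \varphi| < 0.02$ are flagged
   `latitude indeterminate` rather than dropped.
3. **Calibration** (`calibrate_sun_angle`): grid search over candidate
   angles; for each, the median great-circle distance from the known site
   (the location bias) is computed over all valid non-equinox twilight
   pairs, requiring at least 20; ties break toward −3.0°, the conventional
   value for this tag family.
4. **Quality control** (`qc_pipeline`), in this order: three-position
   spherical moving average (unit-vector mean, endpoints unchanged), then
   removal of positions within ±15 d of the equinoxes (Mar 20 / Sep 22 by
   default, configurable), then the 500 km/day speed filter, then the
   inland filter (removed only if on land *and* more than 100 km from the
   coast — inland-but-coastal points are kept to avoid biasing the
   distribution offshore). Smoothing precedes filtering because outlier
   damping benefits every later distance computation; the speed filter
   then operates on the track that the metrics will actually use.
5. **Migration metrics**: tri-monthly (10-day-bin) median locations
   (component-wise medians — the simplest reading of "median location" and
   robust at these sample sizes); total migration distance as the
   great-circle chain colony → medians → colony; the mean
   distance/location/date-span of the eight farthest validated positions;
   monthly mean distances; and a return-migration onset rule. Distances
   use the haversine formula on a sphere of radius 6371.0 km.
6. **At-sea rerouting** (`at_sea_distance`): puffins do not cross the
   Greenland Ice Sheet, but median locations sometimes fall on it when a
   bird transits rapidly around Cape Farewell. Whenever a chain segment,
   sampled every 25 km, intersects a land polygon, the distance is
   replaced by the cheapest deflection through a configured waypoint
   (default: Cape Farewell, 59.77° N, 43.93° W). 25-km sampling is far
   finer than tag error, so nothing is gained by exact polygon clipping.

### Speed-filter tie rule

When consecutive positions imply more than the speed limit, the member of
the violating pair with the largest summed speed to its surviving
neighbours is removed (ties to the later point) and speeds are recomputed
to a fixed point. This removes isolated spikes first — the likelier
outlier — and guarantees that no surviving pair violates the limit.

### Return-onset rule

"Began moving northward in the general direction of the colony" is not
quantitative, so the package operationalises it: the onset is the first
median strictly after the maximum-distance median from which the distance
to the colony declines over at least two consecutive steps while latitude
increases across them. Outbound-only tracks (failed tags) return no onset.
The rule is a package convention and is labelled as such in outputs.

## Solar ephemeris

Declination and the equation of time use the NOAA low-accuracy Fourier
fits in the fractional year (validity 1950–2100, accuracy ≈ 0.1–0.3° and
≈ 1 min). Against a tag error of roughly 185 km, a 0.3° ephemeris error is
negligible, and the formulas have no external dependencies. The test suite
checks them against an independent Meeus-style orbital-elements
implementation.

## The synthetic generator and what it does (not) show

`make_track` interpolates waypoints along great circles;
`simulate_light` renders light as a clipped logistic function of solar
elevation at the true position, plus random shading, rounded to integers
on a 0–64 scale every 10 min. Defaults define the study conditions:

| parameter | default | why |
|---|---|---|
| sampling interval | 10 min | typical for this tag family; configurable |
| light scale | 0–64, threshold 10 | the convention a threshold of 10 implies |
| true sun angle | −3.0° | the deployed calibration value (−2.5° the alternate) |
| shading | i.i.d. per sample, p = 0.05, attenuation 0.1 | "moderate" shading; block mode (geometric runs) emulates leg-tucking |
| logistic ramp width | 3.5° (2–98%) | see below |

Two anchoring choices matter. First, the ramp is positioned so the light
value equals the detection threshold exactly when solar elevation equals
the nominal sun angle — this is the operational meaning of a tag's sun
elevation angle, and it is what lets a calibration grid search recover the
generating angle rather than an offset of it. Second, the ramp width: 1.5°
of elevation corresponds to only ~13 min of twilight at mid-latitudes,
narrower than the sampling interval, and the chord interpolation across so
sharp a logistic biases detected twilights by ~0.3° of elevation (~60 km of
median position error on noise-free data). A 3.5° ramp (~30–40 min of
twilight, the realistic range for these loggers) removes the artefact;
both are configurable.

The generator emulates: clipped, shaded light along a moving track; a
stationary calibration year at the colony; polar day (24-h light, June at
76.5° N) and polar night; equinox degeneracy. It does **not** emulate
weather-driven correlated attenuation, sensor drift, wet/dry or
temperature channels, or behaviourally clustered shading beyond the
optional block mode. Passing tests therefore demonstrate the *method's*
correctness and its error budget under known noise, not field performance
of any particular tag.

## Problem sizes and numerical conventions

Property-style tests and the acceptance script use: a four-waypoint winter
transit track between 40–65° N (November–February, outside equinox
windows), 20 seeds of moderate shading, ~200 retained positions per seed;
a five-month colony calibration series (~100 twilight pairs). These sizes
give stable medians while keeping the whole suite fast. Under these
conditions the pipeline's median position error is ~35 km, comfortably
inside the 185 km error ceiling quoted for this tag family.

Other conventions: crossing-time interpolation is linear in light (the
sampling interval dominates error); longitudes wrap to (−180°, 180°];
tri-monthly bins spanning more than 180° of longitude are rejected
(antimeridian unsupported — irrelevant in the North Atlantic); reported
distances round to whole km and coordinates to 0.1°, halves away from
zero, matching the published tables.

## Cohort statistics

`load_table1_fixture` packages the published per-bird table (12 deployment
seasons, 9 birds) with completeness footnotes applied; `group_stats`,
`sex_difference` and `monthly_table` reproduce the published summary
arithmetic, using the sample (n−1) standard deviation and counting
repeated seasons of the same bird per season. Mass summaries use one row
per bird among complete-migration birds. The published monthly table's
female-minus-male difference row cannot be derived from its own printed
means for January, February and May; `monthly_table_discrepancies` flags
these, and the package always recomputes differences from the means.

## Known limitations

- Latitude is unavailable near equinoxes by physics, not implementation;
  the ±15-day windows are removed rather than modelled.
- The land mask shipped for examples is a coarse synthetic Greenland
  outline (~30 vertices); analyses needing faithful coastal distance
  should supply a full-resolution GeoJSON via `read_landmask`.
- Rerouting considers single-waypoint deflections only; multi-leg routes
  around complex coastlines are out of scope.
- No state-space or curve-fit refinement: the package implements the
  threshold method as used in the source analysis, by design.
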