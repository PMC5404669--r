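---
title: "Methods: central-place foraging analysis and its synthetic testbed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: central-place foraging analysis and its synthetic testbed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what it computes, the
assumptions behind each stage, the parameters that matter, and what the
synthetic testbed does and does not establish about real tracking data.

## The system and the analysis

Breeding lesser kestrels are colonial central-place foragers: every
foraging excursion starts and ends at an anchor site (the breeding colony
or a nearby roost). A GPS deployment yields a fix table — UTC timestamp,
lon/lat (WGS84), altitude, instantaneous speed — at one of five cadences
(1 s; 1, 3, 5, 10 min). The analysis chain turns these tracks into
movement variables at two levels and compares them between sexes across
the breeding season.

**Geodesy.** All distances are great circles on a sphere of radius
6371 km. Trips span at most tens of km, so the ellipsoidal correction
(< 0.3 %) is far below the variability of any quantity modelled here.
Positions are never projected; everything works on lon/lat directly.

**Solar times.** Complete tracking days are defined by daylight coverage,
so sunrise and sunset come from an in-package NOAA-style ephemeris
(Julian-century series, zenith 90.833°). Against an independent
Julian-transit implementation it agrees to well under two minutes at the
study latitude, which is an order of magnitude finer than the 15-min
coverage tolerance that consumes it. Polar conditions raise an error —
they are outside the method's domain.

**Trip segmentation.** A fix is *at anchor* when within the site's
attendance radius (50 m; the boundary counts as inside). Maximal runs of
non-anchor fixes are candidate excursions; an excursion is a *foraging
trip* when (i) its maximum distance from the colony strictly exceeds
300 m and (ii) it contains a detected foraging event. Departure is the
last fix inside the buffer before exit and arrival the first fix inside
after return, which bounds trip duration consistently across cadences.
Excursions whose start or end was not observed are flagged incomplete and
excluded from all statistics; excursions beyond 300 m without a foraging
event are retained as non-foraging excursions. They contribute to daily
distance (the bird did fly) but not to trip-level statistics.

**Foraging events.** The field description of a foraging event —
clumped locations at low altitude with highly variable speed — is
operationalised with three thresholds: all fixes within
`clump_radius = 100` m of the window centroid, at least `min_fixes = 3`
fixes, and a speed coefficient of variation of at least
`speed_cv_min = 0.5`. These are package defaults, exposed in
configuration, not published values; sensitivity to them should be
explored on any real deposit. The optional low-altitude criterion
(median ≤ 50 m above a ground reference) is off unless a reference is
supplied, because no terrain model is bundled; a reasonable reference is
the median altitude of colony-attendance fixes per deployment.

**Daily metrics.** A day is complete when the first fix is within 15 min
after sunrise, the last within 15 min before sunset, and no internal gap
exceeds 3 sampling intervals. Colony attendance accrues per inter-fix
interval: full credit when both endpoints are inside the colony buffer,
half credit when exactly one is — unbiased for symmetric crossings.
Attendance is colony-only; roost time never counts. Trip counts are
assigned to the departure date.

**Perch hunting.** A perching bout is a maximal run of consecutive
displacements strictly below the cadence threshold (1 / 5 / 15 / 25 /
50 m at 1 s / 1 / 3 / 5 / 10 min — wider at coarser cadence because GPS
accuracy degrades). Bout duration is the span between the first and last
fix of the run, so at cadences ≥ 1 min every detected bout lasts at
least one full interval and the 30 s minimum-duration filter (which
removes stationary spells indistinguishable from hovering) only bites on
1 s data — the package asserts this structurally. Bouts are searched only
outside anchor buffers: colony perching is attendance, not hunting. This
is a deliberate convention; the alternative (counting within-buffer
stationary runs as hunting) would conflate nest attendance with foraging
behaviour.

## The statistical layer

Each movement variable is modelled by a GLMM with the sex ×
phenological-period interaction (periods: establishment; courtship = the
21 days before the first egg; incubation; nestling — start-inclusive,
end-exclusive, so they partition the breeding window) and random
intercepts for individual, year and colony (crossed; the nesting is not
identifiable from the design and crossed intercepts are the neutral
choice). Families/links: gaussian/identity (with log transform for
multiplicative responses and arcsine-square-root for proportions, the
latter applied to fractions in [0, 1] — percentages are divided by 100
first, since arcsin needs that domain), poisson/log for daily trip
counts, binomial/logit for perching presence.

Estimation is maximum likelihood wherever models are compared by
likelihood-ratio tests (backward-stepwise elimination: repeatedly drop
the least-significant droppable term with LRT p ≥ 0.05, never dropping a
term nested in a surviving interaction and never dropping the declared
correction factor), and REML for reported coefficients and smooths. This
ML/LRT + REML/report split is standard mixed-model practice. Lognormal
responses keep zero counts out by construction (the log transform
refuses non-positive values with an explicit error rather than silently
dropping rows).

Penalized-smooth models (`fit_smooth`) use thin-plate splines with REML
smoothness selection and random intercepts as `bs = "re"` terms. The
basis dimension defaults to `k = 20`: a seasonal body-mass trend needs
roughly 7–8 effective df, and the basis must sit comfortably above what
the penalty will select, otherwise curve misfit leaks into the parametric
coefficients' standard errors (we verified exactly this failure mode with
`k = 10`). A pure-noise response shrinks to ~1 edf.

Post-hoc contrasts for a fitted interaction form two families — sex
within each period (4 tests) and period pairs within each sex (12 tests)
— Wald tests on the model scale, Holm-corrected over the combined 16-test
family by default (`family = "within"` corrects each family separately;
the choice is exposed because the published convention is ambiguous).
Within-sex period comparisons are summarised as a compact letter display
(insert-and-absorb algorithm, implemented in-package).

Akaike weights are `exp(-Δi/2)` renormalised; the habitat-use comparison
is a Pearson chi-squared homogeneity test on the 2 × 9 sex-by-habitat
count table (df = 8), with an explicit warning when expected counts fall
below 5.

## The synthetic testbed

Real deployments for this system are not redistributable, so the
generator builds days with the statistical structure the analysis
assumes, carrying exact ground truth for every stage.

A simulated day is a schedule from sunrise to sunset: anchor bouts
(colony or roost, with local movement inside the 50 m buffer) alternate
with excursions. A foraging trip is a sinuous commute (sinuosity 1.24) to
a patch placed at a lognormal range from the colony, area-restricted
search inside the patch (short "hover/handling" steps every third fix,
longer relocations otherwise — the regular cycle keeps the speed CV above
the detection threshold even in minimal windows, and every active step is
bounded below 1.6 × the perch threshold so patch search can never
masquerade as perching), optional planted perch runs (sub-threshold
jitter around a fixed point; total perch time extends the trip, as
sitting adds time rather than displacing flight), and a commute back.
Non-foraging "loafing" excursions (two straight legs, never clumped)
and within-buffer movement carry the daily distance and time that real
birds accumulate outside qualifying trips.

Key distributional choices: Poisson daily trip counts; lognormal
durations, ranges and perch times (the published summaries have sd of
the order of the mean, demanding right skew), moment-matched so the
requested arithmetic mean/sd are exact; Beta daily attendance fractions;
duration–range correlation 0.6 (far patches take longer trips); and a
busy-day trade-off scaling a day's duration scale by `(rate/K)^0.6` —
without it, independently drawn counts and durations overflow daylight
on a large fraction of days, which no real central-place forager does.
Each individual-day has its own RNG stream derived from (master seed,
individual, date), so any day regenerates independently.

The pooled preset is *calibrated*: its parameters are analytically
moment-matched and then adjusted by small fixed multiplicative factors
(between 0.96 and 1.15, frozen in code) so that the *pipeline output* on
the default cohort design — 30 individuals × 10 days at 1-min cadence,
days spread 2/3/2/3 over the four periods, two colonies with a roost
each — reproduces the pooled field summaries it targets: 6.67 trips/day,
1.16 h and 10.98 km per trip, 3.68 km maximum range, 97.82 km/day,
19.41 % attendance, 21.79 min total perching per perching trip. The
factors absorb schedule-feasibility truncation, segmentation edge
effects (departure/arrival snap to the fix grid) and the geometry of
patch movement. Calibration was fitted once over three master seeds and
not revisited; at that design the mean deviation on every target is
under ~1.5 %, with per-seed Monte-Carlo spread of 1–6 % depending on the
variable.

Those published pooled means are mutually inconsistent with a
colony-and-trips-only day (6.67 × 1.16 h of trips plus 19.41 % of
daylight at the colony leaves hours unaccounted, and 6.67 × 10.98 km
falls ~25 km short of the 97.82 km daily distance), which is why roosts,
loafing flights and within-buffer movement are structural parts of the
generator rather than decoration.

The per-cell (sex × period) parameter grid is fully supported — the
role-specialisation scenario in `analysis/04_movement_models.R` plants
cell-specific trip rates and shows the framework recovering them — but
the shipped preset is homogeneous across cells because per-cell field
summaries are not published; users with access to them can supply their
own grid.

**What passing tests show — and what they do not.** Ground-truth
recovery (100 % of planted trips, exact per-day counts, perch
recall/precision ≥ 0.999 at 1-min) demonstrates the pipeline's internal
correctness: segmentation, metrics and bout detection measure what was
planted. It does not demonstrate that the event-detection thresholds are
right for real kestrels: the generator's patches are cleaner than real
area-restricted search, its GPS has no positional noise outside anchors
and patches, altitude is schematic, and commutes never detour through
incidental hunting. On real data the completeness rules also face
device-reconfiguration gaps and mid-deployment cadence changes that the
generator only exercises through its per-deployment `sampling_interval`
field.

## Body mass and habitat

Body masses follow `baseline + offset·male + curve(doy) + individual
intercept + noise` with a female baseline of 147 g, planted offset
−18.28 g, a shared seasonal curve (slow rise to incubation, logistic
decline through the nestling period), individual sd 5 g and residual sd
6 g — magnitudes chosen once as field-realistic for a ~130–150 g falcon.
Thirty adults with ~9 measurements each span day-of-year 65–200. The
seven-model AIC comparison (smooth or linear day-of-year, with/without
sex, with/without interaction) and the recovery of the planted offset by
the smooth-plus-sex model are exercised in `analysis/05_body_mass.R` and
the test suite. Habitat counts are multinomial draws from the published
nine-class composition (renormalised to sum to one), 161 foraging
locations per sex.

## Problem sizes and numerical conventions

The validation suite runs the full cohort (30 × 10 days, ~240 k fixes,
~2000 trips) once and shares it across acceptance checks; power-style
properties (type-I error of the fit → LRT → Holm chain at 500 nulls,
100-replicate offset recovery, 1000-vector Holm oracle comparisons) use
sizes chosen to keep the whole suite in the minutes range while leaving
the Monte-Carlo error well inside each asserted band. Ties and
degeneracies are handled explicitly: duplicate timestamps keep the first
fix with a warning; empty segmentations return typed empty tables;
non-convergent mixed fits are flagged on the result object, never
silently accepted; and the day simulator resamples infeasible schedules
(counting them) rather than emitting days that overflow daylight.
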