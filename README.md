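# cpforage

Movement-ecology toolkit for GPS-tracked colonial central-place foragers,
built around the breeding lesser kestrel (*Falco naumanni*): birds that
commute from a breeding colony to open farmland, hunt from perches or in
short flights over a patch, and return — many times a day, with the
division of labour between the sexes shifting across the breeding season.

The package implements the full analysis chain such a study needs, plus a
synthetic track generator with complete ground truth so every stage can be
validated without field data:

1. **Track model** — Movebank-style CSV ingest with configurable column
   dialects, great-circle geodesy (haversine, R = 6371 km), and a NOAA-style
   solar ephemeris for sunrise/sunset (all timestamps UTC).
2. **Phenology** — assignment of fixes/trips/days to the four breeding
   periods anchored on each pair's laying and hatching dates:
   establishment, courtship (the 21 days before the first egg), incubation,
   nestling; eldest-chick age with hatch day = 0.
3. **Trip segmentation** — colony-attendance bouts (fixes within the 50 m
   anchor buffer, colony or roost), candidate excursions, and foraging
   trips: excursions that extend strictly beyond 300 m from the colony and
   contain a detected foraging event (spatially clumped fixes with highly
   variable instantaneous speed). Complete sunrise-to-sunset tracking days
   are identified by a coverage-and-gap rule.
4. **Movement metrics** — per trip: duration (h), accumulated distance
   (km), maximum distance from the colony (km); per day: daily distance,
   number of trips, and colony attendance as an interval-weighted
   percentage of daylight.
5. **Perch hunting** — perching bouts as maximal runs of consecutive
   displacements strictly below a cadence-specific threshold (1 m at 1 s;
   5 / 15 / 25 / 50 m at 1 / 3 / 5 / 10 min), discarding bouts under 30 s,
   summarised per trip (binary presence + total minutes).
6. **Statistics** — the mixed-model comparison framework: GLMMs
   (gaussian/identity, poisson/log, binomial/logit) with random intercepts
   for individual, year and colony; log and arcsine-square-root response
   transforms; likelihood-ratio backward-stepwise selection respecting
   marginality; penalized-smooth (GAMM) day-of-year models with REML-chosen
   effective df; Akaike weights `w_i = exp(-Δ_i/2)/Σ exp(-Δ_j/2)`;
   Holm-corrected post-hoc contrasts with compact letter displays; and the
   sex-by-habitat chi-squared homogeneity test.
7. **Synthetic data** — a day-schedule simulator (colony/roost bouts,
   commutes, foraging patches, planted perch runs, non-foraging loafing
   flights, all clipped to daylight) whose pooled preset is
   moment-calibrated so the *pipeline output* reproduces the published
   pooled field summaries; plus body-mass and habitat-count generators.

## Worked example

```r
library(cpforage)

sim <- simulate_cohort(n_individuals = 30, days_per_individual = 10,
                       cadence = 60, seed = 42)
pl  <- run_pipeline(sim$fixes, sim$sites, sim$individuals, sim$breeding)
t(pooled_summary(pl))
```

yields (field reference values in parentheses):

```
n_trips                2016      complete foraging trips
n_days                  300      complete tracking days
trip_duration_h        1.14      (1.16 h)
trip_distance_km      11.07      (10.98 km)
trip_max_distance_km   3.72      (3.68 km)
daily_distance_km     98.82      (97.82 km)
trips_per_day          6.72      (6.67)
attendance_pct        20.10      (19.41 %)
perch_time_min        21.84      (21.79 min, perching trips only)
```

Every planted trip is recovered (2016/2016; per-day trip counts exact on
all 300 days) and planted perch bouts are matched with recall 1.000 /
precision 0.999.

The numbered drivers under `analysis/` run the same chain as a narrative
workflow — `01_simulate_tracks.R` writes the raw CSV deposit,
`02_segment_trips.R` re-reads it through the standard readers and writes
`results/trips.csv` / `results/days.csv`, `03_perch_hunting.R` adds bout
detection, `04_movement_models.R` fits the GLMM set (including a
role-specialisation scenario with planted sex-by-period structure that the
backward-stepwise + Holm contrast machinery localises exactly),
`05_body_mass.R` runs the seven-model AIC comparison for body mass, and
`06_habitat_use.R` the habitat chi-squared test.

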