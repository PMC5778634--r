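---
title: "Measuring public open space use from GPS and accelerometer streams"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring public open space use from GPS and accelerometer streams}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(posuse)
```

## The measurement problem

Adolescents' physical activity at public open spaces (POS) — streets,
squares, parks, playgrounds, parking lots, vacant lots, transit stops —
cannot be read off either device stream alone. An accelerometer tells you
*how intensely* someone moved in each 15 s epoch; a GPS logger tells you
*where* they were every 30 s. Only the fused streams, segmented into
domains (home, school, leisure, transport) and joined with interview-style
annotations of what each stationary location was, yield the outcome of
interest: minutes of sedentary time, light (LPA), moderate-to-vigorous
(MVPA) and vigorous (VPA) activity accumulated *at POS during leisure
time, including the trips to and from the POS*.

`posuse` implements that measurement chain and the association analysis on
top of it, plus a synthetic-cohort generator that produces all six input
streams with full ground truth so every stage has a known-answer test
surface.

## Processing model

1. **Intensity.** Counts per 15 s epoch are classified with Evenson
   cutpoints: sedentary ≤ 100 < LPA < 2296 ≤ MPA < 4012 ≤ VPA. The four
   half-open intervals partition the count axis, so classification is a
   total function.
2. **Non-wear.** A maximal run of ≥ 60 min of consecutive zero counts
   (≥ 240 epochs) is non-wear and removed from all totals. The rule is
   applied with zero interruption tolerance — any non-zero epoch breaks
   the run — and runs truncated by the recording edge still count. Days
   are local civil dates; runs are evaluated within a day.
3. **Valid days.** A day is valid at ≥ 9 h (540 min) worn; a participant
   is included with ≥ 1 valid day. "Valid" refers to worn minutes only;
   GPS availability is accounted for separately, during fusion.
4. **Fusion.** Each GPS fix anchors a 30 s fused epoch and claims the two
   count epochs in [fix, fix + 30 s), with a ±5 s clock-drift tolerance.
   Worn count epochs with no fix become *location-missing* epochs: they
   keep contributing to wear and intensity totals but never to spatial
   domains.
5. **Plausibility.** Between consecutive located points, the later fix is
   invalid when implied speed > 130 km/h, jump > 1000 m, or |Δelevation|
   > 100 m (skipped when elevation is missing). Invalid fixes become
   location-missing and the speed chain restarts from the last valid fix.
6. **Movement.** Speed bands partition [0, ∞): stationary < 1 km/h ≤
   pedestrian < 10 ≤ bicycle < 25 ≤ motorized. Epochs with undefined
   speed (first of a bout, post-dropout) default to stationary — the
   conservative choice that avoids phantom trips. Single-epoch flicker
   flanked by an identical state is absorbed (`smooth_epochs = 1`) so
   one-epoch noise does not fragment trips. Interview-based corrections
   can overwrite movement inside declared windows (the congested-bus
   case: a motorized trip at bicycle speed).
7. **Domains.** Stationary epochs are school (subclassified PE / recess /
   class from the class timetable) when within 100 m of the school during
   school hours on a school day; otherwise home within 100 m of home;
   otherwise leisure. School precedes home when buffers overlap during
   school hours, because the school rule is the more specific one. Being
   at the school outside school hours is leisure. The buffer test is
   great-circle and boundary-inclusive (≤ 100 m).
8. **Segments and visits.** Maximal runs of identically labelled epochs
   are consolidated into events and trips. Annotations type leisure
   events (maximal-overlap assignment, ties to the earlier event). A
   POS-typed leisure event is a visit; the trip ending within one epoch
   of its start is its inbound trip, the trip starting within one epoch
   of its end its outbound trip. A trip bridging two POS events is
   counted once, as the outbound trip of the earlier visit. Trips whose
   adjacent events are non-POS are never attributed — cycling through a
   park on the way to school is a trip to school.
9. **Aggregation.** Per-participant means are taken over valid days;
   POS intensity minutes include attributed trip minutes; company counts
   increment once per reported company per visit.

## The association models

POS time per day is zero-heavy and right-skewed, so associations are
estimated with a two-part (hurdle) multilevel model: a logistic occurrence
part (any POS use) on all participants and a gamma log-link amount part on
the users, each with a normal school random intercept. Estimation is
Laplace-approximate maximum likelihood via `glmmTMB`, with the gamma shape
estimated jointly; Wald standard errors give CIs as exp(β ± 1.96·SE).
Exponentiated coefficients are odds ratios (occurrence) or proportional
differences in minutes (amount). Complete separation in the occurrence
part is surfaced with a warning, never silently penalized, because a
Firth-style fallback would change the estimand.

Model building follows a four-step procedure: (1) all candidate
covariates (residence, wear time, POS visits/day, number of days, rain,
sun, temperature, plus the matching total-intensity term for intensity
outcomes) entered simultaneously, retained at p < 0.05, with per-outcome
forced covariates always kept; (2) each individual factor (age, gender,
ethnicity, education, sport-club membership) separately, covariate
adjusted; (3) the significant factors jointly; (4) each social factor
(per-company visit counts) separately, adjusted for the step-3 factors.
Trends at p < 0.1 are marked "°" in reports but never move a factor into
step 3 — selection uses α = 0.05 only.

Outcomes with structural zeros (total POS time, POS VPA) get both parts;
POS sedentary time, LPA and MVPA are modelled with the gamma part only,
on the POS-user subset (`hurdle = FALSE` in `stepwise_procedure`).

Two covariate families are excluded from the occurrence part by design:
mean POS visits/day and the per-company visit counts both logically imply
the occurrence indicator (any visit means the participant used a POS), so
a logistic model containing them is separated by construction. They enter
the amount part only. For the same robustness reasons, candidates with no
variation in the analysis subset are dropped before screening (with a
message), and a model whose Hessian is not positive definite raises an
error carrying the gradient norm rather than returning unusable standard
errors.

## What the generator emulates — and what it does not

`sim_config()` fixes the study conditions: 30 s fixes, 15 s counts, two
measured days (one school day, one weekend day), six schools with
three classes each (Mon–Fri 08:30–15:30, two recess blocks, one weekly
two-hour PE block), homes 0.3–2.5 km from school, and demographic
marginals typical of a Belgian urban adolescent cohort (54.4% girls, mean age 14.2 ± 1.1,
28.3% non-western-European, 68.8/22.0/9.2% general/vocational/technical
education, 22.5% low SES, 58% sport-club members, mostly urban).

The POS outcome process is itself a hurdle: a daily visit probability on
the logit scale (reference 0.5/day, so ~75% of participants use a POS at
least once over two days) shifted by configurable log-odds effects and a
school random intercept, and a gamma dwell time (shape 2, reference mean
25 min) shifted by log-scale effects. Visit sites are drawn from a
catalog whose category mix is dominated by transit stops, as observed in
this population. Counts come from context-conditional lognormal regimes
whose medians sit inside the target Evenson band, giving realistic right
skew while keeping intensity labels recoverable; mode speeds (5, 16,
40 km/h) sit well inside their bands so modal classification is
recoverable. Non-wear is injected as a zero-count run of 60–120 min
(15% of days), GPS dropout as 5–20 min of deleted fixes (20% of days).
Trip durations, dwell distributions and visit probabilities are free
parameters — the source study reports none of them — so they are
documented defaults, not estimates of any real cohort.

Deliberate simplifications: trips are straight-line interpolations at
constant speed (no road network), there is no indoor/outdoor distinction,
weekends differ from weekdays only by the absence of school blocks, all
timestamps live in one civil timezone with no DST transition, and
annotations are error-free. Passing tests therefore demonstrate that the
pipeline recovers what the measurement model defines — not that it is
robust to urban-canyon GPS noise, device clock resets, or unreliable
interview recall.

## Numerical choices

* Distances are haversine on a 6,371,000 m sphere; the 100 m buffer is
  boundary-inclusive.
* Intensity minutes are always accumulated from 15 s classifications
  (0.25 min each); 30 s count sums are diagnostics only, because doubling
  15 s thresholds is not equivalent.
* Trip adjacency for visit attribution tolerates a one-epoch (30 s) gap,
  since consolidation may insert location-missing epochs at boundaries.
* GLMM convergence follows the backend's default relative tolerance
  (~1e-8 on the objective); non-convergence is an error carrying the
  optimizer message, not a silent result. Observed reproducibility of
  fixed effects across equivalent fits is ~1e-5 on the link scale.
* Per-participant-day random streams derive from the master seed by a
  counter-based integer hash, so any subset of the cohort regenerates
  identically regardless of generation order.
* Simulation problem sizes in the shipped tests: trajectory-level checks
  run at 50 participants × 2 days; model-layer recovery and type-I
  experiments at 200 replicate cohorts of n = 1000 and n = 400 drawn from
  the summary-level simulator. These sizes give Monte-Carlo error small
  enough to resolve 5% bias and coverage near 0.95.

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config(n_participants = 50, n_schools = 6, seed = 1)
sim <- simulate_dataset(cfg)
res <- run_pipeline(sim)
res$descriptives

sw <- stepwise_procedure(res$summaries, "pos_min_day")
sw
```

## Known limitations

* The event/transport split is purely speed-based; PALMS-style processors
  also consult acceleration internally, in ways that are not publicly
  documented. Corrections exist precisely to patch the cases speed cannot
  separate (slow buses, fast cycling).
* Transit-stop events followed by motorized trips are counted as POS
  visits — no "pure transfer" exclusion is attempted, since the data
  cannot distinguish waiting-as-leisure from waiting-to-board.
* The gamma amount part requires strictly positive outcomes; occasional
  zero intensity minutes among POS users (e.g. a user with zero POS
  sedentary time) are excluded from that part's subset by construction.
* Multi-leg journeys attribute only the leg adjacent to the POS event;
  chained attribution is out of scope of the default and exposed as a
  documented extension point.
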