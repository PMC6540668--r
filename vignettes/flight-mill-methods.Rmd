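---
title: "Processing and modelling tethered flight-mill telemetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Processing and modelling tethered flight-mill telemetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beemill)
library(dplyr)
```

## The measurement model

A tethered flight mill converts flight into rotation: the insect is glued to
a magnetised tag, attached to a revolving arm, and a Hall sensor emits one
impulse per revolution ("circuit") of known circumference (0.848 m here).
The raw record of a flight session is therefore an ordered sequence of
inter-impulse intervals, one per completed circuit. Everything downstream —
distance, duration, velocity, endurance classification — is a function of
that interval sequence plus per-subject covariates (colony of origin,
treatment arm, intertegular span as the body-size proxy, tag-fit rating,
feeding outcome).

`beemill` treats the interval sequence, not absolute timestamps, as the
canonical representation, because that is what the sensor natively reports;
`timestamps_to_log()` converts timestamped acquisitions by differencing and
rejects non-monotone stamps. Circuit indexing is 1-based, with the index
stored explicitly in every file so "the first circuit" is never ambiguous.

## Stoppage detection and the in-test window

Behaviourally, a flight stoppage is the bee landing; operationally it is
enforced as a 20 s rest, so stoppages are recoverable post hoc as circuits
whose interval strictly exceeds `stoppage_threshold_s` (20 s). Two protocol
rules shape detection (`detect_stoppages()`):

* a qualifying *first* circuit is discounted — it is an acclimatisation
  stall, not a stoppage, and does not count against the budget;
* the test ends at the earlier of the circuit carrying the sixth genuine
  stoppage (`max_stoppages = 5` permitted) and the circuit on which
  cumulative duration reaches the 60-minute cap. The straddling circuit is
  retained; anything after the termination point is out-of-test and ignored
  everywhere downstream.

Ties at exactly 20.0 s are deliberately *not* stoppages (the rule is
strictly "greater than"), and the cap comparison is `>=` on cumulative
in-test duration, stops included.

## Circuit cleaning and session metrics

Take-off is stimulated (stand removal, leg taps) and produces strikingly
fast circuits; likewise the frictionless arm coasts after a landing. Velocity
analysis therefore uses a cleaned circuit set (`clean_circuits()`): the
first five circuits of the session, the five circuits after each stoppage,
and the circuit before each stoppage are excluded, windows clipped to the
in-test range and unioned where stoppages are close together. The stoppage
circuit itself is also excluded: its interval contains the 20 s rest and
arm coasting, so a "velocity" computed from it would be meaningless.
Exclusion affects velocities only — total distance is the in-test circuit
count times the circumference, and total duration is the sum of all in-test
intervals, stops included, exactly as the protocol defines endurance.

Per-circuit velocity is circumference over interval; mean velocity is the
cleaned distance over the cleaned duration (so it is the duration-weighted,
not arithmetic, mean of circuit velocities); maximum velocity is the
fastest cleaned circuit. Two binary endurance outcomes are derived: flying
beyond 100 m (the inclusion threshold — frequency plots of this assay show
a spike of terminations below it, and 118 circuits of 0.848 m are the first
to exceed 100 m) and flying longer than 2 000 s (the observed duration
distribution is bimodal with its trough there). A session is "complete"
when in-test duration reaches the 3 600 s cap.

When cleaning leaves no circuit (very short flights), velocity fields are
`NA` while endurance fields are still computed — such bees are below the
100 m threshold anyway.

## The filter cascade

`apply_cascade()` reduces the tested cohort to the endurance analysis set
through ordered inclusion steps, recording per-treatment counts at each:
fed; fed > 60 s (satiation proxy); no technical failure; ideal tag fit
(rating 1 — unideal fits measurably depress distance); flew; flew > 100 m;
and finally body-size trimming. Counts are non-increasing by construction
and the two treatment columns always partition the total; a property test
checks both against a sequential brute-force filter on randomised cohorts.

Trimming (`trim_its_extremes()`) removes the `k` smallest and `k` largest
bees by intertegular span with `k = round(0.10 * n)` (half-up; for the
67-bee reference cohort `k = 7`), *pooled* across treatments. Pooling is
deliberate: it is what allows the per-treatment removal counts to be
unequal when the two arms' size distributions differ, which is exactly why
the step exists (normalising a size imbalance between arms). Boundary ties
are broken by bee id so the subset is reproducible. Half-up rounding is
adopted because it reproduces the reference 7 + 7 removal on n = 67;
round-half-even would too, but half-up is the convention stated here once
and used everywhere.

`summarize_effects()` reports per-arm means with standard errors and two
derived contrasts: the percent reduction of the exposed arm's mean distance
relative to control, and the implied foraging-area decline
`100 (1 - (1 - r)^2)` — central-place foragers make return trips, so
accessible area scales with the square of flight range.

## The model suite

Every outcome is modelled by maximum likelihood with fixed effects
`treatment * its_mm` and a colony random intercept: binomial-logit for the
binary outcomes (fed, flew, > 100 m, > 2 000 s), gaussian for the
continuous ones (feeding time, distance, mean and maximum velocity). Two
departures from a plain `lme4` call are built in:

* **Zero-variance fallback.** When the colony intercept variance is
  estimated below `var_tol = 1e-8` (variance scale), the random term
  explains none of the variance and the model is refitted as a GLM/LM with
  `fallback_applied` set. The threshold is a numerical-zero criterion, not
  a significance test. Note the ML variance estimator under a truly zero
  random effect lands exactly on the boundary in only roughly three
  quarters of samples (the rest are small spurious positives), so the
  fallback is a majority, not a certainty, under a true zero; a genuinely
  non-zero colony effect essentially never triggers it. When the mixed fit
  fails outright (e.g. quasi-separation in a binomial outcome), the
  fixed-effects fit is returned flagged `mixed_fit_failed` rather than
  aborting.
* **Wald reporting with `n - p` residual df.** Binomial fits report z
  statistics; gaussian fits report t statistics on `n - p` degrees of
  freedom. Small-sample df corrections (Kenward–Roger, Satterthwaite) are
  out of scope; with the cohort sizes involved the difference is
  immaterial.

Gaussian responses can be log-transformed: `transform = "auto"` applies the
log when a Shapiro–Wilk check on the (positive) response rejects normality
at 0.05, and the choice is recorded on the fit. Where the
treatment-by-size interaction is significant, `run_flight_model_suite()`
refits per-treatment size slopes, mirroring the usual follow-up analysis.

### Velocity trajectories

Early-flight dynamics are modelled on binned repeated measures
(`bin_velocity()`, `fit_velocity_trajectory()`): mean cleaned velocity per
block of 50 original circuit indices over the first 900 circuits, giving up
to 18 measures per bee (empty blocks are `NA`, and bees with fewer than two
informative blocks are dropped with a notice). Binning plus z-scoring the
circuit position is what makes the repeated-measures model well
conditioned; fitting all 900 raw measures per bee is numerically fragile
and statistically pointless at this noise level. The model is a linear
mixed model with a per-bee random intercept and fixed effects treatment,
body size, scaled circuit position, and the treatment-by-circuit
interaction. A per-bee intercept is the defensible reading of the
repeated-measures structure here; no random slope is fitted because 18
points per bee at this noise level do not support one.

## The synthetic cohort simulator

`simulate_cohort()` exists so that every pipeline stage and model is
testable at desk scale without hardware data. Its default configuration
(`default_calibration()`) encodes the study conditions this package was
built around: 111 bees per arm balanced over three colonies; intertegular
spans from a truncated normal (mean 4.9 mm, sd 0.35 mm, support
[3.5, 6.5] mm, caliper-rounded to 0.01 mm); logit-linear feeding and
flight propensities in body size, the control flight curve passing through
probability 0.49 at 4 mm and 0.92 at 6 mm; lognormal feeding durations with
arm means 138 s / 127 s; and flight sessions generated circuit by circuit:

* velocity of circuit *i* is `base * (1 + h * exp(-i / 900)) * (1 + e_i)`,
  with a per-bee baseline (mean 0.63 m/s, between-bee sd 0.08),
  multiplicative noise (sd 0.12), and an exposure-only hyperactivity boost
  `h = 0.42` decaying over the early flight phase — neonicotinoids are
  nicotinic-receptor agonists and transiently elevate locomotor output, and
  the decay constant is a free calibration parameter since the real assay
  shows elevated exposed-arm velocity over roughly the first 900 circuits
  without a stated functional form;
* stoppages arrive at rate 5e-4 per circuit and are written as
  20 s + exponential excess, so they are detectable by the > 20 s rule by
  construction;
* termination is a memoryless per-circuit hazard in two phases: elevated
  over the first 118 circuits (2.2e-3 control / 4.7e-3 exposed per
  circuit) and lower thereafter (1.5e-4 / 1.45e-3). A single constant
  hazard cannot reproduce both the sub-100 m termination spike and the long
  right tail of control flights (with most control bees reaching the cap),
  which is why the hazard is piecewise-constant; it remains one memoryless
  mechanism. The late-phase hazard falls log-linearly with body size in the
  control arm only (slope 0.8 per mm), which is what lets larger control
  bees fly farther while exposure flattens that relationship.

Sessions additionally end at the stoppage budget or the 60-minute cap,
whichever comes first, exactly as the protocol terminates real tests.
Identical `(config, seed)` pairs yield bit-identical cohorts.

**What the simulator does not emulate.** Within-bee velocity
autocorrelation (noise is independent per circuit; real flight is smoother
on short timescales), diurnal or bout structure, colony-level random
effects (the defaults inject none, matching an assay in which colony
explained no variance — which also makes the fallback path the typical
one), wind-down coasting dynamics, and any pharmacokinetics of the
exposure. Passing tests on simulated cohorts therefore demonstrate that
the pipeline recovers the structure this generator injects, not that the
generator is a complete model of bee flight.

`null_config()` copies all treatment-dependent parameters from the exposed
arm to the control arm (hazards at exposed levels, no hyperactivity, no
propensity offsets), producing exchangeable arms for type-I-error studies;
it uses the short-flight (exposed) dynamics so null replications stay
cheap.

## Numerical choices and degenerate inputs

* Stoppage rule strictly `> 20 s`; ties are flight.
* Cap rule `>=` on cumulative duration; the straddling circuit is kept.
* Exclusion windows are clipped at sequence boundaries and unioned.
* `circuits_for_distance()` is a guarded ceiling
  (`ceiling(d / c - 1e-9)`) so exact multiples of the circumference do not
  round up.
* Empty logs are legal (a bee that never flew): endurance fields are zero,
  velocity fields `NA`, `flew = FALSE`.
* Trim ties break by bee id; `2k >= n` is an error rather than a silent
  empty set.
* Simulated intervals are rounded to 0.1 ms *before* the termination rules
  are applied, so written logs satisfy the cap invariant exactly as
  validated on read-back.
* Stored ITS values are rounded to 0.01 mm (caliper precision).

## Problem sizes used by the test suite

Replicate-based checks are sized to run on a single CPU in minutes while
keeping Monte-Carlo error well below the tolerances they assert: oracle
equivalence on 1 000 randomised sessions and 1 000 randomised mini-cohorts;
type-I error of the endurance treatment effect from 500 null cohorts of 60
bees per arm, checked against two-sided binomial bounds around 0.05;
sign-recovery of the injected velocity, hazard and size effects on 50
cohorts at the default 111 bees per arm; calibration anchors on 200 default
cohorts; trajectory-model offset recovery and null size on 200 replicates
of 30 + 30 bees with 18 bins each.

## Worked example

```{r example}
sim <- simulate_cohort(default_calibration(), seed = 1)
metrics <- process_cohort(sim$logs, sim$bees)
cascade <- apply_cascade(sim$bees, metrics)
cascade$counts

effects <- summarize_effects(cascade$analysis_set)
effects

suite <- run_flight_model_suite(cascade)
tidy(suite) %>% filter(term == "treatmentpesticide")
```

```{r trajectory}
binned <- binned_velocity_table(metrics, sim$bees)
trajectory <- fit_velocity_trajectory(binned)
tidy(trajectory)
```

## Known limitations

* Residual df for mixed fits are the `n - p` approximation; p-values for
  small cohorts are mildly liberal relative to Satterthwaite-type df.
* The trajectory model assumes a linear trend over scaled circuit position
  within the 900-circuit window; curvature in the hyperactivity decay is
  absorbed into the residual.
* The cascade takes feeding outcomes from the subject table as recorded;
  it does not re-derive them from raw observation.
* External datasets must be adapted to the canonical CSV dialects
  (`bee_id,circuit_index,interval_s`; see `read_bee_table()`), since raw
  deposit layouts vary by acquisition script.
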