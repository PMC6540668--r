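# beemill

Tethered flight-mill assays measure insect flight capacity directly: the
subject is tethered to a frictionless revolving arm and a Hall sensor logs
the time of every revolution ("circuit") of known circumference. `beemill`
is an R package for the full analysis pipeline of such assays in bees —
from raw per-circuit interval logs to cleaned flight metrics, cohort
accounting, and the statistical models of flight propensity, endurance and
velocity dynamics. It was built for behavioural-ecotoxicology studies of
sublethal pesticide effects (e.g. acute neonicotinoid exposure in bumblebee
workers), where the questions are: who flies, how far, how fast, and how
does that change under exposure and with body size?

## What it computes

For one session with circuit intervals $t_1, \dots, t_n$ (seconds) on a
mill of circumference $c$ (metres):

* **Stoppages** are circuits with $t_i > 20$ s (the enforced rest period);
  a qualifying first circuit is discounted as acclimatisation, and the test
  ends at the sixth genuine stoppage or the 60-min cap, whichever first.
* **Endurance**: total distance $D = n\,c$ over in-test circuits, total
  duration $T = \sum_i t_i$ (stops included), plus binary outcomes
  $D > 100$ m and $T > 2000$ s and cap completion $T \ge 3600$ s.
* **Velocity** (cleaned circuits only — the first five of the session, five
  after each stoppage, one before each stoppage and the stoppage itself are
  excluded): per-circuit $v_i = c / t_i$, mean velocity
  $\bar v = \sum_{i \in \mathrm{clean}} c \,/\, \sum_{i \in \mathrm{clean}} t_i$,
  maximum velocity $\max_i v_i$.
* **Cohort cascade**: fed → fed > 60 s → no technical failure → ideal tag →
  flew → > 100 m → pooled 10 % body-size trim, with per-treatment counts at
  every step and derived contrasts (percent distance reduction $r$ and the
  central-place foraging-area decline $100\,(1-(1-r/100)^2)$).
* **Models**: maximum-likelihood (G)LMMs with fixed effects
  `treatment * ITS` and a colony random intercept that falls back to a
  GLM/LM when the colony variance is estimated at zero; plus a
  repeated-measures LMM of binned velocity (18 blocks of 50 circuits over
  the first 900) with a per-bee random intercept and a
  treatment-by-circuit interaction.
* **Synthetic cohorts**: a calibrated generative model of the whole assay
  (size-dependent propensities, exposure hyperactivity with decay,
  two-phase termination hazards, stoppages, the session cap) so the
  pipeline and models can be exercised and power-checked without hardware.

## Worked example

```r
library(beemill)
library(dplyr)

sim     <- simulate_cohort(default_calibration(), seed = 1)
metrics <- process_cohort(sim$logs, sim$bees)
cascade <- apply_cascade(sim$bees, metrics)
cascade$counts
#> # A tibble: 8 × 4
#>   step              control pesticide total
#>   <chr>               <int>     <int> <int>
#> 1 started               111       111   222
#> 2 fed                   104       103   207
#> 3 fed_over_60s           93        89   182
#> 4 no_technical_fail      92        86   178
#> 5 tag_rating_1           73        69   142
#> 6 flew                   54        55   109
#> 7 over_100m              39        37    76
#> 8 its_trimmed            33        27    60
```

The counts are the attrition of one simulated 222-bee cohort through the
filter cascade: how many fed, fed to satiation, survived technical checks,
carried an ideal tag, initiated flight, exceeded the 100 m threshold, and
remained after trimming the body-size extremes.

```r
summarize_effects(cascade$analysis_set)
#> <mill_effects>
#> # A tibble: 2 × 10
#>   treatment     n mean_distance_m se_distance_m mean_duration_s se_duration_s
#>   <fct>     <int>           <dbl>         <dbl>           <dbl>         <dbl>
#> 1 control      33           1983.          86.4           3355.          123.
#> 2 pesticide    27            726.         108.             993.          171.
#> distance reduction: 63.4%   foraging-area decline: 86.6%
```

Exposed bees in this simulated cohort fly roughly a third of the control
distance; squaring the range ratio turns the 63 % distance reduction into
an 87 % decline in accessible foraging area.

```r
suite <- run_flight_model_suite(cascade)
tidy(suite) %>% filter(term == "treatmentpesticide", response == "total_distance_m")
#> # A tibble: 1 × 8
#>   response         family       n term               estimate std.error statistic p.value
#>   <chr>            <chr>    <int> <chr>                 <dbl>     <dbl>     <dbl>   <dbl>
#> 1 total_distance_m gaussian    60 treatmentpesticide    -8.51      3.86     -2.21  0.0315
```

(The distance model was log-transformed by the automatic normality check;
the coefficient is on the log scale.) The binned velocity trajectory over
the first 900 circuits shows the exposure hyperactivity and its decay:

```r
binned <- binned_velocity_table(metrics, sim$bees)
tidy(fit_velocity_trajectory(binned))
#> # A tibble: 5 × 5
#>   term                          estimate std.error statistic  p.value
#> 1 (Intercept)                   0.735     0.120        6.12  1.16e- 9
#> 2 treatmentpesticide            0.192     0.0154      12.5   3.90e-34
#> 3 circuit_z                     0.000333  0.000448     0.742 4.58e- 1
#> 4 its_mm                       -0.0238    0.0241      -0.986 3.24e- 1
#> 5 treatmentpesticide:circuit_z -0.0516    0.000802   -64.3   0
```

Exposed bees fly about 0.19 m/s faster over the window, and the negative
treatment-by-circuit interaction is the boost decaying with circuit.

A thin command-line wrapper over the same functions ships in
`inst/cli/beemill` (`simulate`, `process`, `analyze` subcommands), and
`vignettes/flight-mill-methods.Rmd` documents the methods, parameters and
design decisions in full.

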