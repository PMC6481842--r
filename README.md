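# ednaoccu

Hierarchical inference for paired **visual encounter surveys (VES)** and
**environmental DNA (eDNA)** monitoring of stream species, built around the
wood turtle (*Glyptemys insculpta*) use case: detect a cryptic, declining
species at dozens of stream sites, ask whether filtering water for DNA can
replace or complement wading in and looking, and decide how many replicates
of each method a monitoring program should buy.

The package is aimed at quantitative ecologists and monitoring-program
designers. It chains together:

- **Single-season site-occupancy models** with imperfect detection.
  Per site *i* with detection history *y<sub>ij</sub>* over occasions *j*,

  L<sub>i</sub> = ψ<sub>i</sub> ∏<sub>j</sub> p<sub>ij</sub><sup>y<sub>ij</sub></sup> (1−p<sub>ij</sub>)<sup>1−y<sub>ij</sub></sup> + (1−ψ<sub>i</sub>) I[all y<sub>ij</sub> = 0],

  with logit links on occupancy ψ and detection p, covariates on both, and
  an "occupied sites" (OS) variant that fixes ψ = 1 to study detection alone.
- **N-mixture abundance estimation** from repeated counts with a
  zero-inflated Poisson state model: latent abundance N<sub>i</sub> ~ ZIP(λ<sub>i</sub>, φ),
  counts c<sub>ij</sub> ~ Binomial(N<sub>i</sub>, p<sub>ij</sub>), with the latent sum truncated at a
  checked bound. Model-averaged site abundance divided by stream volume gives
  the turtle-density covariate used in the eDNA detection models.
- **Two-stage AICc model selection**: every observation-covariate
  combination (≤ 3 per model) screened with the state model held constant,
  the winning combination crossed with every site-covariate combination
  (≤ 2 per model); AICc = −2LL + 2K + 2K(K+1)/(n−K−1), Akaike weights over
  the full candidate set, and model averaging on the link scale with
  unconditional (Burnham–Anderson) intervals.
- **Survey planning** with the cumulative detection probability
  p\* = 1 − (1 − p)<sup>n</sup> and its inverse (smallest n reaching a target
  confidence).
- **Method comparison**: likelihood-ratio g-tests of independence on the
  site-level cross-classification, and Wald proportion intervals for naive
  occupancy.
- **A survey cost ledger** with startup/recurring lines, laboratory
  overhead, and per-study / per-site / per-sample amortization.
- **A calibrated synthetic-data generator** that simulates the whole chain
  (covariates → occupancy → abundance → counts, detections, and filter
  replicates) for parameter-recovery and end-to-end testing.

## Worked example

Simulate a 37-site study from the calibrated reference scenario and run the
full chained analysis:

```r
library(ednaoccu)

sim <- simulate_study(wood_turtle_scenario(n_sites = 37, seed = 2))
res <- run_survey_pipeline(sim$ves, sim$counts, sim$edna,
                           sim$bundle, sim$volumes)
res
#> <pipeline_result>
#> # A tibble: 6 × 5
#>   method quantity        estimate lower upper
#>   <chr>  <chr>              <dbl> <dbl> <dbl>
#> 1 ves    naive_occupancy    0.459 0.378 0.541
#> 2 ves    detection          0.883 0.718 0.957
#> 3 ves    occupancy          0.459 0.286 0.642
#> 4 edna   naive_occupancy    0.432 0.351 0.514
#> 5 edna   detection          0.634 0.420 0.806
#> 6 edna   occupancy          0.491 0.254 0.732
#> method independence: G = 43.009, df = 1, p = 0.000
```

Reading the table: turtles were seen at 45.9% of sites and eDNA detected at
43.2% (naive rates with ±1 SE bands); correcting for imperfect detection,
the model-averaged occupancy estimates of the two methods agree (0.46 vs
0.49), while a single VES survey is far more sensitive than a single filter
replicate (0.88 vs 0.63). The g-test rejects independence of the two
methods — they find the same sites.

How many filter replicates does a monitoring program need? Chain the
occupied-sites detection estimate into the cumulative detection curve:

```r
d <- res$edna$os_detection   # per-filter detection, occupied sites only
cumulative_curve(d$estimate, lower = d$lower, upper = d$upper, n_max = 4)
#> # A tibble: 4 × 4
#>       n p_star lower upper
#>   <int>  <dbl> <dbl> <dbl>
#> 1     1  0.654 0.480 0.794
#> 2     2  0.880 0.730 0.958
#> 3     3  0.958 0.860 0.991
#> 4     4  0.986 0.927 0.998
min_replicates(d$estimate, 0.95)
#> [1] 3
```

and compare what the two designs cost per sample:

```r
amortize(wood_turtle_cost_ledger())
#> # A tibble: 2 × 4
#>   method per_study per_site per_sample
#>   <chr>      <dbl>    <dbl>      <dbl>
#> 1 ves       22026.     551.      275.
#> 2 edna      10215.     255.       42.6
```

An eDNA sample costs $42.6 against $275.3 for a VES survey once lab
overhead and field costs are amortized over a 40-site design.

`autoplot()` methods draw the detection curves (`predict_detection()`) and
cumulative detection bands (`cumulative_curve()`); `tidy()` and `glance()`
give broom-style coefficient and fit summaries for `fit_occupancy()` and
`fit_nmixture()` objects.

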