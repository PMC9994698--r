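# popantel

Open-population Jolly–Seber (POPAN) mark–recapture analysis for monitored
release programs in which the number and timing of entrants are **known**
and part of the animals carry radio transmitters. The motivating system is
a headstarted Blanding's Turtle (*Emydoidea blandingii*) population: 260
juveniles released 2015–2020 into a small urban wetland complex, tracked by
radio-telemetry and live-trapped in annual surveys, with the goal of
estimating abundance, apparent survival, and the post-release sex ratio.

## The model

Individuals are grouped by release cohort and by the number of consecutive
annual occasions they were radio-tracked (23 groups). Three POPAN
parameters are **fixed** by the study design rather than estimated:

- probability of entry *b*: 1 at each group's release occasion, 0
  elsewhere (release timing is known);
- the group superpopulation *N*: the number released in that group;
- detection probability *p*: 1 while a group is telemetered (a tracked,
  live animal is always found), 0 before release and in years without
  survey effort, and a free logit-scale parameter in survey years
  (2018–2020) otherwise.

What remains is a likelihood over encounter histories ω with free apparent
survival Φ and free detection *p*. For a history with first detection *f*
and last detection *l*, released at occasion *r*:

    P(ω) = [ Π_{k=r}^{f-1} (1 − p_k) Φ_k ] · p_f ·
           [ Π_{k=f}^{l-1} Φ_k · p_{k+1}^{x_{k+1}} (1 − p_{k+1})^{1 − x_{k+1}} ] · χ_l

with the backward recursions ζ_t (never seen from *t* on) and χ_t (never
seen after *t*); released-but-never-seen animals contribute ζ_r. Because
*p* = 1 while tracked, a telemetered animal that disappears contributes
directly to mortality: certain detection with no encounter implies no
survival.

Candidate submodels index Φ and *p* by time, by acclimation
(`New` = first interval after release, `Exp` afterwards), by cohort, and by
a dedicated 2019-new-release level that captures a mass-mortality event;
models are ranked by AICc with Akaike weights, goodness of fit is assessed
with Fletcher's ĉ, and annual abundance is derived from the release
schedule and fitted survival with Delta-method confidence intervals.

## Worked example

No field data ship with the package; the synthetic-data module generates
encounter histories with exactly the structure the likelihood assumes, and
its defaults are the study conditions (release schedule 21/36/49/49/48/57,
the 23-group telemetry plan, Φ = 0.89 with 0.43 for new 2019 releases,
*p* = 0.34/0.10/0.04).

```r
library(popantel)
library(dplyr)

scenario  <- simulation_scenario(seed = 42)
histories <- simulate_histories(scenario)
design    <- build_design()
fit       <- fit_popan(histories, design, "Phi(acc2019) p(t)")
fit
#> <popan_fit> Phi(acc2019) p(t)
#>   logLik: -173.39529  k: 5  converged: TRUE
#>   observed individuals: 136  superpopulation: 260

tidy(fit) %>% select(term, estimate, std.error, conf.low, conf.high)
#> # A tibble: 5 × 5
#>   term           estimate std.error conf.low conf.high
#>   <chr>             <dbl>     <dbl>    <dbl>     <dbl>
#> 1 phi              0.917     0.0246   0.854     0.954
#> 2 phi(2019)[New]   0.488     0.118    0.275     0.706
#> 3 p(2020)          0.0275    0.0122   0.0114    0.0648
#> 4 p(2019)          0.110     0.0293   0.0644    0.182
#> 5 p(2018)          0.336     0.0518   0.243     0.444
```

`phi` is the shared annual apparent survival (true value 0.89),
`phi(2019)[New]` the first-interval survival of the 2019 releases (true
0.43), and the `p(year)` rows the survey detection probabilities. At the
study's own sample size the estimates carry the sampling error visible
here; the confidence intervals cover the generating truth.

```r
abundance <- derive_abundance(fit)
abundance
#> # A tibble: 6 × 6
#>   occasion  year abundance std.error conf.low conf.high
#>      <int> <int>     <dbl>     <dbl>    <dbl>     <dbl>
#> 1        1  2015      21       0         21        21
#> 2        2  2016      55.3     0.516     54.2      56.3
#> 3        3  2017      99.7     1.83      96.1     103.
#> 4        4  2018     140.      4.13     132.      148.
#> 5        5  2019     177.      7.23     163.      191.
#> 6        6  2020     198.     11.3      176.      221.

density_estimate(abundance$abundance[6], area_ha = 9)
#> # A tibble: 1 × 4
#>   abundance area_ha density density_rounded
#>       <dbl>   <dbl>   <dbl>           <dbl>
#> 1      198.       9    22.0              22
```

Abundance starts at the 21 animals released in 2015 (no uncertainty: the
release is known), jumps by each later release, and declines with
mortality in between. `autoplot(abundance)` draws the trajectory with its
confidence ribbon. The sex-ratio module compares first-capture counts
against the 1:1.5 male:female incubation ratio:

```r
sex_ratio_test(c(23, 23), expected_ratio = "1:1.5") %>%
  select(statistic, df, p.value)
#> # A tibble: 1 × 3
#>   statistic    df p.value
#>       <dbl> <int>   <dbl>
#> 1      1.92     1   0.166
```

Multi-model workflows go through `default_candidates()` (the 18-model
set), `fit_popan()` per model, and `rank_models()` for the AICc table with
Akaike weights and a parsimony annotation. `cmd_fit()`, `cmd_rank()`,
`cmd_simulate()`, `cmd_abundance()`, and `cmd_sexratio()` wrap the same
functions with on-disk artifacts and provenance headers; a thin
command-line wrapper lives at `inst/cli/popantel.R`.

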