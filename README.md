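# flocknet

Social-network inference and dietary-decision models for RFID-tracked
foraging birds.

Wild birds fitted with RFID tags visit instrumented feeders in loose
fission–fusion flocks, leaving a bursty stream of timestamped antenna
reads. `flocknet` turns that stream into science: it segments the bursts
into flocking events, builds weighted social networks from co-membership,
and models how a bird's social centrality predicts its dietary decisions
when a novel food appears next to a familiar one — while a synthetic-data
generator with full ground truth makes every step of the chain testable.

## The method in brief

1. **Flock detection.** Detection times within a site-day are modelled as
   a 1-D Gaussian mixture; the number of components is selected by BIC
   (gap-statistic start, local hill search, tied variances, small-weight
   pruning). Each mixture component is a flocking event; its members are
   the tags assigned to it. The result is a group-by-individual matrix.
2. **Social network.** The dyadic association is the Simple Ratio Index,
   `SRI(A,B) = x / (n_A + n_B − x)` — the proportion of events involving
   either bird in which both were seen. Networks are symmetric, weighted,
   built per site and period. Node metrics: weighted strength `Σ_b SRI(a,b)`,
   average edge weight, eigenvector centrality (largest component, scaled
   to max 1), mean flock size, number of unique associates, and the
   typical group size `Σn² / Σn`.
3. **Dietary models.** Per trial and bird: novel vs familiar detection
   counts (usage), first-arrival choice (neophobia), two latencies, and
   post-first-use counts. Usage models are binomial-logit GLMs with
   quasi-binomial dispersion `φ = χ²_Pearson/(n−p)`; latencies are
   gaussian. Each trial uses the network from the period immediately
   before it.
4. **Permutation inference.** Because network metrics are mutually
   dependent, each term also gets
   `p_rand = (1 + #{|coef_perm| ≥ |coef_obs|}) / (B + 1)` from B node
   permutations that reshuffle the response within site strata and refit
   with everything else untouched.

## Worked example

```r
library(flocknet)

cfg    <- sim_config(n_individuals_per_site = 25, baseline_days = 6,
                     trial_days = 4, seed = 2024)
study  <- simulate_study(cfg)                       # detections + truth
events <- detect_flocks(study$detections, seed = 2024)

metrics <- dplyr::bind_rows(lapply(c("S1", "S2"), function(s) {
  ev <- events[events$period == "baseline" & events$site_id == s, ]
  g  <- build_gbi(ev)
  node_metrics(sri_network(g, period = "baseline"), g)
}))

resp <- build_responses(subset(study$detections, period == "trial1"))
mdat <- assemble_model_data(resp, metrics, traits = study$population)
fit  <- fit_dietary_glm(mdat, response = "usage", metric = "strength",
                        covariates = c("site_id", "sex", "age", "immigrant"))
tidy(fit)
#> # A tibble: 6 × 5
#>   term          estimate std.error statistic  p.value
#>   <chr>            <dbl>     <dbl>     <dbl>    <dbl>
#> 1 (Intercept)    -1.53      0.174     -8.75  5.19e-11
#> 2 strength        0.796     0.0880     9.05  2.05e-11
#> 3 site_idS2      -1.59      0.0908   -17.5   6.22e-21
#> 4 sexM            0.0731    0.0859     0.851 4.00e- 1
#> 5 agejuvenile    -0.0168    0.0857    -0.196 8.45e- 1
#> 6 immigrantTRUE  -0.0433    0.0834    -0.518 6.07e- 1

tidy(permutation_test(fit, n_permutations = 1000, seed = 2024))
#> # A tibble: 6 × 3
#>   term          estimate   p_rand
#>   <chr>            <dbl>    <dbl>
#> 1 (Intercept)    -1.53   0.000999
#> 2 strength        0.796  0.000999
#> 3 site_idS2      -1.59   0.000999
#> 4 sexM            0.0731 0.696
#> 5 agejuvenile    -0.0168 0.925
#> 6 immigrantTRUE  -0.0433 0.828
```

Reading the output: birds one unit higher in weighted strength use the
novel feeder at 0.796 higher log-odds (the generator's sociality→diet
effect, recovered), the site whose novel food is green avoids it strongly
(the colour contrast), and the demographic terms are null — all confirmed
by the permutation p-values, where 0.000999 = 1/1001 is the smallest
value 1,000 permutations can produce.

The whole chain — simulate/load, validate, segment, network, fit,
permute, report — also runs as one call:

```r
res <- run_pipeline(run_config(sim = cfg, seed = 2024), out_dir = "run1")
res$results      # one row per model term, with coef/se/t/p/p_rand/φ
```

`autoplot()` methods draw the network (`sri_network`), the fitted usage
curve (`diet_fit`) and the permutation nulls (`perm_test`); `tidy()` and
`glance()` return tibbles throughout.

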