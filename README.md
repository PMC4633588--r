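# platypopdyn

Survival, movement and population viability analysis for pool-dwelling
platypus (*Ornithorhynchus anatinus*) populations monitored by long-term
capture-mark-recapture netting surveys — and, more generally, for any
riverine species observed the same way.

Long-term platypus studies face a chain of inferential problems: capture
probabilities vary with netting effort and river flow, so raw counts
mislead; apparent survival estimated from mark-recapture confounds death
with dispersal out of the study reach, biasing survival low (severely so
for dispersing juvenile males); and viability verdicts depend on how that
bias is corrected.  `platypopdyn` implements the whole chain as tested,
reusable functions:

- **Cormack-Jolly-Seber inference** — open-population likelihood
  conditional on first capture, with the unobserved-tail recursion
  χ<sub>t</sub> = (1−Φ<sub>t</sub>) + Φ<sub>t</sub>(1−p<sub>t+1</sub>)χ<sub>t+1</sub>,
  logit-linear covariate models for apparent survival Φ (sex, age class,
  weight, lagged cumulative flows) and detection p (capture-month flow,
  net-hours, age class), AICc ranking with Akaike weights, 99%
  cumulative-weight model averaging, and detectability-corrected
  abundance trends (N̂<sub>t</sub> = C<sub>t</sub>/p̂<sub>t</sub>).
- **Bayesian building blocks** — Binomial–Beta proportion tests
  (posterior Beta(1+x, 1+n−x)), a semi-conjugate Gibbs linear model for
  morphometrics, Metropolis Poisson regression of lactation on flow, and
  breeding/composition summaries.
- **Residency adjustment** — pool-residency probabilities r from
  consecutive recaptures and the correction S = Φ / r separating true
  survival from emigration.
- **Two-sex stochastic viability model** — an age-structured,
  Vortex-style annual simulator (breed → die → disperse → age → truncate
  to K) reporting the stochastic growth rate r̄ = mean ln(N<sub>t+1</sub>/N<sub>t</sub>),
  extinction probabilities and times, with Leslie-matrix and Euler–Lotka
  oracles.
- **Sensitivity analysis** — Latin-hypercube sweeps over class
  mortalities and dispersal success, smoothed by a GCV-selected cubic
  smoothing spline with effective-degrees-of-freedom and ±2SE bands, and
  viability-threshold reports.
- **Synthetic data** — a seeded generator for pool-structured populations
  with known survival, residency, movement, detection and morphometrics,
  so every estimator is testable against ground truth without field data.

## Worked example

Simulate a 20-year survey of a 15-pool reach, fit CJS models, estimate
residency, adjust survival, and project viability:

```r
library(platypopdyn)

cfg <- truth_config(years = 20, initial_n = 120, seed = 7)
sim <- simulate_dataset(cfg, "demo")            # writes the CSV file set
records <- read_capture_records("demo/capture_records.csv")
occ <- build_occasions(records, read_flow_series("demo/flows.csv"))
ch  <- build_capture_histories(records, occ)

fits <- list(
  fit_cjs(ch, cjs_design(~1, ~1,             label = "phi(.) p(.)")),
  fit_cjs(ch, cjs_design(~sex, ~1,           label = "phi(sex) p(.)")),
  fit_cjs(ch, cjs_design(~sex + age, ~flow_1m, label = "phi(sex+age) p(flow)")))
rank_and_average(fits)
#> CJS model table (3 models, 99% retention)
#>                 model npar AICc delta    weight retained weight_99
#>  phi(sex+age) p(flow)    6 2282     0 1.000e+00     TRUE         1
#>         phi(sex) p(.)    3 2543   261 2.118e-57    FALSE        NA
#>           phi(.) p(.)    2 2618   336 1.072e-73    FALSE        NA
```

The generator's survival really does differ by sex and age and its
detection really does respond to flow, and the AICc ranking recovers
that structure decisively.  Residency from consecutive recaptures:

```r
moves <- consecutive_moves(records, read_pool_map("demo/pools.csv"), occ)
residency_and_distances(moves, seed = 1)
#>             class n_pairs residency residency_lcl residency_ucl mean_distance
#> 1 female_juvenile      52     0.926         0.843         0.979           106
#> 2    female_adult     454     0.789         0.751         0.826           259
#> 3   male_juvenile      48     0.420         0.288         0.558           779
#> 4   male_subadult      76     0.654         0.546         0.755           449
#> 5      male_adult      95     0.629         0.531         0.722           486
```

Juvenile males move most and stay least — the dispersal signal that
biases their apparent survival.  Adjusting published apparent survival
by residency and projecting:

```r
vr <- derive_vital_rates(
  phi = c(female_juvenile = 0.27, female_adult = 0.76, male_juvenile = 0.13,
          male_subadult = 0.38, male_adult = 0.57),
  residency = c(female_juvenile = 0.846, female_adult = 0.855,
                male_juvenile = 0.45, male_subadult = 0.66, male_adult = 0.74))
vr
#>             class  phi residency survival dispersal mortality
#> 1 female_juvenile 0.27     0.846    0.319     0.154     0.681
#> 2    female_adult 0.76     0.855    0.889     0.145     0.111
#> 3   male_juvenile 0.13     0.450    0.289     0.550     0.711
#> 4   male_subadult 0.38     0.660    0.576     0.340     0.424
#> 5      male_adult 0.57     0.740    0.770     0.260     0.230

summarize_pva(run_pva(pva_scenario("adjusted", seed = 42)))
#> Stochastic r: -0.0362 (sd 0.1381)
#>   P(extinct by year 50): 0.169
#>   P(extinct by year 100): 0.647
#>   Median time to extinction: 64.0 years
```

Adjusted adult mortality drops from 24% to 11% (females) and 43% to 23%
(males), moving the population from catastrophic decline (the
`"apparent"` preset gives r̄ ≈ −0.24 and extinction within ~16 years) to
near-stationary growth.  Note the extinction risk printed above is for
the default small population (N0 = 50, K = 200): with demographic
stochasticity and male-limited breeding, even a near-stationary r̄
leaves a small population at substantial risk, and extinction
probability — unlike r̄ — is strongly scale-dependent (see the methods
vignette).

`run_pipeline()` chains all stages (simulate → CJS → residency →
adjustment → viability → sensitivity) into one seeded, checksummed run.

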