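# noisebn

Hospital wards routinely exceed recommended noise levels, and patients differ
in how strongly they react to noise. `noisebn` is an R package for analysts of
hospital soundscapes and environmental-health cohorts who want to quantify how
objective noise exposure and trait noise sensitivity jointly shift the
probabilities of three patient outcomes — noise annoyance, acoustic comfort,
and the intention to leave the hospital early.

The pipeline has four stages:

1. **Acoustics.** Interval Leq logs are pooled energetically
   (10·log₁₀ of the mean of 10^(L/10)) into day (07–19), evening (19–23) and
   night (23–07) levels, and combined into the day-evening-night indicator

   L_den = 10·log₁₀( (12·10^(L_day/10) + 4·10^((L_evening+5)/10) + 8·10^((L_night+10)/10)) / 24 ),

   with the standard +5 dB evening and +10 dB night penalties. Intervals that
   straddle a period boundary are split proportionally by overlap hours.
2. **Discretization.** Each continuous measure (L_den in dB, Weinstein noise
   sensitivity 0–105, annoyance VAS 0–100, comfort 1–7, intention-to-leave VAS
   0–100) is mapped to low (< P25), moderate (P25–P75, closed band), or
   high (> P75) using type-7 sample quantiles.
3. **Bayesian network.** Over a mediating DAG — exposure and sensitivity as
   exogenous roots feeding annoyance and comfort, which feed intention to
   leave — conditional probability tables are fit by relative frequency
   (optional Laplace smoothing), and hard evidence is propagated by exact
   variable elimination (cross-checked in the tests against a brute-force
   enumeration oracle).
4. **Delta-p sensitivity analysis.** For each evidence scenario (e.g.
   "L_den high 100%"), Δp = 100·(updated − baseline) per target state, in
   percentage points; positive means the state became more likely.

A synthetic cohort generator with a known ground-truth network
(`sample_cohort()`, `default_generating_net()`) stands in for patient-level
data, so every stage is testable end to end, including CPT parameter
recovery.

## Worked example

```r
library(noisebn)
cohort <- sample_cohort(generator_config(n_patients = 226, seed = 42))
fit <- noisebn(cohort$patients)
fit
#> Hospital-noise Bayesian network fit
#>   n = 226 patients, 5 variables, 6 edges, pseudocount = 0
#>   cut-offs (P25/P75):
#>     lden         53.76 / 63.43
#>     sensitivity  26.70 / 51.29
#>     annoyance    22.77 / 49.05
#>     comfort      3.88 / 5.94
#>     itl          15.28 / 34.22
#> Prior (baseline) marginals
#>   lden         low 0.252  moderate 0.496  high 0.252
#>   sensitivity  low 0.252  moderate 0.496  high 0.252
#>   annoyance    low 0.249  moderate 0.497  high 0.254
#>   comfort      low 0.252  moderate 0.494  high 0.254
#>   itl          low 0.255  moderate 0.495  high 0.250
```

The cut-offs are the per-variable P25/P75 of this cohort (dB for `lden`,
scale points otherwise); baseline marginals sit near 25/50/25% because that
is what percentile discretization produces. Evidence propagation and the
delta-p report for two of the five packaged scenarios:

```r
reports <- run_scenarios(fit$net, default_scenarios())
delta_p_table(reports)[, 1:4]
#>     variable    state lden_high sensitivity_high
#>         lden      low         -              0 %
#>         lden moderate         -              0 %
#>         lden     high         -              0 %
#>  sensitivity      low       0 %                -
#>  sensitivity moderate       0 %                -
#>  sensitivity     high       0 %                -
#>    annoyance      low    +1.5 %           -9.3 %
#>    annoyance moderate    -7.7 %           -0.3 %
#>    annoyance     high    +6.1 %           +9.6 %
#>      comfort      low    +8.1 %           +5.8 %
#>      comfort moderate    -0.5 %           +4.1 %
#>      comfort     high    -7.7 %            -10 %
#>          itl      low    -1.9 %           -3.2 %
#>          itl moderate    -0.2 %           +0.2 %
#>          itl     high      +2 %           +2.9 %
```

Reading the `lden_high` column: instantiating high exposure raises the
probability of high annoyance by 6.1 percentage points and of low comfort by
8.1 in this simulated cohort, nudges intention to leave up by 2, and — because
the two roots are d-separated — leaves sensitivity at exactly 0. Evidence
variables are shown as `-`.

The package also bundles, as plain-text worked-example inputs, a reference
set of baseline marginals and updated distributions for a 226-patient
hospital cohort:

```r
ref <- reference_distributions()
delta_p(ref$marginals$annoyance, ref$updated$lden_high_sensitivity_high$annoyance)
#>      low moderate     high
#>    -19.6     -6.3     25.9
```

i.e. with both exposure and sensitivity instantiated high, low annoyance
loses 19.6 percentage points and high annoyance gains 25.9.

The standalone acoustic utility works off any interval log:

```r
log <- read_noise_log(system.file("extdata", "example_noise_log.csv", package = "noisebn"))
lden_by_location(log)
#>    location_id l_day l_evening l_night lden_db
#>  ward_internal 61.08     55.64   51.31   61.09
#>       ward_ccu 58.60     54.41   50.10   59.29
```

Night levels around 50 dB still push L_den within a decibel of the daytime
level because of the +10 dB night penalty.

See `vignettes/hospital-noise-bn.Rmd` for the model assumptions, the
generator design, and numerical conventions.

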