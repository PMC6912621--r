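# drinkstates

Latent drinking-pattern analysis for weekly drinking diaries from
randomized trials in students with risky alcohol use.

Participants in app-based alcohol intervention trials record one week of
daily standard-drink counts at each of four waves (baseline, ~7, ~14 and
~20 weeks). `drinkstates` implements the full analysis chain over those
diaries:

* **Outcomes** — weekly quantity, frequency, binge occasions (>= 4
  drinks/day for women, >= 5 for men), estimated blood alcohol
  concentration by the Widmark formula
  (eBAC = 100·d·g / (10³·w·r) − β·t, floored at 0, with r = 0.68/0.55 for
  men/women, β = 0.017 %/h, g = 12 g per Swedish standard drink), and
  hazardous (AUDIT >= 6 women / 8 men) and excessive (> 9 / > 14
  drinks/week) status.
* **Latent states** — a population hidden Markov model over each
  student's 28 concatenated daily counts (4 waves × 7 days), with hurdle
  emissions per state k (drinking probability p_k; zero-truncated Poisson
  count with rate λ_k given drinking), fitted by multi-restart
  Baum–Welch EM with scaled forward–backward recursions (RcppArmadillo),
  missing waves marginalised out of the likelihood, and the number of
  states selected by minimising BIC = −2ℓ + q·log n with
  q = (K−1) + K(K−1) + 2K free parameters.
* **Frequent-heavy analysis** — identification of the frequent-heavy
  state (max expected drinking days/week 7·p_k among states with
  7·p_k >= 3.5 and self-transition >= 0.5), continual/itinerant member
  classification from Viterbi paths, Welch-t / pooled-Z baseline
  comparisons against the rest of the cohort, and arm-wise trends in the
  daily drinking probability (day-level logistic regression of drinking
  on wave × arm with student-clustered sandwich standard errors;
  OR = exp(interaction)).
* **Synthetic cohorts** — a tested generator emulating the trial design
  (2166 students, 1:1:1 arms, nested TeleCoach/waitlist add-on for
  excessive drinkers at follow-up, weekday-anchored drinking classes, a
  7% frequent-heavy class at 4.55 drinking days/week, arm-dependent
  log-odds slopes, wave-level missingness at 55–83% response rates), so
  every stage is testable without participant data.

See the methods vignette
(`vignettes/latent-drinking-patterns.Rmd`) for the models, parameter
defaults and design rationale.

## Worked example

```r
library(drinkstates)

# simulate a scaled study cohort and run the whole pipeline
cfg <- pipeline_config(sim = sim_config(n_students = 1000, seed = 1),
                       K_range = 5:10, n_restarts = 3, restart_iter = 15,
                       seed = 1)
report <- run_pipeline(cfg)
report
```

```
<analysis_report> seed 1 - sequence length 28 days
Selected K = 8 by BIC
# A tibble: 8 × 4
  state label          drinking_days_per_week self_transition
  <int> <chr>                           <dbl>           <dbl>
1     1 wednesday                       1.04       0.00000467
2     2 frequent_heavy                  4.29       0.997
3     3 friday                          4.68       0.00466
4     4 sunday                          1.72       0.000107
5     5 thursday                        1.20       0.00278
6     6 tuesday                         0.728      0.0000470
7     7 monday                          0.479      0.00447
8     8 saturday                        3.88       0.00568
Frequent-heavy state 2 : 56 continual / 0 itinerant members
```

The fitted model recovers the generator's structure: the diary sequence
is 28 days long; BIC selects eight hidden states; seven of them lock onto
one calendar weekday each (their decoded occupancy cycles through the
week, so their self-transitions are near zero), with drinking probability
peaking in the Friday/Saturday states; the eighth is a highly persistent
(self-transition 0.997) state drinking 4.3 days a week — the
frequent-heavy class — whose decoded membership (~6% of students here)
can then be compared against the rest of the cohort and followed over
waves:

```r
tidy(report$fh$trend[[1]])
```

```
# A tibble: 1 × 8
  contrast         odds_ratio se_log_or conf_low conf_high p_value flagged note
  <chr>                 <dbl>     <dbl>    <dbl>     <dbl>   <dbl> <lgl>   <chr>
1 control vs prom…      0.834     0.171    0.596      1.17   0.290 FALSE   ""
```

Under the default generator, the control arm's daily drinking log-odds
fall by 0.02/wave against 0.05/wave for Promillekoll, a true trend odds
ratio of exp(0.03) ≈ 1.03. With only 56 frequent-heavy members in the
stratum the day-level estimate is noisy (point estimate 0.83), but the
student-clustered 95% CI (0.60–1.17) covers the generative value; the
test suite shows the estimator is unbiased and consistent as the stratum
grows (mean OR 1.060 over 20 replicates of 400 frequent-heavy students
at a generative slope difference of 0.06/wave).

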