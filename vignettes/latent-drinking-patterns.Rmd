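---
title: "Latent drinking patterns in weekly diary trials: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent drinking patterns in weekly diary trials: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drinkstates)
```

## The analysis problem

University students with risky alcohol use record, at four time points
(baseline and roughly 7, 14 and 20 weeks), one week of daily standard-drink
counts each. `drinkstates` turns those diaries into the standard drinking
outcomes, then asks a structural question: do the 28 daily observations per
student (4 waves x 7 days, concatenated with no gap modelling) organise into
a small number of latent *drinking states* -- and in particular, is there a
small, stable *frequent-heavy* class that drinks most days of the week at
excessive levels, distinct from the majority who anchor their drinking to
one or two weekdays?

The package is organised as a tidyverse-style pipeline: tibbles in, tibbles
out, with `tidy()`/`glance()` accessors and `autoplot()` methods on fitted
objects. Because no participant-level data are distributable, a synthetic
cohort generator is a first-class, tested part of the package: every
downstream stage is exercised against cohorts whose ground truth is known by
construction.

## Drinking outcomes

**eBAC.** Estimated blood alcohol concentration uses the Widmark formula:

$$\mathrm{eBAC} = 100\cdot\frac{d \cdot g}{10^3\, w\, r} - \beta t,$$

floored at zero, with $d$ standard drinks, $g = 12$ g ethanol per Swedish
standard drink, $w$ body weight in kg, $r$ the body-water distribution
ratio (0.68 men, 0.55 women), $\beta = 0.017$ %/h the elimination rate and
$t$ the occasion duration in hours. All constants are configurable through
`widmark_constants()`; these defaults are the conventional Widmark values.
Output is on the percent (g/dL x 100) scale, or per-mille (exactly 10x) on
request -- weekly-average eBACs (a few hundredths of a percent) and
single-occasion peaks (above one per-mille) live on visibly different
scales, so the package exposes both rather than committing to one
internally.

Two summaries per student and wave: the *weekly mean* averages occasion
eBACs over all seven days, counting dry days as zero (this is what makes
weekly means an order of magnitude smaller than peaks); the *peak* is the
maximum occasion over the recall window, for which the wave's observed week
stands in. A fully missing week yields a missing summary, never zero.

**Quantity, frequency, binge.** Weekly quantity is the sum of the seven
counts; frequency counts days with at least one drink (the diary's one
count per day makes "occasion" and "drinking day" synonymous); binge
occasions count days at or above 4 (women) / 5 (men) drinks -- the
conventional gendered heavy-episodic threshold, configurable, since the
source analyses never define "binge" operationally. *Hazardous* use is
AUDIT >= 6 (women) / 8 (men); *excessive* drinking is > 9 / > 14 drinks
per week (Swedish national recommendations). Both cutoffs sit exactly at
the stated boundaries: a woman at AUDIT 6 is hazardous, a man at 14
drinks/week is not excessive.

**Occasion durations.** Diaries carry drink counts, not durations, so the
generator supplies `max(1, drinks/2)` hours per drinking day. This keeps
simulated eBACs in plausible ranges; real diaries with measured durations
can be supplied through the same columns.

## The hidden Markov model

Each student's 28-day count sequence is modelled as an independent
realisation of one population-level HMM with $K$ states: initial
distribution $\pi$, row-stochastic daily transition matrix $A$, and
per-state *hurdle* emissions -- state $k$ drinks on a day with probability
$p_k$, and the count given drinking is zero-truncated Poisson with rate
$\lambda_k$. The hurdle family represents the dominant zero mass of daily
diaries explicitly, keeps the BIC parameter count well-defined
($(K-1) + K(K-1) + 2K$), and makes the generator's quantity model and the
emission family coincide, so parameter recovery is well-posed.

Numerical choices:

* Forward–backward runs with per-step scaling (equivalently, log-space
  normalisation): 28-step probability products underflow in linear space.
  The scaled pass is implemented in C++ (RcppArmadillo) over all sequences
  simultaneously; sequences share their day grid, so the E-step is a
  sequence-parallel matrix recursion.
* Missing days enter with emission probability one -- they are marginalised
  out of the likelihood (missing-at-random handling by maximum likelihood,
  no imputation). Whole waves go missing jointly, matching
  questionnaire-level nonresponse.
* Baum–Welch EM restarts from random draws: Dirichlet(1) initial and
  transition rows, $p_k \sim U(0.05, 0.95)$,
  $\lambda_k \sim U(0.5, 8)$; 20 restarts by default. For large state
  spaces an optional economy (`restart_iter`) runs every restart briefly
  and polishes only the best -- the standard short-run strategy.
* Convergence: relative log-likelihood change below $10^{-6}$ or 500
  iterations. The observed-data log-likelihood is checked to be
  non-decreasing within $10^{-8}$ on every fit in the test suite.
* Degenerate states: drinking probabilities are kept $10^{-6}$ off the
  simplex boundary *except* when the weighted drinking mass is exactly
  zero, in which case $\hat p_k = 0$ exactly (all-dry data should say so).
  A warning is issued when $K$ exceeds the number of distinct observed
  sequences, and states with vanishing posterior occupancy are flagged.
* Viterbi ties break toward the lower state index, and label switching is
  handled only at evaluation time (matching estimated states to truth in
  tests), never inside EM.

$K$ is chosen by minimising BIC, $-2\ell + q\log n$, where $n$ counts
observed (non-missing) daily observations across all students -- the most
common convention for sequence HMMs, stated here because the source
analysis does not fix one. Ties go to the smaller $K$; a failure at one
candidate is recorded, not fatal.

## The synthetic cohort generator

`sim_config()` defaults emulate the study conditions: 2166 students
randomised 1:1:1 (control / Promillekoll / PartyPlanner), 67.5% women, age
25.8 (SD 6.6), AUDIT 11 (SD 4.3) truncated to the hazardous-use inclusion
range, motivation 4.1 (SD 2.6), body weight Normal(70, 10) kg for women
and Normal(82, 12) for men truncated at 45 kg (plausible Swedish student
anthropometrics -- purely a fixture choice), and per-wave response rates
(0.78, 0.60, 0.65) inside the reported 55–83% band, with whole waves
dropped jointly and response allowed to depend on baseline AUDIT (a
missing-at-random mechanism; frequent-heavy members, who score higher,
respond somewhat more, as observed).

**Latent classes.** Seven weekday-anchored moderate classes plus one
frequent-heavy class (7% prevalence). Moderate drinking follows a shared
weekend-peaked base profile (Monday–Sunday daily drinking probabilities
.06/.08/.11/.17/.46/.42/.17) with a personal bump to 0.85 on the class's
own weekday, and class prevalences concentrated on Friday/Saturday/Sunday.
Two realism constraints drove this design. First, the marginal weekday
profile must vary strongly -- student drinking is weekend-heavy -- because
that calendar signal is what lets a population HMM support a seven-state
weekly cycle; with a flat off-day rate the cycle is not worth its
parameters and BIC honestly prefers far fewer states. Second, the class
means reproduce the reported cohort descriptives: moderates average about
2 drinking occasions and ~8.5 drinks per week; the frequent-heavy class
drinks on 65% of days (4.55 days/week) at ~3.6 drinks per occasion
(~16 drinks/week), far above the recommended limits.

**Itinerancy.** Classes carry a daily pattern persistence; the
frequent-heavy default 0.992 means roughly a fifth of its members leave
the heavy pattern at some point across the 28 observed days (matching the
reported continual:itinerant split), after which they drink like the
prevalence-weighted average of the other classes and return only rarely
(0.02/day). Departures are deliberately wave-scale: the four observed
weeks sit ~6–7 calendar weeks apart, so a genuine behavioural change
plausibly persists, and a one-day "excursion" would be observationally
meaningless -- a dry day is a perfectly ordinary frequent-heavy day.

**Arm effects.** Each arm shifts every member's daily drinking log-odds by
a per-wave slope (defaults −0.02 control, −0.05 Promillekoll, −0.04
PartyPlanner), giving the downstream trend estimator a known estimand.
The nested add-on assignment mirrors the trial: app-arm students excessive
at the first follow-up split 1:1 into TeleCoach/waitlist; control-arm
students excessive at baseline form the assessment-only comparison.

**What the generator does not emulate.** AUDIT item responses (score
only), app usage/engagement, seasonal or holiday effects, within-person
quantity autocorrelation beyond the class structure, day-level (as opposed
to wave-level) nonresponse, and any drift in covariates over waves.
Passing tests therefore demonstrate correct recovery of *this* structure,
not performance on real diaries, whose state structure may be less clean.

## Interpreting the fitted model

`label_states()` assigns the frequent-heavy label first:
`identify_frequent_heavy()` selects the state maximising expected drinking
days/week ($7 p_k$) among states with $7 p_k \ge 3.5$ and self-transition
$A_{kk} \ge 0.5$ (ties to the more stable state; both thresholds
configurable and reported). The qualitative description being
operationalised -- "drinks several days a week" and "a very stable state"
-- fixes only the shape of the rule, so the thresholds sit midway between
the moderate classes (~2 days/week, cycling states with near-zero
self-transition) and the frequent-heavy pattern (~4.6 days/week, high
self-transition). Remaining states take the calendar weekday (Monday-first)
holding at least half of their decoded occupancy, or stay unlabelled.

Membership follows the decoded Viterbi paths: *continual* members spend
every observed decoded day in the frequent-heavy state, *itinerant*
members some but not all days, everyone else is a non-member. A
decodability caveat belongs here: with hurdle emissions, a frequent-heavy
member's short excursion into moderate drinking is nearly
indistinguishable from their ordinary dry days, so itinerant members whose
departure happens late in the observation window are systematically
decoded as continual, and weekend-anchored moderates with a dense month
can decode as members. The membership accuracy measured in the test suite
against generative truth falls short of the aspirational three-class
target for exactly this reason -- a property of the information in 28
daily counts at this separation, not of the estimation machinery; the
binary member/non-member distinction is recovered much more reliably.

`compare_groups()` reproduces the baseline-table machinery: Welch
two-sample t statistics (Welch–Satterthwaite df) for continuous variables
and the pooled two-proportion Z for binary ones, comparing total
frequent-heavy members against everyone else (the continual/itinerant
split is descriptive only).

`drinking_trend()` estimates how arms differ in their *trend* of daily
drinking probability: a day-level logistic regression of the drinking
indicator on wave (coded 0–3), an arm indicator and their interaction,
within the frequent-heavy stratum, with cluster-robust (by student)
sandwich standard errors. The exponentiated interaction is the per-wave
odds ratio between arms. This is the simplest maximum-likelihood estimator
consistent with a reported per-day drinking-probability odds ratio; the
source does not name its model, and this regression reading is documented
as such. Add-on contrasts use waves 1–3 only (the add-on app existed from
the first follow-up onwards). Degenerate strata (no drinking variation,
separation, empty arms) return a flagged result rather than an estimate.

## Problem sizes used by the tests

The automated suite scales the studies to keep a full run in minutes:
oracle equivalence uses exhaustive path enumeration at $K \le 3$,
$T \le 8$; parameter recovery uses 500 simulated 28-day sequences;
BIC selection runs ten seeds at $n = 300$ (three flat classes, scan
2–5) and ten seeds at $n = 1000$ (the default eight-class design, scan
5–10, short-run restarts); trend coverage and recovery use 20
replicates at 250–400 students per stratum. The acceptance script
re-runs the study-scale scan at $n = 1000$. These sizes are the package's
scaled-down study designs; the generator itself defaults to the full
2166-student cohort.

## Known limitations

* One shared HMM across students: no covariate-dependent transitions, no
  student-level random effects, no Bayesian uncertainty on $K$.
* The trend model treats wave as linear on the log-odds scale and ignores
  within-week weekday structure; it is an estimator of the generator's
  slope contrast, not a causal model of app effects.
* Occasion durations are a deterministic convention; eBAC levels (not
  orderings) shift under other duration models.
* The eight-state recovery result is a property of the weekend-peaked
  default design; cohorts whose drinking is uniform across weekdays will
  -- correctly -- select fewer states.
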