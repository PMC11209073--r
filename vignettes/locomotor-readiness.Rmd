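---
title: "Locomotor efficiency, weekly readiness and load periodization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Locomotor efficiency, weekly readiness and load periodization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(locoeff)
```

## The monitoring problem

Elite football squads train five to six times a week and play most weekends.
Tracking devices summarize every session as a handful of external-load
metrics — distances in speed bands, acceleration counts, maxima — plus
PlayerLoad, an accelerometer-derived measure of the total mechanical load
accumulated by the body. Coaches need a cheap, non-invasive answer to one
question each week: is this player ready to be loaded, or does he need to be
unloaded?

`locoeff` implements a residual-based answer. A regression model learns what
PlayerLoad a session's *locomotor output* should cost a typical player. A
session where the measured body load exceeds that expectation suggests the
player produced his output inefficiently — a marker of accumulated
neuromuscular fatigue. The package turns that residual into an individually
standardized index, classifies weekly readiness and week-to-week load
fluctuation, and estimates — with player-level mixed models — which load
manipulation strategies actually move readiness.

## The Locomotor Efficiency Index

For session $s$ of player $i$, with predicted PlayerLoad $\widehat{PL}_{is}$
and measured $PL_{is}$:

$$\Delta PL_{is} = \widehat{PL}_{is} - PL_{is}, \qquad
LEI_{is} = \frac{\Delta PL_{is} - \overline{\Delta PL}_i}{s_{\Delta PL,i}}$$

Positive LEI: the player did his locomotor work at a lower-than-usual body
load (efficient, ready). Negative LEI: more body load than expected
(inefficient, fatigued). The standardization uses each player's mean and
sample (n−1) standard deviation over the *entire* supplied window, so the
index is unit-free and comparable across players with very different
habitual loads; it is invariant to any positive affine rescaling of a
player's residual series. Days with two sessions contribute the arithmetic
mean of their session LEIs.

The predictor set is seven session metrics: total distance, running distance
above 7.2 km/h, counts of accelerations above 2.5 m/s² and decelerations
below −2.5 m/s², maximal speed, maximal acceleration and maximal
deceleration. (Published predictor lists for this family of models repeat
the maximal-deceleration entry; we read the duplicate as maximal
acceleration and carry both features.)

Two modelling decisions matter here:

* **Out-of-fold prediction** (default, K = 5). A flexible ensemble fit
  in-sample can nearly memorize PlayerLoad, collapsing $\Delta PL$ toward
  zero and destroying the index. Each session's prediction therefore comes
  from a model that never saw that session. The in-sample scheme remains
  available for comparison.
* **Pluggable regressor.** The default is a random-forest-style ensemble
  (200 trees, bootstrap resampling, per-split feature subsampling),
  implemented in compiled code inside the package because no tree-ensemble
  package is assumed at runtime. A pooled linear model (`regressor = "lm"`)
  and arbitrary user functions are accepted behind the same interface; the
  index is defined by the residual construction, not by one learner.

Players attending fewer than 60% of team session days are excluded
(training-continuity filter; exactly 60% is retained). Players whose
residual spread is numerically zero — which happens exactly when the model
predicts them perfectly, e.g. in noise-free simulations — are flagged and
excluded rather than standardized, since z-scoring numerical noise would
manufacture spurious readiness signal. "Numerically zero" is
`sd <= 1e-8 * max(1, mean |residual|)`.

## Weekly readiness and training scenarios

Weeks are non-overlapping Monday-anchored 7-day blocks. Disjoint windows are
required for week-to-week transitions to be meaningful; a rolling 7-day view
would make consecutive "weeks" share six days of data. Per player-week the
package computes:

* **Weekly load**, summed over all training sessions and matches, for three
  metrics: total distance (m), high-speed distance above 25.2 km/h (m), and
  mechanical load (count of accelerations > 3.5 m/s² plus decelerations
  < −3.5 m/s²).
* **Weekly LEI**: the mean of the daily LEI values.
* **Readiness**: bad if weekly LEI < −0.5, good if > 0.5, normal in the
  closed interval between (so −0.5 exactly is normal).

For each pair of consecutive qualifying weeks (both with at least 3
sessions) the weekly load change is expressed as a percentage,
$(w_{t+1}-w_t)/w_t \times 100$, and binned:

| category | percentage change |
|---|---|
| large decrease | < −30 |
| moderate decrease | [−30, −10) |
| no variation | [−10, +10] |
| moderate increase | (+10, +30] |
| large increase | > +30 |

The endpoint conventions are a documented choice (the verbal definitions of
these bands are ambiguous at the boundaries) and configurable; the mapping
is total and monotone whatever the bounds. A zero previous-week load (which
can genuinely happen for high-speed distance) makes the percentage
undefined; that transition is dropped for that metric and counted in the run
log.

The outcome of a transition is the **signed** LEI variation,
$\overline{LEI}_{w+1}-\overline{LEI}_w$. We deliberately use the signed
difference although such quantities are sometimes described as "absolute"
differences: category-level mean LEI variations are empirically negative
under load increases, which is impossible under a true absolute value, and
the whole point of the analysis is to distinguish improvement from
deterioration.

Each transition is conditioned on the readiness of the **earlier** week:
the practical question is "given the player's current state, what should
next week's load be?", so the prescription must be indexed by the state in
which it was chosen. Conditioning on the later week is available by
configuration.

## The mixed model

Within each readiness subset (bad / normal / good) and for each load metric,
the package fits

$$z(\Delta LEI)_{pt} = \beta_{c(pt)} + u_p + \varepsilon_{pt},
\qquad u_p \sim N(0, \sigma_u^2)$$

a linear mixed model of the subset-standardized LEI variation on the five
fluctuation categories with a per-player random intercept $u_p$ for the
repeated measurements, estimated by restricted maximum likelihood (lme4).
`no_variation` is the reference, so each $\beta$ asks: compared with keeping
the weekly load constant, did this manipulation change next week's
readiness?

Choices and caveats:

* "Standardized coefficients" means the outcome is z-scored within the
  fitted subset; 0/1 category indicators are left unscaled (a flag enables
  full predictor standardization). Standardizing the outcome makes $\beta$ a
  unit-free effect size and leaves p-values unchanged.
* Inference is Wald with a normal reference distribution — standard for
  longitudinal squads with many players; no Kenward–Roger/Satterthwaite
  small-sample correction is applied, and p-values in very small subsets are
  accordingly approximate.
* Singular fits (random-intercept variance estimated at zero) are flagged
  (`boundary`), not discarded; fixed effects remain valid.
* No multiple-testing adjustment is applied across the up-to-45 contrasts,
  mirroring the conventional α = 0.05 reporting practice for this analysis;
  adjust downstream if desired.
* Subsets with fewer than 10 transitions, fewer than 2 players, or without
  an occupied reference category are skipped with a logged reason. Empty
  categories are reported absent rather than as zero effects.

## The simulated squad: what world the generator states

Because real club monitoring data are private, the package ships a
simulator whose ground truth makes every downstream stage testable. Its
defaults are the stated world of the package's validation; they were chosen
once, on the grounds below, and the tests are run against them.

**Schedule.** 100 players, 80 weeks (two 40-week seasons), one match
(Saturday) plus five training days per week; 10% of training days carry a
second, half-volume session. Habitual training-session distance is drawn
per player from N(5000, 500²) m — typical elite-football session volumes —
and match volume is 1.3× the habitual session, making the match the weekly
peak. Training-day volumes follow a fixed microcycle profile (heavier early
and mid-week, a 0.7× taper on the last training day before the match), as
club periodization practice does.

**Periodization.** Each player-week is independently programmed as an
unload (probability 0.2: volumes ×0.75 and the heaviest training day
dropped), an overload (probability 0.2: volumes ×1.15 and second sessions
at probability 0.6), or a normal week, plus a log-normal week-level jitter
(σ = 0.08). The unload/overload mechanics intentionally move weekly dose
partly through *session count*, not only per-session volume: in practice
clubs unload by cutting sessions, and — importantly for validity — a
per-session-volume-only manipulation would let the load model infer the
weekly dose from each session's features and absorb most of the fatigue
signal into its fitted curve.

**Latent fatigue.** Each player carries a daily fatigue state
$F_t = F_{t-1}e^{-1/\tau_f} + k_f u_t$, an impulse-response recurrence in
which $u_t$ is the day's dose (session distance / habitual volume, so a
typical day is ≈ 1). Defaults: $\tau_f$ = 3.5 days and $k_f$ = 0.25.
The short time constant (half-life ≈ 2.4 days) encodes *acute*
neuromuscular fatigue that builds within a loaded week and dissipates over
several rest days, which is the component a weekly readiness index can see;
with a much slower constant the state is dominated by previous weeks'
history and a big week following an unload would, counter-intuitively but
correctly for that world, carry below-average fatigue. $k_f$ = 0.25 puts
the steady state near $F \approx 1$ at habitual dose, making $\gamma$
interpretable.

**Measurement.** Fatigue-free PlayerLoad is a fixed linear combination of
the seven predictors (≈ 370 AU for a habitual session), scaled per player
by small coefficient heterogeneity (σ = 5%); measured PlayerLoad is
inflated multiplicatively by $1+\gamma F$ with $\gamma$ = 0.10 (≈ 10%
inflation at steady fatigue) plus N(0, 10²) AU noise (≈ 3% of a session,
in line with reported accelerometer test–retest variability). The linear
fatigue-free truth is deliberate: it gives the index an analytic
perfect-model limit (a pooled linear model with no noise, no inflation and
no heterogeneity must drive every residual to zero — and does, at 1e−6).

**What the simulator does not emulate.** No positional roles, injuries,
congested multi-match weeks, seasonal drift, or GPS trace-level error; the
true load–PlayerLoad relation is linear rather than the mildly non-linear
one a real squad presents. Green tests therefore establish that the
pipeline recovers the stated dynamics from data *of this structure* — not
that any particular club's effect sizes are reproduced.

## Validation harnesses

`run_recovery()` repeatedly simulates squads, runs the full pipeline and
tabulates the mixed-model contrasts against the ground truth:

* **Null calibration** (γ = 0): fatigue never touches the measurement, so
  every category contrast is null; across 20 replicates of a 40-player,
  30-week squad (> 700 contrasts) the empirical type-I rate sits near the
  nominal 0.05.
* **Sign recovery** (γ = 0.10): the harness runs at the monitored cohort's
  own scale — 100 players over two 40-week seasons — since that is the
  design in which the effects are claimed detectable; at 40 × 30 the
  bad-readiness subset holds only ≈ 50 transitions per replicate and the
  large-decrease contrast has only ≈ 85% power. At cohort scale the two
  hallmark effects — unloading helps players in bad readiness (positive
  large-decrease contrast), overloading hurts players in normal readiness
  (negative large-increase contrast) — are recovered in essentially every
  replicate.

Harness pipelines use the pooled linear regressor: it is correctly
specified for the simulator's linear truth and keeps 20-replicate harnesses
to about a minute; the random-forest ensemble remains the default for real
data, where the true relation is not known to be linear.

## Numerical and degenerate-input conventions

* Reproducibility: every stochastic step (simulation, fold assignment,
  ensemble bootstrap) is a pure function of an integer seed; functions
  restore the caller's RNG state.
* Readiness cutoffs are closed at ±0.5 (both endpoints are `normal`);
  fluctuation bins are closed on the `no_variation` interval as tabled
  above.
* Zero-spread and short-history players, zero-denominator transitions and
  short weeks are excluded with logged reasons; the pipeline log accounts
  for every input row.
* The reference category's contrast is identically 0 with no interval, by
  construction, in every coefficient table.

## A worked run

```{r, eval = FALSE}
sim <- simulate_squad(squad_config(n_players = 40, n_weeks = 30, seed = 1))
pipe <- run_pipeline(sim$sessions, pipeline_config(seed = 1))
pipe$grid          # readiness x metric coefficient tables
lei_descriptives(pipe$transitions)
run_recovery(n_replicates = 5, seeds = 1:5)
```
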