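---
title: "Multistate models of male reproductive life-histories: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multistate models of male reproductive life-histories: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(socialstate)
```

## The system and the discrete time step

In cooperatively breeding banded mongoose groups, all adult females enter
oestrus in a synchronized window of 7-10 days (an *oestrus event*), around
four times per year. During each event every adult male of the group can be
classified into one of three live reproductive states: **guard** (mate-guards
a female on at least one day), **sneaker** (predominantly uses opportunistic
tactics; rare), or inactive **subordinate**. The oestrus event is the natural
discrete time step: a male observed in state $s$ at event $t$ either dies
before event $t+1$ (absorbing state) or is observed in some live state at
$t+1$.

`socialstate` implements this as a two-part discrete-time multistate model:

1. **Mortality submodel.** A Bernoulli GLMM for death before the next event,
   $$\operatorname{logit} p_i = \alpha_{s(i)} + \beta_{s(i)} w_i +
     \gamma' a_i + \delta\,\Delta t_i + u_{e(i)} + u_{g(i)} + u_{m(i)},$$
   with state-specific intercepts $\alpha_s$, state-specific slopes
   $\beta_s$ on group-centred weight $w$ (the state-by-weight structure that
   lets guards but not subordinates pay condition-dependent mortality
   costs), a shared age term $a$ (either age rank, or age and age$^2$), and
   the standardized time to the next oestrus event $\Delta t$ as an
   exposure-length control. Interval-by-covariate interactions exist behind
   `time_interactions = TRUE`, default off.
2. **Transition submodel.** Conditional on survival, a multinomial-logit
   GLMM over the destination state with subordinate as reference:
   $$\eta_{i,d} = \alpha_{s(i),d} + \beta_d w_i + \gamma_d' a_i +
     u_{e(i),d} + u_{g(i),d} + u_{m(i),d}, \qquad d \in \{K, G\}.$$
   By default the covariate slopes are origin-state-specific
   (`share_slopes = FALSE`); sharing them across origins is a config
   switch used where parsimony or runtime matters.

Both submodels carry crossed Gaussian random effects for oestrus event,
group, and male identity. The full $4 \times 4$ transition matrix is only
composed at prediction time (`transition_matrix_at()`): each live row is
$(1 - p_{\text{death}}) \cdot \operatorname{softmax}(\text{live destinations})$
and the dead row is absorbing. This factorization means the two submodels can
be fitted separately — mirroring how the motivating analysis ran them — while
the composed matrix always has rows summing to one.

Because age rank and age are strongly collinear (rank is essentially a
within-group ranking of age), each model is fitted twice: an `age_rank`
variant and a `quadratic_age` variant. Group-centred weight appears in both.

## Companion fitness models

* **Paternity share** (`fit_paternity`): pups sired by a male in an event,
  binomial with the event's total assigned pups as trials and a logit-linear
  predictor in group-centred weight plus the variant's age terms, with the
  same three crossed random effects.
* **Oestrus weight change** (`fit_weight_change`): percentage weight change
  over an event, Gaussian, regressed on state (subordinate versus guard
  only). Age is deliberately omitted: state and age are collinear in this
  system, and the motivating analysis dropped it for exactly that reason.
  The fit reports derived posteriors for the subordinate mean and the guard
  mean, plus whether the guard interval excludes zero while the subordinate
  interval spans it.
* **Lifetime reproductive success** (`fit_lrs`): total offspring over life,
  zero-inflated negative binomial. The count part is log-linear in condition
  at first guarding (relative variant: group-centred weight and age rank;
  absolute variant: weight and age) with a group random intercept; the
  zero-inflation part is intercept-only by default since nothing in the
  source analysis pins covariates to it. The NB is parameterized by mean
  $\mu$ and dispersion $\phi$ with variance $\mu + \mu^2/\phi$;
  `zinb_logpmf()` documents the exact mixture.

## Standardization

Numerical covariates whose observed range is not contained in $[0, 1]$ are
centred and scaled to unit SD; covariates already inside $[0, 1]$ (dummy
indicators) pass through. The fitted centres and scales persist in a
`covariate_scaler` that prediction reuses and inverts exactly. The square of
standardized age is used as the quadratic term, so the switch point of the
quadratic effect back-transforms as
$\text{age}^\ast = c + s \cdot (-b_1 / 2 b_2)$.

## Priors, sampler, diagnostics

Priors (all overridable in `model_spec()`): fixed effects
$\mathcal N(0, 2.5^2)$ on the standardized scale; random-effect SDs
half-$\mathcal N(0, 1)$; Gaussian residual SD half-$\mathcal N(0, 5)$; ZINB
log-dispersion $\mathcal N(0, 1.5^2)$. The source analysis does not state
its priors; these are weakly-informative defaults of the kind its tooling
uses.

The sampler is an adaptive random-walk Metropolis-within-Gibbs kernel
compiled in C++: every scalar (fixed effect, latent random effect,
hyper-SD, auxiliary scale) is updated singly, with per-parameter proposal
scales adapted toward 44% acceptance during burn-in only, so the
post-burn-in chain is a fixed Markov kernel. Two implementation details
matter for correctness and speed:

* Per-row linear predictors, multinomial category exponentials and row
  log-likelihood terms are cached and updated incrementally over only the
  rows a proposal touches; caches are rebuilt from scratch every 500
  iterations to stop floating-point drift.
* Random-effect SDs get both the centred conditional update (cheap,
  likelihood-free given the latents) and a non-centred *interweaving*
  rescale move that proposes $\sigma' $ while holding $u/\sigma$ fixed.
  Without the second move the hyper-SD chains mix an order of magnitude
  more slowly on Bernoulli data with little information per level, and
  conditional intercepts inherit the bias.

Default chain settings mirror the motivating analysis (mortality: 50 000
iterations, burn-in 5000; all other models: 20 000, burn-in 2000; thinning
100; 3 chains). Tests and the acceptance suite run deliberately shortened
chains; convergence is checked everywhere with split-$\hat R$ (`rhat()`),
warning at the conventional 1.1. Monte-Carlo standard errors use batch
means (`mcse()`). Correctness of the kernel is enforced by tests, not
assumed: a one-parameter Bernoulli model is compared against trapezoid
quadrature of the exact posterior, and the full parameter-recovery suite
below exercises every family.

## The synthetic cohort: a stated world

`simulate_population()` draws complete datasets from a known
parameterization (`true_params()`), so that every downstream stage can be
validated by parameter recovery. The defaults *are* the stated conditions of
the study system, chosen once:

* groups breed about 4 times/year with log-normal gap jitter; events last
  7-10 days; males enter events from sexual maturity at 1 year;
* ~8 adult males per group (male-biased adult sex ratio within the
  10-30-adult group sizes typical of the system), maintained by Poisson
  recruitment;
* growth is monotone saturating to an adult plateau of 1456 g (the study's
  mean male weight), frozen at a senescence onset of 8 years and declining
  linearly at 25 g/year thereafter, with individual frailty (SD 60 g) and
  weighing noise (SD 20 g). The source only shows this shape qualitatively,
  so the curve is an explicit stand-in, not a reconstruction;
* transition intercepts reproduce the reported mean transition
  probabilities (stay-subordinate 0.72 and subordinate-to-guard 0.20
  conditional on survival; guard-to-subordinate slightly above stay-guard);
  the sneaker destination carries a strongly negative intercept so sneakers
  stay rare (< 0.10); the quadratic-age law peaks at 6.5 years;
* between-event mortality sits near 0.07 with a strongly negative weight
  slope for guards (−0.55 per 150 g) and none for subordinates —
  condition-dependent costs of guarding;
* guards lose 2.36% of body weight per event on average against +0.21% for
  subordinates (residual SD 4%);
* paternity is allocated per event by a softmax over males, skewed toward
  guards and heavier males, so per-event totals always equal the sum of
  per-male sired counts.

Coefficients live on fixed, documented covariate scales (age centred at 5
years, scale 2.5; rank centred at 4, scale 3; weight per 150 g; interval per
30 days around 91). `scaler_from_params()` exports those constants as a
scaler, which is how recovery tests make fitted coefficients directly
comparable with the truth. Production fits instead standardize from the
data, as the source analysis did.

What the generator does *not* emulate: female identity and oestrus ordering,
eviction and dispersal, inter-group variation in food supply, pedigree
errors, and observation gaps (every alive adult male is observed at every
event). A green recovery test therefore establishes that the inference
machinery recovers the generating process at the study's scale — it does not
establish robustness to the missingness patterns of real field data.

## Inclusion filters and a deliberate recovery-design choice

Preprocessing implements the study's filters: males must attend at least two
oestrus events, and males whose death falls more than a year after their
last event contribute no terminal interval (earlier intervals are kept).
Deaths after a group's final observed event have no "next event" and are
likewise dropped, with counts reported.

The two-event rule has a quantifiable side effect: a male who dies in his
*first* interval is removed entirely, so first-interval deaths are censored
while first-interval survivors stay. In simulation experiments at the
study's scale this deflates the fitted subordinate mortality intercept and
tilts its weight slope positive — a length-biased selection artifact of the
data-collection rule, not of the estimator, and one the source estimates
carry as well. `build_transition_table()` therefore exposes `min_events`
(default 2, the study's rule). The parameter-recovery acceptance suite runs
at `min_events = 1`, where the estimand is well-defined and the artifact
vanishes; the pipeline default remains the study's rule. This is the one
place the validation design intentionally departs from the default
preprocessing path, and it is why, if you re-fit with `min_events = 2`, you
should expect the subordinate mortality intercept a tenth or two low.

## Numerical and policy choices

* Guard-versus-sneak ties in the daily-behaviour summary resolve to guard
  (guarding on any day is the stated default).
* Age-rank ties (littermates) break lexicographically by male id, so ranks
  are always a permutation of $1..n$ and reproducible.
* The group mean in group-centred weight includes the focal male; within a
  fully weighed event the centred weights sum to zero exactly.
* Weight at an event is the most recent record within a 30-day lookback
  before event start (the matching rule is unstated in the source;
  configurable).
* The interval-length covariate is always event-end to next-event-start in
  days, dead rows included (the source states the mortality model used time
  to the next oestrus event); the death date itself only decides the
  outcome and the one-year filter.
* Litters link to events whose end lies 44-74 days before birth, nearest to
  59 days on ties; unlinked litters are reported, never silently dropped.
* "Below average weight" means group-centred weight strictly below zero;
  zero counts as average-and-above.
* Credible intervals are equal-tailed 95% quantiles throughout; prediction
  curves hold non-focal covariates at their training-sample means and set
  random effects to zero, warn on extrapolation beyond the observed
  support, and warn when an involved parameter has $\hat R \ge 1.1$.
* Switch points skip draws with $b_2 = 0$ (counted), and when the posterior
  mass of $b_2$ is not predominantly negative there is no interior maximum:
  the support boundary is reported with a warning.

## Pipeline

`run_pipeline()` executes simulate → preprocess → fit → predict → report
from one validated config (unknown keys rejected; at least two chains
enforced), expands a single global seed into per-stage sub-seeds by a
documented affine rule, writes every artifact as CSV/JSON with an md5
manifest, and logs one structured line per stage. `scripts/acceptance.R`
runs exactly this pipeline on a mid-sized synthetic cohort.

## Known limitations

* The sampler is a random-walk kernel: adequate at the study's scale
  (~3000 intervals), but chain lengths in the tens of thousands would be
  needed for publication-grade effective sample sizes on hyper-SDs.
* The sneaker state is carried in the likelihood (the transition matrix
  would not be stochastic without it) but no sneaker-specific outputs are
  produced; sneaker-origin coefficients are weakly informed at realistic
  sneaker frequencies and lean on the prior.
* LRS in the pipeline is computed from the simulated pedigree, whose
  generative law is the paternity softmax compounded over a lifetime — not
  a ZINB — so the ZINB fit there is a descriptive model, exactly as in the
  field analysis; exact-recovery validation of the ZINB machinery uses
  `simulate_lrs()`, which draws from the ZINB directly.
* Group demography is stationary; no group fission, eviction, or war.
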