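---
title: "Adjusting cross-cultural ordinal comparisons with anchoring vignettes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adjusting cross-cultural ordinal comparisons with anchoring vignettes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The measurement problem

Self-report questionnaires such as the Edinburgh Postnatal Depression Scale
(EPDS; ten items, each rated 0–3) are routinely compared across countries.
Such comparisons silently assume that a given response category means the
same level of the underlying trait everywhere. When groups differ in
*response style* — where they place the subjective cutpoints between
"not at all", "sometimes" and so on — the same latent depression level maps
to different observed ratings, a form of differential item functioning
(DIF), and naive group comparisons can be biased in either direction.

Anchoring vignettes address this by adding rating tasks whose true severity
is fixed by design: short descriptions of a hypothetical mother, rated on
the same response scale as the self-report. Because the vignette character's
severity is the same for every rater, systematic differences in how two
countries rate the *same* vignette identify the countries' different
response thresholds, which can then be removed from the self-report
comparison.

`avgrm` implements this logic as a pair of probit graded response models,
a synthetic-data generator for the three-cohort design the method was used
in, and the simulation machinery to verify that the estimator recovers
generating parameters under realistic missingness.

## The models

Ratings are modeled through a continuous latent propensity cut by three
ordered thresholds into the four observed categories; the propensity
disturbance is standard normal (probit link).

**Naive one-factor model.** Person $i$ in country $c$ has latent depression
$\theta_i \sim N(\mu_c, 1)$, with India the reference ($\mu_{IN} = 0$) and
$d = \mu_{UK}$ the country contrast in latent SD units. The self-report
propensity for item $j$ is $\lambda_j \theta_i$, cut by thresholds
$\tau_{jk}$ *shared across countries*. Any country difference in response
style is forced into $\hat d$.

**Vignette-adjusted two-factor model.** Two orthogonal factors: depression
$\theta_i \sim N(\mu_c, 1)$ and response style $\eta_i \sim N(0, 1)$.

* self-report propensity, item $j$:
  $\lambda_j \theta_i + \gamma_j \eta_i$;
* vignette propensity, vignette $v$ of item $j$:
  $\beta_{jv} + \gamma_j \eta_i$ — the severity anchor $\beta_{jv}$ is a
  constant shared across countries, and the depression factor does not
  enter vignette ratings;
* thresholds $\tau_{cjk}$ are country-specific but shared between
  self-reports and vignettes within a country (the response-consistency
  assumption);
* loadings $\lambda, \gamma$ and severities $\beta$ are shared across
  countries (vignette equivalence).

Country-level response style is carried entirely by the thresholds;
individual-level style by $\eta$. Because both countries rate the same
anchored severities through their own thresholds, the thresholds are
identified separately from the depression distribution, and $\hat d$
becomes a style-adjusted contrast.

### Identification constraints

$\theta$: India mean 0, variance 1 in both countries; $\eta$: mean 0,
variance 1 in both countries; $\beta$ shared; post-fit sign normalization
($\lambda_1 > 0$; the largest-magnitude $\gamma$ positive). We fix the UK
depression variance at 1 rather than freeing it: it keeps $\mu_{UK}$
directly interpretable as the effect size $d$ and matches the symmetric
Wald intervals the method reports. (A freed UK variance is a modest
extension — one extra gradient term — but is deliberately not exposed as an
option; a single fully specified model keeps the recovery studies crisp.)

With 10 items and 6 vignettes the adjusted model has
$10\,(\lambda) + 10\,(\gamma) + 60\,(\beta) + 60\,(\tau) + 1\,(\mu_{UK})
= 141$ free parameters.

## Estimation

Marginal maximum likelihood. Each person's latent factors are integrated
out with a tensor-product Gauss–Hermite rule, 21 nodes per dimension by
default (`fit_control(Q = )`). Propensity scales here are of order 1–2, for
which a fixed 21-node rule is ample; the test suite checks that doubling to
41 nodes moves a moderate person log-likelihood by less than $10^{-6}$.
Persons contributing only vignette ratings involve no $\theta$, so their
depression dimension integrates out exactly; they also contribute no
information about $\mu_{UK}$, which is what makes the auxiliary-sample
design work.

The likelihood and its analytic score are computed in compiled code
(category probabilities are cached per country × item × rating × node, and
score contributions accumulated from posterior node weights); with 141
parameters a finite-difference-only optimizer would be impractical, and the
finite-difference gradient is instead retained as a test oracle against the
analytic one. Optimization is quasi-Newton (`nlminb`) on an unconstrained
scale: thresholds are reparameterized per (country, item) as
$(\tau_1, \log(\tau_2-\tau_1), \log(\tau_3-\tau_2))$, so every proposal has
strictly ordered thresholds. Probabilities are floored at $10^{-300}$
before the log so extreme proposals survive. Convergence is declared at the
optimizer's relative-decrease criterion ($10^{-8}$) or a gradient
$\infty$-norm below $10^{-4}$; the final gradient norm is always reported
in the `av_fit` object. Starting values invert pooled cumulative category
proportions (clamped to $[0.001, 0.999]$) for thresholds, place each
severity at its vignette's observed exceedance of the scale midpoint, and
start loadings flat.

Standard errors come from the observed information (central finite
differences of the analytic score on the unconstrained scale), mapped to
the natural scale by the delta method; a non-positive-definite information
matrix yields absent standard errors with a diagnostic, never fabricated
ones. Intervals are Wald, matching the symmetric intervals the method
reports; interval calibration is itself checked by simulation (below).

## The packaged parameter sets

`load_printed_parameters()` ships the published estimates from a
two-country (India / UK) EPDS anchoring-vignette study as reference
generating truth: the naive set (standardized loadings 0.27–0.90, shared
thresholds, $d = 0.47$) and the adjusted set (standardized depression
loadings 0.48–0.86, style loadings 0.01–0.31, vignette severities per item,
country-specific thresholds, $d = -0.25$). Published loadings lie in
$(0,1)$ and are treated as standardized; they are converted to raw
propensity-scale loadings on load ($\lambda = \lambda^*/\sqrt{1 -
\lambda^{*2} - \gamma^{*2}}$, etc.). Thresholds and severities are treated
as raw propensity-scale values: severities up to 5.51 exceed any
standardized bound, so the raw reading is the only internally consistent
one. This scale question is the one genuine ambiguity in the source
material and is flagged in the fixture metadata.

These two parameter sets encode the study's headline phenomenon: the UK
thresholds for most items sit *lower* than the Indian thresholds at
$\tau_1, \tau_2$ and similar-or-higher at $\tau_3$ (items 2 and 10 are the
exceptions, shifted uniformly up and down respectively). Simulating data
from the adjusted set (true $d = -0.25$) and fitting the naive model yields
a *positive* $\hat d \approx +0.41$ at large $n$ — the sign reversal arises
mechanically from the thresholds, and `reversal_experiment()` reproduces it
on one command.

## What the generator emulates — and what it does not

`sim_config()` defaults are the study conditions: 549 Indian mothers
(self-reports and vignette ratings), 828 UK mothers (self-reports only),
226 UK mothers in a separate auxiliary calibration sample (vignette ratings
only, latents drawn from the same UK population), two random vignettes of
six per item per rater. Assignment designs: `FULL` (all six), `RANDOM_K`
(uniform random $k$-subset; study value $k = 2$), and `ADAPTIVE`, which
matches the vignette pair to the observed self rating. The source study
never states which vignettes its adaptive algorithm chose, so the mapping
(0 → {E,F}, 1 → {D,E}, 2 → {B,C}, 3 → {A,B}) is this package's own
severity-matched overlapping-pairs rule, exposed as an argument so recovery
can be shown robust to it. Both `RANDOM_K` and `ADAPTIVE` depend only on
observed data, so the induced missingness is MAR by construction, and
marginal ML remains consistent — the property the recovery study verifies.
The study's real administration mixed an adaptive phase with a later random
phase in unreported proportions; the generator supports the pure designs
and makes no attempt to infer the mixture. The nested Indian vignette
subsample (247 of 549 in the study) is available via `n_india_av`; the
default gives vignettes to all Indian persons.

One shared random stream is split into substreams per (cohort, stage)
(`substream_seed()`), so changing one cohort's size leaves every other
cohort's draws untouched.

Features of real data the generator deliberately does not emulate: item
nonresponse beyond the design's structural missingness, administration-mode
effects (the Indian cohort heard audio vignettes; the UK samples read
them), literacy selection into the vignette subsample, and any violation of
response consistency or vignette equivalence. Passing recovery tests
therefore show that the estimator is correct *under the model's own
assumptions and design-based missingness* — they cannot validate those
assumptions for real data.

## The recovery and calibration studies

`run_scenario()` generates replicate datasets (one substream per
replicate), fits the adjusted model, and aggregates bias, empirical SD,
RMSE and (optionally) Wald coverage for a monitored parameter set.
Non-converged replicates are excluded from aggregates but counted, keeping
bias estimates honest. The shipped test suite runs, among others:

* study-scale single-replicate recovery from both packaged parameter sets
  (full $n$ = 549/828/226, `RANDOM_K` $k = 2$);
* the sign-reversal experiment on the same dataset;
* bias checks under `RANDOM_K` and `ADAPTIVE` at $n$ = 180/180/80 with 5
  replicates — sizes chosen to exercise the full three-cohort likelihood
  while keeping a multi-replicate suite responsive;
* an auxiliary-split versus integrated-design comparison at $n$ =
  250/250/120 (the same vignette records handed to the self-reporting UK
  persons instead of a separate sample);
* Wald interval coverage for $d$ over 200 replicates at $n$ = 150/150/60
  with a 15-node rule, compared to the nominal 95% within binomial error.

## Numerical and design notes

* **Tie-breaking in vignette ranks** (`rank_vignettes()`): integer ranks
  with ties resolved by the a-priori severity order (A most severe), since
  the method's descriptive tables print integer ranks 1–6.
* **Rating range**: defined as max − min of the per-vignette means. The
  source tables' "range" rows are not always consistent with their own
  printed means; the package computes the definition, not the printed cell.
* **Reverse coding** (`reverse_code()`): EPDS items 1, 2 and 4 are
  reverse-keyed and flipped ($r \mapsto 3 - r$) on both self-reports and
  vignette ratings before analysis; an orientation flag on the dataset
  prevents double application.
* **Degenerate inputs**: single-country data make $\mu_{UK}$ inestimable
  (hard error); an (item, vignette) cell never rated freezes that severity
  at its starting value with a warning; a rating category never observed in
  a (country, item) cell clamps its starting threshold with a warning.
* **Vignette ratings are conditionally independent given $\eta$**: no
  person-level vignette factor is modeled, matching the source model's
  structure as far as it is documented.

## Limitations

The package fits exactly the two documented models; it offers no Bayesian
estimation, no nonparametric vignette ordering, and no fit indices beyond
the log-likelihood. Wald intervals are first-order asymptotic; at very
small cohort sizes their coverage will degrade before the point estimates
do. The adjusted model's validity for real data rests on response
consistency and vignette equivalence, which no within-dataset check can
fully establish.
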