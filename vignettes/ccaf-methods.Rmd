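---
title: "Models and methods behind ccaf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ccaf}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccaf)
```

This vignette documents the statistical model, the simulator, the numerical
choices and the known limitations of `ccaf`. It is the place where design
decisions that were genuinely open are written down, so that a user can
judge what the package's tests do and do not establish.

## The task and the choice model

One session of the concurrent-choice alcohol–food task presents 96 forced
choices between an alcohol and a snack image, each worth 1 or 3 points
towards the corresponding real reward. The *relative point level*
$x = \text{alcohol points} - \text{snack points}$ takes the values $-2$,
$0$ and $+2$, 32 trials each, and the participant who accumulates more
alcohol than snack points receives an alcohol drink at the end of the
session, otherwise a snack.

Choice behaviour is modelled as a binomial logistic psychometric function

$$
P(\text{alcohol} \mid x) \;=\; \mathrm{logit}^{-1}\!\big(\beta\,(x-\alpha)\big),
$$

with the **location–slope** parameterisation rather than
intercept–slope. The location $\alpha$ is the **point of subjective
equality** (PSE): the relative point level at which alcohol and snack are
chosen equally often. This makes the quantity of scientific interest a
model parameter, so "interpolating the PSE" is the identity map, and no
delta-method step (or the ratio $-b_0/b_1$ of a GLM fit) is needed. The
slope $\beta$, in logit units per relative-point unit, indexes sensitivity
to the cost manipulation.

Assumptions worth keeping in mind:

* trials are conditionally independent given $(\alpha,\beta)$ —
  no sequential effects, no learning across the session;
* the curve is symmetric on the logit scale and asymptotes at 0 and 1.
  A stimulus-independent **lapse rate** $\lambda$
  ($P = \lambda + (1-2\lambda)\,\mathrm{logit}^{-1}(\beta(x-\alpha))$) is
  available in the *simulator* (`choice_probability()`, default 0) but is
  deliberately **not** part of the default fitted model, which mirrors
  plain logistic regression; this lets robustness be probed without
  changing the fitted model's meaning.

## The synthetic cohort generator

No raw data are distributed with the task, so the package ships a
first-class generator whose defaults encode the study conditions the
analysis is meant for: two groups (light drinkers LD, heavy drinkers HD)
of 30 subjects each, sexes balanced 15/15 within group, 96 trials per
subject.

Parameters with a published anchor use it directly:

| parameter | LD | HD | anchor |
|---|---|---|---|
| group mean PSE $\alpha$ | $+0.9$ | $-0.1$ | fitted group curves |
| group mean slope $\beta$ | $0.98$ | $0.76$ | fitted group curves |
| AUDIT mean ± sd | $7.57 \pm 3.91$ | $15.17 \pm 4.97$ | sample table |
| drinks/week mean ± sd | $5.1 \pm 3.43$ | $16.47 \pm 3.74$ | sample table |
| AUDIT–drinks correlation | $0.74$ | $0.74$ | reported r |

Quantities with no published individual-level value were fixed once, on
the following reasoning, and are not meant to be tuned per analysis:

* **Between-subject sd of $\alpha$: 0.8.** Individual curves in this kind
  of study range from near-exclusive alcohol choosers to near-exclusive
  snack choosers; an sd of 0.8 relative-point units reproduces a
  comparable three-way split of individual preference categories
  (alcohol / snack / none) in both groups while keeping the pooled group
  curves close to the configured means.
* **Between-subject sd of $\beta$: 0.25, truncated at 0.05.** Slopes are
  necessarily positive for subjects who attend to the points; truncation
  at 0.05 keeps every simulated subject's curve monotone without creating
  a point mass at implausibly flat curves. Population distributions are
  normal — the minimal assumption given that only group-level fits are
  published.
* **AUDIT–drinks dependence** uses a bivariate normal (a Gaussian copula
  with normal marginals) at the configured correlation, after which AUDIT
  is rounded and clipped to its 0–40 range and drinks clipped at 0. The
  rounding attenuates the sample correlation only marginally (checked in
  the test suite at n = 2000 per group).
* **Lapse and omission rates default to 0.** The 3-second response window
  implies omissions are possible; `p_miss` simulates them, omitted trials
  earn no points and leave the denominator of every downstream proportion.

Every subject draws from an RNG substream derived deterministically from
the root seed and the subject id, so simulated datasets do not depend on
the order in which subjects are processed.

**What the generator does not emulate:** sequential dependence,
reaction times, satiety or fatigue drift across the session, a sex-linked
mechanism for the published sex × level interaction (only an additive PSE
shift by sex is exposed, default 0), and any relationship between AUDIT
and the psychometric parameters (the AUDIT-covariate analysis therefore
has a null generating model unless the user builds one). Passing tests on
simulated data consequently validate the *estimators and their
calibration*, not the behavioural realism of any particular dataset.

## Preprocessing: the adjusted logit

Choice percentages at the extreme levels sit near floor and ceiling, so a
plain logit of observed proportions is undefined for 0% and 100% cells.
The group analysis therefore uses the **empirical logit**
$\ln\!\big((k+0.5)/(n-k+0.5)\big)$, which is finite for all $k$, exactly
antisymmetric under $k \leftrightarrow n-k$, and strictly increasing in
$k$. A raw logit with clamped proportions is available behind the
`adjust = 0` switch for sensitivity analyses. Percentages are carried on
the 0–100 scale for reporting; all modelling happens on the logit scale.

## Fitting, separation, and the bootstrap

The binomial log-likelihood is maximised by Newton scoring (IRLS) on the
standardized predictor, vectorised over many count vectors at once so that
a 1000-replicate parametric bootstrap refit costs a single pass of matrix
arithmetic. Numerical safeguards:

* Newton steps are capped at 4 standardized units per iteration, which
  prevents overshoot on near-separated data; convergence is declared at a
  step below $10^{-9}$ within 60 iterations.
* The engine is cross-checked in the test suite against the
  intercept–slope `stats::glm` route (agreement to $10^{-6}$) and against
  a brute-force likelihood grid at $10^{-3}$ resolution.
* **Separation** (all observed proportions 0/1, or an unpenalised
  standardized slope exceeding 15) triggers a refit with a weak ridge
  penalty $\lambda \beta_{std}^2$, $\lambda = 10^{-4}$, and sets
  `separation_flag`. Flagged estimates are finite bounded summaries, not
  maximum-likelihood estimates. Individual subjects produce such data
  routinely.
* **Constant all-or-none choosers** (alcohol on every trial, or snack on
  every trial) have no finite PSE and an unidentified slope. These fits
  are returned as explicit boundary objects ($\alpha = \mp\infty$), refuse
  a bootstrap, and are classified directly by their unambiguous direction
  of preference with `NA` interval bounds.

Confidence intervals are **percentile parametric-bootstrap** intervals
with 1000 resamples by default: counts are redrawn from the fitted
binomial model at each design point and refit. Resamples whose
unpenalised refit diverges are refit with the same ridge; resamples that
still fail are dropped and counted, and more than 20% failures aborts
with an error rather than reporting unreliable intervals. Percentile
intervals (not BCa) are the simplest method consistent with standard
practice for this design; their coverage is verified empirically in the
acceptance suite (target band 92–98% at the study's size).

Group curves **pool counts across subjects** (binomial weights) rather
than averaging subject proportions; the alternative weighting can be
obtained by fitting averaged summaries, but pooling is the default
because it matches the binomial likelihood the bootstrap resamples from.
One consequence, visible in every simulation at the default
heterogeneity, is **attenuation**: the slope of a pooled curve over
subjects with dispersed PSEs is flatter than the mean individual slope
(mixing logistic curves is not logistic). The parameter-recovery test
therefore checks recovery of the configured group means within ±0.15 at
the study's size, a band that accommodates the attenuation at
$\mathrm{sd}(\alpha) = 0.8$.

The published group slopes are treated as being in logit units per
relative-point unit; the source does not state units, and this is the
only reading consistent with a logistic fit on the three levels.

## Preference classification and contingency tests

A subject prefers alcohol if the 95% bootstrap interval of their PSE lies
entirely below 0, snacks if entirely above, and neither if it covers 0
(an interval touching 0 counts as covering). χ² tests of independence on
the group × category table use the uncorrected Pearson statistic by
default. The AUDIT ≥ 7 group comparison is conventionally run with the
Yates continuity correction — the published value for that 2×2 table
matches the corrected statistic, while the published preference-table
values match the uncorrected one, and the package documents rather than
hides this inconsistency. A further note for users comparing against the
published per-category 2×2 statistics: the values printed for the
alcohol-preferring and snack-preferring categories appear transposed
relative to their printed counts (the uncorrected statistics on the
printed counts are ≈5.96 and ≈6.94), so the package's tests reproduce
only the 2×3 table (8.92) and the no-preference 2×2 (0.29) exactly.

## The split-plot model

The published analysis is described as a linear mixed-effects model with
relative point level (within subject) and group (between subjects) as
predictors and sex as covariate. On a complete balanced design this is
numerically identical to the classical **split-plot decomposition**, which
is what `split_plot_model()` computes via `stats::aov()` error strata:
between-subject effects are tested against the between-subject residual,
within-subject effects against the within-subject residual. The test
suite verifies the equivalence against an independently fitted
subject-random-intercept model (`lmerTest`, Satterthwaite df) to a
relative $10^{-6}$ on balanced data. An iterative mixed-model fit for
*unbalanced* data is out of scope — incomplete subjects must be dropped,
and the error message lists them — because the exact random-effects
structure of the original analysis is unstated.

Model form decisions, all of which reproduce the published df structure:

* sex enters as a between-subjects **factor** with its interactions
  (including group × sex), giving the between-residual 56 df at 60
  subjects;
* level is **categorical** (2 df) in the group model — the full
  `group*sex*level` factorial leaves 112 within df, matching the
  published within-subject tests;
* the AUDIT model uses additive between terms (`audit + group + sex`) and
  a **linear** level contrast (1 df), leaving 116 within df, again as
  published. The published 1-df sex × level interaction inside the
  categorical model is inconsistent with a 3-level factor and is not
  reproduced.
* Partial eta squared uses each effect's own error stratum:
  $SS_{effect}/(SS_{effect}+SS_{error})$.

Degenerate variance patterns are flagged rather than silently propagated:
an effectively infinite F (zero error mean square under a real effect) is
capped at $10^6$ and marked `capped`; a 0/0 ratio is `NA` and
`degenerate`; a saturated stratum with no residual df yields
`no-error-df`. Sums of squares are compared against the grand total at a
relative $10^{-10}$ to decide what counts as an exact zero.

Cell means are reported back on the percentage scale by inverse-logit of
the cell's mean empirical logit, with t intervals computed from the
spread of per-subject values in the cell (subjects first reduced to their
mean logit for between-subject margins). These are descriptive intervals
accompanying the ANOVA, not model-based emmeans.

## Other fixed conventions

* **Level-0 point pairs:** (1,1) and (3,3) each occur on half the level-0
  trials, keeping mean point magnitude balanced across levels; side
  counterbalancing is enforced *within* each level (stronger than overall
  balance), which removes a side × level confound in simulation studies.
  Whether the original task additionally constrained runs of identical
  levels or sides is unknown; the schedule here is a plain seeded
  permutation.
* **Reward tie-break:** an exact points tie goes to the snack (with a
  warning and a flag); a seeded random tie-break is available. A fixed
  default keeps runs reproducible.
* All user-facing randomness flows through explicit seed arguments; the
  pipeline derives per-stage and per-subject substreams from one root
  seed and records it in the output manifest.

## Problem sizes used in validation

The calibration studies run at sizes chosen to make Monte-Carlo error
small relative to the tolerance being checked while keeping the suite
quick to run routinely: 300 replicates × 1000 resamples for bootstrap
coverage (binomial se ≈ 1.3 percentage points against a 92–98% band),
1000 null cohorts for the type-I error of the group test (se ≈ 0.7
percentage points against a 3.5–6.5% band), and 200 cohorts at the full
study size for parameter recovery. The same quantities are recomputed by
`scripts/acceptance.R` from a user-supplied seed.

## Known limitations

* The fitted model has no lapse parameter; heavy lapsing in simulated
  data biases $\beta$ downward (the simulator exposes `lapse` precisely
  so users can quantify this).
* Percentile bootstrap intervals are first-order accurate only; for very
  small per-subject trial counts the individual-PSE intervals are wide
  and their nominal coverage approximate.
* The split-plot route requires complete balanced data.
* Group-curve attenuation under heterogeneity (above) means pooled group
  slopes systematically underestimate mean individual slopes; comparisons
  *between* groups of similar heterogeneity remain meaningful.
* The AUDIT-covariate fit treats each subject's counts as binomial at
  their AUDIT value; overdispersion from subject-level heterogeneity is
  not modelled and its bootstrap intervals are accordingly anti-
  conservative for that analysis.
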