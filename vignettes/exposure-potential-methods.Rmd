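---
title: "Exposure potential, restriction, and bias amplification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exposure potential, restriction, and bias amplification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The question

Some people cannot be exposed at all: men cannot take oral contraceptives,
nobody could receive a COVID vaccine before 2020. Writing $Z$ for the
exposure-potential indicator ($Z = 1$ when exposure is possible, so
$\Pr[A = 1 \mid Z = 0] = 0$), the analyst of a cohort with such a stratum
faces a design decision: drop the no-potential stratum (restriction on $Z$),
adjust for $Z$, or ignore it. The answer depends on the causal role of $Z$:

* If $Z$ is a confounder (it affects the outcome directly), it must be
  controlled — by adjustment or by restriction, which are equivalent here.
* If $Z$ is **not** a confounder it is an instrumental variable: it is
  strongly associated with exposure and touches the outcome only through
  exposure. Conditioning on an instrument amplifies whatever residual
  confounding is left in the analysis, so restriction can *increase* bias.

`eprr` implements this trade-off as a fully simulated and exactly solvable
system: a generative model in which sex determines exposure potential, a
log-binomial estimator for each analysis recipe, a Monte Carlo loop that
produces the bias/SE/MSE table, and an exact 16-cell oracle that gives every
Monte Carlo number a closed population-level counterpart.

## The generative model

Each individual carries four binary variables: sex (male = 1; males have no
exposure potential), a confounder $C$, an exposure $A$, and an outcome $Y$.
The mechanism is purely multiplicative on the risk-ratio scale, with no
product terms — the conditional risk ratio of $A$ is the same in every
stratum:

$$
\Pr[A = 1 \mid \text{female}, C] = p_0\, \mathrm{RR}_{C\to A}^{\,C},
\qquad
\Pr[A = 1 \mid \text{male}] = 0,
$$
$$
\Pr[Y = 1 \mid \text{sex}, C, A] =
p_{Y0}\; \mathrm{RR}_{A\to Y}^{\,A}\;
\mathrm{RR}_{C\to Y}^{\,C}\;
\mathrm{RR}_{\text{male}\to Y}^{\,\text{male}} .
$$

The default parameters are the study conditions: $\mathrm{RR}_{A\to Y} =
1.3$ (the target effect), $\mathrm{RR}_{C\to A} = \mathrm{RR}_{C\to Y} =
1.75$, and 69% of women exposed, with cohorts of $n = 10\,000$ and 1000
Monte Carlo iterations. Two presets differ only in the direct effect of sex
on the outcome: `confounder` ($\mathrm{RR}_{\text{male}\to Y} = 0.75$, sex
is independently preventive) and `instrument`
($\mathrm{RR}_{\text{male}\to Y} = 1$).

$p_0$ is not free: `calibrate_exposure_baseline()` solves the linear
constraint $p_0\,[(1 - p_C) + \mathrm{RR}_{C\to A}\, p_C] = 0.69$ exactly,
and `validate_spec()` enforces the feasibility bounds (no cell risk above 1;
$p_0\,\mathrm{RR}_{C\to A} \le 1$ whenever a $C = 1$ stratum exists — the
bound is vacuous at $p_C = 0$).

Three nuisance parameters are needed that the headline conditions do not
pin down; they are fixed once, at values a cohort simulation in this field
would call unremarkable, and not revisited: $p_{\text{female}} = 0.5$ (so
restriction keeps about 5000 of 10 000 people), $p_C = 0.5$ (a balanced
confounder, the least favourable case for "residual confounding is
negligible" arguments), and $p_{Y0} = 0.10$ (a common-outcome setting, the
regime where risk ratios and odds ratios genuinely part ways and
log-binomial — not logistic — regression is the natural model). $C$ is
drawn independently of sex: the mechanism posits no sex–$C$ arrow, and
independence is the minimal structure consistent with that. A sensitivity
check in the package's development showed the asymptotic biases of the
mis-specified analyses are essentially invariant to $p_{Y0}$ — they are
determined by the headline parameters — while the Monte Carlo *standard
errors* scale with the event rate, so the SE and MSE columns of the report
should be read as properties of these defaults, not universal constants.

## Estimation: damped IRLS for the log-binomial model

`fit_log_binomial()` maximizes the Bernoulli likelihood with a log link.
This model is boundary-prone: the parameter space is constrained by
$\exp(x^\top\beta) \le 1$, and unguarded Newton steps can walk through the
boundary. The fitter therefore:

* starts at the intercept-only MLE $(\log \bar y, 0, \dots, 0)$, which is
  always feasible;
* halves each Newton (IRLS) step until the proposal keeps every fitted
  probability $\le 1$ and does not decrease the log-likelihood;
* declares convergence when the largest coefficient change in a step falls
  below $10^{-10}$ — a coefficient-scale criterion, chosen over a
  log-likelihood-change criterion because the near-quadratic likelihood
  makes $10^{-10}$ in log-likelihood worth only about $10^{-5}$ in the
  coefficients, too loose for the package's own exact-recovery checks at
  $10^{-8}$;
* flags any fit whose fitted probabilities come within $10^{-8}$ of 1 as
  `converged = FALSE` (a boundary maximum is not an interior MLE and its
  information-based SE is not trustworthy).

Nonconverged fits are dropped from Monte Carlo summaries and counted
(`n_dropped`); a plan losing half its iterations aborts the run, since that
indicates mis-specification rather than occasional boundary trouble. Under
the default scenarios drops essentially never occur — all fitted risks stay
below about 0.23.

Records are collapsed to covariate-pattern counts before fitting (at most
$2^4$ patterns; the weighted likelihood is identical), which is why the full
12-cell grid of 12 000 fits takes seconds. The same weighted fitter, fed
cell *probabilities* instead of counts, is the exact oracle
`asymptotic_effect()`: the population-level fit is the large-$n$ limit of
the Monte Carlo mean.

## The six analysis plans and their exact relationships

`canonical_plans()` encodes the six recipes: adjusted for $C$; adjusted for
$C$ and sex; adjusted for $C$, restricted to women; no adjustment; adjusted
for sex; restricted to women only. Two structural identities hold and are
tested exactly, not statistically:

* **Adjust-for-sex $=$ restrict-on-sex, per cohort.** With terms
  $\{A, \text{sex}\}$ the model is saturated on the three observed
  categories (exposed woman, unexposed woman, unexposed man), so the $A$
  coefficient is the female-only cell contrast — men inform only nuisance
  parameters. Hence rows "Adjusted for sex" and "Restriction on sex" of the
  report are identical to numerical precision in every iteration.
* **Adjust-for-$C$-and-sex $=$ adjust-for-$C$-with-restriction, at the
  population level.** Both are correctly specified, so both limits equal
  $\log 1.3$; in finite samples they differ only in how the $C$ coefficient
  is pooled.

The mis-specified plans' limits quantify the taxonomy
(`classify_restriction_effect()`): in the confounder scenario restriction
removes the sex confounding (and leaves the $C$ bias untouched when $C$ is
unadjusted); in the instrument scenario restriction or adjustment for sex
*amplifies* the residual $C$ bias above the crude analysis's.

## Monte Carlo design and reporting

One cohort is sampled per iteration and all plans are evaluated on it.
Sharing cohorts across plans makes within-iteration contrasts exact and
reduces the Monte Carlo noise of between-plan comparisons; the cost — the 12
report cells are not mutually independent — is irrelevant to the quantities
reported. Each iteration draws from its own substream, seeded
deterministically from (base seed, iteration index) by an integer mix
computed exactly in double precision, so any single cell of the report is
reproducible without regenerating the cohorts before it.

The report columns follow the estimator-evaluation conventions: `se` is the
**empirical** SD of the per-iteration log RR estimates (not the mean
model SE) — this is the definition consistent with the decomposition
$\mathrm{MSE} = \mathrm{bias}^2 + \mathrm{variance}$, which the summarizer
satisfies to $10^{-12}$ by construction; the interval around the
exponentiated mean is normal-theory, $\exp(\text{mean} \pm 1.96\,
\text{SE})$. Empirical quantiles would be an equally defensible interval at
these sample sizes; the normal-theory choice is recorded here and in the
report metadata. The model-based SE is not discarded: a property test checks
it tracks the empirical SD within 20% for correctly specified plans.

## Diagnostics

`pooled_unexposed_mean()` returns the weighted-average decomposition of the
unexposed mean, $\mathrm{E}[Y \mid A=0] = \sum_z \mathrm{E}[Y \mid A=0,
Z=z]\Pr(Z=z \mid A=0)$, exactly on cohorts and on the exact table.

`partial_exchangeability_check()` computes the observable contrast
$\mathrm{E}[Y \mid A=0, Z=1] - \mathrm{E}[Y \mid A=0, Z=0]$ behind the
partial-exchangeability assumption $Y^{a=0} \perp\!\!\!\perp Z$. Its
interpretability flag is deliberately *caller-supplied* structural
knowledge: whether an open backdoor path exists between $A$ and $Y$ is a
subject-matter judgement, not something the data decide. The instrument
preset is the cautionary example: partial exchangeability holds by
construction, yet the contrast is nonzero because conditioning on $A = 0$
opens a collider path — unexposed women are depleted of $C$ relative to
men, who are all unexposed.

`positivity_report()` tabulates exposure prevalence per stratum of a
candidate adjustment set. Positivity fails only when sex enters the set
(male strata are structural zeros); adjusting for $C$ alone leaves exposed
women in every stratum, which is why lack of exposure potential does not by
itself violate positivity.

`gformula_truth()` standardizes the conditional risks over the covariate
distribution. The default target population is the exposure-potential
stratum: $\mathrm{E}[Y^{a=1}]$ is not well defined for people who cannot be
exposed, so whole-population counterfactuals are refused unless the caller
explicitly asserts well-definedness, in which case the male risks under
exposure are taken from the generating multiplicative model (they have zero
support in the data).

## The exposure-compulsion mirror

A stratum that *must* be exposed ($\Pr[A = 1 \mid Z=1] = 1$) is the same
problem after recoding $A' = 1 - A$. `mirror_compulsion()` flips a recode
flag on the scenario: data generation is unchanged, the analysed exposure is
relabelled, and the true conditional risk ratio becomes
$1/\mathrm{RR}_{A\to Y}$. Because a log-link linear predictor is invariant
under the reparameterization $A \mapsto 1 - A$ (only the intercept shifts),
every analysis's bias in the mirrored scenario is exactly the negative of
its bias in the original on the log scale — a property the test suite
verifies against the exact oracle. Mirroring twice restores the original
scenario.

## What the simulation does and does not show

The generator emulates exactly the structure under study: binary variables,
a multiplicative risk model with no effect modification, one confounder,
sex independent of $C$, and perfectly measured data. Passing tests
therefore demonstrate the bias-amplification arithmetic under that
structure; they say nothing about continuous confounders, several
confounders, effect-measure modification on the RR scale, measurement
error, or selection — all deliberately out of scope. The
magnitude-dependent report cells (the biased rows' bias/SE/MSE values)
depend on the full parameter vector, including values the headline
conditions do not fix; the package treats their *ordering and sign
structure* as the reproducible content and checks the correctly specified
cells (which are invariant to the nuisance parameters) as hard numeric
targets.

## Problem sizes used by the shipped checks

Unit tests run on cohorts of 1000–10 000 with tens of iterations; the
acceptance suite and `scripts/acceptance.R` run the study conditions in
full — two scenarios at $n = 10\,000$ with 1000 iterations each — which the
pattern-collapsed fitter completes in well under a minute on one CPU.
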