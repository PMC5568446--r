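---
title: "Modelling valence- and type-asymmetric reinforcement learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling valence- and type-asymmetric reinforcement learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rlbias)
```

## The scientific question

Instrumental learning updates option values from prediction errors
(PEs).  Human learners often weight these updates asymmetrically, and
two axes of asymmetry can be separated when the forgone outcome is also
shown: the *valence* of the PE (positive vs. negative) and its
*information type* (obtained vs. forgone outcome).  A confirmation
bias is the specific pattern in which choice-confirming events —
positive PEs on the chosen option and negative PEs on the unchosen
option — drive larger updates than choice-disconfirming events.
`rlbias` implements the full simulation-and-inference pipeline needed
to characterise such biases: because no human dataset ships with the
package, every analysis runs on synthetic cohorts generated by the same
model family that is later fitted, which makes the whole chain testable
end to end.

## Task model

The task is a repeated two-armed bandit organised in fixed choice
contexts (cue pairs).  The default design, `task_config()`:

* 2 sessions × 4 contexts × 24 context trials = 192 trials;
* per session: one Symmetric context (both options rewarded with
  probability .50), two Asymmetric contexts (.75/.25) and one Reversal
  context (.83/.17 for the first 12 context trials, swapped
  thereafter);
* outcomes are +1 or −1, drawn independently per option on every
  trial.  The independence is analytically consequential: the obtained
  and forgone outcomes coincide with probability
  `p1·p2 + (1−p1)(1−p2)` — 50%, 37.5% and 28.2% in the three
  conditions (`expected_concordance()`);
* feedback is either *partial* (obtained outcome only) or *complete*
  (forgone outcome also shown).

Design choices where the design space was genuinely open:

* **Interleaving.** Contexts are interleaved within a session by a
  seeded uniform shuffle.  No constraint (e.g. against long runs) is
  imposed, since the conditions are learned simultaneously and the
  value updates are context-local; a pseudo-randomised variant would
  only matter for sequential effects the models do not contain.
* **Reversal clock.** The contingency reversal triggers on the
  context-local trial counter (after the 12th presentation of that
  context), not on a global trial index.
* **Session reset.** The second session uses fresh context instances
  (new stimuli), so Q-values re-initialise to 0 per context instance.
* **Outcome coding.** Outcomes are ±1 (win/lose a point), which makes
  `Q = 0` the correct prior expectation of an unknown option and keeps
  all values inside `[−1, 1]` for learning rates in `[0, 1]`.

## Learning and choice model

Per context instance, values start at 0 and follow the delta rule with
valence-gated rates (`factual_update()`, `counterfactual_update()`);
the counterfactual module runs only when the forgone outcome is
displayed.  A PE of exactly 0 is a no-op (both branches of the gated
rule agree in the limit, so no third rate is needed).  Choice follows
the scaled softmax of `choice_probability()`; `β` multiplies the
decision variable, so larger `β` means *more* deterministic choice
(an inverse-temperature reading of the printed rule, regardless of the
"temperature" label sometimes attached to it).

The model family ties the four rate slots:

* `Full` — αc+, αc−, αu+, αu− free (5 df);
* `Information` — ties across valence: α_C, α_U (3 df);
* `Valence` — ties across type: α+, α− (3 df); under partial feedback
  this is also the natural two-rate factual-only model;
* `Confirmation` — α_CON = {αc+, αu−}, α_DIS = {αc−, αu+} (3 df);
* `One` — a single rate (2 df);
* `Perseveration` — the Information tying plus a choice-repetition
  weight π (4 df).  The family definition fixes 4 df for this model;
  building it on the valence-unbiased (Information) tying is the one
  reading consistent with that count, and it is also the scientifically
  useful control: can unbiased learning plus a tendency to repeat
  choices mimic a confirmation bias?
* **Perseveration mechanism.** π is added to the previously chosen
  option's decision variable *inside* the softmax
  (`exp(β·(Q + π·repeat))`), per context, with no bonus on a context's
  first trial.  This is the simplest mechanism matching "increasing the
  likelihood of repeating the same choice regardless of the previous
  outcome"; an additive-on-βQ variant would only rescale π.

Nested tyings are exact: `Confirmation(a, a)`, `Full(a, a, a, a)` and
`One(a)` produce identical trial-by-trial likelihoods, which the test
suite asserts.

## Estimation

`negative_log_likelihood()` replays the updates over the observed
sequence (in C++ for speed; an independently coded plain-R replay
oracle checks it in the tests) and sums `−log` softmax probabilities,
computed with max-subtraction so extreme `β·Q` cannot overflow.

Two objectives:

* **MLE** (`fit_mle()`): bounded minimisation with learning rates in
  `[0, 1]` and `β ∈ [0, 100]`.  The upper bound on β is a practical
  cap (the theoretical range is unbounded); fits that hit it indicate
  near-deterministic behaviour where β is weakly identified anyway.
  MLE values feed `bic()` = `log(n)·df + 2·nll` and BIC-based model
  comparison.  The BIC uses the number of trials entering the
  likelihood (192 pooled; the subset size for per-condition fits).
* **MAP** (`fit_map()`): adds log priors — `Gamma(shape 1.2, scale 5)`
  on β (mean 6; the shape/scale reading of the convention) and
  `Beta(1.1, 1.1)` on every free learning rate, identical across rates
  so rate comparisons are not differentially shrunk; flat on π, which
  has no stated prior.  The Beta prior vanishes at 0 and 1, so MAP
  learning-rate estimates are always interior — this is why
  learning-rate analyses (bias indices, group splits) use MAP
  estimates, while BIC uses MLE.

Both use `stats::optim` (L-BFGS-B) from 10 random interior starting
points (seeded, so fits are reproducible); the best restart wins and a
`converged` flag records whether any restart converged rather than
failing silently.  MAP bounds keep rates in `[0.001, 0.999]` so the
optimiser never evaluates the infinite boundary penalty.

## Group model selection

Per-subject BICs become approximate log evidences (`−BIC/2`) and enter
the standard random-effects scheme (`rfx_bms()`): models are treated as
random effects across subjects with a uniform Dirichlet prior
(`alpha0 = 1`), estimated by alternating subject-wise responsibility
updates and Dirichlet count updates.  Exceedance probabilities are
Monte-Carlo estimates from the fitted Dirichlet; the default 10⁶
samples keep the Monte-Carlo standard error below 0.005.  Chance
attribution is `1/K` for whatever K-model set is compared — 0.25 for a
four-model space, 1/6 for the full family — and `compare_models()`
reports it alongside the attributions.

A caveat established while testing against an exact oracle: on very
small cohorts (2–4 subjects) with moderate evidence differences, the
mean-field scheme is systematically overconfident relative to the
exact Dirichlet-multinomial posterior (deviations up to about 0.1 in
attribution, with the per-subject ranking preserved).  It is exact in
the symmetric and dominance limits.  This is a property of the
standard algorithm, not of this implementation; at realistic cohort
sizes (N = 20) the approximation is unproblematic.

## Synthetic cohorts: what they do and do not emulate

`make_virtual_cohort()` generates agents under the stated task with

* `"empirical-like"` parameters drawn from the fitting priors
  (rates `Beta(1.1, 1.1)`, β `Gamma(1.2, 5)`).  The original recovery
  design drew generating values from fits to human data, which are not
  available; drawing from the priors is the self-consistent,
  reproducible substitute and spans the same support.
* discrete profiles for the recovery designs: `unbiased`
  (0.30/0.30), `semi-biased` (0.45/0.15 chosen, 0.30/0.30 unchosen)
  and `biased` (0.45/0.15 chosen **and** 0.15/0.45 unchosen — the
  confirmation pattern) at β = 5.  The exact generating values of the
  published discrete designs appear only in figures, so these defaults
  are representative, not copied; the `biased` profile follows the
  confirmation reading of that design (its verbal description is
  internally inconsistent about the direction of the unchosen-rate
  asymmetry).

The synthetic data reproduce the trial structure, contingencies,
feedback regimes and outcome independence, and agents are exactly the
fitted models.  They deliberately do **not** emulate response times,
attention lapses, session fatigue, or any model-misspecification gap
between true human learning and the Q-learning family.  A green
recovery or model-selection test therefore establishes that the
pipeline is *self-consistent* (the estimation recovers what the model
generated), not that humans obey the model.

## Behavioural indices

* `preferred_choice_rate()` — Symmetric-condition rate of the modal
  option; ≥ 0.5 by construction.  An exact 50/50 tie returns 0.5 with
  a flag (the ">50%" definition is silent on ties).
* `correct_choice_rate()` — rate of choosing the option with the
  higher scheduled probability in force on that trial; in the Reversal
  condition the second-half correct option is the initially worse one.
* `normalized_bias()` — experiment 1: `(αc+−αc−)/(αc++αc−)`;
  experiment 2 (default): `((αc+−αc−)−(αu+−αu−))` over the four-rate
  sum, which is +1 for a pure confirmation pattern and −1 for its
  mirror image.  The printed variant of the second numerator term (a
  sum rather than a difference) is available via `form = "printed"`:
  as printed, the index is not +1 at the pure confirmation pattern and
  conflates overall counterfactual learning with its asymmetry, which
  is why the difference form is the default.
* `median_split()` — high = strictly above the median, low = at or
  below; equal group sizes for even N with distinct values.
* `model_estimate_curves()` / `curve_squared_distance()` — replays
  fitted parameters over the subject's actual sequence and scores the
  mean squared distance between the predicted probability of the
  condition's designated option and the observed 0/1 choice indicator,
  per condition, then averaged over conditions per subject.  Scoring
  against the binary indicator (rather than between smoothed mean
  curves) keeps the distance defined per subject, as needed for
  across-subject comparisons; a cohort generated by an asymmetric
  model is fitted detectably better by the asymmetric tying than by
  its unbiased restriction under this metric.

## Numerical choices and degenerate inputs

* Softmax computed with max-subtraction; `β = 0` gives exactly 0.5.
* Zero-variance columns in correlation matrices are flagged (`NA` plus
  a warning), never silently propagated.
* Failed fits in recovery experiments are excluded with a logged
  count, not imputed.
* All randomness flows through explicit integer seeds; cohort members
  get distinct derived sub-seeds, so any subject can be regenerated in
  isolation.

## Known limitations

* No hierarchical (empirical-Bayes) estimation or MCMC posteriors —
  per-subject point estimates only, as in the original procedure.
* No protected exceedance probabilities or family-level inference.
* The perseveration mechanism's placement (additive on the decision
  variable, absent on first trials) is one defensible reading of a
  verbally specified model.
* Model-recovery confusion matrices (fitting every model to every
  generator) are a natural extension not included here.
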