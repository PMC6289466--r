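---
title: "Modelling strategies in deterministic trial-and-error learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling strategies in deterministic trial-and-error learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drplearn)
```

## The task

Each learning block introduces four novel stimuli that map one-to-one onto
the four fixed response keys `d f k l`. Feedback is deterministic, so a
single trial is decisive evidence about its stimulus-response pair — and,
through the bijectivity of the mapping, about every other pair as well. A
block ends once every stimulus has been answered correctly eight times
(minimum possible length 4 × 8 = 32 trials) or after 70 trials. A subject
performs 20 blocks, each with a fresh hidden mapping.

The analysis question the package addresses: *which per-trial decision
policy best explains a subject's responses during the initial learning
phase* — the trials from block start until each stimulus has been answered
correctly at least once?

## The four model families

All families emit, per trial, a preference vector over the four responses
for the current stimulus, which one shared softmax turns into selection
probabilities: $p_{ij} \propto \exp(\mathrm{pref}_{ij}/\tau)$, with noise
$\tau \ge 0$. At $\tau = 0$ selection is uniform over the preference
maximizers.

A note on the softmax parameterisation: the preferences are *divided* by
$\tau$, so $\tau$ is a temperature and $1/\tau$ an inverse temperature.
This is forced by the stated noise-free limit — at $\tau = 0$ responses
are uniform over the *maximal* preferences, which only the divisive form
approaches; a multiplicative $\tau$ would make $\tau = 0$ uniform over all
responses. The fitting grid $\tau \in \{0, 1/6.0, 1/5.8, \dots, 1/0.2\}$
then spans inverse temperatures 6.0 down to 0.2.

**Q-learning** keeps a value $q_{ij}$ per pair, starting at 0, updated
only for the tried pair: $q \leftarrow (1-\alpha)q + \alpha$ after reward,
$q \leftarrow (1-\alpha)q - \alpha$ after an error, $\alpha \in (0,1]$.
The implied reward magnitudes are the fixed points $\pm 1$ of this update;
they are not free parameters. Q-learning draws no inference across pairs,
so it cannot exploit the one-to-one structure — the property the other
three families exist to contrast.

**Free optimal play (FOP)** is the ideal observer. Its state is the
*consistency set*: the subset of the 24 candidate mappings compatible with
the history. Negative feedback removes the mappings containing the tried
pair; positive feedback retains only those containing it (which
automatically blocks that response for the other stimuli). Preferences are
the exact marginals $\hat p_{ij}$ — the fraction of surviving mappings
assigning $j$ to $i$, computed by counting over at most 24 members, so all
probabilities are exact rationals and no tolerance questions arise.

**Binarized play (BP)** applies FOP's consistency tracking but flattens
each preference row to uniform over its nonzero entries, modelling a
learner who excludes taken responses without tracking graded
probabilities.

**Deterministic response patterns (DRP)** test responses in a fixed order
(31 characters of state: which response is designated or confirmed per
stimulus). We implement the designated response as *the first response in
the order with nonzero consistency-set marginal for this stimulus*. One
mechanism then yields both behaviours the pattern needs: skipping
responses confirmed for other stimuli, and the forced indirect inferences
(when all but one response is excluded for a stimulus, the survivor is
designated regardless of order position). Under selection noise a chosen
response can deviate from the designated one; a deviating response updates
the internal state only on positive feedback. Negative feedback on a
deviation is deliberately ignored: a backward deviation was already
falsified (nothing to learn) and updating on a forward deviation would
jump the order over possibly-correct responses and corrupt the pattern.
Whether a deviation should advance any pointer is genuinely open; we keep
the state unchanged, the simplest rule consistent with that reasoning.

FOP and BP, by contrast, condition their consistency set on *every* trial
including deviant ones — with deterministic feedback every observed
outcome is valid evidence about the mapping, whatever policy produced the
response.

## Maximum-likelihood fitting

`fit_models()` evaluates each model on the subject's *actual* responses
and feedback (the state is evolved along the data, not along the model's
preferred actions) and sums log selection probabilities over the initial
learning phase of blocks 6–20. The first five blocks are excluded because
strategies are still stabilising there; both choices are fixed by the
study design the package emulates. Two boundary decisions:

- The trial that completes the initial phase (the fourth stimulus's first
  correct response) is *included* in the likelihood window — the phase
  ends at, not before, that trial.
- In the rare block where the 70-trial cap is reached while some stimulus
  was never answered correctly, the phase never ends and the full block
  enters the likelihood.

The search is an exhaustive grid: 31 τ values, crossed with 20 α values
for Q-learning, one parameter set per subject per model fitted jointly
across the 15 blocks. Joint fitting (rather than per block) is required so
that the per-block log-likelihoods extracted at the optimum are paired
observations for the signed-rank tests. Ties break towards the first grid
point in enumeration order, so results are exactly reproducible. τ = 0 is
kept in the grid; a trial the noise-free model gives probability zero
contributes −∞, a valid ordering value that simply loses the argmax unless
prediction is perfect. Natural logarithms throughout.

The grid search exploits one structural fact: the preference trajectory
along fixed data does not depend on τ (and for Q-learning depends only on
α), so each block's trajectory is computed once and the 31 τ values are
evaluated vectorised against it.

## Hierarchical model comparison

Models are compared per subject over the 15 paired per-block
log-likelihoods with one-sided Wilcoxon signed-rank tests at p < 0.05,
staged from the most to the least specific predictions: first the two
plausible response patterns (*dfkl*, *lkfd*; each must beat all four
rivals), then FOP (must beat BP and Q), then BP (must beat Q), then Q
(beating either FOP or BP suffices — the disjunctive reading of the final
stage), else `none`. The stage order is part of the procedure's
definition: a subject whose pattern wins all four tests is a pattern
subject even if FOP also beats BP and Q, and a regression test freezes
this.

The signed-rank statistic is implemented in the package: zero differences
dropped (the classical convention — the procedure's source is silent on
zeros, and dropped-zeros-with-exact-null is the standard reading at
n = 15), midranks for tied magnitudes, and an exact tie-aware null for
n ≤ 25 computed by subset-sum convolution over the doubled midranks
(equivalent to enumerating all 2^n sign assignments), with a
tie-corrected, continuity-corrected normal approximation above. No
multiple-testing correction within a subject, matching the procedure as
specified. Tests cross-check the implementation against a full 2^n
enumeration oracle for all n ≤ 8 (including ties and zeros) and against
the classical exact distribution when no ties are present.

`preliminary_ranking()` reproduces the unconstrained 27-model comparison
(all 24 orders + FOP + BP + Q) by raw best likelihood; it is biased —
submitting more models of one class makes that class more likely to
contain the winner — which is exactly why the constrained staged procedure
above is the primary tool.

## The synthetic-cohort generator

No behavioural data ship with the package, so every downstream stage is
exercised on simulated cohorts with known ground truth. The generator
emulates the task statistics: 20 blocks per subject, a fresh mapping per
block drawn uniformly from the 24 permutations, stimuli presented
uniformly at random among those not yet finished (immediate repeats
allowed — the minimal reading of "randomized order"; the real experiment's
sequence constraints, if any, are unknown), deterministic feedback, and
the 8-correct/70-trial termination rule. Responses come from any of the
four families at chosen parameters. Each subject gets an independent RNG
stream derived from the master seed, so cohorts are bit-reproducible and
insertion or removal of subjects does not perturb the others.

The default cohort mirrors the composition inferred for the 85-subject
human sample (36 *dfkl* + 7 *lkfd* patterns, 18 FOP, 19 BP, 5 Q) with
τ = 1/4 — a mid-grid noise level typical of fitted estimates — and
α = 0.5 for Q-learners. These defaults are fixtures for testing the
pipeline, not claims about any particular dataset.

What the generator does *not* emulate: the strategy-adaptation period of
the first few blocks (early blocks are drawn from the same stationary
model), omitted or late responses, response times, fatigue, and
within-subject strategy mixtures. Passing recovery tests therefore show
that the pipeline identifies stationary, pure-strategy agents under the
task's trial statistics — not that human data meet those idealisations.

## Error taxonomy and generative checks

Errors are classified against the *ideal observer run on the trial's
history prefix* — not against the behaving model's internal state — so the
same classifier applies to any agent: optimal errors (chosen response had
maximal $\hat p$), suboptimal errors (nonzero but not maximal), and
zero-probability errors subdivided into repeatedly-wrong,
correct-for-a-different-stimulus, both, or neither (the "neither" case is
precisely an error an indirect inference would have avoided), plus an
after-first-correct flag. A trial can carry several labels;
optimal/suboptimal/zero-probability partition all errors, and the
zero-probability "neither" category is read as $\hat p = 0$ minus the
repeatedly-wrong and taken-response cases.

`s4_check()` verifies the structural fact that makes pattern behaviour
detectable at the population level: on any stimulus sequence the 24
response orders produce one and the same multiset of optimal-error counts,
and noise-free FOP's count distribution converges to that same reference —
so FOP's error count is sequence-independent while each individual
pattern's count varies with the sequence. To compare the 24 orders "on the
same sequence" even though presentation adapts to performance, all orders
within one replicate consume a shared uniform random stream for the
stimulus draws. Replay-based checks (`generative_replay()`) regenerate a
fitted subject's blocks (same mappings, fresh sequences) to compare
realized subjects against model expectations, mirroring how generative
performance is usually assessed: subject points are single 15-block
realisations, model points are replay averages, which is why realized
pattern cohorts show visibly larger between-subject variability in optimal
errors than replay-averaged ideal-observer predictions, even though the
marginal per-block distributions coincide under random mappings.

## Numerical and testing choices

- All consistency-set probabilities are exact counts over ≤ 24 members;
  comparisons like "maximal probability" are exact, no tolerances.
- Softmax evaluation subtracts the row maximum before exponentiating.
- The test suite sizes simulations to what the checks need: recovery
  studies use cohorts of 20 subjects per family at 20 blocks (the study's
  subject-block geometry), oracle comparisons use 100–120 random histories
  at 5 × 10^5 Monte-Carlo samples each, and the optimal-error invariance
  check uses 20 sequences × 24 orders plus 10^4 ideal-observer replays.
- `run_pipeline()` writes every stage's CSV/JSON output plus a log with
  per-stage timings; identical configuration and seed give byte-identical
  outputs.

## Known limitations

- **(α, τ) identifiability.** On initial-phase windows (~15–20 trials per
  block), the Q-learning likelihood is nearly flat along the α/τ ridge:
  early in a block the values scale with α and the softmax divides by τ,
  so mainly the ratio is constrained. The grid MLE is consistent — with
  ~100 blocks per subject both coordinates are pinned to the truth — but
  at 15 blocks individual coordinates carry several grid steps of sampling
  noise while the ratio is recovered tightly. Interpret fitted α and τ
  from initial-phase data jointly, not separately.
- **FOP vs BP power.** The two models differ only on trials whose
  preference rows are graded, which are a minority; over 15 blocks the
  signed-rank contrast between them is underpowered, and simulated
  ideal-observer subjects are often assigned the BP label even though FOP
  fits better on average. Assignment frequencies for these two families
  should be read as conservative lower bounds on FOP-like behaviour.
- The pattern models' deviation rule (ignore negative feedback on
  deviating responses) is the simplest defensible choice, not a validated
  cognitive claim; sensitivity to it has not been explored.
- Omissions are not modelled; blocks are assumed to contain a response on
  every trial.
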