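---
title: "Models and methods behind the iblt package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the iblt package}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iblt)
library(dplyr)
```

## The task and its design

The Information Bias Learning Task (IBLT) is a two-armed probabilistic
choice task in which two outcome channels — a win worth +10p and a loss
worth −10p — each appear over one of two stimuli on every trial,
independently of each other and of the participant's choice. The
participant collects the payoff of whatever lands on the chosen stimulus;
when win and loss co-locate, the trial nets zero regardless of choice.
What makes the task a *bias* manipulation is volatility: the probability
that an outcome appears over stimulus A is either

* **volatile** — alternating between 0.2 and 0.8 in runs of 14–30 trials,
  making that outcome informative about the near future, or
* **stable** — fixed at 0.5, making the outcome useless for prediction.

A session is five 80-trial blocks: a both-volatile block, three training
blocks in which exactly one valence is volatile (losses for negative
training, wins for positive training), and a final both-volatile block
that probes near transfer. Each block uses a fresh stimulus pair and, by
construction, contains exactly 40 trials on which win and loss co-locate.

`schedule_config()` holds these constants; `build_block()` and
`build_session()` generate conforming designs. Three generation choices
deserve comment:

* **Run partitioning.** Run lengths are drawn uniformly from [14, 30]
  under a dynamic feasibility constraint (the remaining trials must still
  be partitionable), so a block never ends with a truncated short run. An
  80-trial block therefore always has 3, 4 or 5 runs — a fact the tests
  verify against brute-force enumeration of all partitions.
* **Exact-frequency realization.** Within each run, the number of
  outcome-on-A trials equals `round(length × p)` with positions permuted
  uniformly, rather than i.i.d. Bernoulli draws. This makes nominal
  probabilities exactly realized and the 40-co-location constraint
  attainable by rejection sampling with a modest budget (10,000 attempts
  per drawn design; the run boundaries are redrawn, up to 100 times, for
  the occasional design whose alignment makes 40 practically unreachable).
  An i.i.d. mode is available via `realization = "bernoulli"`.
* **Independence.** Win and loss run boundaries are always drawn
  independently, including in both-volatile blocks, and the first volatile
  level is chosen uniformly at random.

Schedules are pure functions of seed and configuration: the same seed
reproduces a session bit-identically.

## The generative choice model

Beliefs about where each outcome will appear follow a valence-specific
delta rule. Writing $r^{win}_i$ for the estimated probability that the win
appears over stimulus A on trial $i$ (initialized at 0.5 each block, since
a new stimulus pair carries no prior information), the update after
observing the realized location $o_i \in \{0, 1\}$ is

$$r^{win}_{i+1} = r^{win}_i + \alpha_{win}\,(o_i - r^{win}_i),$$

and identically for the loss channel with its own learning rate
$\alpha_{loss}$. The prediction error is taken as *outcome minus
prediction*, so updates converge toward observed frequencies; both
channels update on every trial because both outcome locations are
displayed whether or not their stimulus was chosen. The two belief
estimates map to a choice through a softmax with inverse temperature
$\beta$ and an additive bias $t$:

$$P(\text{choice} = A) = \frac{1}{1 + e^{-\beta\,(r^{win} + t - r^{loss})}}.$$

$\beta = 0$ gives random responding; large $\beta$ approaches greedy
choice of the option with the better biased value difference. The
implementation evaluates the log-sigmoid in a branch that never
exponentiates a large positive argument, so extreme $\beta$ values are
safe.

`simulate_cohort()` emulates the study structure around this model:
20 participants per arm (the published sample size), two sessions each
with counterbalanced sham/active stimulation order, and a fresh realized
schedule per session (the default; a shared-schedule mode exists because
the original task may have fixed one schedule — the deposited data would
tell, and both modes are supported). Per-participant parameters are drawn
once per agent:

| parameter | distribution | default | rationale |
|---|---|---|---|
| $\alpha_{win}, \alpha_{loss}$ | logit-normal | mean logit(0.3), sd 0.5 | mid-range rates with realistic person-to-person spread |
| $\beta$ | log-normal | mean $\ln 8$, sd 0.4 | noisy but clearly value-guided choice |
| $t$ | normal | mean 0, sd 0.05 | small idiosyncratic side bias |

These produce behaviour that is learnable but far from deterministic —
the regime a fitter actually faces. The optional *volatility-adaptive*
mode shifts each agent's learning rate by ±1 on the logit scale toward
the volatile valence of the current block, emulating the adaptation the
task is designed to train; without it, the downstream ANOVA stage would
have no valence effect to recover. Stimulation offsets default to zero (a
null effect), matching what the task's own analyses concluded.

What the generator does **not** emulate: reaction times, within-trial
display order, attention lapses, drift in parameters across a session, or
any physiological effect of stimulation. Passing tests therefore show
that the pipeline recovers what this model family generates under the
published design — not that human data satisfy the model.

## Grid-based posterior estimation

Parameters are estimated separately for each participant × session ×
block, as in the analysis the task was built for: the purpose is to
*measure* block-wise learning rates, not to model their adaptation
mechanism. The likelihood of the observed choices is evaluated at every
node of a fixed grid:

* $\alpha$ axes: 30 points uniform in **logit** space over [0.02, 0.98];
* $\beta$ axis: 25 points uniform in **log** space over [0.1, 30];
* $t$ axis: 15 points linear over [−0.5, 0.5].

The transformed spacings match the transformations under which the
parameters are later analysed, and the prior is uniform over grid nodes —
i.e. uniform in that transformed space. The joint posterior is then the
normalized likelihood; marginals follow by summation, and the reported
estimate of each parameter is the expectation of its marginal on the raw
scale (`estimate = "mode"` is available). All normalization happens in
log space with max-subtraction: a 70-trial likelihood product underflows
double precision at plausible parameter values, so naive arithmetic is
reserved for the tiny-fixture oracle tests that cross-check the log-space
path to 1e−10.

The first 10 trials of each block are omitted from the likelihood —
early choices reflect estimation under a fresh prior more than stable
learning — but beliefs still update through them, since omission is about
scoring, not dynamics. AIC ($2k - 2\ell_{max}$) and BIC
($k\ln n - 2\ell_{max}$) use the grid-maximum log-likelihood with
$n = 70$ scored trials. `compare_models()` evaluates nested restrictions
(shared learning rate, no bias, fixed $\beta$) by collapsing the relevant
axes, which is how a model family is compared on a common grid.

Numerical notes: the grid bounds clip extreme agents (an $\alpha$ of
0.99 cannot be estimated above 0.98), posterior means shrink toward the
interior of the axes as data get less informative, and a block of pure
noise leaves the $\alpha$ marginals close to, but not exactly, the prior
(the $\beta$ axis excludes zero, so the likelihood is never perfectly
flat). The parameter-recovery checks measure the correlation between true
and fitted logit learning rates across blocks whose true rates span
[0.05, 0.95] — the standard recovery design; at a single fixed parameter
value a correlation is undefined, so the fixed-centre condition
($\alpha_{win}=0.2$, $\alpha_{loss}=0.6$, $\beta=8$) is used for the
directional check instead. At study scale (40 blocks, 70 scored trials
each) the recovery correlation for the volatile valence is ≈ 0.9.

## The model-free statistic

On a both-outcome trial the next choice is the model-free readout of
which valence dominates: selecting the stimulus that carried both
outcomes (by staying on it, or by switching to it) is *win-driven*; the
complementary moves are *loss-driven*. The proportion of win-driven
follow-ups over the block's both-outcome trials — 40 by construction —
is the statistic; its complement is the loss-driven proportion. A
both-outcome trial in final block position has no follow-up and is
excluded from numerator and denominator alike (the eligible count is
reported, so the choice is auditable). Proportions are computed per
block, the ANOVA's unit of analysis. The statistic is invariant to
relabelling the stimuli, and a $\beta = 0$ agent sits at 0.5 up to
Monte-Carlo error — both are tested properties.

## The inference layer

Learning rates enter the ANOVA after a logit transformation and inverse
temperatures after a log transformation, mapping both onto the real line.
`mixed_rm_anova()` implements the balanced fully-crossed mixed design the
task's analyses use: within-participant factors (outcome valence,
block or pre/post time, stimulation condition) with stimulation order
between participants. The sums-of-squares decomposition is the classical
multi-stratum one with participant as the blocking unit, computed via
`aov()` error strata; for balanced orthogonal designs every SS type
coincides, which is precisely why unbalanced or incomplete designs are
rejected outright rather than imputed. Effect sizes are generalized
eta-squared (Olejnik–Algina, with no effects declared "observed"), the
default of the `ez` front-end commonly used for such analyses; classical
eta-squared sits behind `effect_size = "classical"`. For within effects
with more than one numerator df a Greenhouse–Geisser-corrected p is
reported alongside the uncorrected one; epsilon is computed from the
orthonormal-contrast covariance pooled within between-groups (the SPSS
convention — an implementation that pools across groups will differ in
the third decimal, which the cross-checks in the test suite account for).

Degenerate inputs are handled explicitly: a constant response vector
yields all-zero effect SS and $F = 0$ with $p = 1$ (not NaN), and a
paired t on zero-variance nonzero differences reports an infinite t with
a flag rather than an error. The layer is validated three independent
ways: exact agreement with the paired-t closed form on any two-level
within design, exact SS conservation, and uniformity of null-simulation
p-values; frozen cross-checks against an independent implementation pin
F, p, generalized eta-squared and epsilon on seeded fixtures.

## Pipeline, reproducibility, and problem sizes

`run_pipeline()` chains simulate → fit → behavioural statistic → ANOVA
and writes five artifacts including a manifest (configuration, seed,
package version, MD5 digests) sufficient to reproduce a run
bit-identically. Every source of randomness descends from one master
seed through named substreams (`substream_seed()`), so any stage can be
re-run in isolation.

The shipped checks run at deliberately chosen sizes: 500 blocks for
schedule conformance, 40 blocks for parameter recovery, 200 agents for
the behavioural-statistic direction, 500 replicates for the null-ANOVA
uniformity check, and one full 20-participant cohort for the end-to-end
valence effect. These sizes give stable Monte-Carlo estimates on a
single desktop core in a few minutes; the package's functions accept
larger sizes unchanged.

## Known limitations

* The grid fitter's bounds and resolution are a design choice; estimates
  on real data can differ slightly from ones produced under another
  unstated grid, especially for participants near the bounds.
* Whether information criteria should use the grid-maximum or an
  expected likelihood is convention-dependent; this package uses the
  maximum, the textbook definition.
* The model family here is the delta-rule/softmax family; volatility-
  estimating (Bayesian learner) models are out of scope.
* The ANOVA layer is balanced-design-only by intent; covariate
  adjustment (ANCOVA) is not provided.
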