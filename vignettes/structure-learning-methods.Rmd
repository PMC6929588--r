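---
title: "Detecting spontaneous task-set formation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting spontaneous task-set formation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tasksetmem)
```

## The scientific problem

When people learn to map four two-dimensional stimuli (say, red/blue squares
and circles, or young/old female/male faces) onto four response keys, they
can either memorize all four stimulus-response associations directly (a
*flat* mapping) or organize them hierarchically: one *supraordinate*
dimension selects which rule over the other (*sub-ordinate*) dimension
applies. Hierarchical learners pay a *switch cost* — slower and less
accurate responding — on trials where the supraordinate level changes
relative to trials where it repeats, because the task-set has to be
reconfigured. Flat learners, having no task-set, should show no such cost.

`tasksetmem` implements the full analysis chain for this inference problem:
it generates the trial structures of four experiments that bias task-set
formation through *motor clustering* (placing the two responses within each
supraordinate level on adjacent keys), simulates flat and hierarchical
learner agents, applies the trial- and participant-level filters, and tests
structure formation with within-participant label-permutation nulls. A
second analysis axis quantifies the cost of structure formation to
*incidental encoding*: memory for the trial-unique images encountered during
learning, probed by a surprise old/new recognition test and analysed with
binned repeated-measures ANOVAs.

## The switch-cost statistic

For one participant, trials are classified by the transition from the
previous trial under a candidate supraordinate dimension: supraordinate
*repeat* (the candidate level repeats), supraordinate *switch* (the
candidate level changes while the other dimension's level repeats), or
*double feature switch* (both change; excluded because the cost cannot be
attributed to either rule). The first trial is excluded. RT analyses keep
correct, responded trials with 200 ms <= RT <= 1250 ms (the response
window); accuracy analyses keep all responded trials, since correctness is
the outcome. Boundary values are retained: the printed exclusions are
strict inequalities.

With condition means $\mu_S, \mu_N$ and SDs $\sigma_S, \sigma_N$ on switch
and repeat trials, the package reports the signed cost
($\mu_S - \mu_N$ for RT; repeat minus switch for accuracy, so that positive
always reads "structure evidence"), its absolute value, and the normalized
(d-prime-style) cost

$$ z = \frac{\mu_S - \mu_N}{\sqrt{\tfrac12(\sigma_S^2 + \sigma_N^2)}} $$

plus a SEM-based variant ($\sigma^2/n$ in place of $\sigma^2$) used for
group-level aggregation, which treats participants as exchangeable units of
similar variance. The normalized cost is scale invariant — multiplying all
RTs by a constant leaves it unchanged — and does not index the *strength*
of structure formation, only its detectability against within-participant
noise.

## The permutation tests

Because the sign of the cost merely indicates which dimension is
supraordinate, inference is run on the absolute normalized cost against a
within-participant label-exchange null: the repeat/switch labels are
shuffled over the participant's included trials (condition counts fixed)
and the statistic recomputed, 10,000 times by default. The observed
statistic is deemed significant when its percentile — the fraction of null
draws strictly below it — reaches 97.5% (the upper tail of a two-sided
2.5% criterion). Permutation draws with zero pooled spread score 0.

* **Individual level**: the SD-normalized statistic per participant; a
  participant counts as a *structure former* when either the RT or the
  accuracy test is significant (union flag). Under the null the union rate
  is about $1 - 0.975^2 \approx 4.9\%$ when the two measures are
  independent; the measures share trials, so mild dependence is possible,
  and the calibration suite checks the realized rate against its binomial
  interval.
* **Group level**: the mean over participants of the absolute
  SEM-normalized cost, compared against null means formed by pairing the
  $k$-th independent per-participant shuffle across participants
  (per-participant streams are seeded from one master seed, so runs are
  reproducible and parallelizable).

Only the upper tail is flagged; raw percentiles are always reported so a
reader preferring a lower-tail reading can recover it. Percentiles live on
a $1/n_\text{perm}$ lattice; for discrete measures (accuracy) ties between
observed and permuted statistics make the strict-inequality percentile
conservative, which is visible as a slightly depressed accuracy flag rate
in calibration.

### Supraordinate-dimension inference

Each participant's supraordinate dimension is inferred by computing the
signed RT cost under each candidate dimension and reporting the one with
the larger cost; exact ties fall back to the mapping's biased dimension
(clustered) or the first dimension, and are flagged. Exact category
repetitions are excluded for this purpose (unlike for the cost estimate
itself): they are labelled "repeat" under *both* candidates, so they carry
no information about which dimension is supraordinate. The decision reduces
to the sign of the contrast between the two single-switch trial classes;
with an injected 80 ms cost, lognormal RT noise of $\sigma_{\log} = 0.25$
and 120 trials, its error rate is about 5% — the recovery rate hovers at
the 95% mark and is sensitive to the assumed RT noise, which real data do
not pin down.

## The simulator

The synthetic-data generator emulates the statistical structure the
analyses assume, not a mechanistic model of task-set inference:

* **Accuracy** follows an exponential approach from 4-alternative chance,
  $p(t) = p_\infty - (p_\infty - 0.25)\,e^{-t/\tau}$, with $\tau = 5$
  trials by default (associations essentially learned within ~15 trials)
  and $p_\infty = 0.9$; a 2% lapse rate adds stimulus-independent errors.
  Instructed designs start at asymptote. After the Experiment-3 rule
  switch, the two *negative-transfer* categories (whose keys changed)
  restart their learning curve; *positive-transfer* categories continue —
  this reproduces the transfer-by-time interaction the analysis targets.
* **RT** is lognormal (right-skewed, positive) with median 650 ms and
  log-sd 0.25 — conventional magnitudes, since the study's own RT
  distributions are not published as parameters. Hierarchical agents add
  their switch cost (default 80 ms) on the natural scale whenever their
  supraordinate level changes. Responses slower than the 1250 ms window
  become timeouts, and independent timeouts occur at 3% per trial,
  matching the ~3% reported rate. The window truncation clips slightly
  more mass from (shifted) switch trials, so recovered costs carry a small
  negative bias (about -2 ms at default settings) — a property of the
  measurement, not a bug.
* **Recognition memory** is equal-variance signal detection: old items draw
  strength from $N(d_b, 1)$ with a per-learning-bin strength $d_b$, new
  items from $N(0, 1)$, and three ascending criteria map strength onto the
  four confidence ratings; "old" responses are those above the middle
  criterion. Defaults ($d = (1.1, 0.95, 0.8, 0.7)$ across bins, criteria
  $(-0.5, 0.75, 1.5)$) give hit rates around 0.48-0.64 declining across
  bins and false-alarm rates around 0.23, the magnitudes typical of this
  paradigm, with the primacy profile (earlier items remembered better) the
  analyses probe. Cohort defaults give the clustered group a bin-1
  encoding deficit of 0.2 d-prime units (about 0.08 in hit-rate units) —
  the early-encoding cost of structure formation — and leave later bins
  identical across groups.
* **Cohorts** split participants evenly into clustered/non-clustered
  groups, assign counterbalanced versions round-robin, and draw each
  participant's strategy (hierarchical fraction 0.6 clustered, 0.15
  non-clustered by default, echoing the observation that clustering biases
  but does not determine structure formation). Clustered hierarchical
  agents adopt their mapping's biased dimension; non-clustered hierarchical
  agents pick a dimension at random.

What the simulator does **not** reproduce: RT speedup with practice,
sequential autocorrelation beyond the switch structure, accuracy switch
costs for hierarchical agents (only RT costs are injected), individual
heterogeneity in lapse/timeout rates, and any mechanistic account of how a
learner discovers structure. Passing tests therefore certify the analysis
machinery under its own assumptions, not conclusions about real behavioral
data.

## Design arithmetic

Key positions are integers 1-4 for the v, b, n, m keys, and keyboard
distance is the absolute position difference. The clustered layout nests
the sub-dimension within each supraordinate level at keys {1,2} and {3,4},
giving same-feature distances (1, 1, 2, 2), mean 1.5. The non-clustered
layout follows the instructed example pattern — one supraordinate level on
keys {1,4}, the other on {3,2} — giving (3, 1, 2, 2), mean 2.0. (A
published distance list of (2, 2, 4, 1), mean 2.3, cannot arise from any
bijection of four adjacent keys, whose maximum distance is 3; we treat it
as a typo and do not attempt to match it.)

The memory phase shows every learning image once plus roughly one third new
images, rounded up to the nearest multiple of four to keep categories
balanced: 128 old gives 44 new (172 trials), 120 old gives 40 new (160
trials). Learning trials are binned (30, 30, 30, 38) for 128 trials and
(30, 30, 30, 30) for 120; participants with fewer than 10 responded old
trials in any bin are excluded from binned analyses. The synthetic face
catalog mirrors the curated stimulus set: 52 faces per age-by-gender
category, 43 white plus 9 of other racial categories each, all neutral in
emotion — 208 ids in total, with no image files involved.

## Memory analyses

Confidence ratings are collapsed to binary old/new; hits are old items
rated old, false alarms new items rated old. Encoding above chance is
tested by a paired t-test of hit against false-alarm rates per group, with
$d_z = t/\sqrt{n}$ and the common-language effect size $\Phi(d_z)$;
independent comparisons use $d_s$ from the pooled SD and $\Phi(d_s/\sqrt2)$.
These conventions are fixed and documented rather than fitted: published
$d$/CL pairs in this literature are not mutually consistent across reports,
so the package's values are its own.

The binned ANOVAs (bin within, group between, optional centered switch-cost
covariates) are type-III repeated-measures ANOVAs computed through
`car::Anova` on a multivariate linear model with sum contrasts;
Greenhouse-Geisser correction is applied whenever the within factor has
more than two levels and $\epsilon$ is always reported (for two-level
factors sphericity holds trivially and $\epsilon = 1$). Partial eta squared
is $SS_\text{effect}/(SS_\text{effect}+SS_\text{error})$. The test suite
checks this machinery against an independent `aov` Error-stratum fit on a
fixed balanced toy table to six decimals; the toy uses six participants
(three per group) because an unbalanced between factor would make
sequential and type-III sums of squares differ for reasons unrelated to
correctness.

Source memory (Experiment 1 only) is analysed for old images: accuracy per
question type (each stimulus dimension) split by the collapsed recognition
rating, tested against chance 0.5 and with a rated-old versus rated-new
paired t-test per group, plus the type-by-rating-by-group ANOVA. False
alarms have no defined source accuracy and are excluded, as in the source
analyses this implements.

## Numerical and procedural choices

* Exact category repetitions count as supraordinate repeats for cost
  estimation (the supraordinate rule persists); a flag allows excluding
  them for sensitivity analyses. Dimension inference excludes them by
  default (see above).
* Only trial 1 is excluded globally; in the Experiment-3 pre/post
  comparison, transition labels are re-derived within each half, so trial
  61 becomes that half's excluded "first" trial. This treats the post-switch
  regime as its own sequence without discarding additional data elsewhere.
* Undefined costs (fewer than 2 trials in a condition) drop the participant
  from that analysis rather than erroring the cohort; drops are recorded.
* All seeds derive deterministically from one master seed keyed by
  participant id and stage, so any single participant's records or
  permutation stream can be regenerated in isolation.
* Problem sizes used by the verification suites — 1,000 agents at 2,000
  permutations for calibration, 1,000 agents for recovery, 200 replicate
  cohorts of 60 for the memory direction check, full enumeration only for
  8-trial toys — were chosen to keep Monte-Carlo error comfortably inside
  the tolerances being checked.

## Known limitations

The permutation machinery assumes exchangeability of condition labels
within participant; time-varying RT (e.g. fatigue) correlated with label
order would violate it, and the simulator does not generate such data. The
group-level test averages absolute SEM-normalized costs, so it is sensitive
to any systematic departure from zero in either direction rather than to a
signed group effect; a signed variant can be computed from the per-
participant output. Dimension recovery operates at the information floor of
a two-class mean contrast and should not be expected to exceed ~95% at an
80 ms cost under realistic RT noise. Finally, agent parameters are not
fitted to data — the simulator is a verification instrument, not a model of
human learners.
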