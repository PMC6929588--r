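# tasksetmem

Tools for studying **spontaneous hierarchical task-set formation** in
trial-and-error category learning, and its cost to **incidental recognition
memory**.

When people learn to map four two-dimensional stimuli (red/blue
squares/circles; young/old female/male faces) onto four keys, they may
memorize the four stimulus-response pairs directly (a *flat* mapping) or
organize them hierarchically, letting one *supraordinate* dimension select
which rule over the other dimension applies. Hierarchical learners pay a
switch cost when the supraordinate level changes between trials; flat
learners do not. The package implements the complete analysis chain for
detecting this structure and measuring what it costs memory:

* **Design generation** — the four experiments' trial structures: 2 x 2
  stimulus categories, motor-clustered vs. non-clustered key mappings
  (clustering places the two responses within each supraordinate level on
  adjacent keys), counterbalanced versions, learning/memory trial lists,
  and the Experiment-3 implicit mid-phase rule switch with its
  positive/negative transfer classification.
* **Agent simulation** — flat and hierarchical learner agents with
  exponential learning curves, lognormal RTs carrying an injectable switch
  cost, response-window timeouts, and signal-detection recognition memory
  with per-bin encoding strengths.
* **Switch-cost inference** — trial filtering, supraordinate-transition
  labelling, the normalized switch cost

  $$z = \frac{\mu_S - \mu_N}{\sqrt{\tfrac12(\sigma_S^2 + \sigma_N^2)}},$$

  within-participant label-permutation tests at the individual (SD form)
  and group (SEM form) level with an upper-tail 97.5% criterion, union
  "structure former" flags, and supraordinate-dimension inference from the
  sign of the raw RT costs.
* **Memory analysis** — hit/false-alarm rates after collapsing 4-level
  confidence ratings, chance tests with Cohen's d and common-language
  effect sizes, baseline-category group comparisons, Greenhouse-Geisser
  corrected repeated-measures ANOVAs on binned hit rates with optional
  switch-cost covariates, source-memory analysis (Experiment 1) and
  post-switch transfer analysis (Experiment 3).

See `vignettes/structure-learning-methods.Rmd` for the models, assumptions,
defaults and limitations.

## Worked example

Simulate an Experiment-2-style cohort (20 participants per learner group,
2,000 permutations) and run the full pipeline:

```r
library(tasksetmem)
cfg <- run_config(2, n_per_group = 20, n_perm = 2000, seed = 42)
res <- run_pipeline(cfg)
report(res)
```

```
== Structure-formation pipeline ==

Structure-formation analysis (Experiment 2, 2000 permutations)
  40 of 40 participants included

Group-level permutation percentiles (mean |z|, SEM form):
  clustered     rt        100.00% * (n=20)
  clustered     accuracy   82.10% (n=20)
  nonclustered  rt         11.60% (n=20)
  nonclustered  accuracy   40.05% (n=20)

Individual structure formers (union of RT/accuracy flags):
  clustered     5 of 20
  nonclustered  1 of 20

== Recognition memory ==
  clustered hit vs FA: t(19) = 15.517, p = 0.0000, Cohen's d = 3.470, CL = 100.0% (mean diff 0.315)
  nonclustered hit vs FA: t(19) = 18.699, p = 0.0000, Cohen's d = 4.181, CL = 100.0% (mean diff 0.342)
  baseline-category group test: t(38) = 0.921, p = 0.3630, Cohen's d = 0.291, CL = 58.2% (mean diff 0.026)

Binned hit-rate ANOVA (n = 40):
    effect df1 df2     F         p   pes gg_eps      p_gg
     group   1  38 3.120 8.537e-02 0.076     NA        NA
       bin   3 114 9.051 2.002e-05 0.192  0.976 2.429e-05
 group:bin   3 114 0.348 7.908e-01 0.009  0.976 7.859e-01

Mean hit rates by learning-phase bin:
        group  hit_bin1  hit_bin2  hit_bin3  hit_bin4
    clustered 0.5681691 0.5572053 0.5423668 0.4840558
 nonclustered 0.6132175 0.5886633 0.5621310 0.4864797
```

Reading the output: the clustered group's mean normalized RT switch cost
exceeds every one of its 2,000 permutation means (percentile 100%, starred
as significant at the 97.5% upper-tail criterion), while the non-clustered
group sits inside its null — the motor-clustering manipulation induced
structure formation. Five clustered but only one non-clustered individual
cross the individual 97.5% criterion on either measure. Both groups
remember the task images far above chance (hit minus false-alarm differences
of 0.32-0.34), memory declines across learning-phase bins (significant bin
effect), and the non-clustered group's advantage is concentrated in the
earliest bin — the simulated encoding cost of early structure learning.

Lower-level entry points: `simulate_cohort()`, `structure_analysis()`,
`permute_switch_cost()`, `binned_hit_anova()`, `write_design()`. A thin
command-line wrapper lives at `inst/cli/tasksetmem.R`:

```sh
Rscript inst/cli/tasksetmem.R run --experiment 2 --n-per-group 30 --seed 1 --out results/run1
```

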