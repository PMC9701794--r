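---
title: "Within-lifetime learning and neutral genetic drift: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Within-lifetime learning and neutral genetic drift: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(driftlearn)
```

## The question

Classical treatments of genetic drift let the intensity of drift depend on
census size, the number of breeders, and variance in reproductive success.
They do not ask whether *non-heritable, within-lifetime* changes in survival
ability — an animal learning to evade a predator, immunological memory after
an infection — can alter how fast neutral diversity is lost. driftlearn
implements a forward-time, individual-based model built to isolate exactly
that question: prey under predation with a fixed per-step kill quota, where
escaping an attack may raise an individual's future escape probability, but
nothing is inherited, nothing is selected, and population-level mortality is
*identical* whether or not learning occurs.

The central result the model produces: even with matched mortality, a
learning population retains distinct neutral alleles for much longer. The
mechanism is a self-reinforcing pool of experienced, hard-to-kill
individuals whose alleles are temporarily shielded from loss.

## The model

A population of `population_size` prey (default 1000) carries neutral allele
labels drawn from `n_initial_alleles` (default 100) — one label per haploid
individual, two per diploid. There is no mutation, migration, or selection;
alleles are bookkeeping labels only. Every individual has an escape
probability, initially `initial_escape` (0.5).

Each time step applies, in order:

1. **Age-cap mortality** (optional; `max_age`, default unbounded). Everyone
   strictly older than the cap dies. These deaths do *not* count toward the
   predation quota.
2. **Predation to quota.** A living individual is drawn uniformly at random
   (with replacement — escapees remain targetable) and killed with
   probability 1 − its escape probability. Attacks repeat until exactly
   `n_removed` prey have died. The quota, not the attack count, is fixed:
   a learning population simply absorbs more attacks per step.
3. **Learning** (if enabled). Under `step_end` timing (the default), every
   survivor that escaped at least one attack this step receives exactly one
   update, however many attacks it escaped; under `immediate` timing the
   update applies after every escape, during the attack loop. The update is
   either *accelerating*, `p <- min(cap, p * (1 + rate))`, a proportional
   gain that compounds until the cap binds, or *decelerating*,
   `p <- p + rate * (cap - p)`, a gain proportional to the remaining
   headroom. The cap `escape_cap` (default 0.99) guarantees every attack
   retains a positive kill probability, so the quota loop always
   terminates.
4. **Reproduction** restores the population to `population_size`. Asexual:
   a surviving parent is drawn uniformly with repetition; the offspring
   copies its allele. Haploid sexual: a random pair of distinct survivors;
   the offspring's single allele comes from one parent at random. Diploid
   sexual: a random pair; one allele drawn uniformly from each parent's
   pair. Every newborn starts at age 0 with the *initial* escape
   probability — learning is never inherited.
5. **Metrics** are recorded (distinct alleles, allele spectrum, deaths by
   cause, attack count, mean escape probability, age histogram).
6. **Ages advance** by one completed step; newborns stay at age 0 through
   their birth step.

Because generations overlap, a lucky learner can reproduce many times; this
is what converts a non-heritable survival advantage into slower allele loss.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `population_size` | 1000 | census size, restored every step |
| `n_initial_alleles` | 100 | distinct neutral labels at step 0 |
| `n_removed` | 500 | predation kill quota per step (identical across compared arms) |
| `initial_escape` | 0.5 | newborn escape probability |
| `escape_cap` | 0.99 | ceiling on learned escape ability |
| `learning_rate` | 0.09 | proportion per update |
| `learning_mode` | accelerating | proportional vs headroom update |
| `learning_timing` | step_end | one update per step vs per escape |
| `max_age` | Inf | optional hard age cap |
| `n_steps` | 100 | simulated horizon |

The ratio `n_removed / population_size` sets the per-step marginal death
probability of the non-learning arm exactly (the quota forces it), hence a
geometric lifespan with mean `population_size / n_removed`. The learning
effect on allele retention peaks at intermediate predation: too little
predation and drift is slow anyway; too much and learners do not live long
enough to accumulate experience.

### Reconstructed settings

Two settings of the published baseline experiment are not printed in its
description and had to be chosen here. The per-step quota is taken as 500
(the value stated for the escape-cap series experiment). For the learning
rate, 0.09 is the only rate printed anywhere; however, at quota 500 it
yields roughly half the reported learning-arm allele retention (about 25
remaining alleles versus the reported 50.2), whereas rate 0.20 reproduces
*both* reported arm means simultaneously (about 50 learning, 12 non-learning
versus reported 50.2 and 12.4) and is also the only candidate under which
the diploid high-predation experiment shows its reported learning effect.
The figure/table presets therefore default to `learning_rate = 0.20`, with
0.09 kept as an explicit documented candidate; both are reported by the
reproduction script, and both remain overridable arguments of `preset()`.
`sim_config()` itself defaults to 0.09, the one value with a printed
provenance.

## Conventions

**Lifespan** is counted in completed steps survived after birth: an
individual dying in the k-th step after the step of its birth has lifespan
k. Under this convention non-learning lifespans are exactly geometric with
success probability `n_removed / population_size`. Published lifespan
tables for this model report larger means (about 1.5 × the geometric mean)
and much larger SDs under an unstated accounting; driftlearn does not try
to reproduce those absolute levels and instead verifies the *relational*
claims (matched means between arms, inflated SD under learning), which are
convention-independent. Note one exact consequence of the quota: with
censored individuals included, the pooled mean lifespan is *identical*
between learning and non-learning arms by construction, because both the
total number of individual-steps lived and the total number of individuals
ever alive are fixed.

**Censoring.** Individuals alive at the end of a run have incomplete
lifespans and are excluded from `lifespan_stats()` by default
(`include_censored = TRUE` adds them at their current age). For
closed-form checks, the test suite additionally restricts to cohorts born
at least 30 steps before the end: right-censoring then truncates less than
2^-30 of the geometric mass, removing a small (~0.016 step) downward bias
that pooled dead-only lifespans otherwise show over a 100-step run.

**Generation time** is the mean parental age at offspring births, computed
per individual and averaged, unweighted, over individuals with at least one
offspring; both parents are credited in sexual modes. An individual's value
is settled at its death, so censored reproducers are excluded by default.
This matters: in learning scenarios the censored individuals are precisely
the long-lived learners, and including them makes the learning arm's
generation time look longer everywhere. With the at-death accounting, the
low-rate regime (rate 0.09, removals 135–360, step-end timing) shows
essentially no generation-time difference between arms even though the
allele difference there remains large — the model's demonstration that the
drift-buffering effect is not merely a longer generation interval.

**Ages** are recorded at the metrics stage, after reproduction and before
the increment, so the age-0 bin of a step's histogram contains both that
step's newborns and the previous step's surviving newborns; the geometric
decay of the stationary age distribution starts at age 1.

## Randomness and reproducibility

All randomness flows through R's global RNG, seeded once per run. The three
implementations — the compiled engine (default), the pure-R operator
composition (`engine = "r"`), and the deliberately naive `oracle_run()` —
consume draws in one documented order (per attack: target, then kill
decision; per birth: parent position(s), then allele pick(s); learning
updates consume nothing) and share the same alive-list semantics (creation
order, swap-remove on predation kills, stable filter for the age cap,
newborns appended). Under a shared seed they are therefore identical event
for event, which the test suite checks on a hundred randomized small
configurations each run. Replicate seeds are derived deterministically from
`(base_seed, scenario label, replicate)` via `derive_seed()` and logged in
every manifest, so any reported number can be regenerated from the manifest
alone. Paired designs can opt into common random numbers
(`seed_policy = "paired"`); the default is independent streams per arm,
matching how replicated simulation studies are usually run.

## Degenerate inputs and numerical choices

* Configurations are validated up front: the quota must leave at least one
  survivor (two in sexual modes), escape probabilities must satisfy
  `0 < initial_escape <= escape_cap < 1` (the upper bound strictly below 1
  guarantees the attack loop terminates), rates must be non-negative, and
  the balanced initialization scheme requires divisibility.
* If an age-cap cull or predation would leave fewer survivors than
  reproduction requires, the run aborts with a structured diagnostic; the
  population is never silently padded.
* A zero learning rate consumes no extra randomness and changes no state,
  so a rate-0 learning run is bit-identical to the non-learning run under a
  shared seed (tested).
* The accelerating update is capped with `min()`, the decelerating update
  approaches the cap smoothly; neither can decrease an escape probability.
* Allele labels are integers `0 .. n_initial_alleles - 1` and are never
  created or mutated after initialization, so the distinct-allele count is
  non-increasing and at least 1.

## What the simulations do and do not show

All experiments here are self-generating: the model *is* the study system,
and the package's claims are claims about the model. The simulations
emulate a constant-size population under stationary predation pressure with
instantaneous replacement and a hard kill quota. Real populations do not
have fixed per-step death counts, constant size, memoryless targeting, or
learning that only ever improves; predation pressure in nature covaries
with density and season. Passing tests therefore demonstrate the internal
logic — that a systematic, non-heritable survival improvement slows neutral
allele loss at matched population-level mortality — not the magnitude of
any such effect in nature. Estimating that would require knowing how
effectively real animals learn to evade real threats, and learning ability
is itself heritable and selectable, which this model deliberately excludes.

## Problem sizes

The shipped test suite and the reproduction script run the full published
population size (1000 individuals, 100 steps) for the paired comparisons
(20 replicates per arm), the lifespan table (10 per arm and condition), the
escape-cap series (20 per arm and cap), and the diploid comparisons (10
per arm); sweep grids are evaluated on reduced lattices of 3–16 cells at 10
replicates per arm with the response read at step 50, where the published
sweeps quote their largest effects. Engine/oracle equivalence uses
populations of 6–40 individuals, where the naive oracle is fast, across 100
randomized configurations. A full paired baseline experiment (40 runs of
roughly 2×10^5 attack events each) completes in a few seconds.

## Known limitations

* The alternative lifespan accountings used by some published tables cannot
  be recovered from their description; only relational lifespan claims are
  checked (see Conventions).
* The baseline experiment's learning rate is a reconstruction (see
  Reconstructed settings).
* Sweep axes beyond the anchor values (rate 0.09; removals 135–360 and
  200/500/800) are package choices: rates 0.01–0.20 and removals 100–800 by
  default, overridable per call.
* No explicit predator agents, spatial structure, density dependence,
  mutation, migration, or selection — by design, and matching the model
  this package implements.
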