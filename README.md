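# driftlearn

Forward-time, individual-based simulation of a prey population under
predation, built to answer one question in population genetics: can a
**systematic, non-heritable improvement in individual survival** — learning
to escape predators, immunological memory — slow the loss of neutral
genetic diversity by drift, even when population-level mortality is held
exactly constant?

The package is for population geneticists and theoretical ecologists who
want to run, extend, or audit this class of overlapping-generations drift
experiments: it provides the simulation engine, the paired
learning/non-learning experiment designs, parameter sweeps, life-history
summaries, tidy CSV outputs with full seed manifests, and a deliberately
naive reference implementation for validating the engine event-for-event.

## The model

A population of *N* prey (default 1000) carries neutral allele labels (100
initially; one per haploid individual, two per diploid). There is no
mutation, migration, or selection. Each time step:

1. predators attack prey drawn uniformly at random, killing each victim
   with probability 1 − *p*ᵢ, where *p*ᵢ is the prey's escape probability
   (initially 0.5); attacks repeat until **exactly *d* prey are dead** (the
   kill quota, default 500) — so mortality per step is identical whether or
   not prey learn;
2. survivors that escaped an attack may **learn**: accelerating updates
   *p* ← min(cap, *p*(1 + λ)) or decelerating *p* ← *p* + λ(cap − *p*),
   capped at 0.99, applied once per step (default) or after every escape;
3. survivors reproduce (asexually or sexually, haploid or diploid) until
   the population is back at *N*; every newborn starts at *p* = 0.5 —
   **learning is never inherited**.

Because generations overlap, lucky learners survive and reproduce many
times, temporarily shielding the alleles they carry. The package tracks
distinct-allele trajectories, allele spectra, age distributions, lifespans
(geometric with mean *N*/*d* in the non-learning arm), and generation time.

## Worked example

```r
library(driftlearn)

cfg <- sim_config(learning_enabled = TRUE, learning_rate = 0.2)
sim <- run_simulation(cfg, seed = 1)
sim
#> <drift_sim> haploid_asexual, seed 1 (cpp backend)
#>   100 steps, N = 1000, quota 500/step, learning on (accelerating, step_end, rate 0.2)
#>   distinct alleles: 100 at step 1 -> 49 at step 100
```

One learning run keeps 49 of 100 alleles after 100 steps. Note the engine's
bookkeeping in the trajectory: the quota is met exactly every step, while
the *attack count* floats well above it as the population gets harder to
kill (mean escape probability ~0.68):

```r
tail(sim$trajectory[c("step", "n_alleles", "deaths_predation",
                      "n_attacks", "mean_escape")], 3)
#>     step n_alleles deaths_predation n_attacks mean_escape
#> 98    98        51              500      2108    0.681112
#> 99    99        50              500      1926    0.677586
#> 100  100        49              500      1801    0.679654
```

The paired experiment — identical in everything but the ability to learn —
is the package's central design:

```r
pair <- scenario_pair(sim_config(learning_rate = 0.2),
                      n_replicates = 20, label = "baseline")
res <- run_replicates(pair, base_seed = 42)
aggregate(n_alleles ~ arm, pair_alleles_at(res, step = 100), mean)
#>           arm n_alleles
#> 1    learning     51.80
#> 2 nonlearning     12.15
```

After 100 steps the learning arm retains about 52 alleles against 12 —
a four-fold difference in retained diversity at *matched mortality*. The
life-history table shows why averages hide the mechanism: pooled mean
lifespans are *identical* between arms (the quota fixes them), but learning
inflates lifespan variability and generation time — a pool of long-lived,
experienced individuals is carrying the diversity:

```r
pair_life_history(res, include_censored = TRUE)
#>           arm lifespan_mean lifespan_sd       n generation_time
#> 1    learning      1.960784    5.336349 1020000        2.191351
#> 2 nonlearning      1.960784    1.399368 1020000        1.600799
```

Experiment presets (`preset("fig1")` … `preset("table1")`) package the
study's full designs — escape-cap series, immediate-learning variant,
age-capped and generation-time sweep grids, diploid comparisons, lifespan
table — and `write_experiment()` emits tidy CSVs plus a `manifest.json` of
configs and per-replicate seeds sufficient to regenerate every number. A
thin command-line front end ships in `inst/cli/driftlearn`
(`run` / `pair` / `sweep` / `preset` subcommands).

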