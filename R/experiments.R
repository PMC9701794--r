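#' Derive a per-replicate seed
#'
#' Deterministically maps `(base_seed, scenario label, replicate)` to a
#' 32-bit seed via a small string hash and a linear-congruential mix, so
#' replicate streams are reproducible, distinct across scenarios and arms,
#' and loggable. Paired designs that want common random numbers simply use
#' the same label for both arms.
#'
#' @param base_seed Integer base seed.
#' @param scenario Character scenario label.
#' @param replicate Replicate index (1-based).
#' @return An integer seed in `[0, 2^31)`.
#' @export
derive_seed <- function(base_seed, scenario, replicate) {
  h <- 0
  for (ch in utf8ToInt(as.character(scenario)))
    h <- (h * 131 + ch) %% 1048573
  s <- (as.double(base_seed) %% 2147483647) * 48271 +
    h * 2053 + as.double(replicate) * 7919
  as.integer(s %% 2147483629)
}

#' Define a paired learning / non-learning scenario
#'
#' The central experimental unit: two arms that share every parameter --
#' including the per-step kill quota, so population-level mortality is
#' matched by construction -- and differ only in `learning_enabled`.
#'
#' @param base_config A [sim_config()]; its `learning_enabled` is overridden
#'   per arm.
#' @param n_replicates Replicates per arm.
#' @param label Scenario label used in outputs and seed derivation.
#' @param seed_policy `"independent"` (each arm gets its own seed stream, as
#'   in independent simulation runs) or `"paired"` (common random numbers:
#'   replicate r shares one seed across arms).
#' @return A `scenario_pair` object.
#' @export
scenario_pair <- function(base_config, n_replicates = 20L,
                          label = "pair",
                          seed_policy = c("independent", "paired")) {
  validate_config(base_config)
  structure(list(base_config = base_config,
                 n_replicates = as.integer(n_replicates),
                 label = label,
                 seed_policy = match.arg(seed_policy)),
            class = "scenario_pair")
}

arm_config <- function(base, learning) {
  base$learning_enabled <- learning
  base
}

#' Run all replicates of a paired scenario
#'
#' Executes `n_replicates` runs per arm with logged, derived seeds.
#'
#' @param pair A [scenario_pair()].
#' @param base_seed Integer base seed.
#' @return A `pair_result`: `runs$learning` / `runs$nonlearning` (lists of
#'   `drift_sim`), and `seeds` (arm, replicate, seed).
#' @export
run_replicates <- function(pair, base_seed) {
  stopifnot(inherits(pair, "scenario_pair"))
  arms <- c("learning", "nonlearning")
  runs <- list(); seeds <- list()
  for (arm in arms) {
    cfg <- arm_config(pair$base_config, arm == "learning")
    tag <- if (pair$seed_policy == "paired") pair$label
           else paste(pair$label, arm)
    sds <- vapply(seq_len(pair$n_replicates),
                  function(r) derive_seed(base_seed, tag, r), integer(1))
    runs[[arm]] <- lapply(sds, function(s) run_simulation(cfg, seed = s))
    seeds[[arm]] <- data.frame(arm = arm,
                               replicate = seq_len(pair$n_replicates),
                               seed = sds)
  }
  structure(list(pair = pair, base_seed = as.integer(base_seed),
                 runs = runs, seeds = do.call(rbind, seeds)),
            class = "pair_result")
}

#' Distinct-allele counts of a pair at a step
#'
#' @param res A `pair_result`.
#' @param step Step at which to read the count (default: final step).
#' @return A data.frame: arm, replicate, n_alleles.
#' @export
pair_alleles_at <- function(res, step = NULL) {
  stopifnot(inherits(res, "pair_result"))
  out <- lapply(names(res$runs), function(arm) {
    vals <- vapply(res$runs[[arm]], function(sim) {
      s <- if (is.null(step)) nrow(sim$trajectory) else step
      sim$trajectory$n_alleles[s]
    }, numeric(1))
    data.frame(arm = arm, replicate = seq_along(vals), n_alleles = vals)
  })
  do.call(rbind, out)
}

#' Tidy per-step trajectories of a pair
#'
#' @param res A `pair_result`.
#' @return A data.frame: scenario, replicate, step, n_alleles,
#'   deaths_predation, deaths_agecap, n_attacks, mean_escape.
#' @export
pair_trajectories <- function(res) {
  stopifnot(inherits(res, "pair_result"))
  out <- lapply(names(res$runs), function(arm) {
    do.call(rbind, lapply(seq_along(res$runs[[arm]]), function(r) {
      tr <- res$runs[[arm]][[r]]$trajectory
      cbind(scenario = arm, replicate = r, tr)
    }))
  })
  do.call(rbind, out)
}

#' Pooled life-history summaries of a pair
#'
#' Pools the replicates of each arm (the convention used for lifespan
#' tables: replicates pooled together, one mean/SD per arm).
#'
#' @param res A `pair_result`.
#' @param include_censored Passed to [lifespan_stats()].
#' @return A data.frame: arm, lifespan_mean, lifespan_sd, n_dead,
#'   generation_time.
#' @export
pair_life_history <- function(res, include_censored = FALSE) {
  stopifnot(inherits(res, "pair_result"))
  out <- lapply(names(res$runs), function(arm) {
    ls <- lifespan_stats(res$runs[[arm]], include_censored = include_censored,
                         end_step = res$pair$base_config$n_steps)
    data.frame(arm = arm, lifespan_mean = ls$mean, lifespan_sd = ls$sd,
               n = ls$n, generation_time = generation_time(res$runs[[arm]]))
  })
  do.call(rbind, out)
}

#' Parameter sweep over learning rate and predation intensity
#'
#' Runs a paired learning / non-learning comparison in every cell of a
#' `learning_rate x n_removed` grid and reports the per-cell mean
#' difference (learning minus non-learning) in distinct alleles at the
#' requested steps and, optionally, in generation time. This is the
#' heatmap experiment: the learning effect peaks at intermediate predation
#' intensity and grows with the learning rate.
#'
#' @param rates Learning-rate grid values (default: 10 values spanning
#'   0.01-0.20).
#' @param removals Kill-quota grid values (default: 10 values spanning
#'   100-800).
#' @param base_config Shared configuration for every cell.
#' @param n_replicates Replicates per arm per cell.
#' @param base_seed Integer base seed.
#' @param at_steps Steps at which allele counts are read (default: step 50
#'   and the final step, clipped to `n_steps`).
#' @param gen_time Also compute the generation-time difference per cell.
#' @return A data.frame with one row per cell: learning_rate, n_removed,
#'   n_reps, mean learning/non-learning alleles and their difference at each
#'   requested step, and (if `gen_time`) generation times and difference.
#' @export
run_sweep <- function(rates = seq(0.01, 0.20, length.out = 10),
                      removals = round(seq(100, 800, length.out = 10)),
                      base_config = sim_config(),
                      n_replicates = 10L, base_seed = 1L,
                      at_steps = NULL, gen_time = FALSE) {
  validate_config(base_config)
  if (is.null(at_steps))
    at_steps <- unique(pmin(c(50L, base_config$n_steps),
                            base_config$n_steps))
  cells <- expand.grid(learning_rate = rates, n_removed = removals)
  rows <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    cfg <- base_config
    cfg$learning_rate <- cells$learning_rate[i]
    cfg$n_removed <- as.integer(cells$n_removed[i])
    validate_config(cfg)
    label <- sprintf("sweep r=%g d=%d", cfg$learning_rate, cfg$n_removed)
    acc <- list(learning = NULL, nonlearning = NULL)
    gt <- c(learning = 0, nonlearning = 0)
    for (arm in names(acc)) {
      armcfg <- arm_config(cfg, arm == "learning")
      mat <- matrix(0, n_replicates, length(at_steps))
      gts <- numeric(n_replicates)
      for (r in seq_len(n_replicates)) {
        s <- derive_seed(base_seed, paste(label, arm), r)
        sim <- run_simulation(armcfg, seed = s)
        mat[r, ] <- sim$trajectory$n_alleles[at_steps]
        if (gen_time) gts[r] <- generation_time(sim)
      }
      acc[[arm]] <- colMeans(mat)
      gt[arm] <- mean(gts)
    }
    row <- data.frame(learning_rate = cfg$learning_rate,
                      n_removed = cfg$n_removed, n_reps = n_replicates)
    for (k in seq_along(at_steps)) {
      row[[paste0("alleles_learning_step", at_steps[k])]] <- acc$learning[k]
      row[[paste0("alleles_nonlearning_step", at_steps[k])]] <- acc$nonlearning[k]
      row[[paste0("allele_diff_step", at_steps[k])]] <-
        acc$learning[k] - acc$nonlearning[k]
    }
    if (gen_time) {
      row$gen_time_learning <- gt[["learning"]]
      row$gen_time_nonlearning <- gt[["nonlearning"]]
      row$gen_time_diff <- gt[["learning"]] - gt[["nonlearning"]]
    }
    rows[[i]] <- row
  }
  do.call(rbind, rows)
}

#' Packaged experiment presets
#'
#' Fully specified, runnable versions of the study's experiments:
#' * `fig1` -- haploid asexual baseline pair, cap 0.99, step-end learning,
#'   20 replicates/arm. The removal count and learning rate of this
#'   experiment are not pinned down by the published description; candidate
#'   values are `n_removed = 500` (the quota the cap-series experiment
#'   states) with `learning_rate` 0.09 (the one rate printed anywhere) or
#'   0.20 (the rate that reproduces the baseline experiment's reported
#'   allele means and the diploid high-predation effect). The defaults are
#'   500 and 0.20; both remain explicit, overridable choices.
#' * `fig2` -- escape-cap series {0.90, 0.95, 0.975, 0.99} at quota 500,
#'   20 replicates/arm.
#' * `fig3` -- as `fig1` but with immediate (per-escape) learning.
#' * `fig4` -- age-capped (max age 10) sweep grids, one per learning timing,
#'   10 replicates/arm per cell.
#' * `fig5` -- generation-time difference sweep grids, one per timing,
#'   10 replicates/arm per cell.
#' * `fig6` -- diploid sexual pairs at quotas {500, 800}, cap 0.99,
#'   10 replicates/arm.
#' * `table1` -- lifespan table: quota {200, 500, 800} x timing
#'   {step_end, immediate}, 10 replicates/arm, pooled lifespans.
#'
#' @param name Preset name.
#' @param scale Fraction in (0, 1] multiplying replicate counts (rounded up)
#'   for reduced-cost reruns; sweeps also shrink their grids to a coarse
#'   lattice when `scale < 1`.
#' @param n_removed,learning_rate Candidate values for the parameters the
#'   baseline experiment leaves open.
#' @return An `experiment_preset` describing every scenario to run; execute
#'   with [run_experiment()].
#' @export
preset <- function(name = c("fig1", "fig2", "fig3", "fig4", "fig5", "fig6",
                            "table1"),
                   scale = 1, n_removed = 500L, learning_rate = 0.20) {
  name <- match.arg(name)
  stopifnot(scale > 0, scale <= 1)
  reps <- function(n) max(2L, as.integer(ceiling(n * scale)))
  base <- sim_config(n_removed = n_removed, learning_rate = learning_rate)
  p <- list(name = name, scale = scale)
  if (name == "fig1") {
    p$pairs <- list(baseline = scenario_pair(base, reps(20), "fig1"))
  } else if (name == "fig2") {
    p$pairs <- setNames(lapply(c(0.90, 0.95, 0.975, 0.99), function(cap) {
      cfg <- base; cfg$escape_cap <- cap
      scenario_pair(cfg, reps(20), sprintf("fig2 cap=%g", cap))
    }), paste0("cap_", c(0.90, 0.95, 0.975, 0.99)))
  } else if (name == "fig3") {
    cfg <- base; cfg$learning_timing <- "immediate"
    p$pairs <- list(immediate = scenario_pair(cfg, reps(20), "fig3"))
  } else if (name %in% c("fig4", "fig5")) {
    grid <- if (scale < 1) list(rates = c(0.05, 0.09, 0.15, 0.20),
                                removals = c(200L, 350L, 500L, 650L))
            else list(rates = seq(0.01, 0.20, length.out = 10),
                      removals = round(seq(100, 800, length.out = 10)))
    p$sweeps <- lapply(c("step_end", "immediate"), function(tm) {
      cfg <- base; cfg$learning_timing <- tm
      if (name == "fig4") cfg$max_age <- 10L
      list(timing = tm, base_config = cfg, rates = grid$rates,
           removals = grid$removals, n_replicates = reps(10),
           gen_time = name == "fig5")
    })
  } else if (name == "fig6") {
    p$pairs <- setNames(lapply(c(500L, 800L), function(d) {
      cfg <- base; cfg$n_removed <- d
      cfg$reproduction_mode <- "diploid_sexual"
      scenario_pair(cfg, reps(10), sprintf("fig6 d=%d", d))
    }), paste0("d_", c(500, 800)))
  } else if (name == "table1") {
    grid <- expand.grid(d = c(200L, 500L, 800L),
                        timing = c("step_end", "immediate"),
                        stringsAsFactors = FALSE)
    p$pairs <- setNames(lapply(seq_len(nrow(grid)), function(i) {
      cfg <- base
      cfg$n_removed <- grid$d[i]
      cfg$learning_timing <- grid$timing[i]
      scenario_pair(cfg, reps(10),
                    sprintf("table1 d=%d %s", grid$d[i], grid$timing[i]))
    }), sprintf("d%d_%s", grid$d, grid$timing))
  }
  class(p) <- "experiment_preset"
  p
}

#' Execute an experiment preset
#'
#' @param p An [preset()] object.
#' @param base_seed Integer base seed.
#' @return A list with class `experiment_result`: `preset`, `base_seed`, and
#'   either `pairs` (named [run_replicates()] results) or `sweeps` (named
#'   [run_sweep()] tables).
#' @export
run_experiment <- function(p, base_seed) {
  stopifnot(inherits(p, "experiment_preset"))
  out <- list(preset = p, base_seed = as.integer(base_seed))
  if (!is.null(p$pairs))
    out$pairs <- lapply(p$pairs, run_replicates, base_seed = base_seed)
  if (!is.null(p$sweeps))
    out$sweeps <- setNames(lapply(p$sweeps, function(sw)
      run_sweep(rates = sw$rates, removals = sw$removals,
                base_config = sw$base_config,
                n_replicates = sw$n_replicates, base_seed = base_seed,
                gen_time = sw$gen_time)),
      vapply(p$sweeps, `[[`, character(1), "timing"))
  class(out) <- "experiment_result"
  out
}
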