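#' @useDynLib driftlearn, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats runif sd setNames var
#' @importFrom utils write.csv
NULL

# 1-based draw into a list of n slots; consumes exactly one uniform, the
# same one the compiled backend consumes (floor(u * n)).
draw_index_r <- function(n) {
  j <- floor(runif(1) * n) + 1L
  if (j > n) n else as.integer(j)
}

#' Initialize a prey population
#'
#' Creates the step-0 population: `population_size` individuals at age 0,
#' every escape probability equal to `initial_escape`, and allele labels
#' (`0 .. n_initial_alleles - 1`) assigned per `init_allele_scheme` --
#' `uniform_random` draws every allele slot independently and uniformly,
#' `balanced` gives each label exactly `population_size / n_initial_alleles`
#' copies per slot (deterministic block assignment). Diploid individuals
#' carry two allele slots.
#'
#' Uses the R session RNG; call `set.seed()` first for reproducibility.
#'
#' @param config A [sim_config()].
#' @return A `population_state`: the living individuals' table, the
#'   alive-list ordering used by all per-step operators, and the step counter.
#' @export
init_population <- function(config) {
  validate_config(config)
  N <- config$population_size
  A <- config$n_initial_alleles
  diploid <- config$reproduction_mode == "diploid_sexual"
  if (config$init_allele_scheme == "balanced") {
    a1 <- rep(seq_len(A) - 1L, each = N %/% A)
    a2 <- if (diploid) a1 else rep(NA_integer_, N)
  } else {
    a1 <- integer(N)
    a2 <- rep(NA_integer_, N)
    for (i in seq_len(N)) {           # slot order matches the draw contract
      a1[i] <- draw_index_r(A) - 1L
      if (diploid) a2[i] <- draw_index_r(A) - 1L
    }
  }
  pop <- list(
    tab = list(
      birth_step = rep(0L, N), death_step = rep(NA_integer_, N),
      cause = rep(0L, N), allele1 = a1, allele2 = a2,
      n_offspring = rep(0L, N), offspring_age_sum = rep(0, N),
      escape_prob = rep(config$initial_escape, N), age = rep(0L, N),
      survived_flag = rep(FALSE, N)),
    alive = seq_len(N),
    step = 0L,
    last = list(),
    events = list(attacks = list(), births = list())
  )
  class(pop) <- "population_state"
  pop
}

#' @export
print.population_state <- function(x, ...) {
  cat(sprintf("<population_state> step %d: %d alive, %d distinct alleles, %d ever born\n",
              x$step, length(x$alive), count_distinct_alleles(x),
              length(x$tab$birth_step)))
  invisible(x)
}

#' Age-cap mortality
#'
#' Removes, at the start of a step and before predation, every individual
#' strictly older than `max_age`. These deaths are additional to the
#' predation quota; the end-of-step reproduction pass replaces them too. A
#' no-op when `max_age` is infinite.
#'
#' @param pop A `population_state`.
#' @param config A [sim_config()].
#' @param step Step index being executed (defaults to `pop$step + 1`).
#' @return The updated population; `pop$last$deaths_agecap` holds the count
#'   and `pop$last$agecap_ids` the removed ids.
#' @export
age_cap_mortality <- function(pop, config, step = pop$step + 1L) {
  pop$last$deaths_agecap <- 0L
  pop$last$agecap_ids <- integer(0)
  if (is.infinite(config$max_age)) return(pop)
  over <- pop$tab$age[pop$alive] > config$max_age
  if (any(over)) {
    ids <- pop$alive[over]
    pop$tab$death_step[ids] <- step
    pop$tab$cause[ids] <- 2L
    pop$alive <- pop$alive[!over]          # stable filter keeps list order
    pop$last$deaths_agecap <- length(ids)
    pop$last$agecap_ids <- ids
    need <- if (config$reproduction_mode == "haploid_asexual") 1L else 2L
    if (length(pop$alive) - config$n_removed < need)
      stop(sprintf("step %d: age cap leaves %d alive; quota %d leaves fewer than the %d survivor(s) reproduction requires",
                   step, length(pop$alive), config$n_removed, need),
           call. = FALSE)
  }
  pop
}

#' Predation to a fixed kill quota
#'
#' Repeats random attacks -- pick one living individual uniformly (with
#' replacement; escapees stay targetable), kill it with probability
#' `1 - escape_prob` -- until exactly `n_removed` individuals have been
#' removed. On escape, learning either applies at once (`immediate` timing)
#' or sets the survived-attack flag for the single end-of-step update
#' (`step_end` timing). The quota makes population-level mortality identical
#' between learning and non-learning scenarios by construction.
#'
#' @inheritParams age_cap_mortality
#' @param log_events Record every attack in `pop$events$attacks`.
#' @return Updated population; `pop$last` gains `n_killed` (always equal to
#'   the quota), `n_attacks`, and `killed_ids`.
#' @export
predation_step <- function(pop, config, step = pop$step + 1L,
                           log_events = FALSE) {
  d <- config$n_removed
  alive <- pop$alive
  esc <- pop$tab$escape_prob
  flag <- pop$tab$survived_flag
  immediate <- config$learning_enabled && config$learning_timing == "immediate"
  step_end <- config$learning_enabled && config$learning_timing == "step_end"
  killed_ids <- integer(d)
  killed <- 0L; attacks <- 0L
  n_alive <- length(alive)
  ev_id <- integer(0); ev_escaped <- integer(0)
  while (killed < d) {
    attacks <- attacks + 1L
    j <- draw_index_r(n_alive)
    id <- alive[j]
    dead <- runif(1) < 1 - esc[id]
    if (log_events) {
      ev_id[attacks] <- id
      ev_escaped[attacks] <- as.integer(!dead)
    }
    if (dead) {
      killed <- killed + 1L
      killed_ids[killed] <- id
      alive[j] <- alive[n_alive]           # swap-remove, matches the backend
      n_alive <- n_alive - 1L
    } else if (immediate) {
      esc[id] <- learn_update(esc[id], config$learning_mode,
                              config$learning_rate, config$escape_cap)
    } else if (step_end) {
      flag[id] <- TRUE
    }
  }
  pop$alive <- alive[seq_len(n_alive)]
  pop$tab$escape_prob <- esc
  pop$tab$survived_flag <- flag
  pop$tab$death_step[killed_ids] <- step
  pop$tab$cause[killed_ids] <- 1L
  pop$last$n_killed <- killed
  pop$last$n_attacks <- attacks
  pop$last$killed_ids <- killed_ids
  if (log_events)
    pop$events$attacks[[length(pop$events$attacks) + 1L]] <-
      data.frame(step = step, target_id = ev_id, escaped = ev_escaped)
  pop
}

#' End-of-step learning update
#'
#' Applies exactly one [learn_update()] to every survivor whose
#' survived-attack flag is set, regardless of how many attacks it escaped
#' during the step, then clears all flags. A no-op when learning is disabled
#' or timing is `immediate`.
#'
#' @inheritParams age_cap_mortality
#' @return Updated population.
#' @export
apply_step_end_learning <- function(pop, config) {
  if (!config$learning_enabled || config$learning_timing != "step_end")
    return(pop)
  ids <- pop$alive[pop$tab$survived_flag[pop$alive]]
  if (length(ids)) {
    pop$tab$escape_prob[ids] <- learn_update(
      pop$tab$escape_prob[ids], config$learning_mode,
      config$learning_rate, config$escape_cap)
    pop$tab$survived_flag[ids] <- FALSE
  }
  pop
}

#' Reproduction to restore population size
#'
#' Appends `n_births` newborns at the end of the step. Asexual: one parent
#' drawn uniformly with repetition among survivors; the offspring copies its
#' allele. Haploid sexual: a random pair of distinct survivors; the single
#' allele is taken from one parent at random. Diploid sexual: a random pair;
#' one allele drawn uniformly from each parent's pair. Every newborn starts
#' at age 0 with `escape_prob = initial_escape` -- learning is never
#' inherited. Parentage is credited to the life-history log (both parents in
#' sexual modes).
#'
#' @inheritParams predation_step
#' @param n_births Number of newborns (defaults to the deficit below
#'   `population_size`).
#' @return Updated population, restored to `population_size` individuals.
#' @export
reproduce <- function(pop, config, n_births = NULL, step = pop$step + 1L,
                      log_events = FALSE) {
  n_surv <- length(pop$alive)
  if (is.null(n_births)) n_births <- config$population_size - n_surv
  if (n_births == 0L) return(pop)
  sexual <- config$reproduction_mode != "haploid_asexual"
  diploid <- config$reproduction_mode == "diploid_sexual"
  if (n_surv < if (sexual) 2L else 1L)
    stop(sprintf("step %d: %d survivor(s) cannot reproduce in mode %s",
                 step, n_surv, config$reproduction_mode), call. = FALSE)
  surv <- pop$alive[seq_len(n_surv)]      # newborns never parent this step
  tab <- pop$tab
  M <- length(tab$birth_step)
  new_ids <- M + seq_len(n_births)
  c1 <- integer(n_births); c2 <- rep(NA_integer_, n_births)
  p1v <- integer(n_births); p2v <- rep(NA_integer_, n_births)
  for (b in seq_len(n_births)) {
    if (!sexual) {
      p1 <- surv[draw_index_r(n_surv)]
      c1[b] <- tab$allele1[p1]
    } else {
      j1 <- draw_index_r(n_surv)
      j2 <- draw_index_r(n_surv - 1L)
      if (j2 >= j1) j2 <- j2 + 1L
      p1 <- surv[j1]; p2 <- surv[j2]
      if (!diploid) {
        c1[b] <- if (runif(1) < 0.5) tab$allele1[p1] else tab$allele1[p2]
      } else {
        c1[b] <- if (runif(1) < 0.5) tab$allele1[p1] else tab$allele2[p1]
        c2[b] <- if (runif(1) < 0.5) tab$allele1[p2] else tab$allele2[p2]
      }
      p2v[b] <- p2
      tab$n_offspring[p2] <- tab$n_offspring[p2] + 1L
      tab$offspring_age_sum[p2] <- tab$offspring_age_sum[p2] +
        (step - tab$birth_step[p2])
    }
    p1v[b] <- p1
    tab$n_offspring[p1] <- tab$n_offspring[p1] + 1L
    tab$offspring_age_sum[p1] <- tab$offspring_age_sum[p1] +
      (step - tab$birth_step[p1])
  }
  tab$birth_step <- c(tab$birth_step, rep(step, n_births))
  tab$death_step <- c(tab$death_step, rep(NA_integer_, n_births))
  tab$cause <- c(tab$cause, rep(0L, n_births))
  tab$allele1 <- c(tab$allele1, c1)
  tab$allele2 <- c(tab$allele2, c2)
  tab$n_offspring <- c(tab$n_offspring, rep(0L, n_births))
  tab$offspring_age_sum <- c(tab$offspring_age_sum, rep(0, n_births))
  tab$escape_prob <- c(tab$escape_prob, rep(config$initial_escape, n_births))
  tab$age <- c(tab$age, rep(0L, n_births))
  tab$survived_flag <- c(tab$survived_flag, rep(FALSE, n_births))
  pop$tab <- tab
  pop$alive <- c(pop$alive, new_ids)
  if (log_events)
    pop$events$births[[length(pop$events$births) + 1L]] <-
      data.frame(step = step, child_id = new_ids, parent1_id = p1v,
                 parent2_id = p2v)
  pop
}
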