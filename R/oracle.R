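#' Naive reference run (event-level oracle)
#'
#' A deliberately simple, loop-by-loop re-implementation of the step
#' semantics -- individuals held as plain R lists, no vectorization, no
#' shared code with the engine backends -- used to validate
#' [run_simulation()] event-for-event on small instances. It consumes the
#' RNG stream in the same documented order as the engine (target draw, kill
#' draw, parent draw(s), allele-pick draw(s); swap-remove on predation
#' kills, stable filter on the age cap, newborns appended), so under a
#' shared seed the attack log, birth log and final life-history table must
#' be identical to the engine's.
#'
#' @param config A [sim_config()] with `population_size <= 200` (speed
#'   guard; the oracle is intentionally slow).
#' @param seed Integer seed.
#' @return A list: `attacks` (step, target_id, escaped), `births` (step,
#'   child_id, parent ids), `n_alleles` per-step counts, and `individuals`
#'   (same columns as the engine's life-history log).
#' @export
oracle_run <- function(config, seed) {
  validate_config(config)
  if (config$population_size > 200)
    stop("oracle_run is a validation tool; population_size must be <= 200",
         call. = FALSE)
  set.seed(as.integer(seed))
  N <- config$population_size
  A <- config$n_initial_alleles
  sexual <- config$reproduction_mode != "haploid_asexual"
  diploid <- config$reproduction_mode == "diploid_sexual"

  draw <- function(n) {
    j <- floor(runif(1) * n) + 1
    if (j > n) n else as.integer(j)
  }
  upd <- function(p) {
    q <- if (config$learning_mode == "accelerating")
      p * (1 + config$learning_rate)
    else p + config$learning_rate * (config$escape_cap - p)
    min(q, config$escape_cap)
  }

  make_ind <- function(id, alleles, birth) {
    list(id = id, alleles = alleles, esc = config$initial_escape,
         age = 0L, birth = birth, death = NA_integer_, cause = 0L,
         flag = FALSE, off_n = 0L, off_sum = 0)
  }

  pop <- vector("list", N)
  for (i in seq_len(N)) {
    if (config$init_allele_scheme == "balanced") {
      l1 <- (i - 1L) %/% (N %/% A)
      al <- if (diploid) c(l1, l1) else l1
    } else {
      l1 <- draw(A) - 1L
      al <- if (diploid) c(l1, draw(A) - 1L) else l1
    }
    pop[[i]] <- make_ind(i, al, 0L)
  }
  graveyard <- list()
  next_id <- N + 1L
  at_step <- c(); at_id <- c(); at_esc <- c()
  bi_step <- c(); bi_child <- c(); bi_p1 <- c(); bi_p2 <- c()
  n_alleles <- integer(config$n_steps)

  for (t in seq_len(config$n_steps)) {
    # age-cap mortality (stable filter)
    if (!is.infinite(config$max_age)) {
      keep <- list()
      for (ind in pop) {
        if (ind$age > config$max_age) {
          ind$death <- t; ind$cause <- 2L
          graveyard[[length(graveyard) + 1L]] <- ind
        } else keep[[length(keep) + 1L]] <- ind
      }
      pop <- keep
      need <- if (sexual) 2L else 1L
      if (length(pop) - config$n_removed < need)
        stop(sprintf("step %d: age cap leaves %d alive; quota %d leaves fewer than the %d survivor(s) reproduction requires",
                     t, length(pop), config$n_removed, need), call. = FALSE)
    }
    # predation
    killed <- 0L
    while (killed < config$n_removed) {
      j <- draw(length(pop))
      ind <- pop[[j]]
      dead <- runif(1) < 1 - ind$esc
      at_step <- c(at_step, t); at_id <- c(at_id, ind$id)
      at_esc <- c(at_esc, as.integer(!dead))
      if (dead) {
        ind$death <- t; ind$cause <- 1L
        graveyard[[length(graveyard) + 1L]] <- ind
        pop[[j]] <- pop[[length(pop)]]      # swap-remove
        pop[[length(pop)]] <- NULL
        killed <- killed + 1L
      } else {
        if (config$learning_enabled) {
          if (config$learning_timing == "immediate") ind$esc <- upd(ind$esc)
          else ind$flag <- TRUE
        }
        pop[[j]] <- ind
      }
    }
    # step-end learning
    if (config$learning_enabled && config$learning_timing == "step_end") {
      for (k in seq_along(pop)) {
        if (pop[[k]]$flag) {
          pop[[k]]$esc <- upd(pop[[k]]$esc)
          pop[[k]]$flag <- FALSE
        }
      }
    }
    # reproduction
    n_surv <- length(pop)
    for (b in seq_len(N - n_surv)) {
      if (!sexual) {
        j1 <- draw(n_surv); j2 <- NA_integer_
        al <- pop[[j1]]$alleles
      } else {
        j1 <- draw(n_surv)
        j2 <- draw(n_surv - 1L)
        if (j2 >= j1) j2 <- j2 + 1L
        pa <- pop[[j1]]$alleles; pb <- pop[[j2]]$alleles
        if (!diploid) {
          al <- if (runif(1) < 0.5) pa[1] else pb[1]
        } else {
          al <- c(if (runif(1) < 0.5) pa[1] else pa[2],
                  if (runif(1) < 0.5) pb[1] else pb[2])
        }
      }
      child <- make_ind(next_id, al, t)
      next_id <- next_id + 1L
      bi_step <- c(bi_step, t); bi_child <- c(bi_child, child$id)
      bi_p1 <- c(bi_p1, pop[[j1]]$id)
      bi_p2 <- c(bi_p2, if (sexual) pop[[j2]]$id else NA_integer_)
      pop[[j1]]$off_n <- pop[[j1]]$off_n + 1L
      pop[[j1]]$off_sum <- pop[[j1]]$off_sum + (t - pop[[j1]]$birth)
      if (sexual) {
        pop[[j2]]$off_n <- pop[[j2]]$off_n + 1L
        pop[[j2]]$off_sum <- pop[[j2]]$off_sum + (t - pop[[j2]]$birth)
      }
      pop[[length(pop) + 1L]] <- child
    }
    labs <- unlist(lapply(pop, function(i) i$alleles))
    n_alleles[t] <- length(unique(labs))
    # age increment
    for (k in seq_along(pop))
      if (pop[[k]]$birth < t) pop[[k]]$age <- pop[[k]]$age + 1L
  }

  everyone <- c(graveyard, pop)
  everyone <- everyone[order(vapply(everyone, `[[`, integer(1), "id"))]
  individuals <- data.frame(
    id = vapply(everyone, `[[`, integer(1), "id"),
    birth_step = vapply(everyone, `[[`, integer(1), "birth"),
    death_step = vapply(everyone, `[[`, integer(1), "death"),
    cause = vapply(everyone, `[[`, integer(1), "cause"),
    allele1 = vapply(everyone, function(i) as.integer(i$alleles[1]), integer(1)),
    allele2 = vapply(everyone, function(i)
      if (diploid) as.integer(i$alleles[2]) else NA_integer_, integer(1)),
    n_offspring = vapply(everyone, `[[`, integer(1), "off_n"),
    offspring_age_sum = vapply(everyone, `[[`, numeric(1), "off_sum"),
    escape_prob = vapply(everyone, `[[`, numeric(1), "esc"),
    age = vapply(everyone, `[[`, integer(1), "age"))
  list(
    attacks = data.frame(step = at_step, target_id = at_id, escaped = at_esc),
    births = data.frame(step = bi_step, child_id = bi_child,
                        parent1_id = bi_p1, parent2_id = bi_p2),
    n_alleles = n_alleles,
    individuals = individuals)
}

#' Closed-form baselines for non-learning runs
#'
#' Analytic expectations used as independent test oracles against the
#' simulation. With the kill quota and uniform targeting, and no learning
#' or age cap, each living individual dies in a step with marginal
#' probability `p = n_removed / population_size`, so lifespans (in
#' completed steps) are geometric with mean `1/p` and SD `sqrt(1-p)/p`.
#' Under uniform-random initialization the expected number of distinct
#' alleles at step 0 is the classical occupancy value
#' `A * (1 - (1 - 1/A)^slots)` with one slot per haploid individual and two
#' per diploid.
#'
#' @param config A non-learning [sim_config()] without an age cap.
#' @return A list: `death_prob`, `lifespan_mean`, `lifespan_sd`,
#'   `expected_initial_alleles`.
#' @export
closed_form_baselines <- function(config) {
  validate_config(config)
  if (config$learning_enabled)
    stop("closed-form baselines hold only for non-learning configurations",
         call. = FALSE)
  if (!is.infinite(config$max_age))
    stop("closed-form baselines assume no age cap", call. = FALSE)
  p <- config$n_removed / config$population_size
  A <- config$n_initial_alleles
  slots <- config$population_size *
    (1L + (config$reproduction_mode == "diploid_sexual"))
  list(death_prob = p,
       lifespan_mean = 1 / p,
       lifespan_sd = sqrt(1 - p) / p,
       expected_initial_alleles = A * (1 - (1 - 1 / A)^slots))
}
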