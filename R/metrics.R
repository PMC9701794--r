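as_individuals <- function(x) {
  if (inherits(x, "drift_sim")) return(x$individuals)
  if (is.data.frame(x)) return(x)
  if (is.list(x)) {
    # a list of runs or of individual tables: pool them
    return(do.call(rbind, lapply(x, as_individuals)))
  }
  stop("expected a drift_sim, an individuals data.frame, or a list of them",
       call. = FALSE)
}

#' Count distinct alleles in a living population
#'
#' Number of distinct allele labels present over all allele slots of the
#' living individuals. With no mutation or migration this count can only
#' decrease over a run, down to fixation at 1.
#'
#' @param pop A `population_state` from [init_population()].
#' @return Integer count.
#' @export
count_distinct_alleles <- function(pop) {
  stopifnot(inherits(pop, "population_state"), length(pop$alive) > 0)
  labs <- pop$tab$allele1[pop$alive]
  a2 <- pop$tab$allele2[pop$alive]
  length(unique(c(labs, a2[!is.na(a2)])))
}

#' Age distribution of the living population
#'
#' Histogram of ages (bin width one step) either of a `population_state` or
#' of a [run_simulation()] result at a given recorded step. Ages are
#' recorded at the metrics stage of each step -- after reproduction, before
#' the age increment -- so newborns appear at age 0 and the counts sum to
#' `population_size`.
#'
#' @param x A `population_state` or `drift_sim`.
#' @param step For a `drift_sim`, which recorded step (default: last).
#' @return A data.frame with columns `age` and `count` (zero-count ages
#'   beyond the oldest individual are dropped).
#' @export
age_distribution <- function(x, step = NULL) {
  if (inherits(x, "population_state")) {
    ages <- x$tab$age[x$alive]
    counts <- tabulate(ages + 1L, nbins = max(ages) + 1L)
  } else if (inherits(x, "drift_sim")) {
    if (is.null(step)) step <- nrow(x$trajectory)
    counts <- x$age_hist[step, ]
  } else stop("expected a population_state or drift_sim", call. = FALSE)
  keep <- seq_len(max(which(counts > 0L)))
  data.frame(age = keep - 1L, count = as.integer(counts[keep]))
}

#' Lifespan mean and SD
#'
#' Pooled lifespan statistics from one or several runs' life-history logs.
#' The lifespan convention is completed steps survived after birth: an
#' individual dying in the k-th step after the step of its birth has
#' lifespan k, so under pure quota predation (no learning, no age cap) the
#' lifespan is geometric with success probability `n_removed /
#' population_size` and mean `population_size / n_removed`. Individuals
#' still alive at the end of a run are censored and excluded by default;
#' with `include_censored = TRUE` their current (incomplete) lifespan
#' `end_step - birth_step` enters the pool.
#'
#' @param x A `drift_sim`, an individuals data.frame, or a list of either
#'   (pooled, as when summarizing replicates).
#' @param include_censored Include still-alive individuals at their current
#'   lifespan.
#' @param end_step Final step index, needed only when `include_censored` and
#'   `x` is a bare data.frame (inferred from a `drift_sim`).
#' @return A list with `mean`, `sd` and `n`.
#' @export
lifespan_stats <- function(x, include_censored = FALSE, end_step = NULL) {
  if (inherits(x, "drift_sim") && is.null(end_step))
    end_step <- nrow(x$trajectory)
  ind <- as_individuals(x)
  if (nrow(ind) == 0) stop("empty life-history log", call. = FALSE)
  dead <- !is.na(ind$death_step)
  spans <- ind$death_step[dead] - ind$birth_step[dead]
  if (include_censored) {
    if (is.null(end_step))
      stop("include_censored needs end_step for a bare individuals table",
           call. = FALSE)
    spans <- c(spans, end_step - ind$birth_step[!dead])
  }
  if (length(spans) == 0) stop("no completed lifespans in log", call. = FALSE)
  list(mean = mean(spans), sd = if (length(spans) > 1) sd(spans) else NA_real_,
       n = length(spans))
}

#' Mean generation time
#'
#' Generation time is the mean age of a parent at the births of its
#' offspring, computed per individual (the summed parental ages at each
#' offspring birth divided by that individual's offspring count) and then
#' averaged, unweighted, over individuals. Individuals with no offspring
#' are excluded (the per-individual ratio is undefined for them). In sexual
#' modes every birth credits both parents at their respective ages.
#'
#' An individual's generation time is settled at its death, so individuals
#' still alive at the end of the run are excluded by default; this matters
#' in learning scenarios, where the censored individuals are
#' disproportionately the long-lived learners. Set `include_censored = TRUE`
#' to average over every reproducer regardless.
#'
#' @param x A `drift_sim`, an individuals data.frame, or a list of either
#'   (pooled over replicates).
#' @param include_censored Also include reproducers still alive at the end
#'   of the run.
#' @return Mean generation time in steps.
#' @export
generation_time <- function(x, include_censored = FALSE) {
  ind <- as_individuals(x)
  rep_ <- ind$n_offspring > 0L
  if (!include_censored) rep_ <- rep_ & !is.na(ind$death_step)
  if (!any(rep_)) stop("no individual reproduced; generation time undefined",
                       call. = FALSE)
  mean(ind$offspring_age_sum[rep_] / ind$n_offspring[rep_])
}
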