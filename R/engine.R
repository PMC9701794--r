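#' Run one simulation
#'
#' Executes a full forward-time run of the predator-prey model. Each time
#' step applies, in order: (1) age-cap mortality, (2) predation until the
#' kill quota `n_removed` is met, (3) the end-of-step learning update when
#' configured, (4) reproduction restoring the population to
#' `population_size`, (5) metric recording, (6) the age increment (newborns
#' stay at age 0 through their birth step).
#'
#' Given the same `(config, seed)` the run is fully deterministic, and the
#' compiled backend (`engine = "cpp"`, the default) and the pure-R backend
#' (`engine = "r"`) consume the RNG stream in an identical documented order,
#' so under a shared seed they produce identical event streams, life
#' histories and integer records (floating-point summary columns agree to
#' numerical precision; their summation order may differ). The R backend
#' exists for transparency and validation; the compiled one is the fast path
#' used by experiments.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; defaults to `config$seed`, which must then be
#'   non-`NULL`.
#' @param engine `"cpp"` or `"r"`.
#' @param log_events Record every attack and birth (memory-heavy; intended
#'   for small validation runs).
#' @return A `drift_sim` object: `trajectory` (one row per step: distinct
#'   alleles, deaths by cause, attack count, mean escape probability),
#'   `individuals` (the life-history log of every individual ever alive:
#'   birth/death steps, death cause -- 0 censored, 1 predation, 2 age cap --
#'   alleles, offspring count and summed parental ages at offspring births),
#'   `age_hist` (steps x ages occupancy matrix), `spectrum` (steps x alleles
#'   copy-number matrix), and, with `log_events`, `attacks` and `births`
#'   event tables.
#' @examples
#' cfg <- sim_config(population_size = 60, n_initial_alleles = 12,
#'                   n_removed = 30, n_steps = 15)
#' sim <- run_simulation(cfg, seed = 1)
#' sim$trajectory$n_alleles
#' @export
run_simulation <- function(config, seed = config$seed,
                           engine = c("cpp", "r"), log_events = FALSE) {
  validate_config(config)
  engine <- match.arg(engine)
  if (is.null(seed)) stop("no seed: set config$seed or pass seed=", call. = FALSE)
  set.seed(as.integer(seed))
  raw <- if (engine == "cpp") {
    sim_run_cpp(
      config$population_size, config$n_initial_alleles, config$n_steps,
      config$n_removed, config$initial_escape, config$escape_cap,
      config$learning_enabled,
      match(config$learning_mode, c("accelerating", "decelerating")) - 1L,
      match(config$learning_timing, c("step_end", "immediate")) - 1L,
      config$learning_rate,
      match(config$reproduction_mode,
            c("haploid_asexual", "haploid_sexual", "diploid_sexual")) - 1L,
      if (is.infinite(config$max_age)) -1L else config$max_age,
      config$init_allele_scheme == "balanced", log_events)
  } else {
    sim_run_r(config, log_events)
  }
  trajectory <- data.frame(
    step = seq_len(config$n_steps),
    n_alleles = raw$n_alleles,
    deaths_predation = raw$deaths_predation,
    deaths_agecap = raw$deaths_agecap,
    n_attacks = raw$n_attacks,
    mean_escape = raw$mean_escape)
  out <- list(config = config, seed = as.integer(seed), engine = engine,
              trajectory = trajectory, individuals = raw$individuals,
              age_hist = raw$age_hist, spectrum = raw$spectrum)
  if (log_events) {
    out$attacks <- raw$attacks
    out$births <- raw$births
  }
  class(out) <- "drift_sim"
  out
}

#' @export
print.drift_sim <- function(x, ...) {
  n <- nrow(x$trajectory)
  cat(sprintf("<drift_sim> %s, seed %d (%s backend)\n",
              x$config$reproduction_mode, x$seed, x$engine))
  cat(sprintf("  %d steps, N = %d, quota %d/step, learning %s\n",
              n, x$config$population_size, x$config$n_removed,
              if (x$config$learning_enabled)
                paste0("on (", x$config$learning_mode, ", ",
                       x$config$learning_timing, ", rate ",
                       x$config$learning_rate, ")") else "off"))
  cat(sprintf("  distinct alleles: %d at step 1 -> %d at step %d\n",
              x$trajectory$n_alleles[1], x$trajectory$n_alleles[n], n))
  invisible(x)
}

# Pure-R backend: composes the exported per-step operators.
sim_run_r <- function(config, log_events = FALSE) {
  pop <- init_population(config)
  n_steps <- config$n_steps
  A <- config$n_initial_alleles
  diploid <- config$reproduction_mode == "diploid_sexual"
  n_alleles <- integer(n_steps); dpred <- integer(n_steps)
  dage <- integer(n_steps); attacks <- integer(n_steps)
  mean_esc <- numeric(n_steps)
  age_hist <- matrix(0L, n_steps, n_steps + 1L)
  spectrum <- matrix(0L, n_steps, A)
  for (t in seq_len(n_steps)) {
    pop <- age_cap_mortality(pop, config, step = t)
    pop <- predation_step(pop, config, step = t, log_events = log_events)
    pop <- apply_step_end_learning(pop, config)
    pop <- reproduce(pop, config, step = t, log_events = log_events)
    ids <- pop$alive
    labs <- pop$tab$allele1[ids]
    if (diploid) labs <- c(labs, pop$tab$allele2[ids])
    spectrum[t, ] <- tabulate(labs + 1L, nbins = A)
    n_alleles[t] <- sum(spectrum[t, ] > 0L)
    dpred[t] <- pop$last$n_killed
    dage[t] <- pop$last$deaths_agecap
    attacks[t] <- pop$last$n_attacks
    mean_esc[t] <- mean(pop$tab$escape_prob[ids])
    h <- tabulate(pop$tab$age[ids] + 1L, nbins = n_steps + 1L)
    age_hist[t, ] <- h
    grown <- ids[pop$tab$birth_step[ids] < t]
    pop$tab$age[grown] <- pop$tab$age[grown] + 1L
    pop$step <- t
  }
  ind <- as.data.frame(pop$tab[c("birth_step", "death_step", "cause",
                                 "allele1", "allele2", "n_offspring",
                                 "offspring_age_sum", "escape_prob", "age")])
  ind <- cbind(id = seq_len(nrow(ind)), ind)
  out <- list(n_alleles = n_alleles, deaths_predation = dpred,
              deaths_agecap = dage, n_attacks = attacks,
              mean_escape = mean_esc, age_hist = age_hist,
              spectrum = spectrum, individuals = ind)
  if (log_events) {
    out$attacks <- do.call(rbind, pop$events$attacks)
    out$births <- do.call(rbind, pop$events$births)
  }
  out
}
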