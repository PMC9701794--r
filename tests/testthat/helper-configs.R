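# Small configurations used across the suite; fixtures are always built in
# code, never stored.

small_cfg <- function(...) {
  sim_config(population_size = 30L, n_initial_alleles = 6L, n_removed = 12L,
             n_steps = 6L, ...)
}

# A random valid small configuration spanning every mode, timing and
# reproduction scheme; used for engine/oracle equivalence sweeps.
random_small_cfg <- function() {
  repro <- sample(c("haploid_asexual", "haploid_sexual", "diploid_sexual"), 1)
  need <- if (repro == "haploid_asexual") 1L else 2L
  N <- sample(6:40, 1)
  d <- sample(seq_len(N - need - 1L), 1)
  cap <- runif(1, 0.9, 0.99)
  sim_config(
    population_size = N,
    n_initial_alleles = sample(2:min(N, 10), 1),
    n_steps = sample(3:6, 1),
    n_removed = d,
    initial_escape = runif(1, 0.3, min(0.6, cap)),
    escape_cap = cap,
    learning_enabled = runif(1) < 0.7,
    learning_mode = sample(c("accelerating", "decelerating"), 1),
    learning_timing = sample(c("step_end", "immediate"), 1),
    learning_rate = runif(1, 0, 0.3),
    reproduction_mode = repro,
    max_age = if (runif(1) < 0.3) sample(3:8, 1) else Inf,
    init_allele_scheme = "uniform_random")
}

# Build a population_state by hand (test harness for the step operators).
manual_pop <- function(allele1, allele2 = rep(NA_integer_, length(allele1)),
                       escape = 0.5, age = 0L) {
  n <- length(allele1)
  pop <- list(
    tab = list(
      birth_step = rep(0L, n), death_step = rep(NA_integer_, n),
      cause = rep(0L, n), allele1 = as.integer(allele1),
      allele2 = as.integer(allele2),
      n_offspring = rep(0L, n), offspring_age_sum = rep(0, n),
      escape_prob = rep(escape, length.out = n),
      age = rep(as.integer(age), length.out = n),
      survived_flag = rep(FALSE, n)),
    alive = seq_len(n), step = 0L, last = list(),
    events = list(attacks = list(), births = list()))
  class(pop) <- "population_state"
  pop
}
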