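test_that("distinct-allele counting covers haploid and diploid slots", {
  set.seed(1)
  pop <- init_population(sim_config(init_allele_scheme = "balanced"))
  expect_equal(count_distinct_alleles(pop), 100L)
  expect_equal(count_distinct_alleles(manual_pop(rep(3L, 5))), 1L)
  # diploid genotypes {(A,B),(B,C)} carry three distinct alleles
  expect_equal(count_distinct_alleles(
    manual_pop(allele1 = c(0L, 1L), allele2 = c(1L, 2L))), 3L)
})

test_that("age distributions sum to the population and decay geometrically", {
  set.seed(1)
  pop <- init_population(small_cfg())
  h <- age_distribution(pop)
  expect_equal(h$count, 30L)            # all mass at age 0 at initialization
  expect_equal(h$age, 0L)

  # stationary non-learning distribution at d/N = 0.5: adjacent-bin ratio 1/2
  # (the age-0 bin also holds the previous step's surviving newborns, since
  # ages are recorded before the increment, so the decay starts at age 1)
  cfg <- sim_config(population_size = 1000L, n_initial_alleles = 10L,
                    n_steps = 250L)
  sim <- run_simulation(cfg, seed = 77)
  late <- colMeans(sim$age_hist[101:250, 2:6])
  ratios <- late[-1] / late[-5]
  expect_true(all(abs(ratios - 0.5) < 0.06))
  expect_equal(sum(age_distribution(sim, step = 250)$count), 1000L)
})

test_that("learning shifts mass into the old-age tail", {
  old_mass <- function(learning, seeds) {
    vapply(seeds, function(s) {
      cfg <- sim_config(learning_enabled = learning, learning_rate = 0.2)
      sim <- run_simulation(cfg, seed = s)
      sum(sim$age_hist[100, 7:101]) # individuals older than 5 at the end
    }, numeric(1))
  }
  expect_gt(mean(old_mass(TRUE, 1:5)), mean(old_mass(FALSE, 6:10)))
})

test_that("lifespan statistics follow the completed-steps convention", {
  log <- data.frame(birth_step = c(0L, 3L, 9L), death_step = c(2L, 7L, NA),
                    cause = c(1L, 1L, 0L))
  ls <- lifespan_stats(log)
  expect_equal(ls$mean, 3)              # deaths at ages 2 and 4
  expect_equal(ls$sd, sd(c(2, 4)))
  expect_equal(ls$n, 2L)
  # censored individuals enter at their current age only on request
  ls2 <- lifespan_stats(log, include_censored = TRUE, end_step = 10L)
  expect_equal(ls2$n, 3L)
  expect_equal(ls2$mean, mean(c(2, 4, 1)))
  expect_error(lifespan_stats(log[0, ]), "empty")
})

test_that("generation time averages per-individual parental ages", {
  log <- data.frame(birth_step = c(0L, 0L), death_step = c(8L, 9L),
                    cause = c(1L, 1L), n_offspring = c(2L, 0L),
                    offspring_age_sum = c(2 + 5, 0))
  expect_equal(generation_time(log), 3.5)  # offspring at ages 2 and 5
  log2 <- data.frame(birth_step = 0L, death_step = c(5L, 6L), cause = 1L,
                     n_offspring = c(1L, 2L), offspring_age_sum = c(2, 8))
  expect_equal(generation_time(log2), 3)   # unweighted mean of 2.0 and 4.0
  # censored reproducers excluded by default, included on request
  log3 <- rbind(log2, data.frame(birth_step = 0L, death_step = NA,
                                 cause = 0L, n_offspring = 1L,
                                 offspring_age_sum = 10))
  expect_equal(generation_time(log3), 3)
  expect_equal(generation_time(log3, include_censored = TRUE), mean(c(2, 4, 10)))
  log0 <- data.frame(birth_step = 0L, death_step = 2L, cause = 1L,
                     n_offspring = 0L, offspring_age_sum = 0)
  expect_error(generation_time(log0), "no individual reproduced")
})

test_that("life-history summaries match a naive pass over the raw event log", {
  cfg <- sim_config(population_size = 60L, n_initial_alleles = 10L,
                    n_removed = 25L, n_steps = 12L, learning_enabled = TRUE,
                    reproduction_mode = "haploid_sexual")
  sim <- run_simulation(cfg, seed = 13, log_events = TRUE)
  ind <- sim$individuals

  # rebuild per-individual offspring ages purely from the birth events
  sums <- setNames(rep(0, nrow(ind)), ind$id)
  counts <- setNames(rep(0L, nrow(ind)), ind$id)
  for (k in seq_len(nrow(sim$births))) {
    for (p in c(sim$births$parent1_id[k], sim$births$parent2_id[k])) {
      if (is.na(p)) next
      counts[p] <- counts[p] + 1L
      sums[p] <- sums[p] + sim$births$step[k] - ind$birth_step[p]
    }
  }
  expect_equal(unname(counts), ind$n_offspring)
  expect_equal(unname(sums), ind$offspring_age_sum)

  keep <- counts > 0 & !is.na(ind$death_step)
  naive_gt <- mean(sums[keep] / counts[keep])
  expect_equal(generation_time(sim), naive_gt)

  dead <- !is.na(ind$death_step)
  expect_equal(lifespan_stats(sim)$mean,
               mean(ind$death_step[dead] - ind$birth_step[dead]))
  # every offspring age is non-negative and within its parent's lifespan
  span <- ind$death_step - ind$birth_step
  rep_dead <- dead & ind$n_offspring > 0
  expect_true(all(ind$offspring_age_sum[rep_dead] <=
                    ind$n_offspring[rep_dead] * span[rep_dead]))
  expect_true(all(ind$offspring_age_sum >= 0))
})
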