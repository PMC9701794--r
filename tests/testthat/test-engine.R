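test_that("initialization honors the allele assignment schemes", {
  cfg <- sim_config(init_allele_scheme = "balanced")
  set.seed(1)
  pop <- init_population(cfg)
  counts <- table(pop$tab$allele1)
  expect_length(counts, 100)
  expect_true(all(counts == 10))
  expect_true(all(pop$tab$escape_prob == 0.5))
  expect_true(all(pop$tab$age == 0L))

  # one individual cannot survive a kill quota of 1
  expect_error(sim_config(population_size = 1L, n_initial_alleles = 1L,
                          n_removed = 1L), "survivor")
  tiny2 <- sim_config(population_size = 2L, n_initial_alleles = 1L,
                      n_removed = 1L)
  pop2 <- init_population(tiny2)
  expect_equal(pop2$tab$allele1, c(0L, 0L))
  expect_equal(pop2$tab$escape_prob, c(0.5, 0.5))
})

test_that("uniform-random initialization matches the occupancy closed form", {
  cfg <- sim_config(population_size = 200L, n_initial_alleles = 50L,
                    n_removed = 50L)
  expected <- closed_form_baselines(cfg)$expected_initial_alleles
  set.seed(99)
  distinct <- replicate(300, {
    pop <- init_population(cfg)
    count_distinct_alleles(pop)
  })
  se <- sd(distinct) / sqrt(length(distinct))
  expect_lt(abs(mean(distinct) - expected), 3 * se + 1e-9)
})

test_that("predation kills exactly the quota and leaves survivors targetable", {
  cfg <- small_cfg(learning_enabled = TRUE, learning_timing = "immediate")
  for (seed in 1:5) {
    sim <- run_simulation(cfg, seed = seed)
    expect_true(all(sim$trajectory$deaths_predation == cfg$n_removed))
    expect_true(all(sim$trajectory$n_attacks >= cfg$n_removed))
  }
  # d = 0 at the engine level: nothing happens
  cfg0 <- small_cfg()
  cfg0$n_removed <- 0L                  # below the config-level floor on purpose
  set.seed(3)
  pop <- init_population(small_cfg())
  out <- predation_step(pop, cfg0)
  expect_equal(out$last$n_attacks, 0L)
  expect_equal(out$last$n_killed, 0L)
  expect_equal(length(out$alive), 30L)

  # all escape probabilities forced to 0: every attack succeeds
  pop <- init_population(small_cfg())
  pop$tab$escape_prob[] <- 0
  out <- predation_step(pop, small_cfg())
  expect_equal(out$last$n_attacks, out$last$n_killed)
})

test_that("attack counts match the escape-probability expectation", {
  # each attack kills w.p. 1 - 0.5, so E[attacks per step] = 2 * quota
  cfg <- sim_config(n_steps = 300L)
  sim <- run_simulation(cfg, seed = 8)
  att <- sim$trajectory$n_attacks
  se <- sd(att) / sqrt(length(att))
  expect_lt(abs(mean(att) - 2 * cfg$n_removed), 3 * se)
})

test_that("population size is restored after every full step", {
  for (cfg in list(small_cfg(),
                   small_cfg(reproduction_mode = "diploid_sexual",
                             learning_enabled = TRUE),
                   small_cfg(max_age = 3L, learning_enabled = TRUE))) {
    sim <- run_simulation(cfg, seed = 4)
    expect_true(all(rowSums(sim$age_hist) == cfg$population_size))
    slots <- cfg$population_size *
      (1L + (cfg$reproduction_mode == "diploid_sexual"))
    expect_true(all(rowSums(sim$spectrum) == slots))
  }
})

test_that("escape probabilities stay confined and reset at birth", {
  cfg <- sim_config(population_size = 200L, n_initial_alleles = 20L,
                    n_removed = 100L, n_steps = 30L,
                    learning_enabled = TRUE, learning_rate = 0.2)
  sim <- run_simulation(cfg, seed = 5)
  expect_true(all(sim$individuals$escape_prob >= cfg$initial_escape))
  expect_true(all(sim$individuals$escape_prob <= cfg$escape_cap))
  # newborns of the final step have had no chance to learn: exactly initial
  last_born <- sim$individuals$birth_step == cfg$n_steps
  expect_true(any(last_born))
  expect_true(all(sim$individuals$escape_prob[last_born] == cfg$initial_escape))
  # without learning nothing ever moves
  cfg$learning_enabled <- FALSE
  sim0 <- run_simulation(cfg, seed = 5)
  expect_true(all(sim0$individuals$escape_prob == cfg$initial_escape))
  expect_true(all(sim0$trajectory$mean_escape == cfg$initial_escape))
})

test_that("distinct-allele counts never increase and never hit zero", {
  for (seed in 1:3) {
    cfg <- sim_config(population_size = 100L, n_initial_alleles = 10L,
                      n_removed = 60L, n_steps = 80L,
                      learning_enabled = seed %% 2 == 0)
    sim <- run_simulation(cfg, seed = seed)
    expect_true(all(diff(sim$trajectory$n_alleles) <= 0))
    expect_true(all(sim$trajectory$n_alleles >= 1))
  }
})

test_that("zero-rate learning reproduces the non-learning run bit-for-bit", {
  for (engine in c("cpp", "r")) {
    cfg_l <- small_cfg(learning_enabled = TRUE, learning_rate = 0)
    cfg_n <- small_cfg(learning_enabled = FALSE)
    a <- run_simulation(cfg_l, seed = 11, engine = engine)
    b <- run_simulation(cfg_n, seed = 11, engine = engine)
    expect_identical(a$trajectory, b$trajectory)
    expect_identical(a$individuals, b$individuals)
  }
})

test_that("the age cap removes exactly the over-age individuals", {
  cfg <- sim_config(population_size = 6L, n_initial_alleles = 6L,
                    n_removed = 2L, max_age = 2L)
  pop <- manual_pop(allele1 = 0:5, age = c(0L, 1L, 2L, 3L, 4L, 0L))
  out <- age_cap_mortality(pop, cfg, step = 1L)
  expect_equal(out$last$deaths_agecap, 2L)
  expect_equal(sort(out$last$agecap_ids), c(4L, 5L))
  expect_equal(out$alive, c(1L, 2L, 3L, 6L))   # stable order
  expect_equal(out$tab$cause[4:5], c(2L, 2L))

  # unbounded age: no-op
  out2 <- age_cap_mortality(pop, small_cfg())
  expect_equal(out2$last$deaths_agecap, 0L)
  expect_equal(length(out2$alive), 6L)

  # in a full run with a cap, no living individual ever exceeds it
  cfg3 <- sim_config(population_size = 200L, n_initial_alleles = 20L,
                     n_removed = 60L, n_steps = 40L, max_age = 5L,
                     learning_enabled = TRUE)
  sim <- run_simulation(cfg3, seed = 2)
  expect_true(any(sim$trajectory$deaths_agecap > 0))
  over_cap_cols <- (5 + 2):ncol(sim$age_hist)
  expect_true(all(sim$age_hist[, over_cap_cols] == 0))
  # age-cap deaths are on top of the quota, never counted toward it
  expect_true(all(sim$trajectory$deaths_predation == 60L))
})

test_that("degenerate states abort with a diagnostic instead of padding", {
  cfg <- small_cfg(reproduction_mode = "haploid_sexual")
  pop <- manual_pop(allele1 = 0:5)
  pop$alive <- 1L                        # a single survivor cannot pair
  expect_error(reproduce(pop, cfg, n_births = 2L), "cannot reproduce")

  cfg2 <- small_cfg(max_age = 2L)
  pop2 <- manual_pop(allele1 = rep(0L, 30), age = 5L)
  expect_error(age_cap_mortality(pop2, cfg2), "fewer than")

  # a lone fast-learning survivor eventually outlives the cap, and its cull
  # leaves fewer survivors than the quota requires
  cfg3 <- sim_config(population_size = 20L, n_initial_alleles = 4L,
                     n_removed = 19L, n_steps = 30L, max_age = 2L,
                     learning_enabled = TRUE, learning_timing = "immediate",
                     learning_rate = 5)
  expect_error(run_simulation(cfg3, seed = 5), "fewer than")
})

test_that("offspring inherit alleles by the stated rules", {
  # asexual: exact copy of the single parent's allele
  cfg <- small_cfg()
  pop <- manual_pop(allele1 = rep(7L, 3))
  set.seed(2)
  out <- reproduce(pop, cfg, n_births = 5L)
  expect_equal(out$tab$allele1[4:8], rep(7L, 5))
  expect_equal(out$tab$escape_prob[4:8], rep(0.5, 5))

  # diploid cross (A,B) x (C,D): the four genotypes are equally likely
  cfgd <- sim_config(population_size = 10L, n_initial_alleles = 4L,
                     n_removed = 2L, reproduction_mode = "diploid_sexual")
  pop <- manual_pop(allele1 = c(0L, 2L), allele2 = c(1L, 3L))
  set.seed(42)
  out <- reproduce(pop, cfgd, n_births = 40000L)
  kids <- data.frame(a = out$tab$allele1[-(1:2)], b = out$tab$allele2[-(1:2)])
  # order within the genotype is parent-of-origin; collapse to sets
  geno <- paste(pmin(kids$a, kids$b), pmax(kids$a, kids$b))
  freq <- table(geno) / nrow(kids)
  expect_setequal(names(freq), c("0 2", "0 3", "1 2", "1 3"))
  # binomial SE for p = 1/4 at n = 40000 is ~0.0022
  expect_true(all(abs(freq - 0.25) < 4 * sqrt(0.25 * 0.75 / 40000)))
})

test_that("runs are deterministic given (config, seed)", {
  cfg <- small_cfg(learning_enabled = TRUE)
  a <- run_simulation(cfg, seed = 123)
  b <- run_simulation(cfg, seed = 123)
  expect_identical(a$trajectory, b$trajectory)
  expect_identical(a$individuals, b$individuals)
  c <- run_simulation(cfg, seed = 124)
  expect_false(identical(a$trajectory, c$trajectory))
})
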