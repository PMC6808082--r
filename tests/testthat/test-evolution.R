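test_that("unequal crossover redistributes but conserves units", {
  one <- repeat_array("full")
  out <- unequal_crossover(one, one, offset = 1, breakpoint = 0)
  expect_equal(n_units(out$expanded), 2L)
  expect_equal(n_units(out$contracted), 0L)

  three <- repeat_array(rep("full", 3))
  out3 <- unequal_crossover(three, three, offset = 1, breakpoint = 1)
  expect_equal(n_units(out3$expanded), 4L)
  expect_equal(n_units(out3$contracted), 2L)

  eq <- unequal_crossover(three, three, offset = 0, breakpoint = 2)
  expect_equal(n_units(eq$expanded), 3L)
  expect_equal(n_units(eq$contracted), 3L)

  expect_error(unequal_crossover(three, repeat_array("full"), offset = 2,
                                 breakpoint = 1), "negative")
  unflanked <- repeat_array("full", flanked = FALSE)
  expect_error(unequal_crossover(unflanked, one, 1, 0), "flanked")
})

test_that("random crossovers conserve total unit count, always", {
  set.seed(51)
  for (i in 1:500) {
    na <- sample(1:8, 1)
    nb <- sample(1:8, 1)
    a <- repeat_array(sample(c("full", "truncated"), na, replace = TRUE))
    b <- repeat_array(sample(c("full", "truncated"), nb, replace = TRUE))
    offset <- sample(0:nb, 1)
    bp <- sample(0:min(na, nb - offset), 1)
    out <- unequal_crossover(a, b, offset, bp)
    expect_identical(n_units(out$expanded) + n_units(out$contracted), na + nb)
    expect_identical(n_units(out$expanded), na + offset)
  }
})

test_that("microhomology truncation retypes one full unit in place", {
  arr <- repeat_array(c("full", "full"))
  out <- microhomology_truncation(arr, 2)
  expect_equal(out$units, c("full", "truncated"))
  expect_equal(n_units(out), 2L)
  expect_error(microhomology_truncation(repeat_array("truncated"), 1),
               "full-type")
  expect_error(microhomology_truncation(arr, 5), "range")
})

test_that("no events means a constant two copies per individual", {
  cfg <- evolution_config(population_size = 20, generations = 10,
                          crossover_rate = 0, truncation_rate = 0, seed = 2)
  sim <- simulate_generations(cfg)
  expect_false(sim$extinct)
  expect_true(all(sim$trajectory$mean_copies == 2))
  expect_true(all(sim$trajectory$var_copies == 0))
})

test_that("trajectories are reproducible and never keep double-null zygotes", {
  cfg <- evolution_config(population_size = 30, generations = 20,
                          crossover_rate = 0.2, truncation_rate = 0.01,
                          seed = 9)
  s1 <- simulate_generations(cfg)
  s2 <- simulate_generations(cfg)
  expect_identical(s1$trajectory, s2$trajectory)
  # min diploid total >= 1 in every generation: the null/null genotype dies
  expect_true(all(s1$trajectory$min_copies >= 1))
})

test_that("neutral gamete formation conserves the mean copy number", {
  # one generation from a homogeneous population: viability selection has
  # nothing to prune yet, so the post-generation mean is the parental mean
  finals <- vapply(1:50, function(s) {
    cfg <- evolution_config(population_size = 400, generations = 1,
                            crossover_rate = 0.05, truncation_rate = 0,
                            selection = NULL, seed = 1000 + s)
    tail(simulate_generations(cfg)$trajectory$mean_copies, 1)
  }, numeric(1))
  se <- stats::sd(finals) / sqrt(length(finals))
  expect_lt(abs(mean(finals) - 2), max(4 * se, 0.02))
})

test_that("null lethality prunes the lower tail without runaway drift", {
  # with flat fitness, exchange is conservative at meiosis, but removing
  # inviable null/null zygotes truncates the low-copy tail, so the long-run
  # mean creeps up slightly; it must neither decrease nor run away
  finals <- vapply(1:100, function(s) {
    cfg <- evolution_config(population_size = 20, generations = 10,
                            crossover_rate = 0.05, truncation_rate = 0,
                            selection = NULL, seed = 2000 + s)
    tail(simulate_generations(cfg)$trajectory$mean_copies, 1)
  }, numeric(1))
  expect_gt(mean(finals), 1.9)
  expect_lt(mean(finals), 2.6)
})

test_that("copy-number selection drives sustained expansion", {
  rising <- vapply(1:40, function(s) {
    cfg <- evolution_config(population_size = 30, generations = 50,
                            crossover_rate = 0.05, truncation_rate = 0.001,
                            selection = step_selection(3), seed = 3000 + s)
    tr <- simulate_generations(cfg)$trajectory
    tail(tr$mean_copies, 1) > tr$mean_copies[1]
  }, logical(1))
  expect_gte(mean(rising), 0.95)
})
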